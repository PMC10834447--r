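# Proteome-, panel-, and tree-level synthetic data.

# Approximate average plant proteome residue frequencies, used for inert
# background proteins.
PLANT_AA_FREQ <- c(
  A = 0.063, R = 0.054, N = 0.043, D = 0.053, C = 0.018,
  Q = 0.035, E = 0.063, G = 0.064, H = 0.023, I = 0.053,
  L = 0.095, K = 0.058, M = 0.024, F = 0.044, P = 0.048,
  S = 0.090, T = 0.051, W = 0.012, Y = 0.028, V = 0.068
)

background_is_inert <- function(sequence, config) {
  chars <- seq_chars(sequence)
  n <- length(chars)
  if (n >= config$tm_window) {
    wm <- window_means(hydropathy_of(chars), config$tm_window)
    if (any(wm >= config$tm_threshold - HYDROPATHY_EPS)) return(FALSE)
  }
  if (n >= 13L) {
    H <- chars %in% HYDROPHOBIC_CORE
    P <- chars %in% POLAR_CORE
    m <- n - 12L
    if (any(H[1:m] & H[4:(m + 3L)] & H[6:(m + 5L)] & H[8:(m + 7L)] &
              P[11:(m + 10L)] & H[13:(m + 12L)])) return(FALSE)
  }
  if (!is.null(detect_kinase(sequence))) return(FALSE)
  TRUE
}

random_receptor_spec <- function(cls, seed) {
  has_id <- runif(1) < 0.7
  n2 <- sample(2:8, 1)
  n1 <- sample(1:6, 1)
  nl <- if (runif(1) < 0.3 && n1 >= 2L) sample(15:29, 1) else NULL
  receptor_spec(
    cls = cls,
    n_lrr_before_id = n1,
    id_length = if (has_id) sample(30:90, 1) else NULL,
    n_lrr_after_id = if (has_id) n2 else sample(0:4, 1),
    nl_length = nl,
    gxxxg_chain = if (cls == "ECTODOMAIN_ONLY") 0L else sample(0:3, 1),
    ejm_charge_target = if (cls == "RLP") sample(-6:-1, 1) else
      sample(0:6, 1),
    has_signal_peptide = runif(1) < 0.8,
    id_motif = if (has_id) sample(c("none", "kx5y", "yx8kg", "both"), 1)
      else "none",
    qxxts = sample(c("none", "qxxts", "tqxxx"), 1),
    seed = seed
  )
}

#' Generate a synthetic proteome with planted receptors
#'
#' Emits \code{n_proteins} sequences for one species: planted receptors per
#' class fraction (counts are \code{round(fraction * n_proteins)}) plus
#' inert background proteins drawn from typical plant-proteome residue
#' frequencies and rejection-sampled until they contain no TM window, LRR
#' core, or kinase landmark set.  Byte-for-byte reproducible from the seed.
#'
#' @param species_id Species identifier.
#' @param n_proteins Total number of proteins.
#' @param fractions Named numeric vector of planted class fractions, names
#'   among RLP, RLK, ECTODOMAIN_ONLY; must sum to at most 1.
#' @param seed Integer seed.
#' @param config Analysis configuration.
#' @param background_len Integer range (min, max) of background protein
#'   lengths.
#' @return List with \code{proteins} (data.frame id, species_id, sequence,
#'   length) and \code{truth} (data.frame id, class plus per-receptor
#'   truth list in the \code{receptor_truth} attribute).
#' @export
make_proteome <- function(species_id, n_proteins, fractions,
                          seed = 1L, config = analysis_config(),
                          background_len = c(150L, 600L)) {
  stopifnot(n_proteins >= 1L, all(fractions >= 0), sum(fractions) <= 1)
  bad <- setdiff(names(fractions), c("RLP", "RLK", "ECTODOMAIN_ONLY"))
  if (length(bad) > 0L) stop("unknown receptor class(es): ",
                             paste(bad, collapse = ", "))
  set.seed(seed)
  counts <- round(fractions * n_proteins)
  receptor_seeds <- sample.int(.Machine$integer.max, sum(counts))
  rows <- list(); truth_rows <- list(); receptor_truth <- list()
  k <- 0L
  for (cls in names(counts)) {
    for (i in seq_len(counts[[cls]])) {
      k <- k + 1L
      spec <- random_receptor_spec(cls, receptor_seeds[k])
      rec <- make_receptor(spec, config)
      id <- sprintf("%s_%s_%03d", species_id, tolower(cls), i)
      rows[[k]] <- data.frame(id = id, species_id = species_id,
                              sequence = rec$sequence,
                              length = nchar(rec$sequence),
                              stringsAsFactors = FALSE)
      truth_rows[[k]] <- data.frame(id = id, class = cls,
                                    stringsAsFactors = FALSE)
      receptor_truth[[id]] <- rec$truth
    }
  }
  n_bg <- n_proteins - sum(counts)
  bg_rows <- vector("list", n_bg)
  for (i in seq_len(n_bg)) {
    len <- sample(background_len[1]:background_len[2], 1)
    for (try in 1:500) {
      s <- paste(sample(names(PLANT_AA_FREQ), len, replace = TRUE,
                        prob = PLANT_AA_FREQ), collapse = "")
      if (background_is_inert(s, config)) break
      if (try == 500) stop("failed to draw an inert background protein")
    }
    id <- sprintf("%s_bg_%05d", species_id, i)
    bg_rows[[i]] <- data.frame(id = id, species_id = species_id,
                               sequence = s, length = len,
                               stringsAsFactors = FALSE)
  }
  proteins <- do.call(rbind, c(rows, bg_rows))
  rownames(proteins) <- NULL
  truth <- if (length(truth_rows) > 0L) do.call(rbind, truth_rows) else
    data.frame(id = character(0), class = character(0))
  attr(truth, "receptor_truth") <- receptor_truth
  attr(truth, "planted_counts") <- counts
  list(proteins = proteins, truth = truth)
}

#' Generate a lineage panel with planted family percentages
#'
#' Builds per-species gene-family count tables realizing planted family
#' percentages: each species' percentage is its lineage baseline times a
#' per-species deviation factor, rounded to an integer gene count out of
#' \code{n_searched}.  The ground truth records the realized (post-rounding)
#' percentages and the expansion rates implied by them for each
#' baseline-to-target lineage pair, computed with exact arithmetic.
#'
#' @param lineages Named list: lineage name to character vector of species
#'   ids, in phylogenetic order.
#' @param baseline_pct Matrix of baseline percentages, lineages in rows,
#'   families in columns.
#' @param factors Named list: species id to named numeric vector of
#'   per-family deviation factors (default 1 for all).
#' @param n_searched Searched-gene count per genome.
#' @param pairs List of c(baseline, target) lineage-name pairs for the
#'   truth expansion rates.
#' @return List with \code{counts} (data.frame species_id, lineage, family,
#'   count, n_searched), \code{realized_pct}, and \code{truth_rates}
#'   (data.frame pair, species_id, family, rate).
#' @export
make_lineage_panel <- function(lineages, baseline_pct, factors = list(),
                               n_searched = 20000L,
                               pairs = list()) {
  stopifnot(is.list(lineages), length(lineages) >= 1L)
  if (any(vapply(lineages, length, integer(1)) == 0L))
    stop("every lineage must contain at least one species")
  fams <- colnames(baseline_pct)
  rows <- list()
  for (lin in names(lineages)) {
    for (sp in lineages[[lin]]) {
      for (fam in fams) {
        f <- 1
        if (!is.null(factors[[sp]]) && !is.na(factors[[sp]][fam]))
          f <- factors[[sp]][[fam]]
        pct_target <- baseline_pct[lin, fam] * f
        count <- round(pct_target / 100 * n_searched)
        rows[[length(rows) + 1L]] <- data.frame(
          species_id = sp, lineage = lin, family = fam,
          count = as.integer(count), n_searched = as.integer(n_searched),
          stringsAsFactors = FALSE)
      }
    }
  }
  counts <- do.call(rbind, rows)
  rownames(counts) <- NULL
  counts$pct <- counts$count / counts$n_searched * 100
  truth <- list()
  for (pr in pairs) {
    base <- counts[counts$lineage == pr[1], , drop = FALSE]
    targ <- counts[counts$lineage == pr[2], , drop = FALSE]
    for (fam in fams) {
      med <- stats::median(base$pct[base$family == fam])
      t <- targ[targ$family == fam, , drop = FALSE]
      rate <- if (med > 0) (t$pct - med) / med else NA_real_
      truth[[length(truth) + 1L]] <- data.frame(
        baseline = pr[1], target = pr[2], species_id = t$species_id,
        family = fam, rate = rate, stringsAsFactors = FALSE)
    }
  }
  truth_rates <- if (length(truth) > 0L) do.call(rbind, truth) else NULL
  list(counts = counts[, c("species_id", "lineage", "family", "count",
                           "n_searched")],
       realized_pct = counts$pct, truth_rates = truth_rates)
}

#' Default lineage panel emulating an algae-to-land-plant survey
#'
#' Four lineages (glaucophyte/rhodophyte algae, green algae, bryophytes,
#' tracheophytes) with three families (LRR-RLK, LRR-RLP, NB-ARC), family
#' percentages rising toward land plants, and deviation factors chosen as
#' exact multiples so that rounding is lossless at 20,000 searched genes.
#'
#' @return Arguments for [make_lineage_panel()] as a list.
#' @export
default_panel_spec <- function() {
  lineages <- list(
    glauco_rhodo = paste0("gr", 1:6),
    green_algae = paste0("ga", 1:8),
    bryophytes = paste0("br", 1:6),
    tracheophytes = paste0("tr", 1:10)
  )
  fams <- c("LRR-RLK", "LRR-RLP", "NB-ARC")
  baseline_pct <- matrix(
    c(0.10, 0.10, 0.05,
      0.20, 0.15, 0.10,
      0.60, 0.30, 0.20,
      1.20, 0.50, 0.40),
    nrow = 4, byrow = TRUE,
    dimnames = list(names(lineages), fams))
  # deviation factors are restricted to halves (0.5, 1.5, 2.5, ...) so that
  # every baseline count (a multiple of 10 at 20,000 searched genes) times
  # its factor stays an integer and rounding is lossless
  fac <- c(0.5, 1, 1, 1.5, 2, 2.5, 3, 4, 1, 2)
  factors <- list()
  k <- 0L
  for (lin in names(lineages)) for (sp in lineages[[lin]]) {
    k <- k + 1L
    f <- fac[(k - 1L) %% length(fac) + 1L]
    factors[[sp]] <- stats::setNames(rep(f, length(fams)), fams)
  }
  list(lineages = lineages, baseline_pct = baseline_pct,
       factors = factors, n_searched = 20000L,
       pairs = list(c("glauco_rhodo", "green_algae"),
                    c("green_algae", "bryophytes"),
                    c("bryophytes", "tracheophytes")))
}

#' Generate a tree with planted leaf clusters
#'
#' Builds a newick tree whose cophenetic distances are below \code{cutoff}
#' within each planted cluster and at least \code{d_between} across
#' clusters, so that the threshold-network/Louvain pipeline recovers the
#' planted partition exactly.  Leaf branch lengths are jittered (seeded)
#' but bounded to preserve the distance constraints.
#'
#' @param k_clusters Number of clusters.
#' @param leaves_per_cluster Leaves per cluster.
#' @param d_within Maximum within-cluster cophenetic distance.
#' @param d_between Minimum between-cluster cophenetic distance.
#' @param cutoff The clustering cutoff the tree is built for (must satisfy
#'   d_within < cutoff <= d_between).
#' @param seed Integer seed.
#' @return List with \code{newick} (string), \code{tree} (phylo), and
#'   \code{partition} (data.frame leaf, cluster).
#' @export
make_planted_tree <- function(k_clusters, leaves_per_cluster,
                              d_within = 0.1, d_between = 0.6,
                              cutoff = 0.2, seed = 1L) {
  if (!(d_within < cutoff && cutoff <= d_between))
    stop("need d_within < cutoff <= d_between")
  stopifnot(k_clusters >= 1L, leaves_per_cluster >= 1L)
  set.seed(seed)
  fmt <- function(x) sprintf("%.8f", x)
  cl_strings <- character(k_clusters)
  parts <- list()
  for (i in seq_len(k_clusters)) {
    labs <- sprintf("c%d_l%d", i, seq_len(leaves_per_cluster))
    b <- d_within / 2 * stats::runif(leaves_per_cluster, 0.6, 1.0)
    arm <- d_between / 2 - min(b)
    sub <- paste(paste0(labs, ":", fmt(b)), collapse = ",")
    cl_strings[i] <- paste0("(", sub, "):", fmt(arm))
    parts[[i]] <- data.frame(leaf = labs, cluster = i,
                             stringsAsFactors = FALSE)
  }
  newick <- if (k_clusters == 1L) {
    # single cluster: plain star tree, no root arm needed
    paste0(sub(":[0-9.]+$", "", cl_strings[1]), ";")
  } else {
    paste0("(", paste(cl_strings, collapse = ","), ");")
  }
  partition <- do.call(rbind, parts)
  tree <- parse_newick(text = newick)
  list(newick = newick, tree = tree, partition = partition)
}
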