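# Independent oracles used to validate the package implementations.
# Each oracle is written with a different mechanism than the code under
# test (explicit loops and substring checks rather than cumulative sums,
# regular expressions, or library calls).

KD_TABLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2,
  X =  0.0
)

random_peptide <- function(len, alphabet = names(KD_TABLE)[1:20]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# The generator's LRR template (duplicated here so tests can build motif
# arrays without reaching into package internals).
TPL <- "LPELSLHVNDNSLSGEIPEELSNP"

# Brute-force TM oracle: mark every residue covered by a qualifying window,
# read off maximal covered runs, then apply the same length contract
# (drop < 15, trim > 35 to the best 21-mer by exhaustive scan).
tm_oracle <- function(sequence, window = 19L, threshold = 1.6) {
  chars <- strsplit(sequence, "")[[1]]
  h <- unname(KD_TABLE[chars])
  n <- length(h)
  if (n < window) return(data.frame(start = integer(0), end = integer(0)))
  covered <- logical(n)
  for (s in 1:(n - window + 1L)) {
    # same epsilon as the detector: means are 0.005-granular, so this makes
    # the >= comparison exact in either summation order
    if (mean(h[s:(s + window - 1L)]) >= threshold - 1e-9)
      covered[s:(s + window - 1L)] <- TRUE
  }
  out <- data.frame(start = integer(0), end = integer(0))
  s <- NA
  for (i in seq_len(n + 1L)) {
    on <- i <= n && covered[i]
    if (on && is.na(s)) s <- i
    if (!on && !is.na(s)) {
      e <- i - 1L
      len <- e - s + 1L
      if (len >= 15L) {
        if (len > 35L) {
          best <- -Inf; bs <- s
          for (t in s:(e - 20L)) {
            m <- mean(h[t:(t + 20L)])
            if (m > best) { best <- m; bs <- t }
          }
          out <- rbind(out, data.frame(start = bs, end = bs + 20L))
        } else {
          out <- rbind(out, data.frame(start = s, end = e))
        }
      }
      s <- NA
    }
  }
  out
}

# Compare detect_tm output against the oracle.  Trimmed 21-mers may resolve
# score ties differently (cumulative-sum vs direct means), so spans that
# disagree are accepted only when both are 21-mers of equal mean hydropathy.
tm_spans_agree <- function(sequence, got, want, tol = 1e-9) {
  if (nrow(got) != nrow(want)) return(FALSE)
  if (nrow(got) == 0L) return(TRUE)
  h <- unname(KD_TABLE[strsplit(sequence, "")[[1]]])
  for (k in seq_len(nrow(got))) {
    if (got$start[k] == want$start[k] && got$end[k] == want$end[k]) next
    len_g <- got$end[k] - got$start[k] + 1L
    len_w <- want$end[k] - want$start[k] + 1L
    if (len_g != 21L || len_w != 21L) return(FALSE)
    mg <- mean(h[got$start[k]:got$end[k]])
    mw <- mean(h[want$start[k]:want$end[k]])
    if (abs(mg - mw) > tol) return(FALSE)
  }
  TRUE
}

# Loop-based motif oracles.
kx5y_oracle <- function(s) {
  ch <- strsplit(s, "")[[1]]; n <- length(ch)
  out <- integer(0)
  if (n >= 7L) for (i in 1:(n - 6L))
    if (ch[i] == "K" && ch[i + 6L] == "Y") out <- c(out, i)
  out
}
yx8kg_oracle <- function(s) {
  ch <- strsplit(s, "")[[1]]; n <- length(ch)
  out <- integer(0)
  if (n >= 11L) for (i in 1:(n - 10L))
    if (ch[i] == "Y" && ch[i + 9L] == "K" && ch[i + 10L] == "G")
      out <- c(out, i)
  out
}
qxxts_oracle <- function(s) {
  ch <- strsplit(s, "")[[1]]; n <- length(ch)
  out <- integer(0)
  if (n >= 4L) for (i in 1:(n - 3L))
    if (ch[i] == "Q" && ch[i + 3L] %in% c("T", "S")) out <- c(out, i)
  out
}
gxxxg_chain_oracle <- function(s) {
  ch <- strsplit(s, "")[[1]]; n <- length(ch)
  pos <- integer(0)
  if (n >= 5L) for (i in 1:(n - 4L))
    if (ch[i] == "G" && ch[i + 4L] == "G") pos <- c(pos, i)
  if (length(pos) == 0L) return(list(positions = pos, chain_max = 0L))
  best <- 0L
  for (p in pos) {
    len <- 1L; q <- p
    while ((q + 4L) %in% pos) { len <- len + 1L; q <- q + 4L }
    best <- max(best, len)
  }
  list(positions = pos, chain_max = best)
}
charge_oracle <- function(s) {
  ch <- strsplit(s, "")[[1]]
  sum(ch == "K") + sum(ch == "R") - sum(ch == "D") - sum(ch == "E")
}

# Exhaustive hypergeometric two-sided Fisher p for a 2x2 table.
fisher_oracle_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0L, k - n2); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Cophenetic oracle: path sums on the tree seen as a weighted graph.
cophenetic_oracle <- function(tree) {
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  igraph::E(g)$weight <- tree$edge.length
  ntips <- length(tree$tip.label)
  tips <- as.character(seq_len(ntips))
  d <- igraph::distances(g, v = tips, to = tips,
                         weights = igraph::E(g)$weight)
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

make_record <- function(id, sequence, species = "sp") {
  data.frame(id = id, species_id = species, sequence = sequence,
             length = nchar(sequence), stringsAsFactors = FALSE)
}

# Cohort of receptor specs spanning classes, gap counts, and n2 values.
cohort_specs <- function(n, seed = 20260101) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    cls <- c("RLP", "RLK", "ECTODOMAIN_ONLY")[(i %% 3L) + 1L]
    has_id <- i %% 4L != 0L
    n2 <- 2L + (i %% 7L)            # 2..8
    n1 <- 1L + (i %% 5L)            # 1..5
    with_nl <- i %% 6L == 0L && n1 >= 2L
    receptor_spec(
      cls = cls,
      n_lrr_before_id = n1,
      id_length = if (has_id) 30L + (i * 7L) %% 61L else NULL,
      n_lrr_after_id = if (has_id) n2 else max(2L, n2 - 2L),
      nl_length = if (with_nl) 15L + (i * 3L) %% 15L else NULL,
      gxxxg_chain = if (cls == "ECTODOMAIN_ONLY") 0L else i %% 4L,
      ejm_charge_target = if (cls == "RLP") -((i %% 6L) + 1L) else i %% 7L,
      has_signal_peptide = i %% 2L == 0L,
      id_motif = if (has_id)
        c("none", "kx5y", "yx8kg", "both")[(i %% 4L) + 1L] else "none",
      qxxts = c("none", "qxxts", "tqxxx")[(i %% 3L) + 1L],
      seed = seed + i
    )
  })
}

# Compare one generated receptor's truth with the pipeline output; returns
# a character vector of mismatch descriptions (empty when exact).
roundtrip_mismatches <- function(rec, config = analysis_config()) {
  rd <- make_record("rt", rec$sequence)
  ann <- suppressWarnings(annotate_protein(rd[1, ], config))
  t <- rec$truth
  errs <- character(0)
  if (ann$classification$cls != t$class)
    errs <- c(errs, sprintf("class %s != %s", ann$classification$cls,
                            t$class))
  prof <- architecture_profile(rd[1, ], ann, config)
  if (is.null(prof)) return(c(errs, "missing architecture profile"))
  if (!identical(prof$motif_spans$start, t$motif_spans$start) ||
      !identical(prof$motif_spans$end, t$motif_spans$end))
    errs <- c(errs, "motif spans")
  g1 <- prof$gaps[, c("start", "end", "length", "gap_class", "n1", "n2")]
  g2 <- t$gaps
  rownames(g1) <- NULL; rownames(g2) <- NULL
  if (!isTRUE(all.equal(g1, g2, check.attributes = FALSE)))
    errs <- c(errs, "gap table")
  if (nrow(prof$gaps) > 0L && !all(prof$gaps$passed_lrr_screen))
    errs <- c(errs, "screen")
  if (prof$id_plus_4lrr != t$id_plus_4lrr)
    errs <- c(errs, "id_plus_4lrr flag")
  mr <- motif_scan_report(rd[1, ], prof, config)
  if (mr$has_either_lysine != t$has_either_lysine)
    errs <- c(errs, "lysine motif flag")
  if (mr$n_kx5y != t$n_kx5y || mr$n_yx8kg != t$n_yx8kg)
    errs <- c(errs, "lysine motif counts")
  # TM-anchored regions are only defined when the C3 exists (>= 4 motifs)
  if (!is.null(t$tm) && nrow(t$motif_spans) >= 4L) {
    if (!identical(unname(unlist(prof$tm)), unname(t$tm)))
      errs <- c(errs, "tm span")
    if (is.na(mr$gxxxg_chain_max) || mr$gxxxg_chain_max != t$gxxxg_chain)
      errs <- c(errs, "gxxxg chain")
    if (is.na(mr$ejm_net_charge) || mr$ejm_net_charge != t$ejm_net_charge)
      errs <- c(errs, "ejm net charge")
    if (is.na(mr$ejm_terminal_charge) ||
        mr$ejm_terminal_charge != t$ejm_terminal_charge)
      errs <- c(errs, "ejm terminal charge")
  }
  errs
}
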