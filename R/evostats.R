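# Gene-family expansion statistics: per-genome family percentages,
# lineage-median expansion rates, co-expansion correlations, Mantel
# permutation tests, BH false-discovery correction, and Fisher 2x2 tests.

#' Family size as a percentage of the searched gene set
#'
#' @param count Number of identified genes in the family.
#' @param n_searched Number of searched genes in the genome (> 0).
#' @return \code{count / n_searched * 100}.
#' @export
family_percentage <- function(count, n_searched) {
  if (any(n_searched <= 0)) stop("n_searched must be positive")
  if (any(count < 0)) stop("count must be non-negative")
  if (any(count > n_searched))
    stop("count exceeds n_searched (", max(count), " > ", min(n_searched), ")")
  count / n_searched * 100
}

#' Median family percentage of a baseline lineage
#'
#' The median (mean of the central pair for even n) is used instead of the
#' mean to be robust to outlier genomes within a lineage.
#'
#' @param percents Numeric vector of per-species family percentages.
#' @param lineage Lineage name, used in the error message.
#' @return The median percentage.
#' @export
lineage_median <- function(percents, lineage = "<lineage>") {
  if (length(percents) == 0L)
    stop("no species in baseline lineage ", lineage)
  stats::median(percents)
}

#' Expansion rate relative to a baseline lineage median
#'
#' rate = (pct - baseline_median) / baseline_median.  Values above 0
#' indicate expansion, 0 no change, below 0 contraction.  A zero baseline
#' median yields \code{NA} rather than a division blow-up.
#'
#' @param pct Family percentage in the focal species.
#' @param baseline_median Median percentage of the baseline lineage.
#' @return The expansion rate (possibly \code{NA}).
#' @export
expansion_rate <- function(pct, baseline_median) {
  rate <- (pct - baseline_median) / baseline_median
  rate[rep_len(baseline_median <= 0, length(rate))] <- NA_real_
  rate
}

#' Expansion rates for every species and family against a baseline lineage
#'
#' @param counts Data.frame with columns \code{species_id}, \code{lineage},
#'   \code{family}, \code{count}, \code{n_searched}.
#' @param baseline_lineage Name (or vector of names, pooled) of the lineage
#'   whose median is the baseline.
#' @param target_lineage Name(s) of the lineage(s) whose species are rated.
#' @return Data.frame of expansion records: \code{species_id},
#'   \code{family}, \code{baseline_lineage}, \code{pct},
#'   \code{baseline_median}, \code{rate}.
#' @export
expansion_table <- function(counts, baseline_lineage, target_lineage) {
  need <- c("species_id", "lineage", "family", "count", "n_searched")
  if (!all(need %in% names(counts)))
    stop("counts must have columns ", paste(need, collapse = ", "))
  counts$pct <- family_percentage(counts$count, counts$n_searched)
  base <- counts[counts$lineage %in% baseline_lineage, , drop = FALSE]
  targ <- counts[counts$lineage %in% target_lineage, , drop = FALSE]
  if (nrow(base) == 0L)
    stop("no species in baseline lineage ",
         paste(baseline_lineage, collapse = "+"))
  out <- lapply(unique(targ$family), function(fam) {
    b <- base$pct[base$family == fam]
    med <- lineage_median(b, paste(baseline_lineage, collapse = "+"))
    t <- targ[targ$family == fam, , drop = FALSE]
    data.frame(species_id = t$species_id, family = fam,
               baseline_lineage = paste(baseline_lineage, collapse = "+"),
               pct = t$pct, baseline_median = med,
               rate = expansion_rate(t$pct, med),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pearson co-expansion of every family with a target family
#'
#' Computes Pearson's r between each family's per-genome percentage and the
#' target family's percentage over pairwise-complete genomes, and classifies
#' the correlation strength (strong: r > 0.6; medium: 0.3 <= r <= 0.6 by
#' default).
#'
#' @param table Data.frame or matrix, genomes in rows, families in columns,
#'   cells are family percentages (NA allowed).
#' @param target_family Column name of the reference family.
#' @param config Analysis configuration (strength boundaries).
#' @return Data.frame with \code{family}, \code{target_family}, \code{r},
#'   \code{n} (genomes used), \code{strength} (\code{NA} r for constant
#'   columns, strength \code{"NA"}).
#' @export
correlate_with_family <- function(table, target_family,
                                  config = analysis_config()) {
  table <- as.data.frame(table)
  if (!target_family %in% names(table))
    stop("target family ", target_family, " not in table")
  y <- table[[target_family]]
  fams <- setdiff(names(table), target_family)
  out <- lapply(fams, function(fam) {
    x <- table[[fam]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3L) stop("fewer than 3 genomes with both ", fam, " and ",
                     target_family)
    r <- if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) NA_real_ else
      stats::cor(x[ok], y[ok])
    strength <- if (is.na(r)) "NA"
    else if (r > config$r_strong) "strong"
    else if (r >= config$r_medium) "medium"
    else "weak/none"
    data.frame(family = fam, target_family = target_family, r = r, n = n,
               strength = strength, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Convert per-species fractions to a distance matrix
#'
#' d(i, j) = |f_i - f_j|; species with missing values are excluded with a
#' warning.
#'
#' @param values Named numeric vector (names are species ids).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
fractions_to_distance <- function(values) {
  if (is.null(names(values))) names(values) <- seq_along(values)
  miss <- is.na(values)
  if (any(miss)) {
    warning("excluding species with missing values: ",
            paste(names(values)[miss], collapse = ", "))
    values <- values[!miss]
  }
  if (length(values) < 2L) stop("need at least 2 species")
  d <- abs(outer(values, values, "-"))
  dimnames(d) <- list(names(values), names(values))
  d
}

#' Mantel permutation test between two distance matrices
#'
#' The statistic is Pearson's r over the strictly-upper-triangle entries;
#' the null distribution permutes the rows and columns of \code{D2}
#' simultaneously.  The one-sided (greater) p-value is
#' (1 + #\{r_perm >= r_obs\}) / (1 + n_perm); a two-sided alternative uses
#' |r|.  Deterministic given \code{seed}.
#'
#' @param D1,D2 Square symmetric distance matrices over the same ordered
#'   label set (n >= 4).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param alternative \code{"greater"} (default, as in the vegan
#'   convention) or \code{"two.sided"}.
#' @return List of class \code{"mantel_result"}: \code{r}, \code{p},
#'   \code{n_perm}, \code{seed}, \code{alternative}.
#' @export
mantel_test <- function(D1, D2, n_perm = 10000L, seed = 1L,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  n <- nrow(D1)
  if (!all(dim(D1) == dim(D2)) || ncol(D1) != n)
    stop("D1 and D2 must be square matrices of equal size")
  if (!is.null(rownames(D1)) && !is.null(rownames(D2)) &&
      !identical(rownames(D1), rownames(D2)))
    stop("D1 and D2 must share the same ordered label set")
  if (n < 4L) stop("Mantel test requires at least 4 labels, got ", n)
  ut <- upper.tri(D1)
  v1 <- D1[ut]
  r_obs <- stats::cor(v1, D2[ut])
  iu <- row(D1)[ut]; ju <- col(D1)[ut]
  set.seed(seed)
  P <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  lin <- (P[ju, , drop = FALSE] - 1L) * n + P[iu, , drop = FALSE]
  V <- matrix(D2[lin], nrow = length(v1))
  r_perm <- as.vector(stats::cor(v1, V))
  exceed <- if (alternative == "greater") {
    sum(r_perm >= r_obs)
  } else {
    sum(abs(r_perm) >= abs(r_obs))
  }
  structure(list(r = r_obs, p = (1 + exceed) / (1 + n_perm),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 alternative = alternative),
            class = "mantel_result")
}

#' Benjamini--Hochberg false-discovery-rate correction
#'
#' Step-up BH with monotonicity enforcement, order-preserving by input
#' index (a thin validated wrapper around \code{p.adjust}).
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Vector of q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p-value by summation of hypergeometric probabilities of all
#' tables with fixed margins whose probability does not exceed that of the
#' observed table; the odds ratio is the sample ratio ad/bc (infinite when
#' bc = 0 and ad > 0).
#'
#' @param a,b,c,d Non-negative integer cell counts (row-wise:
#'   \code{[[a, b], [c, d]]}).
#' @return List of class \code{"fisher_result"}: \code{table},
#'   \code{odds_ratio}, \code{p_two_sided}.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  if (sum(cells) == 0) stop("grand total must be positive")
  tab <- matrix(as.integer(cells), nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  or <- if (b * c == 0) {
    if (a * d > 0) Inf else NaN
  } else {
    (a * d) / (b * c)
  }
  structure(list(table = tab, odds_ratio = or, p_two_sided = min(p, 1)),
            class = "fisher_result")
}
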