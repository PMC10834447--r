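test_that("family percentage and expansion rate follow their definitions", {
  expect_equal(family_percentage(200, 20000), 1)
  expect_error(family_percentage(5, 0), "positive")
  expect_error(family_percentage(30, 20), "exceeds")
  expect_equal(expansion_rate(2, 1), 1)
  expect_equal(expansion_rate(1, 1), 0)
  expect_equal(expansion_rate(0.5, 1), -0.5)
  expect_true(is.na(expansion_rate(1, 0)))
  # vectorized over species
  expect_equal(expansion_rate(c(0.4, 0.5, 0.6), 0.2), c(1, 1.5, 2))
})

test_that("lineage median uses the central-pair mean and rejects empty input", {
  expect_equal(lineage_median(c(0.1, 0.2, 0.4, 0.8)), 0.3)
  expect_equal(lineage_median(c(3, 1, 2)), 2)
  expect_error(lineage_median(numeric(0), "algae"), "algae")
})

test_that("expansion_table computes per-species rates against the baseline median", {
  counts <- data.frame(
    species_id = c("a1", "a2", "a3", "b1", "b2"),
    lineage = c("algae", "algae", "algae", "land", "land"),
    family = "F",
    count = c(20, 40, 60, 120, 20),
    n_searched = 20000)
  ex <- expansion_table(counts, "algae", "land")
  # baseline pcts 0.1/0.2/0.3, median 0.2; land pcts 0.6 and 0.1
  expect_equal(ex$baseline_median, c(0.2, 0.2))
  expect_equal(ex$rate, c(2, -0.5))
  expect_error(expansion_table(counts, "missing_lineage", "land"),
               "no species in baseline lineage")
})

test_that("co-expansion correlations are classified by the r boundaries", {
  x <- c(1, 2, 3, 4, 5, 6)
  tab <- data.frame(target = x,
                    pos = 2 * x + 1,          # r = 1, strong
                    neg = -x,                 # r = -1, weak/none
                    mid = c(1, 3, 2, 4, 3, 6),
                    flat = rep(2, 6))         # constant -> NA
  res <- correlate_with_family(tab, "target")
  expect_equal(res$strength[res$family == "pos"], "strong")
  expect_equal(res$strength[res$family == "neg"], "weak/none")
  r_mid <- res$r[res$family == "mid"]
  expect_equal(res$strength[res$family == "mid"],
               if (r_mid > 0.6) "strong" else if (r_mid >= 0.3) "medium"
               else "weak/none")
  expect_true(is.na(res$r[res$family == "flat"]))
  expect_equal(res$strength[res$family == "flat"], "NA")
  expect_error(correlate_with_family(tab[1:2, ], "target"),
               "fewer than 3 genomes")
})

test_that("fraction distances are absolute differences with NA exclusion", {
  d <- fractions_to_distance(c(a = 0.1, b = 0.4, c = 0.2))
  expect_equal(d["a", "b"], 0.3)
  expect_equal(d, t(d))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_warning(d2 <- fractions_to_distance(c(a = 0.1, b = NA, c = 0.2)),
                 "excluding species")
  expect_equal(rownames(d2), c("a", "c"))
  expect_error(suppressWarnings(fractions_to_distance(c(a = 0.1, b = NA))),
               "at least 2")
})

test_that("mantel_test is exact on the identity fixture and deterministic", {
  D <- fractions_to_distance(c(a = 0.1, b = 0.3, c = 0.6, d = 1.0, e = 1.5))
  m <- mantel_test(D, D, n_perm = 999, seed = 5)
  expect_equal(m$r, 1)
  expect_lt(m$p, 0.05)
  m2 <- mantel_test(D, D, n_perm = 999, seed = 5)
  expect_identical(m$p, m2$p)
  expect_error(mantel_test(D[1:3, 1:3], D[1:3, 1:3]), "at least 4")
  expect_error(mantel_test(D, D[c(2, 1, 3, 4, 5), c(2, 1, 3, 4, 5)]),
               "label set")
})

test_that("mantel_test matches vegan on the statistic and the p-value", {
  set.seed(77)
  x <- runif(10)
  D1 <- fractions_to_distance(stats::setNames(x, letters[1:10]))
  D2 <- fractions_to_distance(stats::setNames(x + rnorm(10, sd = 0.3),
                                              letters[1:10]))
  ours <- mantel_test(D1, D2, n_perm = 9999, seed = 3)
  ref <- vegan::mantel(as.dist(D1), as.dist(D2), permutations = 9999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  # both p-values estimate the same permutation tail probability
  expect_lt(abs(ours$p - ref$signif), 0.02)
})

test_that("bh_fdr reproduces the manual step-up procedure", {
  p <- c(0.01, 0.04, 0.03, 0.005, 0.2, 1)
  q <- bh_fdr(p)
  # manual BH: order, scale by n/rank, enforce monotonicity from the top
  ord <- order(p)
  n <- length(p)
  scaled <- p[ord] * n / seq_len(n)
  manual <- rev(cummin(rev(scaled)))[order(ord)]
  expect_equal(q, pmin(manual, 1))
  expect_true(all(q >= p))
  expect_error(bh_fdr(c(0.1, 0)), "0, 1")
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
  expect_error(bh_fdr(c(0.1, NA)), "0, 1")
})

test_that("fisher_2x2 matches the hypergeometric oracle on random tables", {
  set.seed(55)
  for (i in 1:200) {
    cells <- as.integer(sample(0:30, 4, replace = TRUE))
    if (sum(cells) == 0L) next
    f <- fisher_2x2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(f$p_two_sided,
                 fisher_oracle_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10,
                 info = paste(cells, collapse = ","))
  }
})

test_that("fisher_2x2 odds ratio is the sample ratio with Inf on empty cells", {
  expect_equal(fisher_2x2(6, 2, 3, 4)$odds_ratio, 4)
  expect_equal(fisher_2x2(10, 0, 0, 10)$odds_ratio, Inf)
  expect_true(is.nan(fisher_2x2(0, 5, 0, 5)$odds_ratio))
  expect_error(fisher_2x2(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_2x2(0, 0, 0, 0), "grand total")
})
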