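spans <- function(starts, width = 24L) {
  data.frame(start = as.integer(starts), end = as.integer(starts + width - 1L))
}

test_that("motifs merge into one region strictly below the 13-residue bound", {
  # inter-motif distances 0 and 12 merge; 13 splits
  merged <- group_regions(spans(c(1, 25, 61)))    # distances 0, 12
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$start, 1L)
  expect_equal(merged$end, 84L)
  expect_equal(merged$n_motifs, 3L)
  split2 <- group_regions(spans(c(1, 38)))        # distance 13
  expect_equal(nrow(split2), 2L)
  expect_equal(split2$first_motif, c(1L, 2L))
})

test_that("group_regions rejects unsorted or overlapping motif spans", {
  expect_error(group_regions(spans(c(30, 1))), "sorted")
  expect_error(group_regions(spans(c(1, 10))), "overlapping")
})

test_that("gap classes follow the NL/ID length windows at their boundaries", {
  for (len in c(1L, 14L, 15L, 29L, 30L, 90L, 91L, 120L)) {
    # two single-motif regions built directly, so lengths below the merge
    # bound are exercised too
    regions <- data.frame(start = c(1L, 25L + len), end = c(24L, 48L + len),
                          n_motifs = 1L, first_motif = c(1L, 2L),
                          last_motif = c(1L, 2L))
    gaps <- call_gaps(regions)
    expect_equal(gaps$length, len)
    want <- if (len >= 15L && len <= 29L) "NL" else
      if (len >= 30L && len <= 90L) "ID" else "NONE"
    expect_equal(gaps$gap_class, want, info = paste("length", len))
  }
})

test_that("terminal gaps are only called when enabled and given an ecto span", {
  regions <- group_regions(spans(c(41, 105)))     # one 40-residue inner gap
  off <- call_gaps(regions)
  expect_equal(nrow(off), 1L)
  expect_false(any(off$terminal))
  cfg <- analysis_config(include_terminal_gaps = TRUE)
  on <- call_gaps(regions, cfg, ecto_span = c(1L, 160L))
  expect_equal(nrow(on), 3L)
  expect_equal(on$terminal, c(TRUE, FALSE, TRUE))
  expect_equal(on$length, c(40L, 40L, 32L))
  expect_equal(on$gap_class, c("ID", "ID", "ID"))
})

test_that("gap screening drops gaps that contain an LRR motif", {
  expect_true(screen_gap(strrep("STNQ", 15)))
  expect_false(screen_gap(paste0(strrep("ST", 10), TPL, strrep("NQ", 10))))
  expect_true(screen_gap(""))
})

test_that("locate_ids counts flanking motifs and sets the ID+4LRR flag exactly", {
  # 3 motifs, 60-residue ID, 4 motifs -> n1 = 3, n2 = 4, flag on
  starts <- c(1, 25, 49, 133, 157, 181, 205)      # ID residues 73..132
  ms <- spans(starts)
  gaps <- call_gaps(group_regions(ms))
  gaps$passed_lrr_screen <- TRUE
  loc <- locate_ids(gaps, ms)
  expect_equal(loc$gaps$n1, 3L)
  expect_equal(loc$gaps$n2, 4L)
  expect_true(loc$id_plus_4lrr)
  # five trailing motifs -> flag off under the exact-4 rule
  ms5 <- spans(c(starts, 229))
  gaps5 <- call_gaps(group_regions(ms5))
  gaps5$passed_lrr_screen <- TRUE
  expect_false(locate_ids(gaps5, ms5)$id_plus_4lrr)
  # ... but on under the at-most-4 variant with three trailing motifs
  ms3 <- spans(starts[1:6])
  gaps3 <- call_gaps(group_regions(ms3))
  gaps3$passed_lrr_screen <- TRUE
  expect_false(locate_ids(gaps3, ms3)$id_plus_4lrr)
  expect_true(locate_ids(gaps3, ms3,
                         analysis_config(id4_le = TRUE))$id_plus_4lrr)
})

test_that("a screened-out island domain never sets the ID+4LRR flag", {
  starts <- c(1, 25, 109, 133, 157, 181)
  ms <- spans(starts)
  gaps <- call_gaps(group_regions(ms))
  gaps$passed_lrr_screen <- FALSE
  expect_false(locate_ids(gaps, ms)$id_plus_4lrr)
})

test_that("C3/eJM/TM/cJM spans match the planted receptor layout", {
  rec <- make_receptor(receptor_spec(cls = "RLK", n_lrr_before_id = 3,
                                     id_length = 50, n_lrr_after_id = 4,
                                     seed = 11))
  rd <- make_record("r", rec$sequence)
  ann <- annotate_protein(rd[1, ])
  prof <- architecture_profile(rd[1, ], ann)
  t <- rec$truth
  expect_equal(prof$c3, t$c3)
  expect_equal(prof$ejm, t$ejm)
  expect_equal(unname(unlist(prof$tm)), unname(t$tm))
  expect_equal(prof$cjm, t$cjm)
  expect_identical(prof$c3_seq,
                   substr(rec$sequence, t$c3[["start"]], t$c3[["end"]]))
})

test_that("the cJM can run to the C terminus instead of the kinase start", {
  rec <- make_receptor(receptor_spec(cls = "RLK", seed = 12))
  rd <- make_record("r", rec$sequence)
  cfg <- analysis_config(cjm_mode = "to_cterm")
  ann <- annotate_protein(rd[1, ], cfg)
  prof <- architecture_profile(rd[1, ], ann, cfg)
  expect_equal(unname(prof$cjm[["end"]]), rd$length[1])
})

test_that("extract_regions refuses undefined C3 or misplaced TM", {
  rd <- make_record("p3", strrep("A", 300))
  tm <- data.frame(start = 200L, end = 220L)
  expect_error(extract_regions(rd[1, ], spans(c(1, 25, 49)), tm),
               "C3 undefined")
  tm_early <- data.frame(start = 1L, end = 20L)
  expect_error(
    extract_regions(rd[1, ], spans(c(30, 54, 78, 102)), tm_early),
    "N-terminal of all LRR motifs")
})

test_that("architecture_profile restricts motifs to the ectodomain", {
  rec <- make_receptor(receptor_spec(cls = "RLP", seed = 13))
  rd <- make_record("r", rec$sequence)
  ann <- annotate_protein(rd[1, ])
  prof <- architecture_profile(rd[1, ], ann)
  ecto <- ann$classification$ecto_span
  expect_true(all(prof$motif_spans$start >= ecto[["start"]] &
                    prof$motif_spans$start <= ecto[["end"]]))
  expect_null(architecture_profile(
    make_record("bg", strrep("STNQ", 60))[1, ],
    annotate_protein(make_record("bg", strrep("STNQ", 60))[1, ])))
})
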