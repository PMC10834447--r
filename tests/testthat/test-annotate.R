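make_calls <- function(kind, start, end) {
  data.frame(kind = kind, start = as.integer(start), end = as.integer(end),
             score = NA_real_, source = "test", stringsAsFactors = FALSE)
}

test_that("detect_tm finds a single hydrophobic stretch with exact bounds", {
  s <- paste0(strrep("P", 30), strrep("I", 21), strrep("P", 30))
  tm <- detect_tm(s)
  expect_equal(nrow(tm), 1L)
  expect_identical(tm$kind, "TM")
  # brute-force oracle agrees
  o <- tm_oracle(s)
  expect_equal(tm$start, o$start)
  expect_equal(tm$end, o$end)
})

test_that("detect_tm agrees with the brute-force window oracle on random sequences", {
  set.seed(401)
  for (i in 1:300) {
    s <- random_peptide(sample(19:120, 1))
    got <- detect_tm(s)
    want <- tm_oracle(s)
    expect_true(tm_spans_agree(s, got, want), info = s)
  }
})

test_that("detect_tm drops short merged runs and trims long ones to a 21-mer", {
  # with the default 19-residue window a merged run can never be < 15, so
  # exercise the drop rule with a narrow window: 7 hydrophobic residues
  # merge to an 11-residue run, below the 15-residue minimum
  short <- paste0(strrep("N", 10), strrep("I", 7), strrep("N", 10))
  expect_equal(nrow(detect_tm(short, window = 7L)), 0L)
  # a 60-residue hydrophobic run merges far past 35 and is trimmed to 21
  long <- paste0(strrep("N", 10), strrep("I", 60), strrep("N", 10))
  tm <- detect_tm(long)
  expect_equal(nrow(tm), 1L)
  expect_equal(tm$end - tm$start + 1L, 21L)
})

test_that("detect_tm warns and returns no calls on sub-window sequences", {
  expect_warning(res <- detect_tm(strrep("L", 10)), "shorter than TM window")
  expect_equal(nrow(res), 0L)
})

test_that("mask_until excludes the signal peptide from TM detection", {
  # hydrophobic N-terminus would be a TM call without masking
  s <- paste0(strrep("L", 20), strrep("N", 60))
  expect_equal(nrow(detect_tm(s)), 1L)
  expect_equal(nrow(detect_tm(s, mask_until = 20L)), 0L)
})

test_that("signal peptide rule needs an early 7-15 residue run of mean >= 2", {
  sp <- detect_signal_peptide(paste0("MK", strrep("L", 10), "TSANQQN"))
  expect_equal(sp, c(start = 1L, end = 12L))
  # run of mean hydropathy 1.8 (< 2.0) does not qualify
  expect_null(detect_signal_peptide(paste0(strrep("A", 10), strrep("N", 40))))
  # 16-residue run is longer than the h-region bound
  expect_null(detect_signal_peptide(paste0(strrep("L", 16), strrep("N", 40))))
  # qualifying run starting after residue 10 is not a signal peptide
  expect_null(detect_signal_peptide(paste0(strrep("N", 11), strrep("L", 9),
                                           strrep("N", 30))))
})

test_that("detect_kinase requires ordered landmarks within 150-350 residues", {
  cassette <- paste0("GAGTVG", strrep("S", 13), "K", strrep("S", 79),
                     "HRD", strrep("S", 115), "DFG", strrep("S", 30))
  kd <- detect_kinase(cassette)
  expect_equal(kd$kind, "KINASE")
  expect_equal(kd$start, 1L)
  expect_equal(kd$end, 250L)
  # no DFG -> no kinase
  expect_null(detect_kinase(paste0("GAGTVG", strrep("S", 13), "K",
                                   strrep("S", 79), "HRD", strrep("S", 140))))
  # landmarks spread beyond 350 residues -> no kinase
  wide <- paste0("GAGTVG", strrep("S", 13), "K", strrep("S", 79),
                 "HRD", strrep("S", 300), "DFG", strrep("S", 30))
  expect_null(detect_kinase(wide))
})

test_that("detect_lrr calls greedy non-overlapping 24-mers on the core pattern", {
  tandem <- strrep(TPL, 3)
  lrr <- detect_lrr(tandem)
  expect_equal(lrr$start, c(1L, 25L, 49L))
  expect_equal(lrr$end, c(24L, 48L, 72L))
  expect_equal(nrow(detect_lrr(strrep("STNQ", 20))), 0L)
  # final motif clipped at the sequence end (core fits, 24-mer does not)
  clipped <- detect_lrr(substr(tandem, 1, 65))
  expect_equal(clipped$start[nrow(clipped)], 49L)
  expect_equal(clipped$end[nrow(clipped)], 65L)
})

test_that("external annotation loading validates kinds and coordinates", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tkind\tstart\tend\tscore",
               "p1\tTM\t10\t30\t1.9",
               "p1\tKINASE\t100\t300\t0.5",
               "p2\tLRR\t5\t28\tNA"), path)
  ann <- load_external_annotations(path)
  expect_named(ann, c("p1", "p2"))
  expect_equal(nrow(ann$p1), 2L)
  expect_equal(ann$p2$start, 5L)
  expect_true(all(ann$p1$source == "external"))

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tkind\tstart\tend\tscore",
               "p1\tPFAM\t1\t10\t1"), bad)
  expect_error(load_external_annotations(bad), "line 2.*unknown domain kind")
  writeLines(c("protein_id\tkind\tstart\tend\tscore",
               "p1\tTM\t0\t10\t1"), bad)
  expect_error(load_external_annotations(bad), "1-based")
  writeLines(c("protein_id\tkind\tstart\tend\tscore",
               "p1\tTM\t12\t10\t1"), bad)
  expect_error(load_external_annotations(bad), "start 12 > end 10")
})

test_that("classification follows the TM/kinase/LRR decision table", {
  rec <- make_record("p", strrep("A", 400))
  rlk <- classify_receptor(rec, make_calls(c("TM", "KINASE"),
                                           c(100, 150), c(120, 380)))
  expect_equal(rlk$cls, "RLK")
  rlp <- classify_receptor(rec, make_calls("TM", 100, 120))
  expect_equal(rlp$cls, "RLP")
  ecto <- classify_receptor(rec, make_calls("LRR", 10, 33))
  expect_equal(ecto$cls, "ECTODOMAIN_ONLY")
  none <- classify_receptor(rec, make_calls("TM", 1, 20)[0, ])
  expect_equal(none$cls, "OTHER")
  expect_equal(none$filtered_reason, "no_receptor_architecture")
})

test_that("length filters and the TM-count cap apply before classification", {
  short <- classify_receptor(make_record("p", strrep("A", 149)),
                             make_calls("TM", 10, 30))
  expect_equal(short$cls, "OTHER")
  expect_equal(short$filtered_reason, "min_length")
  many_tm <- classify_receptor(make_record("p", strrep("A", 400)),
                               make_calls(rep("TM", 3),
                                          c(10, 60, 110), c(30, 80, 130)))
  expect_equal(many_tm$filtered_reason, "tm_count")
  # LRR-bearing kinase+TM candidate below 250 residues is filtered
  rec249 <- make_record("p", strrep("A", 249))
  f <- classify_receptor(rec249, make_calls(c("TM", "LRR", "KINASE"),
                                            c(60, 1, 90), c(80, 24, 245)))
  expect_equal(f$cls, "OTHER")
  expect_equal(f$filtered_reason, "min_length")
  # without an LRR the same protein is an RLK at 150+
  ok <- classify_receptor(rec249, make_calls(c("TM", "KINASE"),
                                             c(60, 90), c(80, 245)))
  expect_equal(ok$cls, "RLK")
})

test_that("ecto/endo split puts LRRs in the ectodomain and the kinase in the endodomain", {
  rec <- make_record("p", strrep("A", 400))
  calls <- make_calls(c("LRR", "LRR", "TM", "KINASE"),
                      c(10, 40, 120, 160), c(33, 63, 140, 390))
  cls <- classify_receptor(rec, calls)
  sp <- split_ecto_endo(rec, calls, cls)
  expect_equal(sp$ecto, c(start = 1L, end = 119L))
  expect_equal(sp$endo, c(start = 141L, end = 400L))
  expect_false(attr(sp, "tie"))
})

test_that("a two-TM receptor with LRRs on both sides reports the tie-break", {
  rec <- make_record("p", strrep("A", 400))
  calls <- make_calls(c("LRR", "TM", "LRR", "TM"),
                      c(10, 120, 160, 250), c(33, 140, 183, 270))
  cls <- classify_receptor(rec, calls)
  sp <- split_ecto_endo(rec, calls, cls)
  expect_true(attr(sp, "tie"))
  # N-terminal stretch wins the tie
  expect_equal(unname(sp$ecto[1]), 1L)
})

test_that("annotate_protein recovers the planted class and domain layout", {
  rec <- make_receptor(receptor_spec(cls = "RLK", seed = 7))
  ann <- annotate_protein(make_record("rlk1", rec$sequence))
  expect_equal(ann$classification$cls, "RLK")
  expect_true("KINASE" %in% ann$calls$kind)
  expect_equal(sum(ann$calls$kind == "TM"), 1L)
  # all LRRs fall inside the reported ectodomain
  lrr <- ann$calls[ann$calls$kind == "LRR", ]
  expect_true(all(lrr$start >= ann$classification$ecto_span[["start"]] &
                    lrr$end <= ann$classification$ecto_span[["end"]]))
})

test_that("external annotations replace the built-in detectors", {
  # sequence the detectors would classify as OTHER
  rec <- make_record("px", strrep("A", 300))
  ext <- make_calls(c("TM", "LRR"), c(200, 10), c(220, 33))
  ext$source <- "external"
  ann <- annotate_protein(rec, external = ext)
  expect_equal(ann$classification$cls, "RLP")
})

test_that("inconsistent external calls are rejected with the protein id", {
  rec <- make_record("py", strrep("A", 100))
  ext <- make_calls("TM", 90, 120)  # beyond the sequence end
  expect_error(annotate_protein(rec, external = ext), "py")
})
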