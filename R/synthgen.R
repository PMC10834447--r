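# Seeded synthetic receptors, proteomes, lineage panels, and planted-cluster
# trees with machine-readable ground truth.  Sequences are assembled from
# building blocks chosen so that the rule-based detectors recover the
# planted architecture exactly: the LRR template matches the detector's core
# pattern at its first position only, and every filler alphabet avoids the
# residues that could create spurious LRR cores, TM windows, kinase
# landmarks, or diagnostic motifs.

# 24-residue LRR template; core positions 1,4,6,8,13 hydrophobic, 11 = N.
# Contains no K/Y/Q, a single G, and no internal or tandem-offset core match.
LRR_TEMPLATE <- "LPELSLHVNDNSLSGEIPEELSNP"

# Gap (NL/ID) filler alphabet: no hydrophobic core residues, no G (kinase
# landmark safety), no K/R/Y (lysine-motif and charge safety), no F.
GAP_FILLER_ALPHABET <- c("S", "T", "N", "Q", "E", "D", "P", "H")

# Neutral juxtamembrane filler: uncharged, non-hydrophobic.
NEUTRAL_ALPHABET <- c("S", "T", "N", "Q", "P")

# Kinase-cassette filler: no G/H/R/D/F/K and nothing hydrophobic, so the
# only landmark matches are the planted ones.
KINASE_FILLER_ALPHABET <- c("S", "T", "N", "Q", "E", "P")

SIGNAL_BLOCK <- paste0("MK", strrep("L", 10), "TSANQQN")  # detected SP: 1-12
TM_PAD <- strrep("N", 6)

rand_string <- function(n, alphabet) {
  if (n <= 0L) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

tm_block <- function(gxxxg_chain) {
  stopifnot(gxxxg_chain >= 0L, gxxxg_chain <= 3L)
  if (gxxxg_chain == 0L) return(strrep("L", 23L))
  core_len <- 4L * gxxxg_chain + 1L
  core <- strsplit(strrep("L", core_len), "")[[1]]
  core[seq(1L, core_len, by = 4L)] <- "G"
  pl <- (23L - core_len) %/% 2L
  paste0(strrep("L", pl), paste(core, collapse = ""),
         strrep("L", 23L - core_len - pl))
}

kinase_cassette <- function() {
  parts <- c("GAGTVG",                       # 1-6   glycine-rich loop
             rand_string(13L, KINASE_FILLER_ALPHABET),  # 7-19
             "K",                            # 20    beta-3 lysine
             rand_string(79L, KINASE_FILLER_ALPHABET),  # 21-99
             "HRD",                          # 100-102
             rand_string(115L, KINASE_FILLER_ALPHABET), # 103-217
             "DFG",                          # 218-220
             rand_string(30L, KINASE_FILLER_ALPHABET))  # 221-250
  paste(parts, collapse = "")
}

last_motif_variant <- function(qxxts) {
  tpl <- seq_chars(LRR_TEMPLATE)
  if (qxxts == "qxxts") {
    tpl[14:18] <- c("G", "Q", "F", "E", "T")
  } else if (qxxts == "tqxxx") {
    tpl[14:18] <- c("T", "Q", "I", "T", "G")
  }
  paste(tpl, collapse = "")
}

id_filler <- function(len, motif) {
  planted <- switch(motif,
                    none = "",
                    kx5y = "KQNDSTY",
                    yx8kg = "YSSSSSSSSKG",
                    both = paste0("KQNDSTY", "YSSSSSSSSKG"),
                    stop("unknown id_motif: ", motif))
  if (nchar(planted) > len)
    stop("island domain of ", len, " residues too short for motif ", motif)
  paste0(planted, rand_string(len - nchar(planted), GAP_FILLER_ALPHABET))
}

ejm_block <- function(len, charge_target) {
  if (abs(charge_target) > 6L)
    stop("|ejm_charge_target| must be <= 6 so the charge block stays ",
         "inside the terminal window")
  if (abs(charge_target) > len)
    stop("eJM length ", len, " cannot carry charge ", charge_target)
  block <- if (charge_target >= 0L) strrep("K", charge_target) else
    strrep("E", -charge_target)
  paste0(rand_string(len - nchar(block), NEUTRAL_ALPHABET), block)
}

#' Specification of one synthetic receptor
#'
#' @param cls \code{"RLK"}, \code{"RLP"}, or \code{"ECTODOMAIN_ONLY"}.
#' @param n_lrr_before_id,n_lrr_after_id LRR motif counts flanking the
#'   island domain (when no ID is planted the two blocks are contiguous).
#' @param id_length Island-domain length (30--90 residues) or \code{NULL}.
#' @param nl_length N-loopout length (15--29 residues) or \code{NULL}.
#' @param nl_after Motif index after which the NL is inserted (defaults to
#'   the middle of the pre-ID block).
#' @param gxxxg_chain GxxxG chain length in the TM, 0--3.
#' @param ejm_charge_target Net (and terminal) eJM charge, within [-6, 6].
#' @param ejm_length eJM core length, residues.
#' @param has_signal_peptide Prepend a cleavable signal peptide.
#' @param id_motif Lysine motif planted in the ID: \code{"none"},
#'   \code{"kx5y"}, \code{"yx8kg"}, or \code{"both"}.
#' @param qxxts Terminal-LRR variant: \code{"none"}, \code{"qxxts"}
#'   (a GQFET-style loop), or \code{"tqxxx"} (TQITG-style).
#' @param seed Integer seed.
#' @return Validated spec list of class \code{"receptor_spec"}.
#' @export
receptor_spec <- function(cls = c("RLP", "RLK", "ECTODOMAIN_ONLY"),
                          n_lrr_before_id = 2L, id_length = 60L,
                          n_lrr_after_id = 4L,
                          nl_length = NULL, nl_after = NULL,
                          gxxxg_chain = 1L, ejm_charge_target = -4L,
                          ejm_length = 20L,
                          has_signal_peptide = TRUE,
                          id_motif = c("none", "kx5y", "yx8kg", "both"),
                          qxxts = c("none", "qxxts", "tqxxx"),
                          seed = 1L) {
  cls <- match.arg(cls)
  id_motif <- match.arg(id_motif)
  qxxts <- match.arg(qxxts)
  if (!is.null(id_length) && (id_length < 30L || id_length > 90L))
    stop("id_length must lie in [30, 90]")
  if (!is.null(nl_length) && (nl_length < 15L || nl_length > 29L))
    stop("nl_length must lie in [15, 29]")
  if (gxxxg_chain < 0L || gxxxg_chain > 3L)
    stop("gxxxg_chain must be 0-3 (a 23-residue TM fits at most three)")
  n_total <- n_lrr_before_id + n_lrr_after_id
  if (n_total < 1L) stop("at least one LRR motif required")
  if (is.null(id_length) && n_lrr_before_id == 0L)
    stop("n_lrr_before_id must be >= 1 when no ID is planted")
  if (!is.null(id_length) &&
      (n_lrr_before_id < 1L || n_lrr_after_id < 1L))
    stop("an ID needs at least one motif on each side")
  if (!is.null(nl_length)) {
    max_after <- if (!is.null(id_length)) n_lrr_before_id - 1L else
      n_total - 1L
    if (max_after < 1L) stop("no room for an NL insertion")
    if (is.null(nl_after)) nl_after <- max(1L, max_after %/% 2L)
    if (nl_after < 1L || nl_after > max_after)
      stop("nl_after must lie in [1, ", max_after, "]")
  }
  if (ejm_length < 8L) stop("ejm_length must be >= 8")
  structure(list(cls = cls, n_lrr_before_id = as.integer(n_lrr_before_id),
                 id_length = id_length,
                 n_lrr_after_id = as.integer(n_lrr_after_id),
                 nl_length = nl_length, nl_after = nl_after,
                 gxxxg_chain = as.integer(gxxxg_chain),
                 ejm_charge_target = as.integer(ejm_charge_target),
                 ejm_length = as.integer(ejm_length),
                 has_signal_peptide = isTRUE(has_signal_peptide),
                 id_motif = id_motif, qxxts = qxxts,
                 seed = as.integer(seed)),
            class = "receptor_spec")
}

#' Generate one synthetic receptor with ground truth
#'
#' Assembles [signal peptide] + LRR template copies + [NL filler] +
#' [ID filler] + eJM + TM + cJM [+ kinase cassette] and records the planted
#' architecture.  Running the annotation, architecture, and motif stages on
#' the output reproduces the truth exactly.
#'
#' @param spec A [receptor_spec()].
#' @param config Analysis configuration (used to locate the realized TM
#'   boundaries for the truth record).
#' @return List with \code{sequence} and \code{truth} (planted class, motif
#'   spans, gap table with classes and n1/n2, ID+4LRR flag, region spans,
#'   motif and charge flags).
#' @export
make_receptor <- function(spec, config = analysis_config()) {
  stopifnot(inherits(spec, "receptor_spec"))
  set.seed(spec$seed)
  n1 <- spec$n_lrr_before_id
  n2 <- spec$n_lrr_after_id
  n_total <- n1 + n2
  has_id <- !is.null(spec$id_length)

  parts <- character(0)
  pos <- 0L
  sp_span <- NULL
  if (spec$has_signal_peptide) {
    parts <- c(parts, SIGNAL_BLOCK)
    sp_span <- c(start = 1L, end = 12L)
    pos <- pos + nchar(SIGNAL_BLOCK)
  }

  motif_starts <- integer(0)
  gap_rows <- list()
  add_motif <- function(variant = LRR_TEMPLATE) {
    motif_starts <<- c(motif_starts, pos + 1L)
    parts <<- c(parts, variant)
    pos <<- pos + nchar(variant)
  }
  add_gap <- function(len, cls, seqstr, n_before) {
    gap_rows[[length(gap_rows) + 1L]] <<- data.frame(
      start = pos + 1L, end = pos + len, length = len, gap_class = cls,
      n1 = n_before, n2 = n_total - n_before, stringsAsFactors = FALSE)
    parts <<- c(parts, seqstr)
    pos <<- pos + len
  }

  for (i in seq_len(n_total)) {
    variant <- if (i == n_total) last_motif_variant(spec$qxxts) else
      LRR_TEMPLATE
    add_motif(variant)
    if (!is.null(spec$nl_length) && i == spec$nl_after)
      add_gap(spec$nl_length, "NL",
              rand_string(spec$nl_length, GAP_FILLER_ALPHABET), i)
    if (has_id && i == n1)
      add_gap(spec$id_length, "ID",
              id_filler(spec$id_length, spec$id_motif), i)
  }

  ejm_core_span <- NULL; kd_span <- NULL
  if (spec$cls %in% c("RLP", "RLK")) {
    ejm <- ejm_block(spec$ejm_length, spec$ejm_charge_target)
    ejm_core_span <- c(start = pos + 1L, end = pos + nchar(ejm))
    parts <- c(parts, ejm, TM_PAD)
    pos <- pos + nchar(ejm) + nchar(TM_PAD)
    tm <- tm_block(spec$gxxxg_chain)
    tm_planted <- c(start = pos + 1L, end = pos + nchar(tm))
    parts <- c(parts, tm, TM_PAD)
    pos <- pos + nchar(tm) + nchar(TM_PAD)
    cjm_len <- 15L
    if (spec$cls == "RLP") {
      # pad the tail so every RLP clears the 150-residue length filter
      cjm_len <- max(cjm_len, 150L - pos)
    }
    parts <- c(parts, rand_string(cjm_len, NEUTRAL_ALPHABET))
    pos <- pos + cjm_len
    if (spec$cls == "RLK") {
      cassette <- kinase_cassette()
      kd_span <- c(start = pos + 1L, end = pos + nchar(cassette))
      parts <- c(parts, cassette)
      pos <- pos + nchar(cassette)
    }
  } else if (pos < 150L) {
    tail_len <- 150L - pos
    parts <- c(parts, rand_string(tail_len, NEUTRAL_ALPHABET))
    pos <- pos + tail_len
  }

  sequence <- paste(parts, collapse = "")
  stopifnot(nchar(sequence) == pos)

  motif_spans <- data.frame(start = motif_starts,
                            end = motif_starts + 23L)
  gaps <- if (length(gap_rows) > 0L) do.call(rbind, gap_rows) else
    data.frame(start = integer(0), end = integer(0), length = integer(0),
               gap_class = character(0), n1 = integer(0), n2 = integer(0),
               stringsAsFactors = FALSE)
  # generation-time assertion: fillers never contain an LRR core
  if (nrow(gaps) > 0L) {
    for (k in seq_len(nrow(gaps))) {
      gseq <- substr(sequence, gaps$start[k], gaps$end[k])
      if (!screen_gap(gseq))
        stop("internal error: gap filler matches the LRR core pattern")
    }
  }
  id_plus_4lrr <- has_id && n2 == config$id4_n2

  truth <- list(
    class = spec$cls,
    sp = sp_span,
    motif_spans = motif_spans,
    gaps = gaps,
    id_plus_4lrr = id_plus_4lrr,
    has_either_lysine = has_id && spec$id_motif != "none",
    n_kx5y = if (has_id && spec$id_motif %in% c("kx5y", "both")) 1L else 0L,
    n_yx8kg = if (has_id && spec$id_motif %in% c("yx8kg", "both")) 1L else 0L,
    qxxts = spec$qxxts,
    seed = spec$seed
  )

  if (spec$cls %in% c("RLP", "RLK")) {
    mask <- if (is.null(sp_span)) 0L else sp_span[["end"]]
    tm_det <- detect_tm(sequence, config$tm_window, config$tm_threshold,
                        mask_until = mask)
    if (nrow(tm_det) != 1L)
      stop("internal error: expected exactly one detectable TM, found ",
           nrow(tm_det))
    if (tm_det$start <= ejm_core_span[["end"]] ||
        tm_det$start > tm_planted[["start"]] ||
        tm_det$end < tm_planted[["end"]])
      stop("internal error: realized TM span leaves the pad region")
    truth$tm <- c(start = tm_det$start, end = tm_det$end)
    if (n_total >= 4L) {
      truth$c3 <- c(start = motif_spans$start[n_total - 3L],
                    end = motif_spans$end[n_total])
      truth$ejm <- c(start = truth$c3[["end"]] + 1L,
                     end = tm_det$start - 1L)
    }
    cjm_end <- if (spec$cls == "RLK") kd_span[["start"]] - 1L else pos
    truth$cjm <- c(start = tm_det$end + 1L, end = cjm_end)
    truth$kd <- kd_span
    truth$gxxxg_chain <- spec$gxxxg_chain
    truth$ejm_net_charge <- spec$ejm_charge_target
    truth$ejm_terminal_charge <- spec$ejm_charge_target
  }

  list(sequence = sequence, truth = truth)
}
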