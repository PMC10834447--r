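# LRR ectodomain architecture: regions, NL/ID gap calls, ID+4LRR flag,
# and the C3/eJM/TM/cJM region split.

#' Group LRR motifs into LRR regions
#'
#' Adjacent motifs separated by fewer than \code{merge_lt} residues fall into
#' the same region; region boundaries are the outermost member-motif
#' coordinates.
#'
#' @param motif_spans Data.frame with columns \code{start}, \code{end},
#'   sorted and non-overlapping.
#' @param merge_lt Strict upper bound on the inter-motif distance within a
#'   region (residues).
#' @return Data.frame with columns \code{start}, \code{end},
#'   \code{n_motifs}, \code{first_motif}, \code{last_motif} (motif indices).
#' @export
group_regions <- function(motif_spans, merge_lt = 13L) {
  n <- nrow(motif_spans)
  stopifnot(n >= 1L)
  if (is.unsorted(motif_spans$start))
    stop("motif spans must be sorted by start")
  if (n > 1L && any(motif_spans$start[-1] <= motif_spans$end[-n]))
    stop("overlapping motif spans")
  gap_before <- c(Inf, motif_spans$start[-1] - motif_spans$end[-n] - 1L)
  region_id <- cumsum(gap_before >= merge_lt)
  idx <- split(seq_len(n), region_id)
  do.call(rbind, lapply(idx, function(i) data.frame(
    start = min(motif_spans$start[i]),
    end = max(motif_spans$end[i]),
    n_motifs = length(i),
    first_motif = min(i),
    last_motif = max(i)
  ))) -> out
  rownames(out) <- NULL
  out
}

#' Call NL and ID gaps between LRR regions
#'
#' Every stretch between consecutive LRR regions becomes a gap call.  Gaps of
#' 15--29 residues are N-loopouts (NL), gaps of 30--90 residues are island
#' domains (ID), anything else is NONE.  By default only inter-motif gaps are
#' candidates; set \code{include_terminal_gaps} in the configuration (and
#' supply \code{ecto_span}) to also call the stretches before the first and
#' after the last motif.
#'
#' @param regions Output of [group_regions()].
#' @param config Analysis configuration.
#' @param ecto_span Optional c(start, end) of the ectodomain, required only
#'   for terminal gap calling.
#' @return Data.frame with columns \code{start}, \code{end}, \code{length},
#'   \code{gap_class}, \code{terminal} (logical).
#' @export
call_gaps <- function(regions, config = analysis_config(),
                      ecto_span = NULL) {
  stopifnot(nrow(regions) >= 1L)
  starts <- integer(0); ends <- integer(0); terminal <- logical(0)
  k <- nrow(regions)
  if (k > 1L) {
    starts <- regions$end[-k] + 1L
    ends <- regions$start[-1] - 1L
    terminal <- rep(FALSE, k - 1L)
  }
  if (config$include_terminal_gaps && !is.null(ecto_span)) {
    if (regions$start[1] > ecto_span[1]) {
      starts <- c(ecto_span[1], starts)
      ends <- c(regions$start[1] - 1L, ends)
      terminal <- c(TRUE, terminal)
    }
    if (regions$end[k] < ecto_span[2]) {
      starts <- c(starts, regions$end[k] + 1L)
      ends <- c(ends, ecto_span[2])
      terminal <- c(terminal, TRUE)
    }
  }
  len <- ends - starts + 1L
  cls <- rep("NONE", length(len))
  cls[len >= config$nl_min & len <= config$nl_max] <- "NL"
  cls[len >= config$id_min & len <= config$id_max] <- "ID"
  out <- data.frame(start = starts, end = ends, length = len,
                    gap_class = cls, terminal = terminal,
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

#' Screen a gap sequence for residual LRR motifs
#'
#' Only NL/ID gaps without any internal LRR match are kept in the final
#' data set; a gap containing an LRR motif is a detector artefact rather
#' than a genuine insertion.
#'
#' @param gap_sequence Amino-acid string of the gap.
#' @param lrr_detector Function mapping a sequence to a data.frame of LRR
#'   calls (defaults to [detect_lrr()]).
#' @return \code{TRUE} to keep the gap, \code{FALSE} to drop it.
#' @export
screen_gap <- function(gap_sequence, lrr_detector = detect_lrr) {
  if (nchar(gap_sequence) == 0L) return(TRUE)
  nrow(lrr_detector(gap_sequence)) == 0L
}

#' Annotate gaps with motif counts and set the ID+4LRR flag
#'
#' For each gap, \code{n1} counts LRR motifs N-terminal and \code{n2} motifs
#' C-terminal of the gap.  The ID+4LRR architecture flag is set when some
#' surviving (screen-passing) island domain is followed by exactly
#' \code{id4_n2} motifs (default 4); with \code{id4_le = TRUE} in the
#' configuration, at most that many.
#'
#' @param gaps Gap data.frame with \code{passed_lrr_screen} populated.
#' @param motif_spans The ectodomain motif spans.
#' @param config Analysis configuration.
#' @return List with the updated \code{gaps} (columns \code{n1}, \code{n2}
#'   added) and the logical \code{id_plus_4lrr}.
#' @export
locate_ids <- function(gaps, motif_spans, config = analysis_config()) {
  n_motifs <- nrow(motif_spans)
  if (nrow(gaps) == 0L) {
    gaps$n1 <- integer(0); gaps$n2 <- integer(0)
    return(list(gaps = gaps, id_plus_4lrr = FALSE))
  }
  gaps$n1 <- vapply(gaps$start, function(s)
    sum(motif_spans$end < s), integer(1))
  gaps$n2 <- n_motifs - gaps$n1
  surviving_id <- gaps$gap_class == "ID" & gaps$passed_lrr_screen
  flag <- if (config$id4_le) {
    any(surviving_id & gaps$n2 <= config$id4_n2)
  } else {
    any(surviving_id & gaps$n2 == config$id4_n2)
  }
  list(gaps = gaps, id_plus_4lrr = flag)
}

#' Extract the C3, eJM, TM, and cJM regions
#'
#' The C3 region spans the last four LRR motifs of the ectodomain; the eJM
#' is the (possibly empty) stretch between the C3 and the TM; the cJM runs
#' from the TM to the start of the kinase domain for RLKs (configuration
#' \code{cjm_mode}) or to the C terminus for RLPs.
#'
#' @param record Protein record.
#' @param motif_spans Ectodomain motif spans (>= 4 rows required).
#' @param tm_call One-row data.frame of the TM C-terminal of the ectodomain.
#' @param kd_call One-row kinase call or \code{NULL} (RLPs).
#' @param config Analysis configuration.
#' @return List of spans \code{c3}, \code{ejm}, \code{tm}, \code{cjm}
#'   (each \code{c(start, end)}; \code{ejm}/\code{cjm} may be \code{NULL}
#'   when empty) and the corresponding \code{*_seq} strings.
#' @export
extract_regions <- function(record, motif_spans, tm_call, kd_call = NULL,
                            config = analysis_config()) {
  n <- nrow(motif_spans)
  if (n < 4L) stop("C3 undefined: protein ", record$id,
                   " has only ", n, " LRR motifs")
  if (tm_call$start <= min(motif_spans$start))
    stop("TM is N-terminal of all LRR motifs in protein ", record$id)
  c3 <- c(start = motif_spans$start[n - 3L], end = motif_spans$end[n])
  ejm <- NULL
  if (c3[["end"]] + 1L <= tm_call$start - 1L)
    ejm <- c(start = c3[["end"]] + 1L, end = tm_call$start - 1L)
  tm <- c(start = tm_call$start, end = tm_call$end)
  cjm_end <- if (!is.null(kd_call) && config$cjm_mode == "to_kd") {
    kd_call$start - 1L
  } else {
    record$length
  }
  cjm <- NULL
  if (tm_call$end + 1L <= cjm_end)
    cjm <- c(start = tm_call$end + 1L, end = cjm_end)
  sub <- function(span) if (is.null(span)) "" else
    substr(record$sequence, span[["start"]], span[["end"]])
  list(c3 = c3, ejm = ejm, tm = tm, cjm = cjm,
       c3_seq = sub(c3), ejm_seq = sub(ejm), tm_seq = sub(tm),
       cjm_seq = sub(cjm))
}

#' Parse the full LRR architecture of one annotated receptor
#'
#' Composes [group_regions()], [call_gaps()], [screen_gap()],
#' [locate_ids()], and (when at least four motifs and a C-terminal TM are
#' present) [extract_regions()] for one protein.  For RLK/RLP proteins only
#' LRR motifs inside the ectodomain are considered; for ectodomain-only
#' proteins all motifs count.
#'
#' @param record Protein record.
#' @param annotation Output of [annotate_protein()] for the record.
#' @param config Analysis configuration.
#' @return List of class \code{"architecture_profile"}: \code{protein_id},
#'   \code{motif_spans}, \code{regions}, \code{gaps} (with sequences, screen
#'   results, n1/n2), \code{id_plus_4lrr}, and the C3/eJM/TM/cJM spans and
#'   sequences (NULL where undefined), or \code{NULL} when the protein has
#'   no ectodomain LRR motifs.
#' @export
architecture_profile <- function(record, annotation,
                                 config = analysis_config()) {
  cls <- annotation$classification
  calls <- annotation$calls
  lrr <- calls[calls$kind == "LRR", , drop = FALSE]
  ecto_span <- NULL
  if (cls$cls %in% c("RLK", "RLP")) {
    ecto_span <- cls$ecto_span
    lrr <- lrr[lrr$start >= ecto_span[["start"]] &
                 lrr$start <= ecto_span[["end"]], , drop = FALSE]
  }
  if (nrow(lrr) == 0L) return(NULL)
  motif_spans <- data.frame(start = lrr$start, end = lrr$end)
  regions <- group_regions(motif_spans, config$merge_lt)
  gaps <- call_gaps(regions, config, ecto_span)
  if (nrow(gaps) > 0L) {
    gaps$sequence <- substring(record$sequence, gaps$start, gaps$end)
    gaps$passed_lrr_screen <- vapply(gaps$sequence, screen_gap, logical(1),
                                     USE.NAMES = FALSE)
  } else {
    gaps$sequence <- character(0)
    gaps$passed_lrr_screen <- logical(0)
  }
  located <- locate_ids(gaps, motif_spans, config)
  profile <- list(
    protein_id = record$id,
    motif_spans = motif_spans,
    regions = regions,
    gaps = located$gaps,
    id_plus_4lrr = located$id_plus_4lrr,
    c3 = NULL, ejm = NULL, tm = NULL, cjm = NULL,
    c3_seq = NULL, ejm_seq = NULL, tm_seq = NULL, cjm_seq = NULL
  )
  if (nrow(motif_spans) >= 4L && cls$cls %in% c("RLK", "RLP")) {
    tm_calls <- calls[calls$kind == "TM", , drop = FALSE]
    after <- tm_calls[tm_calls$start > max(motif_spans$end), , drop = FALSE]
    if (nrow(after) >= 1L) {
      tm_call <- after[which.min(after$start), ]
      kd <- calls[calls$kind == "KINASE", , drop = FALSE]
      kd_call <- if (nrow(kd) > 0L && cls$cls == "RLK") kd[1, ] else NULL
      reg <- extract_regions(record, motif_spans, tm_call, kd_call, config)
      profile[names(reg)] <- reg
    }
  }
  class(profile) <- "architecture_profile"
  profile
}
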