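# Receptor classification from domain calls, and the ecto/endodomain split.

validate_calls <- function(calls, length, id = "<protein>") {
  if (is.null(calls) || nrow(calls) == 0L) return(invisible(calls))
  if (any(calls$start < 1L) || any(calls$end > length) ||
      any(calls$start > calls$end))
    stop("inconsistent domain calls for protein ", id,
         ": span outside sequence bounds")
  for (kind in c("TM", "LRR")) {
    k <- calls[calls$kind == kind, , drop = FALSE]
    if (nrow(k) > 1L) {
      k <- k[order(k$start), ]
      if (any(k$start[-1] <= k$end[-nrow(k)]))
        stop("overlapping ", kind, " calls for protein ", id)
    }
  }
  invisible(calls)
}

#' Classify a protein as RLK, RLP, ectodomain-only, or other
#'
#' Receptor-like kinases (RLK) carry a kinase domain plus 1--2 transmembrane
#' segments; receptor-like proteins (RLP) carry 1--2 TMs but no kinase
#' domain; ectodomain-only proteins have LRRs but neither TM nor kinase
#' domain.  Proteins shorter than 150 residues are filtered, and
#' LRR-containing kinase+TM candidates additionally require 250 residues.
#'
#' @param record A one-row protein data.frame (or list) with \code{id},
#'   \code{sequence}, \code{length}.
#' @param calls Data.frame of domain calls for this protein.
#' @param config Analysis configuration, see [analysis_config()].
#' @return List of class \code{"receptor_classification"} with elements
#'   \code{cls}, \code{n_tm}, \code{has_kd}, \code{n_lrr},
#'   \code{filtered_reason} (NA when not filtered), and placeholder
#'   \code{ecto_span}/\code{endo_span} (filled by [split_ecto_endo()]).
#' @export
classify_receptor <- function(record, calls, config = analysis_config()) {
  len <- record$length
  validate_calls(calls, len, record$id)
  calls <- calls[order(calls$start), , drop = FALSE]
  n_tm <- sum(calls$kind == "TM")
  has_kd <- any(calls$kind == "KINASE")
  n_lrr <- sum(calls$kind == "LRR")
  cls <- "OTHER"; reason <- NA_character_
  if (len < config$min_len_other) {
    reason <- "min_length"
  } else if (n_tm > 2L) {
    reason <- "tm_count"
  } else if (has_kd && n_tm >= 1L) {
    if (n_lrr >= 1L && len < config$min_len_lrr_rlk) {
      reason <- "min_length"
    } else {
      cls <- "RLK"
    }
  } else if (!has_kd && n_tm >= 1L) {
    cls <- "RLP"
  } else if (!has_kd && n_tm == 0L && n_lrr >= 1L) {
    cls <- "ECTODOMAIN_ONLY"
  } else {
    reason <- "no_receptor_architecture"
  }
  structure(
    list(cls = cls, n_tm = n_tm, has_kd = has_kd, n_lrr = n_lrr,
         ecto_span = NULL, endo_span = NULL, filtered_reason = reason),
    class = "receptor_classification"
  )
}

#' Split a membrane receptor into ecto- and endodomain
#'
#' The maximal TM-free stretches of the protein are the candidate domains.
#' The ectodomain is the stretch containing the most LRR motifs; for RLKs it
#' is the stretch opposite the kinase domain (the kinase-bearing stretch is
#' the endodomain by definition).  The endodomain is otherwise the longest
#' remaining stretch.  Ties are broken toward the N-terminal stretch; for
#' two-TM proteins the tie-break is reported via the \code{tie} attribute.
#'
#' @param record Protein record (needs \code{length}, \code{id}).
#' @param calls Domain calls for the protein.
#' @param cls A \code{receptor_classification} with cls RLK or RLP.
#' @return List with integer vectors \code{ecto} and \code{endo}
#'   (start, end), either possibly \code{NULL} when a side is empty.
#' @export
split_ecto_endo <- function(record, calls, cls) {
  if (!cls$cls %in% c("RLK", "RLP") || cls$n_tm < 1L)
    stop("ecto/endo split requires an RLK or RLP with at least one TM (",
         record$id, ")")
  len <- record$length
  tm <- calls[calls$kind == "TM", , drop = FALSE]
  tm <- tm[order(tm$start), ]
  bounds_s <- c(1L, tm$end + 1L)
  bounds_e <- c(tm$start - 1L, len)
  keep <- bounds_s <= bounds_e
  segs <- data.frame(start = bounds_s[keep], end = bounds_e[keep])
  if (nrow(segs) < 2L)
    stop("cannot split protein ", record$id,
         ": fewer than two TM-free stretches")
  lrr <- calls[calls$kind == "LRR", , drop = FALSE]
  seg_of <- function(pos) which(segs$start <= pos & segs$end >= pos)
  lrr_counts <- vapply(seq_len(nrow(segs)), function(k)
    sum(lrr$start >= segs$start[k] & lrr$start <= segs$end[k]), integer(1))
  tie <- FALSE
  if (cls$cls == "RLK") {
    kd <- calls[calls$kind == "KINASE", , drop = FALSE]
    if (nrow(kd) == 0L) stop("RLK without kinase call: ", record$id)
    endo_i <- seg_of(kd$start[1])
    if (length(endo_i) != 1L)
      stop("kinase domain overlaps a TM in protein ", record$id)
    rest <- setdiff(seq_len(nrow(segs)), endo_i)
    best <- max(lrr_counts[rest])
    cand <- rest[lrr_counts[rest] == best]
    tie <- length(cand) > 1L
    ecto_i <- cand[1]
  } else {
    best <- max(lrr_counts)
    cand <- which(lrr_counts == best)
    tie <- length(cand) > 1L
    ecto_i <- cand[1]
    rest <- setdiff(seq_len(nrow(segs)), ecto_i)
    seg_len <- segs$end - segs$start + 1L
    endo_i <- rest[which.max(seg_len[rest])]
  }
  out <- list(
    ecto = c(start = segs$start[ecto_i], end = segs$end[ecto_i]),
    endo = c(start = segs$start[endo_i], end = segs$end[endo_i])
  )
  attr(out, "tie") <- tie
  out
}

#' Run all built-in detectors on one protein and classify it
#'
#' Detection order follows the published protocol: the signal peptide is
#' located first and masked so that it is never mistaken for a TM, then TM,
#' kinase, and LRR detection run, and the protein is classified.  When
#' external annotations are supplied for the protein they replace the
#' built-in detectors entirely.
#'
#' @param record One-row protein data.frame (id, species_id, sequence,
#'   length).
#' @param config Analysis configuration.
#' @param external Optional data.frame of external domain calls for this
#'   protein.
#' @return List with \code{calls} (data.frame) and \code{classification}
#'   (including \code{ecto_span}/\code{endo_span} for RLK/RLP).
#' @export
annotate_protein <- function(record, config = analysis_config(),
                             external = NULL) {
  if (!is.null(external)) {
    calls <- external
  } else {
    sequence <- record$sequence
    sp <- detect_signal_peptide(sequence)
    mask <- if (is.null(sp)) 0L else sp[["end"]]
    tm <- if (record$length >= config$tm_window) {
      detect_tm(sequence, config$tm_window, config$tm_threshold,
                mask_until = mask)
    } else empty_domain_calls()
    kd <- detect_kinase(sequence)
    lrr <- detect_lrr(sequence)
    calls <- rbind(
      if (!is.null(sp)) domain_call("SIGNAL", sp[["start"]], sp[["end"]]),
      tm, kd, lrr
    )
    if (is.null(calls)) calls <- empty_domain_calls()
  }
  cls <- classify_receptor(record, calls, config)
  if (cls$cls %in% c("RLK", "RLP") && cls$n_tm >= 1L) {
    spans <- split_ecto_endo(record, calls, cls)
    cls$ecto_span <- spans$ecto
    cls$endo_span <- spans$endo
  }
  list(calls = calls[order(calls$start), , drop = FALSE],
       classification = cls)
}
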