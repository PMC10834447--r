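# Rule-based domain detectors.  These are deliberately simple, deterministic
# stand-ins for the external predictors a full-scale survey would use
# (profile-HMM kinase search, dedicated TM and signal-peptide predictors,
# plant-LRR motif models); precomputed annotations can be supplied instead
# via load_external_annotations() and are treated identically downstream.

#' Detect transmembrane segments by hydropathy
#'
#' Slides a window over the sequence and keeps every window whose mean
#' Kyte--Doolittle hydropathy reaches \code{threshold}; overlapping qualifying
#' windows are merged into candidate segments.  Merged segments shorter than
#' 15 residues are dropped and segments longer than 35 residues are trimmed
#' to their maximal-scoring 21-mer, reflecting the physical length range of a
#' membrane-spanning helix.
#'
#' @param sequence Amino-acid string.
#' @param window Odd window width, >= 7 residues.
#' @param threshold Mean hydropathy a window must reach.
#' @param mask_until Residue index up to which the sequence is ignored
#'   (used to exclude a detected signal peptide); 0 scans everything.
#' @return Data.frame of TM domain calls (kind, start, end, score, source),
#'   sorted by start.  A sequence shorter than the window yields an empty
#'   result with a warning.
#' @export
detect_tm <- function(sequence, window = 19L, threshold = 1.6,
                      mask_until = 0L) {
  stopifnot(window >= 7L, window %% 2L == 1L)
  chars <- check_sequence(sequence)
  offset <- as.integer(mask_until)
  if (offset > 0L) chars <- chars[-seq_len(min(offset, length(chars)))]
  n <- length(chars)
  if (n < window) {
    warning("sequence shorter than TM window (", n, " < ", window,
            "); no TM search performed")
    return(empty_domain_calls())
  }
  h <- hydropathy_of(chars)
  wm <- window_means(h, window)
  hit <- which(wm >= threshold - HYDROPATHY_EPS)
  if (length(hit) == 0L) return(empty_domain_calls())
  merged <- merge_intervals(hit, hit + window - 1L)
  calls <- empty_domain_calls()
  for (k in seq_len(nrow(merged))) {
    s <- merged$start[k]; e <- merged$end[k]
    len <- e - s + 1L
    if (len < 15L) next
    if (len > 35L) {
      # trim to the maximal-scoring 21-mer inside the merged run
      sub <- h[s:e]
      m21 <- window_means(sub, 21L)
      best <- which.max(m21)          # leftmost maximum
      s2 <- s + best - 1L
      score <- m21[best]
      s <- s2; e <- s2 + 20L
    } else {
      score <- max(wm[max(1L, s):min(length(wm), e - window + 1L)])
    }
    calls <- rbind(calls, domain_call("TM", s + offset, e + offset, score))
  }
  calls[order(calls$start), , drop = FALSE]
}

#' Detect an N-terminal signal peptide
#'
#' Looks for a maximal run of residues with positive Kyte--Doolittle
#' hydropathy that begins within the first 10 residues, spans 7--15 residues,
#' and has mean hydropathy >= 2.0 (the hydrophobic h-region of a classical
#' signal peptide).  If found, the signal peptide is reported as residues 1
#' through the end of that run; downstream TM detection must mask this
#' interval.
#'
#' @param sequence Amino-acid string.
#' @return Integer vector \code{c(start = 1, end)} or \code{NULL} when no
#'   signal peptide is found.
#' @export
detect_signal_peptide <- function(sequence) {
  chars <- check_sequence(sequence)
  h <- hydropathy_of(chars)
  pos <- h > 0
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    s <- starts[k]; e <- ends[k]; len <- e - s + 1L
    if (s > 10L) break
    if (len >= 7L && len <= 15L && mean(h[s:e]) >= 2.0 - HYDROPATHY_EPS)
      return(c(start = 1L, end = as.integer(e)))
  }
  NULL
}

#' Detect a protein kinase domain by catalytic landmarks
#'
#' Searches for the ordered landmarks of the eukaryotic protein-kinase fold:
#' the glycine-rich loop (G-x-G-x-x-G), the beta-3 lysine within 30 residues
#' of it, the catalytic HRD motif, and the DFG motif of the activation
#' segment, all spanning 150--350 residues.  The span runs from the
#' glycine-rich loop to 30 residues past DFG (clipped to the sequence end).
#' When several candidate spans qualify, the most compact one is kept.
#'
#' @param sequence Amino-acid string.
#' @return A one-row data.frame domain call of kind KINASE, or \code{NULL}.
#' @export
detect_kinase <- function(sequence) {
  chars <- check_sequence(sequence)
  n <- length(chars)
  gstarts <- gregexpr("(?=G.G..G)", sequence, perl = TRUE)[[1]]
  if (gstarts[1] == -1L) return(NULL)
  kpos <- which(chars == "K")
  hrd <- gregexpr("HRD", sequence, fixed = TRUE)[[1]]
  dfg <- gregexpr("DFG", sequence, fixed = TRUE)[[1]]
  if (hrd[1] == -1L || dfg[1] == -1L) return(NULL)
  best <- NULL
  for (g in as.integer(gstarts)) {
    gend <- g + 5L
    k <- kpos[kpos > gend & kpos <= gend + 30L]
    if (length(k) == 0L) next
    k <- k[1]
    h <- hrd[hrd > k]
    if (length(h) == 0L) next
    h <- h[1]
    d <- dfg[dfg >= h + 3L]
    if (length(d) == 0L) next
    d <- d[1]
    span <- (d + 2L) - g + 1L
    if (span < 150L || span > 350L) next
    if (is.null(best) || span < best$span)
      best <- list(g = g, dfg_end = d + 2L, span = span)
  }
  if (is.null(best)) return(NULL)
  domain_call("KINASE", best$g, min(best$dfg_end + 30L, n),
              score = 1 / best$span)
}

#' Detect plant LRR motifs
#'
#' Greedy left-to-right, non-overlapping matches of the plant LRR core
#' pattern: hydrophobic residues (L/I/V/F/M) at core positions 1, 4, 6, 8 and
#' 13 and N/T/S/C at position 11 (the LxxLxLxxNxL consensus).  Each match is
#' reported as a 24-residue motif anchored at the core start, clipped at the
#' sequence end.
#'
#' @param sequence Amino-acid string.
#' @return Data.frame of LRR domain calls sorted by start.
#' @export
detect_lrr <- function(sequence) {
  chars <- check_sequence(sequence)
  n <- length(chars)
  if (n < 13L) return(empty_domain_calls())
  H <- chars %in% HYDROPHOBIC_CORE
  P <- chars %in% POLAR_CORE
  m <- n - 12L
  ok <- H[1:m] & H[4:(m + 3L)] & H[6:(m + 5L)] & H[8:(m + 7L)] &
    P[11:(m + 10L)] & H[13:(m + 12L)]
  cand <- which(ok)
  if (length(cand) == 0L) return(empty_domain_calls())
  starts <- integer(0)
  nxt <- 1L
  for (i in cand) {
    if (i >= nxt) {
      starts <- c(starts, i)
      nxt <- i + 24L
    }
  }
  domain_call("LRR", starts, pmin(starts + 23L, n))
}

#' Load externally computed domain annotations
#'
#' Reads a TSV of precomputed domain calls (for example converted from
#' dedicated TM/kinase/LRR/signal-peptide predictors) with columns
#' \code{protein_id}, \code{kind}, \code{start}, \code{end}, \code{score};
#' coordinates are 1-based inclusive.
#'
#' @param path TSV file path.
#' @return Named list mapping protein id to a data.frame of domain calls
#'   with \code{source = "external"}.
#' @export
load_external_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  need <- c("protein_id", "kind", "start", "end", "score")
  if (!all(need %in% names(tab)))
    stop("annotation TSV must have columns ", paste(need, collapse = ", "))
  if (nrow(tab) == 0L) return(list())
  kinds <- c("SIGNAL", "TM", "KINASE", "LRR")
  start <- suppressWarnings(as.integer(tab$start))
  end <- suppressWarnings(as.integer(tab$end))
  score <- suppressWarnings(as.numeric(tab$score))
  for (i in seq_len(nrow(tab))) {
    line <- i + 1L  # header is line 1
    if (!tab$kind[i] %in% kinds)
      stop("line ", line, ": unknown domain kind '", tab$kind[i], "'")
    if (is.na(start[i]) || is.na(end[i]))
      stop("line ", line, ": non-numeric coordinates")
    if (start[i] < 1L)
      stop("line ", line, ": coordinates are 1-based; start ", start[i],
           " is invalid")
    if (start[i] > end[i])
      stop("line ", line, ": start ", start[i], " > end ", end[i])
  }
  calls <- data.frame(kind = tab$kind, start = start, end = end,
                      score = score, source = "external",
                      stringsAsFactors = FALSE)
  split(calls, tab$protein_id)
}
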