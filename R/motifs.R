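# Diagnostic short-motif scanners for island domains (lysine motifs), the
# terminal LRR of the C3 (QxxT/S), the TM helix (GxxxG chains), and the
# juxtamembrane charge.  All matches, including overlapping ones, are
# reported: downstream summaries count presence, not multiplicity.

all_match_starts <- function(sequence, pattern) {
  m <- gregexpr(pattern, sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Scan an island domain for the conserved lysine motifs
#'
#' Kx5Y is a lysine followed by any five residues and a tyrosine; Yx8KG is a
#' tyrosine, any eight residues, then lysine-glycine.  Both motifs mark
#' island domains whose lysine contributes to co-receptor (BAK1) binding.
#'
#' @param id_sequence Island-domain amino-acid string.
#' @return List with \code{kx5y_positions}, \code{yx8kg_positions} (1-based
#'   match starts, possibly overlapping), and \code{has_either}.
#' @export
scan_lysine_motifs <- function(id_sequence) {
  kx5y <- all_match_starts(id_sequence, "(?=K.{5}Y)")
  yx8kg <- all_match_starts(id_sequence, "(?=Y.{8}KG)")
  list(kx5y_positions = kx5y, yx8kg_positions = yx8kg,
       has_either = length(kx5y) > 0L || length(yx8kg) > 0L)
}

#' Scan the terminal LRR motif for the QxxT/S loop
#'
#' QxxT/S is a glutamine, any two residues, then threonine or serine; the
#' residue immediately preceding the glutamine is reported because
#' receptor clades differ in it (TQxxx variants lack the canonical loop but
#' keep the preceding threonine).
#'
#' @param region_sequence Amino-acid string (the terminal LRR motif of the
#'   C3 region).
#' @return List with \code{positions} (match starts), \code{preceding}
#'   (character vector; \code{NA} for a match at position 1), and
#'   \code{has_tqxxx} (some glutamine directly preceded by threonine).
#' @export
scan_qxxts <- function(region_sequence) {
  pos <- all_match_starts(region_sequence, "(?=Q..[TS])")
  prev <- ifelse(pos > 1L,
                 substring(region_sequence, pos - 1L, pos - 1L),
                 NA_character_)
  has_tqxxx <- length(all_match_starts(region_sequence, "(?=TQ)")) > 0L
  list(positions = pos, preceding = as.character(prev),
       has_tqxxx = has_tqxxx)
}

#' Scan a TM helix for GxxxG motifs and their chains
#'
#' GxxxG is a glycine, any three residues, then glycine.  Consecutive motifs
#' sharing their terminal glycine (match starts four residues apart) form a
#' chain: GxxxGxxxG is a chain of two, GxxxGxxxGxxxG of three.
#'
#' @param tm_sequence TM amino-acid string.
#' @return List with \code{positions} (all match starts) and
#'   \code{chain_max} (longest chain, 0 when no motif).
#' @export
scan_gxxxg <- function(tm_sequence) {
  pos <- all_match_starts(tm_sequence, "(?=G...G)")
  if (length(pos) == 0L) return(list(positions = pos, chain_max = 0L))
  runs <- 1L
  best <- 1L
  if (length(pos) > 1L) {
    for (k in 2:length(pos)) {
      runs <- if (pos[k] - pos[k - 1L] == 4L) runs + 1L else 1L
      best <- max(best, runs)
    }
  }
  list(positions = pos, chain_max = best)
}

#' Net and terminal charge of the eJM region
#'
#' Charge is counted as (#K + #R) - (#D + #E); histidine is treated as
#' neutral.  The terminal charge uses the last \code{window} residues, the
#' stretch abutting the membrane that distinguishes negatively charged
#' RLP juxtamembranes from positively charged RLK ones.
#'
#' @param ejm_sequence eJM amino-acid string (may be empty).
#' @param window Terminal-window width, residues (>= 1).
#' @return List with \code{net_charge} and \code{terminal_charge}
#'   (both 0 for an empty region).
#' @export
ejm_charge <- function(ejm_sequence, window = 10L) {
  stopifnot(window >= 1L)
  n <- nchar(ejm_sequence)
  if (n == 0L) return(list(net_charge = 0L, terminal_charge = 0L))
  charge <- function(s) {
    ch <- seq_chars(s)
    as.integer(sum(ch %in% c("K", "R")) - sum(ch %in% c("D", "E")))
  }
  term <- substring(ejm_sequence, max(1L, n - window + 1L), n)
  list(net_charge = charge(ejm_sequence), terminal_charge = charge(term))
}

#' Full motif scan of one receptor architecture
#'
#' Applies the lysine-motif scan to every surviving island domain, the
#' QxxT/S scan to the terminal LRR motif of the C3, the GxxxG scan to the
#' TM, and the charge computation to the eJM.
#'
#' @param record Protein record.
#' @param profile An \code{architecture_profile}.
#' @param config Analysis configuration (terminal-charge window).
#' @return One-row data.frame with columns \code{protein_id},
#'   \code{n_kx5y}, \code{n_yx8kg}, \code{has_either_lysine},
#'   \code{n_qxxts}, \code{has_tqxxx}, \code{gxxxg_chain_max},
#'   \code{n_gxxxg}, \code{ejm_net_charge}, \code{ejm_terminal_charge},
#'   or \code{NULL} when the profile is \code{NULL}.
#' @export
motif_scan_report <- function(record, profile, config = analysis_config()) {
  if (is.null(profile)) return(NULL)
  ids <- profile$gaps[profile$gaps$gap_class == "ID" &
                        profile$gaps$passed_lrr_screen, , drop = FALSE]
  lys <- lapply(ids$sequence, scan_lysine_motifs)
  n_kx5y <- sum(vapply(lys, function(x) length(x$kx5y_positions), integer(1)))
  n_yx8kg <- sum(vapply(lys, function(x) length(x$yx8kg_positions), integer(1)))
  has_either <- any(vapply(lys, function(x) x$has_either, logical(1)))
  n_qxxts <- NA_integer_; has_tqxxx <- NA
  if (!is.null(profile$c3)) {
    n <- nrow(profile$motif_spans)
    last_motif <- substr(record$sequence, profile$motif_spans$start[n],
                         profile$motif_spans$end[n])
    q <- scan_qxxts(last_motif)
    n_qxxts <- length(q$positions)
    has_tqxxx <- q$has_tqxxx
  }
  chain_max <- NA_integer_; n_gxxxg <- NA_integer_
  if (!is.null(profile$tm_seq)) {
    g <- scan_gxxxg(profile$tm_seq)
    chain_max <- g$chain_max
    n_gxxxg <- length(g$positions)
  }
  net <- NA_integer_; term <- NA_integer_
  if (!is.null(profile$tm_seq)) {
    ch <- ejm_charge(profile$ejm_seq %||% "", config$charge_window)
    net <- ch$net_charge
    term <- ch$terminal_charge
  }
  data.frame(protein_id = record$id,
             n_kx5y = n_kx5y, n_yx8kg = n_yx8kg,
             has_either_lysine = has_either,
             n_qxxts = n_qxxts, has_tqxxx = has_tqxxx,
             gxxxg_chain_max = chain_max, n_gxxxg = n_gxxxg,
             ejm_net_charge = net, ejm_terminal_charge = term,
             stringsAsFactors = FALSE)
}
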