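#' Analysis configuration
#'
#' Bundles every tunable constant of the receptor pipeline in one validated
#' list.  Defaults correspond to the published analysis protocol: LRR motifs
#' less than 13 residues apart are merged into one LRR region, inter-motif
#' gaps of 15--29 residues are N-loopout (NL) candidates and gaps of 30--90
#' residues are island-domain (ID) candidates, the ID+4LRR architecture
#' requires exactly four LRR motifs C-terminal of a surviving ID, proteins
#' shorter than 150 residues are discarded (250 for LRR-kinase candidates),
#' cophenetic distances below 0.2 substitutions/site become network edges,
#' Pearson r above 0.6 counts as a strong family co-expansion and r in
#' [0.3, 0.6] as medium, and Mantel tests use 10,000 permutations.
#'
#' @param merge_lt Motifs closer than this many residues fall in one LRR
#'   region (strictly less-than).
#' @param nl_min,nl_max Inclusive length range of N-loopout gaps, residues.
#' @param id_min,id_max Inclusive length range of island-domain gaps, residues.
#' @param id4_n2 Number of LRR motifs that must follow an ID for the
#'   ID+4LRR flag.
#' @param id4_le If \code{TRUE}, flag IDs with \emph{at most} \code{id4_n2}
#'   following motifs instead of exactly that many.
#' @param min_len_other Minimum protein length (residues) for any candidate.
#' @param min_len_lrr_rlk Minimum length for LRR-containing kinase+TM
#'   candidates.
#' @param tm_window Sliding-window width for transmembrane detection
#'   (odd, >= 7 residues).
#' @param tm_threshold Mean Kyte--Doolittle hydropathy a window must reach.
#' @param charge_window Width of the terminal-charge window at the end of the
#'   eJM region, residues.
#' @param cophenetic_cutoff Distance below which tree leaves are connected in
#'   the similarity network (substitutions/site, strict less-than).
#' @param similarity How distances convert to edge weights:
#'   \code{"relative"} gives 1 - d/cutoff, \code{"linear"} gives 1 - d.
#' @param r_strong,r_medium Pearson-r class boundaries for co-expansion
#'   strength.
#' @param n_perm Mantel permutation count.
#' @param include_terminal_gaps Whether gaps before the first or after the
#'   last LRR motif are NL/ID candidates (default off: only inter-motif gaps
#'   are called).
#' @param cjm_mode For RLKs, whether the cJM region ends at the residue
#'   before the kinase domain (\code{"to_kd"}) or runs to the C terminus
#'   (\code{"to_cterm"}).
#' @param seed Integer seed from which all stage seeds derive.
#' @return A list of class \code{"lrr_config"}.
#' @export
analysis_config <- function(merge_lt = 13L,
                            nl_min = 15L, nl_max = 29L,
                            id_min = 30L, id_max = 90L,
                            id4_n2 = 4L, id4_le = FALSE,
                            min_len_other = 150L,
                            min_len_lrr_rlk = 250L,
                            tm_window = 19L, tm_threshold = 1.6,
                            charge_window = 10L,
                            cophenetic_cutoff = 0.2,
                            similarity = c("relative", "linear"),
                            r_strong = 0.6, r_medium = 0.3,
                            n_perm = 10000L,
                            include_terminal_gaps = FALSE,
                            cjm_mode = c("to_kd", "to_cterm"),
                            seed = 1L) {
  similarity <- match.arg(similarity)
  cjm_mode <- match.arg(cjm_mode)
  stopifnot(
    merge_lt >= 1, nl_min >= 1, nl_min <= nl_max,
    id_min <= id_max, nl_max < id_min,
    id4_n2 >= 1,
    min_len_other >= 1, min_len_lrr_rlk >= min_len_other,
    tm_window >= 7, tm_window %% 2 == 1,
    charge_window >= 1,
    cophenetic_cutoff > 0,
    r_medium > 0, r_medium < r_strong, r_strong < 1,
    n_perm >= 1
  )
  structure(
    list(
      merge_lt = as.integer(merge_lt),
      nl_min = as.integer(nl_min), nl_max = as.integer(nl_max),
      id_min = as.integer(id_min), id_max = as.integer(id_max),
      id4_n2 = as.integer(id4_n2), id4_le = isTRUE(id4_le),
      min_len_other = as.integer(min_len_other),
      min_len_lrr_rlk = as.integer(min_len_lrr_rlk),
      tm_window = as.integer(tm_window), tm_threshold = tm_threshold,
      charge_window = as.integer(charge_window),
      cophenetic_cutoff = cophenetic_cutoff,
      similarity = similarity,
      r_strong = r_strong, r_medium = r_medium,
      n_perm = as.integer(n_perm),
      include_terminal_gaps = isTRUE(include_terminal_gaps),
      cjm_mode = cjm_mode,
      seed = as.integer(seed)
    ),
    class = "lrr_config"
  )
}

#' @export
print.lrr_config <- function(x, ...) {
  cat("lrrscape analysis configuration\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}
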