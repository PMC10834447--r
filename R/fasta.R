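#' Read protein FASTA files into a protein table
#'
#' Each file is read with \pkg{Biostrings}; record ids are truncated at the
#' first whitespace.  The species id is taken from the file name (without
#' extension) unless a manifest maps file paths to species explicitly.
#'
#' @param paths Character vector of FASTA file paths.
#' @param species_ids Optional character vector, one per path, overriding the
#'   file-name-derived species id.
#' @return A data.frame with columns \code{id}, \code{species_id},
#'   \code{sequence}, \code{length}.  Sequences are validated against the
#'   uppercase 20-letter amino-acid alphabet plus X.
#' @export
read_proteins <- function(paths, species_ids = NULL) {
  stopifnot(length(paths) >= 1L)
  if (!is.null(species_ids) && length(species_ids) != length(paths))
    stop("species_ids must match paths in length")
  out <- vector("list", length(paths))
  for (k in seq_along(paths)) {
    p <- paths[k]
    if (!file.exists(p)) stop("FASTA file not found: ", p)
    aas <- Biostrings::readAAStringSet(p)
    if (length(aas) == 0L) stop("no records in FASTA file: ", p)
    ids <- sub("\\s.*$", "", names(aas))
    seqs <- toupper(as.character(aas))
    sp <- if (is.null(species_ids)) {
      sub("\\.(fa|fasta|faa)$", "", basename(p), ignore.case = TRUE)
    } else species_ids[k]
    for (i in seq_along(seqs)) check_sequence(seqs[i], ids[i])
    out[[k]] <- data.frame(id = ids, species_id = sp, sequence = unname(seqs),
                           length = nchar(seqs), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write sequences to a FASTA file
#'
#' @param ids Character vector of record ids.
#' @param sequences Character vector of amino-acid sequences.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(ids, sequences, path) {
  stopifnot(length(ids) == length(sequences))
  aas <- Biostrings::AAStringSet(sequences)
  names(aas) <- ids
  Biostrings::writeXStringSet(aas, filepath = path)
  invisible(path)
}
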