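# Stage orchestration: annotate -> architecture -> motifs over whole
# proteomes, the evolution report, TSV output, and the run manifest.

span_or_na <- function(span) {
  if (is.null(span)) c(NA_integer_, NA_integer_) else
    c(span[["start"]], span[["end"]])
}

#' Annotate, parse, and motif-scan a set of proteomes
#'
#' Runs the full per-protein pipeline (signal-peptide masking, TM, kinase,
#' and LRR detection, classification, ecto/endo split, architecture
#' parsing, motif scanning) over protein FASTA files or an in-memory
#' protein table.  A failure on one protein is logged and skipped, never
#' aborting the run.
#'
#' @param proteins Data.frame from [read_proteins()], or a character vector
#'   of FASTA paths.
#' @param config Analysis configuration.
#' @param external Optional named list (protein id to data.frame) of
#'   external domain calls, see [load_external_annotations()].
#' @param out_dir Optional directory; when given, TSV outputs, per-gap ID
#'   FASTA, and a manifest are written there.
#' @return List with data.frames \code{classifications}, \code{gaps},
#'   \code{architectures}, \code{motifs}, and (when \code{out_dir} is
#'   given) \code{manifest}.
#' @export
run_annotate_arch_motifs <- function(proteins,
                                     config = analysis_config(),
                                     external = NULL, out_dir = NULL) {
  if (is.character(proteins)) proteins <- read_proteins(proteins)
  if (nrow(proteins) == 0L) stop("no parseable protein records")
  cls_rows <- list(); gap_rows <- list(); arch_rows <- list()
  motif_rows <- list(); failures <- character(0)
  for (i in seq_len(nrow(proteins))) {
    record <- proteins[i, ]
    res <- tryCatch({
      ext <- if (!is.null(external)) external[[record$id]] else NULL
      ann <- suppressWarnings(annotate_protein(record, config, ext))
      profile <- if (ann$classification$cls %in%
                     c("RLK", "RLP", "ECTODOMAIN_ONLY")) {
        architecture_profile(record, ann, config)
      } else NULL
      list(ann = ann, profile = profile)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message("skipping protein ", record$id, ": ", conditionMessage(res))
      failures <- c(failures, record$id)
      next
    }
    cls <- res$ann$classification
    ecto <- span_or_na(cls$ecto_span); endo <- span_or_na(cls$endo_span)
    cls_rows[[i]] <- data.frame(
      protein_id = record$id, species_id = record$species_id,
      class = cls$cls, n_tm = cls$n_tm, has_kd = cls$has_kd,
      n_lrr = cls$n_lrr,
      ecto_start = ecto[1], ecto_end = ecto[2],
      endo_start = endo[1], endo_end = endo[2],
      filtered_reason = cls$filtered_reason %||% NA_character_,
      stringsAsFactors = FALSE)
    profile <- res$profile
    if (!is.null(profile)) {
      c3 <- span_or_na(profile$c3); ejm <- span_or_na(profile$ejm)
      tm <- span_or_na(profile$tm); cjm <- span_or_na(profile$cjm)
      arch_rows[[i]] <- data.frame(
        protein_id = record$id,
        n_motifs = nrow(profile$motif_spans),
        n_regions = nrow(profile$regions),
        n_gaps = nrow(profile$gaps),
        id_plus_4lrr = profile$id_plus_4lrr,
        c3_start = c3[1], c3_end = c3[2],
        ejm_start = ejm[1], ejm_end = ejm[2],
        tm_start = tm[1], tm_end = tm[2],
        cjm_start = cjm[1], cjm_end = cjm[2],
        stringsAsFactors = FALSE)
      if (nrow(profile$gaps) > 0L) {
        g <- profile$gaps
        g$protein_id <- record$id
        gap_rows[[i]] <- g[, c("protein_id", "start", "end", "length",
                               "gap_class", "n1", "n2",
                               "passed_lrr_screen", "sequence")]
      }
      mr <- motif_scan_report(record, profile, config)
      if (!is.null(mr)) motif_rows[[i]] <- mr
    }
  }
  if (length(cls_rows) == 0L)
    stop("no protein could be annotated")
  bind <- function(rows, empty) {
    rows <- Filter(Negate(is.null), rows)
    if (length(rows) == 0L) return(empty)
    out <- do.call(rbind, rows); rownames(out) <- NULL; out
  }
  result <- list(
    classifications = bind(cls_rows, NULL),
    architectures = bind(arch_rows, NULL),
    gaps = bind(gap_rows, NULL),
    motifs = bind(motif_rows, NULL),
    failures = failures
  )
  if (!is.null(out_dir)) {
    result$manifest <- write_stage_outputs(result, config, out_dir)
  }
  result
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  path
}

write_stage_outputs <- function(result, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  paths <- c(paths, write_tsv(result$classifications,
                              file.path(out_dir, "classifications.tsv")))
  if (!is.null(result$architectures))
    paths <- c(paths, write_tsv(result$architectures,
                                file.path(out_dir, "architectures.tsv")))
  if (!is.null(result$gaps)) {
    paths <- c(paths, write_tsv(result$gaps,
                                file.path(out_dir, "gaps.tsv")))
    ids <- result$gaps[result$gaps$gap_class == "ID" &
                         result$gaps$passed_lrr_screen, , drop = FALSE]
    if (nrow(ids) > 0L) {
      fa <- file.path(out_dir, "island_domains.fasta")
      write_fasta(sprintf("%s_ID_%d-%d", ids$protein_id, ids$start,
                          ids$end),
                  ids$sequence, fa)
      paths <- c(paths, fa)
    }
  }
  if (!is.null(result$motifs))
    paths <- c(paths, write_tsv(result$motifs,
                                file.path(out_dir, "motifs.tsv")))
  manifest <- data.frame(
    file = basename(paths),
    md5 = unname(tools::md5sum(paths)),
    stringsAsFactors = FALSE)
  cfg <- vapply(config, function(x) paste(x, collapse = ","),
                character(1))
  write_tsv(data.frame(key = names(cfg), value = unname(cfg)),
            file.path(out_dir, "config.tsv"))
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  manifest
}

#' Expansion, correlation, and significance report for a lineage panel
#'
#' For each configured baseline-to-target lineage pair, computes per-species
#' family expansion rates; optionally correlates every family with a target
#' family, runs Mantel tests on supplied distance-matrix pairs (with BH-FDR
#' across them), and Fisher tests on supplied 2x2 tables.
#'
#' @param counts Data.frame with columns species_id, family, count,
#'   n_searched, and either a lineage column or a \code{lineage_map}.
#' @param pairs List of c(baseline_lineage, target_lineage) pairs.
#' @param lineage_map Optional data.frame (species_id, lineage).
#' @param target_family Optional family name for co-expansion correlations.
#' @param mantel_pairs Optional named list of list(D1, D2) distance-matrix
#'   pairs.
#' @param fisher_tables Optional named list of c(a, b, c, d) count vectors.
#' @param config Analysis configuration (seed, permutation count, strength
#'   boundaries).
#' @return List with \code{expansion}, \code{correlation},
#'   \code{mantel} (data.frame with fdr_q), \code{fisher}.
#' @export
run_evolution_report <- function(counts, pairs, lineage_map = NULL,
                                 target_family = NULL,
                                 mantel_pairs = NULL,
                                 fisher_tables = NULL,
                                 config = analysis_config()) {
  if (!is.null(lineage_map)) {
    counts$lineage <- lineage_map$lineage[
      match(counts$species_id, lineage_map$species_id)]
  }
  if (!"lineage" %in% names(counts))
    stop("counts needs a lineage column or a lineage_map")
  if (anyNA(counts$lineage)) {
    missing <- unique(counts$species_id[is.na(counts$lineage)])
    stop("species missing from lineage map: ",
         paste(missing, collapse = ", "))
  }
  expansion <- do.call(rbind, lapply(pairs, function(pr) {
    ex <- expansion_table(counts, pr[1], pr[2])
    ex$target_lineage <- pr[2]
    ex
  }))
  correlation <- NULL
  if (!is.null(target_family)) {
    counts$pct <- family_percentage(counts$count, counts$n_searched)
    wide <- stats::reshape(
      counts[, c("species_id", "family", "pct")],
      idvar = "species_id", timevar = "family", direction = "wide")
    names(wide) <- sub("^pct\\.", "", names(wide))
    rownames(wide) <- wide$species_id
    wide$species_id <- NULL
    correlation <- correlate_with_family(wide, target_family, config)
  }
  mantel <- NULL
  if (!is.null(mantel_pairs)) {
    res <- lapply(seq_along(mantel_pairs), function(k) {
      mp <- mantel_pairs[[k]]
      m <- mantel_test(mp[[1]], mp[[2]], n_perm = config$n_perm,
                       seed = config$seed + k)
      data.frame(test = names(mantel_pairs)[k] %||% as.character(k),
                 r = m$r, p = m$p, n_perm = m$n_perm,
                 stringsAsFactors = FALSE)
    })
    mantel <- do.call(rbind, res)
    mantel$fdr_q <- bh_fdr(mantel$p)
  }
  fisher <- NULL
  if (!is.null(fisher_tables)) {
    res <- lapply(seq_along(fisher_tables), function(k) {
      tb <- fisher_tables[[k]]
      f <- fisher_2x2(tb[1], tb[2], tb[3], tb[4])
      data.frame(test = names(fisher_tables)[k] %||% as.character(k),
                 odds_ratio = f$odds_ratio, p = f$p_two_sided,
                 stringsAsFactors = FALSE)
    })
    fisher <- do.call(rbind, res)
  }
  list(expansion = expansion, correlation = correlation,
       mantel = mantel, fisher = fisher)
}
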