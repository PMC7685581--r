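#' Taxa detected in a sample
#'
#' Labels (at the chosen taxonomic rank) of the OTUs present in a sample:
#' relative abundance strictly positive and at least `min_rel_abund`.
#' Multiple OTUs collapsing to the same rank label are deduplicated.
#' Genus is the default matching rank — 16S OTUs rarely resolve species —
#' with species-level matching available via `rank = "species"`.
#'
#' @param table an [otu_table] with taxonomy.
#' @param sample_id sample to inspect.
#' @param min_rel_abund detection threshold on relative abundance
#'   (default 0: any positive abundance counts as detected).
#' @param rank rank at which OTU lineages are collapsed to taxon labels.
#' @return Character vector of normalized taxon labels (e.g.
#'   `"g__rhodococcus"`); OTUs with no assignment at `rank` are dropped.
#' @export
detected_taxa <- function(table, sample_id, min_rel_abund = 0, rank = "genus") {
  stopifnot(inherits(table, "otu_table"))
  if (is.null(table$taxonomy))
    stop_pathpls("pathpls_validation_error", "OTU table has no taxonomy")
  if (!sample_id %in% sample_ids(table))
    stop_pathpls("pathpls_lookup_error", "unknown sample id: %s", sample_id)
  relm <- as_relative_values(table)
  rel <- stats::setNames(relm[sample_id, ], colnames(relm))
  present <- names(rel)[rel > 0 & rel >= min_rel_abund]
  present <- present[present %in% names(table$taxonomy)]
  labels <- vapply(table$taxonomy[present], taxon_at_rank, "", rank = rank)
  unique(labels[!is.na(labels)])
}

#' Community-wide non-redundant KO set
#'
#' Union of the KO sets of the matched taxa — the orthology-level
#' abstraction of pooling every species' proteins into one non-redundant
#' dataset per sample. With `rank_fallback`, a label that misses the
#' database is retried at progressively coarser ranks (species -> genus ->
#' family), which requires full lineage strings rather than bare labels.
#'
#' @param taxa character vector of taxon labels (or lineage strings when
#'   fallback matching is wanted).
#' @param db an [annotation_db].
#' @param rank_fallback retry unmatched labels at coarser ranks.
#' @return Character vector of KO ids, with attribute `"match_report"`:
#'   data.frame (taxon, status in matched/fallback/unmatched, matched_label).
#' @export
sample_ko_set <- function(taxa, db, rank_fallback = FALSE) {
  stopifnot(inherits(db, "annotation_db"))
  if (length(taxa) == 0L)
    stop_pathpls("pathpls_degenerate_error", "no taxa supplied")
  report <- data.frame(taxon = taxa, status = "unmatched",
                       matched_label = NA_character_, stringsAsFactors = FALSE)
  kos <- character()
  for (i in seq_along(taxa)) {
    lab <- normalize_taxon_label(taxa[i])
    if (lab %in% names(db$sets)) {
      kos <- c(kos, db$sets[[lab]])
      report$status[i] <- "matched"
      report$matched_label[i] <- lab
      next
    }
    if (rank_fallback && grepl(";", taxa[i], fixed = TRUE)) {
      lin <- parse_lineage(taxa[i])
      for (rk in c("species", "genus", "family")) {
        cand <- taxon_at_rank(lin, rk)
        if (!is.na(cand) && cand %in% names(db$sets)) {
          kos <- c(kos, db$sets[[cand]])
          report$status[i] <- "fallback"
          report$matched_label[i] <- cand
          break
        }
      }
    }
  }
  if (!any(report$status != "unmatched"))
    warning("no taxon matched the annotation database", call. = FALSE)
  out <- sort(unique(kos))
  attr(out, "match_report") <- report
  out
}

#' Pathway completeness
#'
#' The fraction of a pathway's required KOs detected in a sample's KO set:
#' `|kos intersect pathway_kos| / |pathway_kos|`. Exactly 1 iff the sample
#' KO set covers the pathway; always a rational with the pathway size as
#' denominator.
#'
#' @param kos character vector of detected KO ids.
#' @param pathway_kos non-empty character vector of the pathway's KO ids.
#' @export
pathway_completeness <- function(kos, pathway_kos) {
  pathway_kos <- unique(pathway_kos)
  if (length(pathway_kos) == 0L)
    stop_pathpls("pathpls_validation_error", "pathway KO set is empty")
  length(intersect(unique(kos), pathway_kos)) / length(pathway_kos)
}

#' Completeness matrix over samples and pathways
#'
#' Runs [detected_taxa] -> [sample_ko_set] -> [pathway_completeness] for
#' every sample against every catalog pathway. Deterministic given the
#' inputs and invariant to the row/column order of `table`.
#'
#' @param table an [otu_table] with taxonomy.
#' @param db an [annotation_db].
#' @param catalog a [pathway_catalog].
#' @param min_rel_abund detection threshold passed to [detected_taxa].
#' @param rank matching rank.
#' @param rank_fallback passed to [sample_ko_set].
#' @return samples x pathways numeric matrix in `[0,1]`, with attributes
#'   `"ko_set_size"` (named integer per sample) and `"match_reports"`.
#'   A sample whose taxa all miss the database yields an all-zero row
#'   (with a warning).
#' @export
completeness_matrix <- function(table, db, catalog, min_rel_abund = 0,
                                rank = "genus", rank_fallback = FALSE) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  smp <- sample_ids(table)
  out <- matrix(0, length(smp), length(catalog$ids),
                dimnames = list(smp, catalog$ids))
  ko_n <- stats::setNames(integer(length(smp)), smp)
  reports <- list()
  for (s in smp) {
    taxa <- detected_taxa(table, s, min_rel_abund = min_rel_abund, rank = rank)
    if (length(taxa) == 0L) {
      warning(sprintf("sample %s: no detected taxa above threshold", s),
              call. = FALSE)
      next
    }
    kos <- withCallingHandlers(
      sample_ko_set(taxa, db, rank_fallback = rank_fallback),
      warning = function(w) {
        warning(sprintf("sample %s: %s", s, conditionMessage(w)), call. = FALSE)
        invokeRestart("muffleWarning")
      })
    reports[[s]] <- attr(kos, "match_report")
    ko_n[s] <- length(kos)
    out[s, ] <- vapply(catalog$ko_sets, function(pk) pathway_completeness(kos, pk),
                       0)
  }
  attr(out, "ko_set_size") <- ko_n
  attr(out, "match_reports") <- reports
  out
}

#' Pathways above a completeness threshold
#'
#' Aggregates each pathway's completeness across samples (mean or min) and
#' returns those at or above `threshold`, sorted by decreasing aggregate
#' then pathway id.
#'
#' @param matrix samples x pathways completeness matrix.
#' @param threshold aggregate completeness cutoff in `[0,1]` (inclusive);
#'   0.9 mirrors the conventional "over 90% complete" reading.
#' @param aggregate `"mean"` or `"min"` across samples.
#' @return data.frame (pathway_id, aggregate_completeness), ranked.
#' @export
high_completeness_pathways <- function(matrix, threshold = 0.9,
                                       aggregate = c("mean", "min")) {
  aggregate <- match.arg(aggregate)
  assert_scalar_number(threshold, "threshold")
  if (threshold < 0 || threshold > 1)
    stop_pathpls("pathpls_parameter_error", "threshold must be in [0,1]")
  agg <- apply(matrix, 2L, if (aggregate == "mean") mean else min)
  keep <- agg >= threshold
  out <- data.frame(pathway_id = names(agg)[keep],
                    aggregate_completeness = unname(agg[keep]),
                    stringsAsFactors = FALSE)
  out[order(-out$aggregate_completeness, out$pathway_id), , drop = FALSE]
}

#' Write a completeness matrix TSV
#'
#' @param matrix samples x pathways matrix from [completeness_matrix].
#' @param path output path.
#' @param seed optional seed for the provenance header.
#' @export
write_completeness_matrix <- function(matrix, path, seed = NULL) {
  header <- paste(c("sample_id", colnames(matrix)), collapse = "\t")
  rows <- vapply(seq_len(nrow(matrix)), function(i)
    paste(c(rownames(matrix)[i],
            format(matrix[i, ], scientific = FALSE, trim = TRUE, digits = 15)),
          collapse = "\t"), "")
  writeLines(c(provenance_header(seed), header, rows), path, useBytes = TRUE)
  invisible(path)
}
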