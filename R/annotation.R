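KO_REGEX <- "^K[0-9]{5}$"

validate_kos <- function(kos, where) {
  kos <- unique(trimws(kos))
  kos <- kos[nzchar(kos)]
  bad <- kos[!grepl(KO_REGEX, kos)]
  if (length(bad))
    stop_pathpls("pathpls_format_error",
                 "%s: '%s' is not a KO identifier (K + 5 digits)", where, bad[1L])
  kos
}

#' Taxon-to-KO annotation database
#'
#' Maps taxon labels (normalized: lowercased, rank prefix kept) to
#' non-redundant sets of KEGG Orthology identifiers — the community-level
#' stand-in for per-species protein repertoires collapsed to orthologs.
#'
#' @param sets named list: taxon label -> character vector of KO ids.
#' @param provenance free-text provenance string.
#' @export
annotation_db <- function(sets, provenance = "user") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  names(sets) <- normalize_taxon_label(names(sets))
  if (anyDuplicated(names(sets)))
    stop_pathpls("pathpls_validation_error",
                 "duplicate taxon label after normalization: %s",
                 names(sets)[duplicated(names(sets))][1L])
  labels <- names(sets)
  sets <- lapply(seq_along(sets), function(i) {
    kos <- validate_kos(sets[[i]], labels[i])
    if (!length(kos))
      stop_pathpls("pathpls_validation_error", "taxon %s has an empty KO set",
                   labels[i])
    sort(kos)
  })
  names(sets) <- labels
  structure(list(sets = sets, provenance = provenance), class = "annotation_db")
}

#' @export
print.annotation_db <- function(x, ...) {
  cat(sprintf("annotation_db: %d taxa, %d distinct KOs (%s)\n",
              length(x$sets), length(unique(unlist(x$sets))), x$provenance))
  invisible(x)
}

#' Pathway catalog
#'
#' Ordered set of pathways, each defined by a required KO set; the
#' denominator of the completeness statistic. The study-scale catalog had
#' 146 manually selected microbial pathways; the size here is whatever the
#' input defines.
#'
#' @param ids,names_,ko_sets parallel vectors/list: pathway id, display
#'   name, and non-empty KO set per pathway.
#' @export
pathway_catalog <- function(ids, names_, ko_sets) {
  stopifnot(length(ids) == length(names_), length(ids) == length(ko_sets))
  if (anyDuplicated(ids))
    stop_pathpls("pathpls_validation_error", "duplicate pathway id: %s",
                 ids[duplicated(ids)][1L])
  ko_sets <- lapply(seq_along(ko_sets), function(i) {
    kos <- validate_kos(ko_sets[[i]], ids[i])
    if (!length(kos))
      stop_pathpls("pathpls_validation_error", "pathway %s has no KOs", ids[i])
    sort(kos)
  })
  structure(list(ids = as.character(ids), names = as.character(names_),
                 ko_sets = stats::setNames(ko_sets, ids)),
            class = "pathway_catalog")
}

#' @export
print.pathway_catalog <- function(x, ...) {
  cat(sprintf("pathway_catalog: %d pathways, %d distinct KOs\n",
              length(x$ids), length(unique(unlist(x$ko_sets)))))
  invisible(x)
}

#' @export
length.pathway_catalog <- function(x) length(x$ids)

#' Read / write annotation databases and pathway catalogs
#'
#' Annotation TSV: `taxon_label <TAB> comma-separated KO ids`.
#' Catalog TSV: `pathway_id <TAB> pathway_name <TAB> comma-separated KO ids`.
#' `#` lines are comments. KO lists are deduplicated on read (set
#' semantics); a pathway with an empty KO field is rejected.
#'
#' @param path file path.
#' @name annotation_io
#' @export
read_annotation_db <- function(path) {
  rows <- read_tsv_rows(path, n_fields = 2L, what = "annotation TSV")
  sets <- lapply(rows, function(r) strsplit(r[[2L]], ",", fixed = TRUE)[[1L]])
  names(sets) <- vapply(rows, `[[`, "", 1L)
  annotation_db(sets, provenance = path)
}

#' @rdname annotation_io
#' @export
read_pathway_catalog <- function(path) {
  rows <- read_tsv_rows(path, n_fields = 3L, what = "pathway catalog TSV")
  pathway_catalog(
    ids = vapply(rows, `[[`, "", 1L),
    names_ = vapply(rows, `[[`, "", 2L),
    ko_sets = lapply(rows, function(r) strsplit(r[[3L]], ",", fixed = TRUE)[[1L]])
  )
}

read_tsv_rows <- function(path, n_fields, what) {
  if (!file.exists(path))
    stop_pathpls("pathpls_format_error", "no such file: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  rows <- split_tsv(lines)
  bad <- if (is.na(n_fields)) integer() else which(lengths(rows) != n_fields)
  if (length(bad))
    stop_pathpls("pathpls_format_error", "%s %s: row %d has %d fields, expected %d",
                 what, path, bad[1L], lengths(rows)[bad[1L]], n_fields)
  rows
}

#' @rdname annotation_io
#' @param db an [annotation_db].
#' @param seed optional seed recorded in the provenance header.
#' @export
write_annotation_db <- function(db, path, seed = NULL) {
  stopifnot(inherits(db, "annotation_db"))
  rows <- vapply(seq_along(db$sets), function(i)
    paste(names(db$sets)[i], paste(db$sets[[i]], collapse = ","), sep = "\t"), "")
  writeLines(c(provenance_header(seed), rows), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname annotation_io
#' @param catalog a [pathway_catalog].
#' @export
write_pathway_catalog <- function(catalog, path, seed = NULL) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  rows <- vapply(seq_along(catalog$ids), function(i)
    paste(catalog$ids[i], catalog$names[i],
          paste(catalog$ko_sets[[i]], collapse = ","), sep = "\t"), "")
  writeLines(c(provenance_header(seed), rows), path, useBytes = TRUE)
  invisible(path)
}
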