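#' OTU abundance table
#'
#' Container for a samples x OTUs abundance matrix, the taxonomic block of
#' the pipeline. Rows are samples, columns OTUs — the samples-in-rows
#' convention used throughout the package. Values are either raw read
#' counts (`unit = "counts"`) or relative abundances (`unit = "relative"`);
#' truncated relative tables (row sums < 1, e.g. after a display cutoff)
#' are accepted.
#'
#' @param values numeric matrix, samples in rows, OTUs in columns, with
#'   dimnames giving sample and OTU identifiers.
#' @param unit `"counts"` or `"relative"`. If missing, inferred: an
#'   all-integer matrix is taken as counts.
#' @param taxonomy optional named character vector of lineage strings
#'   (Greengenes-style, `"k__...; p__...; g__..."`), named by OTU id.
#' @return An object of class `otu_table`.
#' @export
otu_table <- function(values, unit = NULL, taxonomy = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_pathpls("pathpls_validation_error", "OTU values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_pathpls("pathpls_validation_error",
                 "OTU matrix needs sample (row) and OTU (column) names")
  if (anyDuplicated(rownames(values)))
    stop_pathpls("pathpls_validation_error", "duplicate sample id: %s",
                 rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop_pathpls("pathpls_validation_error", "duplicate OTU id: %s",
                 colnames(values)[duplicated(colnames(values))][1L])
  if (anyNA(values) || any(values < 0))
    stop_pathpls("pathpls_validation_error",
                 "OTU abundances must be non-negative and non-missing")
  if (is.null(unit)) {
    unit <- if (all(values == round(values))) "counts" else "relative"
  }
  unit <- match.arg(unit, c("counts", "relative"))
  if (unit == "relative" && any(rowSums(values) > 1 + 1e-9))
    stop_pathpls("pathpls_validation_error",
                 "relative abundances: row sums exceed 1 (sample %s)",
                 rownames(values)[which(rowSums(values) > 1 + 1e-9)][1L])
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[colnames(values)[colnames(values) %in% names(taxonomy)]]
    if (length(taxonomy) == 0L) taxonomy <- NULL
  }
  structure(list(values = values, unit = unit, taxonomy = taxonomy),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs (%s)%s\n",
              nrow(x$values), ncol(x$values), x$unit,
              if (is.null(x$taxonomy)) "" else ", with taxonomy"))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$values)

sample_ids <- function(x) rownames(x$values)
otu_ids <- function(x) colnames(x$values)

#' Read an OTU table
#'
#' TSV dialect: lines starting with `#` are comments; the header row names
#' an OTU-id column first, then one column per sample, then optionally a
#' final `taxonomy` column. OTUs are in file rows (the classic orientation)
#' and are transposed into the samples-in-rows matrix. The BIOM dialect
#' parses the JSON (v1-style) dense or sparse format.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"biom_json"`.
#' @param scale multiplier applied to abundances before unit inference;
#'   use `0.01` for tables published as percentages.
#' @return An [otu_table].
#' @export
read_otu_table <- function(path, dialect = c("tsv", "biom_json"), scale = 1) {
  dialect <- match.arg(dialect)
  assert_scalar_number(scale, "scale")
  if (!file.exists(path))
    stop_pathpls("pathpls_format_error", "no such file: %s", path)
  if (dialect == "biom_json") return(read_otu_biom(path))

  lines <- readLines(path, encoding = "UTF-8")
  # '#' lines are comments, except the classic "#OTU ID" header
  drop <- startsWith(lines, "#") & !startsWith(toupper(lines), "#OTU")
  lines <- lines[!drop & nzchar(lines)]
  if (length(lines) < 2L)
    stop_pathpls("pathpls_format_error", "OTU TSV %s: no data rows", path)
  cells <- split_tsv(lines)
  width <- lengths(cells)
  if (length(unique(width)) != 1L)
    stop_pathpls("pathpls_format_error",
                 "OTU TSV %s: ragged row %d (%d fields, expected %d)",
                 path, which(width != width[1L])[1L], width[width != width[1L]][1L],
                 width[1L])
  header <- cells[[1L]]
  body <- cells[-1L]
  has_tax <- tolower(header[length(header)]) == "taxonomy"
  smp_cols <- seq(2L, length(header) - if (has_tax) 1L else 0L)
  smp <- header[smp_cols]
  if (anyDuplicated(smp))
    stop_pathpls("pathpls_format_error", "duplicate sample column: %s",
                 smp[duplicated(smp)][1L])
  ids <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop_pathpls("pathpls_format_error", "duplicate OTU id: %s",
                 ids[duplicated(ids)][1L])
  num <- vapply(body, function(r) {
    v <- suppressWarnings(as.numeric(r[smp_cols]))
    if (anyNA(v))
      stop_pathpls("pathpls_format_error", "OTU TSV %s: unparsable cell in row '%s'",
                   path, r[[1L]])
    v
  }, numeric(length(smp)))
  # vapply gives samples x OTUs already when length(smp) > 1; normalise
  m <- matrix(num, nrow = length(smp), ncol = length(ids),
              dimnames = list(smp, ids)) * scale
  tax <- NULL
  if (has_tax) {
    tax <- vapply(body, function(r) r[[length(header)]], "")
    names(tax) <- ids
  }
  otu_table(m, taxonomy = tax)
}

read_otu_biom <- function(path) {
  b <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(b$rows) || is.null(b$columns) || is.null(b$data))
    stop_pathpls("pathpls_format_error", "%s: not a BIOM-JSON table", path)
  otus <- vapply(b$rows, function(r) r$id, "")
  smp <- vapply(b$columns, function(cc) cc$id, "")
  m <- matrix(0, nrow = length(smp), ncol = length(otus),
              dimnames = list(smp, otus))
  if (identical(b$matrix_type, "dense")) {
    for (i in seq_along(b$data)) m[, i] <- unlist(b$data[[i]])
  } else {
    for (trip in b$data) {
      # BIOM sparse triplets are 0-based [row = OTU, column = sample, value]
      m[trip[[2L]] + 1L, trip[[1L]] + 1L] <- trip[[3L]]
    }
  }
  tax <- NULL
  mt <- lapply(b$rows, function(r) r$metadata$taxonomy)
  if (any(!vapply(mt, is.null, TRUE))) {
    tax <- vapply(mt, function(tt) {
      if (is.null(tt)) NA_character_ else paste(unlist(tt), collapse = "; ")
    }, "")
    names(tax) <- otus
    tax <- tax[!is.na(tax)]
  }
  otu_table(m, taxonomy = tax)
}

#' Write an OTU table as TSV
#'
#' Emits a provenance comment line, then the classic OTUs-in-rows layout
#' read back by [read_otu_table].
#'
#' @param x an [otu_table].
#' @param path output path.
#' @param seed optional seed recorded in the provenance header.
#' @export
write_otu_table <- function(x, path, seed = NULL) {
  stopifnot(inherits(x, "otu_table"))
  header <- c("otu_id", sample_ids(x), if (!is.null(x$taxonomy)) "taxonomy")
  rows <- vapply(otu_ids(x), function(o) {
    vals <- format(x$values[, o], scientific = FALSE, trim = TRUE, digits = 15)
    paste(c(o, vals, if (!is.null(x$taxonomy)) unname(x$taxonomy[o])),
          collapse = "\t")
  }, "")
  writeLines(c(provenance_header(seed), paste(header, collapse = "\t"), rows),
             path, useBytes = TRUE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' @param x an [otu_table] with `unit = "counts"` and positive row sums.
#' @return The table with each row divided by its sum (`unit = "relative"`).
#' @export
to_relative <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  if (x$unit != "counts")
    stop_pathpls("pathpls_parameter_error", "to_relative expects a counts table")
  rs <- rowSums(x$values)
  if (any(rs == 0))
    stop_pathpls("pathpls_degenerate_error", "sample %s has zero total count",
                 sample_ids(x)[which(rs == 0)][1L])
  otu_table(x$values / rs, unit = "relative", taxonomy = x$taxonomy)
}

# Relative view regardless of unit (renormalizes counts; leaves relative as is)
as_relative_values <- function(x) {
  if (x$unit == "counts") to_relative(x)$values else x$values
}

#' Apply a minimum-abundance display cutoff
#'
#' Entries strictly below `threshold` are set to zero per sample, mirroring
#' supplementary tables that omit values below a display cutoff (e.g.
#' 0.05%). An entry exactly equal to the threshold survives. OTUs that end
#' up zero in every sample are dropped. Rows are deliberately NOT
#' renormalized, so row sums may fall below 1 — exactly the shape of a
#' truncated published table.
#'
#' @param x an [otu_table] with `unit = "relative"`.
#' @param threshold relative-abundance fraction in `[0, 1)`; 0.0005 is the
#'   conventional 0.05% display cutoff.
#' @export
filter_min_abundance <- function(x, threshold) {
  stopifnot(inherits(x, "otu_table"))
  assert_scalar_number(threshold, "threshold")
  if (threshold < 0 || threshold >= 1)
    stop_pathpls("pathpls_parameter_error", "threshold must be in [0, 1)")
  if (x$unit != "relative")
    stop_pathpls("pathpls_parameter_error", "filter_min_abundance expects a relative table")
  v <- x$values
  v[v < threshold] <- 0
  keep <- colSums(v) > 0
  if (!any(keep))
    stop_pathpls("pathpls_degenerate_error", "cutoff removed every OTU")
  otu_table(v[, keep, drop = FALSE], unit = "relative", taxonomy = x$taxonomy)
}
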