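#' Geochemistry table with detection-limit semantics
#'
#' Samples x parameters matrix of physicochemical measurements. Parameter
#' names carry their unit strings (e.g. `"Temperature (°C)"`, `"Eh (mV)"`,
#' `"TDS (g/l)"`, `"As (µg/l)"`). A parallel character mask records, per
#' cell, whether the value was `measured`, reported `below_detection_limit`
#' (the "b.d.l." token of field tables), or `missing` ("n.d.").
#'
#' @param values numeric samples x parameters matrix with dimnames; cells
#'   masked `missing` must be `NA`.
#' @param mask character matrix of the same shape; defaults to all
#'   `"measured"` except `NA` cells, which become `"missing"`.
#' @export
geochem_table <- function(values, mask = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_pathpls("pathpls_validation_error", "geochem values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_pathpls("pathpls_validation_error", "geochem matrix needs dimnames")
  if (is.null(mask)) {
    mask <- matrix("measured", nrow(values), ncol(values), dimnames = dimnames(values))
    mask[is.na(values)] <- "missing"
  }
  if (!identical(dim(mask), dim(values)))
    stop_pathpls("pathpls_validation_error", "mask and values must have identical shape")
  if (!all(mask %in% c("measured", "below_detection_limit", "missing")))
    stop_pathpls("pathpls_validation_error", "invalid mask status")
  ph <- grep("^pH", colnames(values), ignore.case = TRUE)
  if (length(ph)) {
    pv <- values[, ph]
    if (any(!is.na(pv) & (pv < 0 | pv > 14)))
      stop_pathpls("pathpls_validation_error", "pH values outside [0, 14]")
  }
  dimnames(mask) <- dimnames(values)
  structure(list(values = values, mask = mask), class = "geochem_table")
}

#' @export
print.geochem_table <- function(x, ...) {
  cat(sprintf("geochem_table: %d samples x %d parameters (%d b.d.l., %d n.d.)\n",
              nrow(x$values), ncol(x$values),
              sum(x$mask == "below_detection_limit"), sum(x$mask == "missing")))
  invisible(x)
}

#' @export
dim.geochem_table <- function(x) dim(x$values)

#' Read a geochemistry TSV
#'
#' Layout: `#` comment lines, a header (`sample_id` then one column per
#' parameter, units embedded in the name), one row per sample. Cells are
#' numerals or the censoring tokens `b.d.l.` (below detection limit) and
#' `n.d.` (no data), case-insensitive.
#'
#' `n.d.` always becomes `NA` with mask `missing`. `b.d.l.` becomes, per
#' `bdl_policy`: `zero` -> 0; `half_dl` -> DL/2 using `dl_map` (named
#' vector, parameter -> detection limit — standard left-censoring
#' practice); `na` -> `NA`. In every case the mask records
#' `below_detection_limit`.
#'
#' @param path file path.
#' @param bdl_policy `"zero"`, `"half_dl"`, or `"na"`.
#' @param dl_map named numeric vector of detection limits, required by
#'   `half_dl` for any censored parameter.
#' @param bdl_tokens,nd_tokens synonym sets for the censoring tokens.
#' @export
read_geochem_table <- function(path, bdl_policy = c("zero", "half_dl", "na"),
                               dl_map = NULL,
                               bdl_tokens = c("b.d.l.", "b.d.l", "bdl", "<dl"),
                               nd_tokens = c("n.d.", "n.d", "nd", "na", "")) {
  bdl_policy <- match.arg(bdl_policy)
  rows <- read_tsv_rows(path, n_fields = NA, what = "geochem TSV")
  width <- lengths(rows)
  if (length(unique(width)) != 1L)
    stop_pathpls("pathpls_format_error", "geochem TSV %s: ragged rows", path)
  header <- rows[[1L]]
  params <- header[-1L]
  body <- rows[-1L]
  smp <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(smp))
    stop_pathpls("pathpls_format_error", "duplicate sample id: %s",
                 smp[duplicated(smp)][1L])
  vals <- matrix(NA_real_, length(smp), length(params), dimnames = list(smp, params))
  mask <- matrix("measured", length(smp), length(params), dimnames = list(smp, params))
  for (i in seq_along(body)) {
    for (j in seq_along(params)) {
      cell <- trimws(body[[i]][[j + 1L]])
      lc <- tolower(cell)
      if (lc %in% tolower(nd_tokens)) {
        vals[i, j] <- NA_real_
        mask[i, j] <- "missing"
      } else if (lc %in% tolower(bdl_tokens)) {
        mask[i, j] <- "below_detection_limit"
        vals[i, j] <- switch(bdl_policy,
          zero = 0,
          na = NA_real_,
          half_dl = {
            dl <- dl_map[[params[j]]] %||% NA_real_
            if (is.na(dl))
              stop_pathpls("pathpls_config_error",
                           "half_dl policy: no detection limit for parameter '%s'",
                           params[j])
            dl / 2
          })
      } else {
        v <- suppressWarnings(as.numeric(cell))
        if (is.na(v))
          stop_pathpls("pathpls_format_error",
                       "geochem TSV %s: unparsable cell '%s' (row %s, column %s)",
                       path, cell, smp[i], params[j])
        vals[i, j] <- v
      }
    }
  }
  geochem_table(vals, mask)
}

#' Write a geochemistry TSV
#'
#' Inverse of [read_geochem_table]: cells masked `below_detection_limit`
#' are written as `b.d.l.`, `missing` as `n.d.`.
#'
#' @param x a [geochem_table].
#' @param path output path.
#' @param seed optional seed for the provenance header.
#' @export
write_geochem_table <- function(x, path, seed = NULL) {
  stopifnot(inherits(x, "geochem_table"))
  header <- paste(c("sample_id", colnames(x$values)), collapse = "\t")
  rows <- vapply(seq_len(nrow(x$values)), function(i) {
    cells <- vapply(seq_len(ncol(x$values)), function(j) {
      switch(x$mask[i, j],
             below_detection_limit = "b.d.l.",
             missing = "n.d.",
             format(x$values[i, j], scientific = FALSE, trim = TRUE, digits = 15))
    }, "")
    paste(c(rownames(x$values)[i], cells), collapse = "\t")
  }, "")
  writeLines(c(provenance_header(seed), header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' ICP-MS detection limit
#'
#' `DL = (3 * sigma * std_conc) / (S - B)`: three standard deviations of
#' the blank (control water) signal, scaled by the standard element
#' concentration over the net standard signal — i.e. 3 SD divided by the
#' instrument sensitivity in counts per unit concentration.
#'
#' @param sigma standard deviation of the blank signal (counts), >= 0.
#' @param std_conc concentration of the calibration standard (µg/l), > 0.
#' @param S standard signal (counts).
#' @param B blank signal at zero analyte concentration (counts); `S > B`
#'   is required (otherwise there is no measurable sensitivity).
#' @return Detection limit in the units of `std_conc`.
#' @export
detection_limit <- function(sigma, std_conc, S, B) {
  assert_scalar_number(sigma, "sigma")
  assert_scalar_number(std_conc, "std_conc")
  assert_scalar_number(S, "S")
  assert_scalar_number(B, "B")
  if (sigma < 0) stop_pathpls("pathpls_parameter_error", "sigma must be >= 0")
  if (std_conc <= 0) stop_pathpls("pathpls_parameter_error", "std_conc must be > 0")
  if (S <= B)
    stop_pathpls("pathpls_domain_error",
                 "standard signal must exceed blank signal (S > B)")
  (3 * sigma * std_conc) / (S - B)
}
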