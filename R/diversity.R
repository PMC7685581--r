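#' Shannon diversity (natural log)
#'
#' `H = -sum(p_i * log(p_i))` over the nonzero entries of the relative
#' abundance vector, in nats. The input is renormalized to sum to one
#' first, so vectors from truncated tables (row sums < 1, after a display
#' cutoff) and raw count vectors are both handled; zero entries are
#' ignored. Natural log is used throughout: with per-sample richness up to
#' ~200 OTUs the observed index values (<= ~4.1) are consistent with ln
#' (ln 206 ~ 5.3), whereas log2 would allow values above 7.
#'
#' @param p non-negative abundance vector (counts or fractions) with a
#'   positive sum.
#' @return Shannon index in nats.
#' @export
shannon <- function(p) {
  p <- check_abundance_vector(p)
  -sum(p * log(p))
}

#' Inverse Simpson diversity
#'
#' `D = 1 / sum(p_i^2)` after renormalization: the effective number of
#' equally abundant OTUs. Ranges from 1 (single dominant OTU) to the
#' richness (perfectly even community).
#'
#' @inheritParams shannon
#' @export
inverse_simpson <- function(p) {
  p <- check_abundance_vector(p)
  1 / sum(p^2)
}

check_abundance_vector <- function(p) {
  if (!is.numeric(p) || length(p) == 0L)
    stop_pathpls("pathpls_degenerate_error", "empty abundance vector")
  if (anyNA(p) || any(p < 0))
    stop_pathpls("pathpls_degenerate_error", "abundances must be non-negative")
  s <- sum(p)
  if (s <= 0)
    stop_pathpls("pathpls_degenerate_error", "all-zero abundance vector")
  p <- p[p > 0]
  p / sum(p)
}

#' OTU richness
#'
#' Count of entries strictly above `presence_threshold`.
#'
#' @param p abundance vector.
#' @param presence_threshold non-negative cutoff; 0 counts every OTU with
#'   any signal.
#' @export
richness <- function(p, presence_threshold = 0) {
  assert_scalar_number(presence_threshold, "presence_threshold")
  if (presence_threshold < 0)
    stop_pathpls("pathpls_parameter_error", "presence_threshold must be >= 0")
  sum(p > presence_threshold)
}

#' Per-sample alpha-diversity report
#'
#' Computes richness, Shannon (nats) and inverse Simpson for every sample
#' of an OTU table at full precision. Rounding to report precision
#' (1 decimal for Shannon, 2 for inverse Simpson, the precision such
#' indices are conventionally printed at) happens only in
#' [write_diversity_report].
#'
#' @param table an [otu_table]; counts are converted to relative
#'   abundances per sample, truncated relative rows are renormalized.
#' @return data.frame with columns `sample_id`, `richness`, `shannon`,
#'   `inverse_simpson`, one row per sample in table order.
#' @export
diversity_report <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  if (nrow(table$values) == 0L)
    stop_pathpls("pathpls_degenerate_error", "empty OTU table")
  rows <- lapply(sample_ids(table), function(s) {
    p <- table$values[s, ]
    if (sum(p) <= 0)
      stop_pathpls("pathpls_degenerate_error",
                   "sample %s has no abundance; diversity undefined", s)
    data.frame(sample_id = s,
               richness = richness(p),
               shannon = shannon(p),
               inverse_simpson = inverse_simpson(p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a diversity report TSV at print precision
#'
#' @param report output of [diversity_report].
#' @param path output path.
#' @param seed optional seed for the provenance header.
#' @export
write_diversity_report <- function(report, path, seed = NULL) {
  rows <- sprintf("%s\t%d\t%.1f\t%.2f", report$sample_id, report$richness,
                  report$shannon, report$inverse_simpson)
  writeLines(c(provenance_header(seed),
               "sample_id\trichness\tshannon\tinverse_simpson", rows),
             path, useBytes = TRUE)
  invisible(path)
}
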