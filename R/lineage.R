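CANONICAL_RANKS <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
                     family = "f", genus = "g", species = "s")

#' Parse a Greengenes-style lineage string
#'
#' Splits `"k__Bacteria; p__Proteobacteria; ...; g__Rhodococcus; s__"` into
#' a named vector over the seven canonical ranks. Empty ranks are allowed
#' (returned as `NA`); ranks must appear in canonical order. A trailing
#' assignment-similarity fraction in parentheses, if present, is exposed as
#' the `"similarity"` attribute.
#'
#' @param x a single lineage string.
#' @return Named character vector `kingdom ... species`.
#' @export
parse_lineage <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  sim <- NA_real_
  m <- regmatches(x, regexec("\\(([0-9.]+)\\)\\s*$", x))[[1L]]
  if (length(m) == 2L) {
    sim <- as.numeric(m[2L])
    if (is.na(sim) || sim < 0 || sim > 1)
      stop_pathpls("pathpls_format_error", "lineage similarity outside [0,1]: %s", x)
    x <- sub("\\(([0-9.]+)\\)\\s*$", "", x)
  }
  parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1L]])
  parts <- parts[nzchar(parts)]
  out <- stats::setNames(rep(NA_character_, length(CANONICAL_RANKS)),
                         names(CANONICAL_RANKS))
  pos <- 0L
  for (p in parts) {
    if (!grepl("^[a-z]__", p))
      stop_pathpls("pathpls_format_error", "rank label without prefix: '%s'", p)
    pre <- substr(p, 1L, 1L)
    idx <- match(pre, CANONICAL_RANKS)
    if (is.na(idx))
      stop_pathpls("pathpls_format_error", "unknown rank prefix '%s__'", pre)
    if (idx <= pos)
      stop_pathpls("pathpls_format_error", "ranks out of canonical order in '%s'", x)
    pos <- idx
    val <- substr(p, 4L, nchar(p))
    if (nzchar(val)) out[idx] <- val
  }
  attr(out, "similarity") <- sim
  out
}

#' Taxon label at a rank
#'
#' Returns the `"g__name"`-style label of a lineage at the requested rank,
#' or `NA` if that rank is unassigned.
#'
#' @param lineage lineage string or the output of [parse_lineage].
#' @param rank one of kingdom, phylum, class, order, family, genus, species.
#' @export
taxon_at_rank <- function(lineage, rank = "genus") {
  rank <- match.arg(rank, names(CANONICAL_RANKS))
  if (is.character(lineage) && is.null(names(lineage)))
    lineage <- parse_lineage(lineage)
  val <- lineage[[rank]]
  if (is.na(val) || !nzchar(val)) return(NA_character_)
  normalize_taxon_label(paste0(CANONICAL_RANKS[[rank]], "__", val))
}

# Exact-match normalization: trim, lowercase; rank prefix kept.
# No fuzzy matching anywhere.
normalize_taxon_label <- function(x) tolower(trimws(x))
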