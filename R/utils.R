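#' @keywords internal
"_PACKAGE"

# Every table writer stamps this provenance line; readers skip '#' comments.
provenance_header <- function(seed = NULL) {
  sprintf("# pathpls %s | samples-in-rows convention | seed=%s",
          as.character(utils::packageVersion("pathpls")),
          if (is.null(seed)) "NA" else format(seed, scientific = FALSE))
}

stop_pathpls <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "pathpls_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# strsplit drops trailing empty fields; TSV rows must keep them
split_tsv <- function(lines) {
  out <- strsplit(paste0(lines, "\x1f"), "\t", fixed = TRUE)
  lapply(out, function(x) {
    x[length(x)] <- sub("\x1f$", "", x[length(x)])
    x
  })
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_pathpls("pathpls_parameter_error", "'%s' must be a finite scalar", name)
  invisible(x)
}

# Deterministic sub-seed derivation; keeps results < 2^31 so they remain
# valid R integer seeds.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- NULL
  } else {
    old <- get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
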