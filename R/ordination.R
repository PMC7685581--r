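#' Analysis block
#'
#' A samples x variables real matrix tagged with its preprocessing state.
#' Paired blocks entering the two-block analysis must share sample ids in
#' the same order and contain no missing values.
#'
#' @param values numeric matrix with dimnames (samples in rows).
#' @param preprocessing one of `raw`, `centered`, `z_scored`, `hellinger`.
#' @export
block <- function(values, preprocessing = "raw") {
  if (!is.matrix(values) || !is.numeric(values))
    stop_pathpls("pathpls_validation_error", "block values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_pathpls("pathpls_validation_error", "block needs sample and variable names")
  preprocessing <- match.arg(preprocessing,
                             c("raw", "centered", "z_scored", "hellinger"))
  structure(list(values = values, preprocessing = preprocessing),
            class = "pls_block")
}

#' @export
print.pls_block <- function(x, ...) {
  cat(sprintf("block: %d samples x %d variables (%s)\n",
              nrow(x$values), ncol(x$values), x$preprocessing))
  invisible(x)
}

#' Hellinger transform of an OTU table
#'
#' Square root of per-sample relative abundances (vegan's `decostand`
#' "hellinger"). Downweights dominant OTUs without overweighting rare
#' ones and makes Euclidean ordination appropriate for community data;
#' a complete (untruncated) row has unit Euclidean norm afterwards.
#'
#' @param table an [otu_table] (counts or relative) with positive row sums.
#' @return A [block] tagged `hellinger`.
#' @export
hellinger_transform <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  rs <- rowSums(table$values)
  if (any(rs == 0))
    stop_pathpls("pathpls_degenerate_error", "sample %s is all-zero",
                 sample_ids(table)[which(rs == 0)][1L])
  h <- vegan::decostand(table$values, method = "hellinger")
  block(as.matrix(h), preprocessing = "hellinger")
}

#' Prepare a block for ordination
#'
#' Optional log10 on named concentration variables (for heterogeneous
#' geochemistry spanning orders of magnitude), then imputation, optional
#' column centering and unit-variance scaling. With `scale = TRUE`,
#' zero-variance columns are dropped with a warning. The log floor added
#' before log10 defaults, per column, to half the smallest positive entry,
#' which keeps censored zeros on scale instead of collapsing to -Inf.
#'
#' @param x a [block], [geochem_table], or bare named matrix.
#' @param center subtract column means.
#' @param scale divide columns by their SD (implies centering).
#' @param log10_vars character vector of variable names to log10.
#' @param impute `"column_median"` or `"fail"` for missing cells.
#' @param log_floor optional explicit floor added inside the log.
#' @return A [block] tagged by the last transform applied.
#' @export
prepare_block <- function(x, center = TRUE, scale = FALSE,
                          log10_vars = character(),
                          impute = c("column_median", "fail"),
                          log_floor = NULL) {
  impute <- match.arg(impute)
  v <- if (inherits(x, "pls_block")) x$values
       else if (inherits(x, "geochem_table")) x$values
       else x
  if (!is.matrix(v)) stop_pathpls("pathpls_validation_error", "cannot coerce to block")
  if (nrow(v) < 3L)
    stop_pathpls("pathpls_validation_error",
                 "ordination needs at least 3 samples, got %d", nrow(v))
  for (nm in intersect(log10_vars, colnames(v))) {
    col <- v[, nm]
    if (any(!is.na(col) & col < 0))
      stop_pathpls("pathpls_domain_error", "log10 on negative values in '%s'", nm)
    fl <- log_floor
    if (is.null(fl)) {
      pos <- col[!is.na(col) & col > 0]
      fl <- if (length(pos)) min(pos) / 2 else 1
    }
    v[, nm] <- log10(col + fl)
  }
  if (anyNA(v)) {
    if (impute == "fail") {
      idx <- which(is.na(v), arr.ind = TRUE)[1L, ]
      stop_pathpls("pathpls_validation_error", "missing cell: sample %s, variable %s",
                   rownames(v)[idx[1L]], colnames(v)[idx[2L]])
    }
    for (j in seq_len(ncol(v))) {
      nas <- is.na(v[, j])
      if (any(nas)) v[nas, j] <- stats::median(v[!nas, j])
    }
    if (anyNA(v))
      stop_pathpls("pathpls_validation_error", "column with no measured values")
  }
  if (scale) {
    sds <- apply(v, 2L, stats::sd)
    if (any(sds == 0)) {
      warning(sprintf("dropping %d zero-variance variable(s): %s",
                      sum(sds == 0),
                      paste(colnames(v)[sds == 0], collapse = ", ")),
              call. = FALSE)
      v <- v[, sds > 0, drop = FALSE]
    }
    v <- base::scale(v, center = TRUE, scale = TRUE)
    attr(v, "scaled:center") <- NULL
    attr(v, "scaled:scale") <- NULL
    return(block(unclass(v)[, , drop = FALSE], preprocessing = "z_scored"))
  }
  if (center) {
    v <- base::scale(v, center = TRUE, scale = FALSE)
    attr(v, "scaled:center") <- NULL
    return(block(unclass(v)[, , drop = FALSE], preprocessing = "centered"))
  }
  block(v, preprocessing = if (inherits(x, "pls_block")) x$preprocessing else "raw")
}

check_paired_blocks <- function(X, Y) {
  stopifnot(inherits(X, "pls_block"), inherits(Y, "pls_block"))
  if (nrow(X$values) < 3L)
    stop_pathpls("pathpls_validation_error", "two-block analysis needs >= 3 samples")
  if (!identical(rownames(X$values), rownames(Y$values))) {
    dx <- setdiff(rownames(X$values), rownames(Y$values))
    dy <- setdiff(rownames(Y$values), rownames(X$values))
    stop_pathpls("pathpls_validation_error",
                 "blocks disagree on samples (only in X: %s; only in Y: %s; %s)",
                 paste(dx, collapse = ","), paste(dy, collapse = ","),
                 "order must match")
  }
  if (anyNA(X$values) || anyNA(Y$values))
    stop_pathpls("pathpls_validation_error", "blocks must be complete (no NA)")
}

#' Two-block partial least squares (PLS-SVD / co-inertia)
#'
#' Singular decomposition of the between-block cross-covariance matrix
#' `t(X) %*% Y / (n - 1)`. Axis k pairs a unit left weight vector `u_k`
#' (on X variables) with a unit right weight vector `v_k` (on Y
#' variables), chosen to maximize the covariance of the paired scores
#' `X u_k` and `Y v_k`; singular values `d_k` are those maximal
#' covariances, in decreasing order. The per-axis Pearson correlation of
#' the paired scores is the headline association statistic.
#'
#' Sign convention: each `(u_k, v_k)` pair is jointly flipped so the
#' largest-magnitude entry of `u_k` is positive, which is byte-stable
#' across linear-algebra backends and leaves `d_k` and the score
#' correlations untouched. Because the blocks are column-centered before
#' decomposition, `d_1 = cov(Xu_1, Yv_1) >= 0` already forces `r_1 >= 0`.
#'
#' @param X,Y paired [block]s: identical sample ids in identical order,
#'   no missing values. Blocks not yet centered are centered here.
#' @param n_axes number of axes to return (truncated to the rank bound).
#' @return Object of class `two_block_pls`: `u`, `v` (columns = axes),
#'   `d`, `scores_x`, `scores_y`, `r` (per-axis score correlation),
#'   `total_covariance` (`sum(d^2)` over the full decomposition), plus the
#'   input dimensions.
#' @export
two_block_pls <- function(X, Y, n_axes = 2L) {
  check_paired_blocks(X, Y)
  n <- nrow(X$values)
  xv <- center_if_needed(X)
  yv <- center_if_needed(Y)
  C <- crossprod(xv, yv) / (n - 1)
  sv <- svd(C)
  rank_bound <- sum(sv$d > max(sv$d[1L], 0) * 1e-12)
  k <- max(1L, min(n_axes, rank_bound))
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(u[, j]))
    if (u[i_max, j] < 0) {
      u[, j] <- -u[, j]
      v[, j] <- -v[, j]
    }
  }
  rownames(u) <- colnames(xv)
  rownames(v) <- colnames(yv)
  sx <- xv %*% u
  sy <- yv %*% v
  r <- vapply(seq_len(k), function(j) {
    if (stats::sd(sx[, j]) == 0 || stats::sd(sy[, j]) == 0) return(NA_real_)
    stats::cor(sx[, j], sy[, j])
  }, 0)
  structure(list(u = u, v = v, d = sv$d[seq_len(k)],
                 scores_x = sx, scores_y = sy, r = r,
                 total_covariance = sum(sv$d^2),
                 n_samples = n, n_axes = k),
            class = "two_block_pls")
}

center_if_needed <- function(b) {
  v <- b$values
  if (b$preprocessing %in% c("centered", "z_scored")) return(v)
  v <- base::scale(v, center = TRUE, scale = FALSE)
  attr(v, "scaled:center") <- NULL
  unclass(v)
}

#' @export
print.two_block_pls <- function(x, ...) {
  cat(sprintf("two_block_pls: %d samples, %d axes\n", x$n_samples, x$n_axes))
  for (j in seq_len(x$n_axes))
    cat(sprintf("  axis %d: d = %.4g, score correlation r = %.3f\n",
                j, x$d[j], x$r[j]))
  invisible(x)
}

#' Permutation test for a two-block PLS axis
#'
#' Rows of Y are permuted uniformly at random (equivalent, under
#' exchangeability, to permuting either block); the decomposition is
#' recomputed from scratch on every permuted pairing and the statistic of
#' the tested axis extracted. The p-value uses the add-one estimator
#' `p = (1 + #{perm >= observed}) / (1 + n_perm)`, with ties counted as
#' exceedances (conservative); it therefore lies in
#' `[1/(n_perm+1), 1]`, and reporting `p < 1e-4` requires >= 1e4
#' permutations.
#'
#' @param X,Y paired [block]s as for [two_block_pls].
#' @param axis axis to test (1 = first).
#' @param n_perm number of permutations, >= 1.
#' @param seed RNG seed (mandatory: permutations are the only stochastic
#'   step of the analysis chain).
#' @param statistic `"axis_correlation"` (score Pearson r) or
#'   `"singular_value"`.
#' @return List: `p_value`, `observed`, `n_perm`, `seed`, `statistic`,
#'   `permuted` (the null draws).
#' @export
pls_permutation_test <- function(X, Y, axis = 1L, n_perm = 999L, seed,
                                 statistic = c("axis_correlation",
                                               "singular_value")) {
  statistic <- match.arg(statistic)
  if (missing(seed)) stop_pathpls("pathpls_parameter_error", "seed is mandatory")
  if (!is.numeric(n_perm) || n_perm < 1)
    stop_pathpls("pathpls_parameter_error", "n_perm must be >= 1")
  n_perm <- as.integer(n_perm)
  check_paired_blocks(X, Y)
  fit <- two_block_pls(X, Y, n_axes = axis)
  if (axis > fit$n_axes)
    stop_pathpls("pathpls_parameter_error", "axis %d out of range (max %d)",
                 axis, fit$n_axes)
  pick <- function(f) if (statistic == "axis_correlation") f$r[axis] else f$d[axis]
  observed <- pick(fit)
  n <- nrow(Y$values)
  yb <- Y$values
  # permutations are drawn over id-sorted positions, so the p-value is
  # exactly invariant under jointly relabeling (reordering) both blocks
  ids <- rownames(yb)
  sorted_ids <- sort(ids)
  pos <- match(ids, sorted_ids)
  permuted <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    s <- sample.int(n)
    src <- match(sorted_ids[s[pos]], ids)
    yp <- block(yb[src, , drop = FALSE], preprocessing = Y$preprocessing)
    rownames(yp$values) <- ids
    pick(two_block_pls(X, yp, n_axes = axis))
  }, 0))
  p <- (1 + sum(permuted >= observed)) / (1 + n_perm)
  list(p_value = p, observed = observed, n_perm = n_perm, seed = seed,
       statistic = statistic, permuted = permuted)
}

#' Principal component analysis of a block
#'
#' Thin wrapper around `stats::prcomp` on the (centered) block with a
#' deterministic sign convention: each component is flipped so its
#' largest-magnitude loading is positive. Requesting more components than
#' the rank supports truncates with a warning.
#'
#' @param b a [block]; centered here if not already.
#' @param n_components number of components to keep.
#' @return List: `scores`, `loadings`, `explained` (variance fractions,
#'   full spectrum sums to 1).
#' @export
pca_block <- function(b, n_components = 2L) {
  stopifnot(inherits(b, "pls_block"))
  v <- center_if_needed(b)
  pr <- stats::prcomp(v, center = FALSE, scale. = FALSE)
  rank_bound <- sum(pr$sdev > pr$sdev[1L] * 1e-10)
  if (n_components > rank_bound) {
    warning(sprintf("only %d informative components (requested %d)",
                    rank_bound, n_components), call. = FALSE)
    n_components <- rank_bound
  }
  keep <- seq_len(n_components)
  load <- pr$rotation[, keep, drop = FALSE]
  sco <- pr$x[, keep, drop = FALSE]
  for (j in keep) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) {
      load[, j] <- -load[, j]
      sco[, j] <- -sco[, j]
    }
  }
  list(scores = sco, loadings = load,
       explained = (pr$sdev^2 / sum(pr$sdev^2))[keep])
}
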