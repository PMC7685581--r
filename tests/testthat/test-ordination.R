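test_that("Hellinger transform gives root relative abundances with unit norm", {
  tab <- otu_table(matrix(c(1L, 0L, 1L, 1L, 9L, 16L), 3L, 2L, byrow = TRUE,
                          dimnames = list(c("A", "B", "C"), c("x", "y"))))
  h <- hellinger_transform(tab)
  expect_equal(unname(h$values["A", ]), c(1, 0))
  expect_equal(unname(h$values["B", ]), rep(sqrt(0.5), 2), tolerance = 1e-12)
  expect_equal(unname(h$values["C", ]), c(sqrt(9 / 25), sqrt(16 / 25)),
               tolerance = 1e-12)
  expect_equal(unname(rowSums(h$values^2)), rep(1, 3), tolerance = 1e-12)
  expect_identical(h$preprocessing, "hellinger")
  zero <- otu_table(matrix(c(1L, 0L, 0L, 0L), 2L, 2L,
                           dimnames = list(c("A", "B"), c("x", "y"))))
  expect_error(hellinger_transform(zero), "B")
})

test_that("block preparation centers, scales, imputes and drops constants", {
  set.seed(5)
  m <- cbind(a = rnorm(6), b = rnorm(6, 10, 3), const = rep(2, 6),
             conc = exp(rnorm(6, 2)))
  rownames(m) <- sprintf("s%d", 1:6)
  expect_warning(z <- prepare_block(m, scale = TRUE), "zero-variance.*const")
  expect_false("const" %in% colnames(z$values))
  expect_equal(unname(colMeans(z$values)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(z$values, 2, sd)), rep(1, 3), tolerance = 1e-12)

  cen <- prepare_block(m[, 1:2], center = TRUE)
  expect_equal(unname(colMeans(cen$values)), c(0, 0), tolerance = 1e-12)
  expect_identical(cen$preprocessing, "centered")

  m2 <- m[, 1:2]; m2[2, "b"] <- NA
  imp <- prepare_block(m2, center = FALSE)
  expect_equal(imp$values[2, "b"], median(m2[-2, "b"]))
  expect_error(prepare_block(m2, impute = "fail"), "sample s2, variable b")

  lg <- prepare_block(m[, c("a", "conc")], center = FALSE,
                      log10_vars = "conc")
  expect_equal(unname(lg$values[, "conc"]),
               unname(log10(m[, "conc"] + min(m[, "conc"]) / 2)),
               tolerance = 1e-12)
  expect_error(prepare_block(m[1:2, 1:2]), "at least 3 samples")
})

test_that("identical and sign-flipped blocks give axis-1 correlation 1", {
  set.seed(9)
  m <- matrix(rnorm(24), 6, 4,
              dimnames = list(sprintf("s%d", 1:6), sprintf("v%d", 1:4)))
  X <- prepare_block(m, center = TRUE)
  fit <- two_block_pls(X, X, n_axes = 2L)
  expect_equal(fit$r[1L], 1, tolerance = 1e-10)
  Yneg <- prepare_block(-m, center = TRUE)
  fit_neg <- two_block_pls(X, Yneg, n_axes = 1L)
  expect_equal(fit_neg$r[1L], 1, tolerance = 1e-10)  # sign indeterminacy resolved
  expect_gte(fit$d[1L], fit$d[2L])
  expect_equal(unname(colSums(fit$u^2)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(colSums(fit$v^2)), c(1, 1), tolerance = 1e-12)
})

test_that("axis 1 matches the brute-force covariance maximizer (oracle)", {
  for (seed in c(101, 202, 303)) {
    blocks <- random_block_pair(seed)
    fit <- two_block_pls(blocks$X, blocks$Y, n_axes = 1L)
    oracle <- brute_force_axis1(blocks$X$values, blocks$Y$values)
    expect_equal(fit$d[1L], oracle$d, tolerance = 1e-6)
    expect_equal(unname(fit$u[, 1L]), oracle$u, tolerance = 1e-5)
    expect_equal(unname(fit$v[, 1L]), oracle$v, tolerance = 1e-5)
  }
})

test_that("squared singular values conserve the cross-covariance norm", {
  for (seed in 1:5) {
    blocks <- random_block_pair(seed, n = 7, p = 5, q = 4)
    fit <- two_block_pls(blocks$X, blocks$Y, n_axes = 4L)
    C <- crossprod(blocks$X$values, blocks$Y$values) / 6
    expect_equal(fit$total_covariance, sum(C^2), tolerance = 1e-10)
  }
})

test_that("mismatched or missing-ridden blocks are rejected", {
  blocks <- random_block_pair(7)
  other <- blocks$Y
  rownames(other$values)[1] <- "intruder"
  expect_error(two_block_pls(blocks$X, other), "intruder")
  nas <- blocks$Y
  nas$values[1, 1] <- NA
  expect_error(two_block_pls(blocks$X, nas), "complete")
})

test_that("permutation p-values follow the add-one estimator and its range", {
  set.seed(15)
  # enough samples that no draw is the identity permutation by chance
  m <- matrix(rnorm(60), 12, 5,
              dimnames = list(sprintf("s%02d", 1:12), sprintf("v%d", 1:5)))
  X <- prepare_block(m, center = TRUE)
  res <- pls_permutation_test(X, X, n_perm = 999L, seed = 1L)
  expect_equal(res$p_value, 0.001)  # nothing beats r = 1, add-one rule
  expect_error(pls_permutation_test(X, X, n_perm = 0L, seed = 1L),
               class = "pathpls_parameter_error")
  expect_error(pls_permutation_test(X, X, seed = 1L, axis = 10L),
               class = "pathpls_parameter_error")

  blocks <- random_block_pair(33)
  r1 <- pls_permutation_test(blocks$X, blocks$Y, n_perm = 99L, seed = 4L)
  expect_gte(r1$p_value, 1 / 100)
  expect_lte(r1$p_value, 1)

  # jointly relabeling samples leaves the p-value unchanged
  idx <- sample(nrow(blocks$X$values))
  Xp <- block(blocks$X$values[idx, , drop = FALSE], "centered")
  Yp <- block(blocks$Y$values[idx, , drop = FALSE], "centered")
  r2 <- pls_permutation_test(Xp, Yp, n_perm = 99L, seed = 4L)
  expect_equal(r2$p_value, r1$p_value)
  expect_equal(r2$observed, r1$observed, tolerance = 1e-12)
})

test_that("PCA explains collinear data with one component and orthogonal scores", {
  t_par <- seq(-2, 2, length.out = 9)
  line <- cbind(x = 3 * t_par, y = -2 * t_par)
  rownames(line) <- sprintf("s%d", 1:9)
  p1 <- pca_block(prepare_block(line, center = TRUE), n_components = 1L)
  expect_equal(p1$explained[1L], 1, tolerance = 1e-12)

  set.seed(8)
  m <- matrix(rnorm(200), 50, 4,
              dimnames = list(sprintf("s%d", 1:50), sprintf("v%d", 1:4)))
  p2 <- pca_block(prepare_block(m, center = TRUE), n_components = 3L)
  expect_lt(abs(cor(p2$scores[, 1L], p2$scores[, 2L])), 1e-10)
  expect_true(all(diff(p2$explained) <= 1e-12))
  expect_lte(sum(p2$explained), 1 + 1e-12)
  # deterministic sign: dominant loading positive
  for (j in 1:3) expect_gt(p2$loadings[which.max(abs(p2$loadings[, j])), j], 0)
  expect_warning(pca_block(prepare_block(line, center = TRUE), n_components = 2L),
                 "informative components")
})
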