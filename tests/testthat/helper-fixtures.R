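# Shared fixtures and independent oracles, all built in code.

make_counts_table <- function() {
  m <- matrix(c(10L, 30L, 0L,
                5L, 5L, 40L), nrow = 2L, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("otu1", "otu2", "otu3")))
  tax <- c(
    otu1 = "k__Bacteria; p__Actinobacteria; c__Actinobacteria; o__Actinomycetales; f__Nocardiaceae; g__Rhodococcus; s__",
    otu2 = "k__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; o__Pseudomonadales; f__Pseudomonadaceae; g__Pseudomonas; s__",
    otu3 = "k__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; o__Pseudomonadales; f__Pseudomonadaceae; g__Pseudomonas; s__putida")
  otu_table(m, unit = "counts", taxonomy = tax)
}

make_demo_db <- function() {
  annotation_db(list(
    g__Rhodococcus = c("K00496", "K05710", "K00022"),
    g__Pseudomonas = c("K00496", "K18293"),
    f__Pseudomonadaceae = c("K03381")
  ), provenance = "test fixture")
}

make_demo_catalog <- function() {
  pathway_catalog(
    ids = c("map00626", "map00362"),
    names_ = c("Naphthalene degradation", "Benzoate degradation"),
    ko_sets = list(c("K00496", "K05710", "K14579", "K14580"),
                   c("K00022", "K18293"))
  )
}

random_block_pair <- function(seed, n = 5L, p = 4L, q = 3L) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%d", 1:n), sprintf("x%d", 1:p)))
  Y <- matrix(rnorm(n * q), n, q,
              dimnames = list(sprintf("s%d", 1:n), sprintf("y%d", 1:q)))
  list(X = prepare_block(X, center = TRUE), Y = prepare_block(Y, center = TRUE))
}

# Independent axis-1 oracle: maximize cov(Xu, Yv) over unit u (best v has
# the closed form C'u/||C'u||) by a coarse random search over the unit
# sphere polished with Nelder-Mead on unconstrained coordinates. No SVD.
brute_force_axis1 <- function(Xv, Yv, n_starts = 400L, seed = 1L) {
  set.seed(seed)
  n <- nrow(Xv)
  C <- crossprod(Xv, Yv) / (n - 1)
  f <- function(w) {                      # w unconstrained -> u on sphere
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) return(0)
    sqrt(sum((crossprod(C, w / nw))^2))   # = max_v u' C v = ||C'u||
  }
  best <- NULL
  for (i in seq_len(n_starts)) {
    w0 <- rnorm(ncol(Xv))
    val <- f(w0)
    if (is.null(best) || val > best$val) best <- list(w = w0, val = val)
  }
  opt <- optim(best$w, function(w) -f(w), method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  opt <- optim(opt$par, function(w) -f(w), method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  u <- opt$par / sqrt(sum(opt$par^2))
  cu <- drop(crossprod(C, u))
  v <- cu / sqrt(sum(cu^2))
  i_max <- which.max(abs(u))
  if (u[i_max] < 0) { u <- -u; v <- -v }
  list(u = unname(u), v = unname(v), d = -opt$value)
}

# Brute-force completeness oracle: plain set enumeration, no shared code
# with pathway_completeness.
oracle_completeness <- function(kos, pathway_kos) {
  pk <- unique(pathway_kos)
  hits <- 0L
  for (k in pk) if (any(kos == k)) hits <- hits + 1L
  hits / length(pk)
}

prepared_study_blocks <- function(ds, min_abund = 5e-4) {
  conc <- colnames(ds$geochem$values)[
    pathpls:::is_concentration_var(colnames(ds$geochem$values))]
  geo <- suppressWarnings(prepare_block(ds$geochem, scale = TRUE,
                                        log10_vars = conc))
  taxa <- prepare_block(hellinger_transform(ds$otu), center = TRUE)
  cm <- suppressWarnings(completeness_matrix(ds$otu, ds$db, ds$catalog,
                                             min_rel_abund = min_abund))
  cmp <- prepare_block(block(cm[, , drop = FALSE]), center = TRUE)
  list(geochem = geo, taxa = taxa, completeness = cmp, matrix = cm)
}
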