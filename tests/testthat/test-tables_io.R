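test_that("OTU TSV parsing infers units, preserves order, and round-trips", {
  tab <- make_counts_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(tab, path, seed = 42L)
  back <- read_otu_table(path)
  expect_equal(back$values, tab$values)
  expect_identical(back$unit, "counts")
  expect_equal(back$taxonomy, tab$taxonomy)
  expect_match(readLines(path)[1L], "^# pathpls .*seed=42")

  rel <- to_relative(tab)
  write_otu_table(rel, path)
  rel_back <- read_otu_table(path)
  expect_identical(rel_back$unit, "relative")
  expect_equal(rel_back$values, rel$values, tolerance = 1e-12)

  # percent-scale tables are rescaled before validation
  pct <- otu_table(rel$values * 100 / 100, unit = "relative")
  writeLines(c("otu_id\tS1\tS2",
               sprintf("otu%d\t%g\t%g", 1:3, rel$values[1, ] * 100,
                       rel$values[2, ] * 100)), path)
  pct_back <- read_otu_table(path, scale = 0.01)
  expect_equal(unname(pct_back$values), unname(rel$values), tolerance = 1e-12)
})

test_that("malformed OTU tables are rejected with the offending id named", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu_id\tS1\tS1", "o1\t1\t2", "o2\t3\t4"), path)
  expect_error(read_otu_table(path), "duplicate sample.*S1")
  writeLines(c("otu_id\tS1\tS2", "o1\t1\t2", "o1\t3\t4"), path)
  expect_error(read_otu_table(path), "duplicate OTU id: o1")
  writeLines(c("otu_id\tS1\tS2", "o1\t1\t2", "o2\t3"), path)
  expect_error(read_otu_table(path), "ragged")
  m <- matrix(c(-1, 1), 1, 2, dimnames = list("S1", c("a", "b")))
  expect_error(otu_table(m), "non-negative")
})

test_that("BIOM-JSON dense and sparse dialects parse to the same table", {
  tab <- make_counts_table()
  dense <- list(
    id = "t", format = "1.0.0", type = "OTU table", matrix_type = "dense",
    shape = c(3L, 2L),
    rows = lapply(otu_ids <- colnames(tab$values), function(o)
      list(id = o, metadata = list(taxonomy = as.list(
        strsplit(tab$taxonomy[[o]], "; ", fixed = TRUE)[[1L]])))),
    columns = lapply(rownames(tab$values), function(s)
      list(id = s, metadata = NULL)),
    data = lapply(seq_len(3L), function(i) as.list(unname(tab$values[, i]))))
  dense_path <- withr::local_tempfile(fileext = ".biom")
  jsonlite::write_json(dense, dense_path, auto_unbox = TRUE, null = "null")
  got_dense <- read_otu_table(dense_path, dialect = "biom_json")
  expect_equal(got_dense$values, tab$values)
  expect_equal(got_dense$taxonomy[["otu1"]], tab$taxonomy[["otu1"]])

  nz <- which(tab$values > 0, arr.ind = TRUE)
  sparse <- dense
  sparse$matrix_type <- "sparse"
  sparse$data <- lapply(seq_len(nrow(nz)), function(i)
    list(nz[i, 2L] - 1L, nz[i, 1L] - 1L, unname(tab$values[nz[i, 1L], nz[i, 2L]])))
  sparse_path <- withr::local_tempfile(fileext = ".biom")
  jsonlite::write_json(sparse, sparse_path, auto_unbox = TRUE, null = "null")
  got_sparse <- read_otu_table(sparse_path, dialect = "biom_json")
  expect_equal(got_sparse$values, got_dense$values)
})

test_that("geochem censoring tokens follow the declared policies", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tTDS (g/l)\tAs (µg/l)",
               "S1\t1.3\tb.d.l.",
               "S2\tn.d.\t8.5"), path)
  half <- read_geochem_table(path, bdl_policy = "half_dl",
                             dl_map = c("As (µg/l)" = 0.02))
  expect_equal(half$values["S1", "As (µg/l)"], 0.01)
  expect_identical(half$mask["S1", "As (µg/l)"], "below_detection_limit")
  expect_identical(half$mask["S2", "TDS (g/l)"], "missing")
  expect_true(is.na(half$values["S2", "TDS (g/l)"]))
  expect_equal(half$values["S1", "TDS (g/l)"], 1.3)
  expect_identical(half$mask["S1", "TDS (g/l)"], "measured")

  zero <- read_geochem_table(path, bdl_policy = "zero")
  expect_equal(zero$values["S1", "As (µg/l)"], 0)

  expect_error(read_geochem_table(path, bdl_policy = "half_dl"),
               class = "pathpls_config_error")
  writeLines(c("sample_id\tpH", "S1\tacidic"), path)
  expect_error(read_geochem_table(path), "unparsable cell 'acidic'.*pH")
})

test_that("geochem tables round-trip including the censoring mask", {
  vals <- matrix(c(65, 2.85, 120, 0.05,
                   40, 6.8, NA, 0.004), 2L, 4L, byrow = TRUE,
                 dimnames = list(c("S1", "S2"),
                                 c("Temperature (°C)", "pH", "Eh (mV)",
                                   "As (µg/l)")))
  mask <- matrix("measured", 2L, 4L, dimnames = dimnames(vals))
  mask["S2", "Eh (mV)"] <- "missing"
  mask["S2", "As (µg/l)"] <- "below_detection_limit"
  g <- geochem_table(vals, mask)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_geochem_table(g, path, seed = 7L)
  back <- read_geochem_table(path, bdl_policy = "half_dl",
                             dl_map = c("As (µg/l)" = 0.008))
  expect_identical(back$mask, g$mask)
  expect_equal(back$values[, 1:3], g$values[, 1:3])
  expect_equal(back$values["S2", "As (µg/l)"], 0.004)
  expect_error(geochem_table(matrix(15, 1, 1, dimnames = list("S1", "pH"))),
               "pH")
})

test_that("annotation and catalog readers deduplicate KOs and reject bad rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("g__Rhodococcus\tK00496,K00496,K05710", path)
  db <- read_annotation_db(path)
  expect_identical(db$sets[["g__rhodococcus"]], c("K00496", "K05710"))

  cat_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("map00626\tNaphthalene degradation\tK14579,K14580", cat_path)
  cat2 <- read_pathway_catalog(cat_path)
  expect_length(cat2$ko_sets[["map00626"]], 2L)

  writeLines("map00626\tNaphthalene degradation\t", cat_path)
  expect_error(read_pathway_catalog(cat_path), "no KOs")
  writeLines("g__x\tK496", path)
  expect_error(read_annotation_db(path), "not a KO identifier")

  db2 <- make_demo_db()
  rt <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_db(db2, rt)
  expect_equal(read_annotation_db(rt)$sets, db2$sets)
  ct <- make_demo_catalog()
  write_pathway_catalog(ct, rt)
  back <- read_pathway_catalog(rt)
  expect_equal(back$ko_sets, ct$ko_sets)
  expect_equal(back$names, ct$names)
})

test_that("to_relative and the abundance cutoff follow their contracts", {
  tab <- make_counts_table()
  rel <- to_relative(tab)
  expect_equal(unname(rowSums(rel$values)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(rel$values["S1", ]), c(0.25, 0.75, 0))

  zero_row <- otu_table(matrix(c(0L, 0L), 1, 2,
                               dimnames = list("S1", c("a", "b"))))
  expect_error(to_relative(zero_row), "S1")

  m <- matrix(c(0.9996, 0.0004, 0.999, 0.0005), 2L, 2L, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("big", "small")))
  t2 <- otu_table(m, unit = "relative")
  f5 <- filter_min_abundance(t2, 0.0005)
  expect_equal(f5$values["S1", "small"], 0)      # strictly below: removed
  expect_equal(f5$values["S2", "small"], 0.0005) # equal: survives
  expect_lt(sum(f5$values["S1", ]), 1)           # no renormalization
  one_gone <- filter_min_abundance(
    otu_table(matrix(c(0.9996, 4e-4), 1, 2,
                     dimnames = list("S1", c("big", "small"))),
              unit = "relative"), 5e-4)
  expect_identical(colnames(one_gone$values), "big")  # all-zero OTU dropped
  expect_equal(filter_min_abundance(t2, 0)$values, t2$values)
  expect_error(filter_min_abundance(t2, 1), class = "pathpls_parameter_error")
})

test_that("abundance cutoff never increases an entry (property)", {
  set.seed(11)
  for (i in 1:20) {
    m <- matrix(runif(30), 5, 6,
                dimnames = list(sprintf("s%d", 1:5), sprintf("o%d", 1:6)))
    m <- m / rowSums(m)
    tab <- otu_table(m, unit = "relative")
    thr <- runif(1, 0, 0.2)
    out <- filter_min_abundance(tab, thr)
    expect_true(all(out$values <= m[, colnames(out$values)] + 1e-15))
  }
})

test_that("detection limit follows the 3-sigma sensitivity formula", {
  expect_identical(detection_limit(sigma = 2, std_conc = 10, S = 500, B = 20),
                   0.125)
  expect_identical(detection_limit(0, 10, 500, 20), 0)
  expect_error(detection_limit(2, 10, 20, 20), class = "pathpls_domain_error")
  # linear in sigma and std_conc; halving the net signal doubles DL
  set.seed(3)
  for (i in 1:10) {
    sg <- runif(1, 0, 5); sc <- runif(1, 1, 50)
    S <- runif(1, 200, 900); B <- runif(1, 0, 100)
    base <- detection_limit(sg, sc, S, B)
    expect_equal(detection_limit(2 * sg, sc, S, B), 2 * base)
    expect_equal(detection_limit(sg, 3 * sc, S, B), 3 * base)
    expect_equal(detection_limit(sg, sc, B + (S - B) / 2, B), 2 * base)
  }
})

test_that("lineage strings parse into canonical ranks", {
  lin <- parse_lineage(
    "k__Bacteria; p__Proteobacteria; c__; o__Pseudomonadales; f__Pseudomonadaceae; g__Pseudomonas; s__ (0.97)")
  expect_identical(lin[["genus"]], "Pseudomonas")
  expect_true(is.na(lin[["class"]]))
  expect_true(is.na(lin[["species"]]))
  expect_equal(attr(lin, "similarity"), 0.97)
  expect_identical(taxon_at_rank(lin, "genus"), "g__pseudomonas")
  expect_true(is.na(taxon_at_rank(lin, "species")))
  expect_error(parse_lineage("g__A; k__B"), "canonical order")
  expect_error(parse_lineage("x__Weird"), "unknown rank prefix")
})
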