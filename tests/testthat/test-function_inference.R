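test_that("detected taxa respect thresholds and collapse ranks", {
  tab <- make_counts_table()
  # S2 relative: otu1 0.1, otu2 0.1, otu3 0.8; otu2/otu3 share g__pseudomonas
  expect_setequal(detected_taxa(tab, "S2"),
                  c("g__rhodococcus", "g__pseudomonas"))
  expect_identical(detected_taxa(tab, "S2", min_rel_abund = 0.5),
                   "g__pseudomonas")
  # S1 has otu3 at zero: threshold 0 still excludes absent OTUs
  expect_setequal(detected_taxa(tab, "S1"),
                  c("g__rhodococcus", "g__pseudomonas"))
  expect_length(detected_taxa(tab, "S2", rank = "species"), 1L)
  expect_error(detected_taxa(tab, "nope"), class = "pathpls_lookup_error")
})

test_that("sample KO sets are unions with a per-taxon match report", {
  db <- make_demo_db()
  kos <- sample_ko_set(c("g__Rhodococcus", "g__Pseudomonas"), db)
  expect_identical(as.character(kos),
                   c("K00022", "K00496", "K05710", "K18293"))
  rpt <- attr(kos, "match_report")
  expect_identical(rpt$status, c("matched", "matched"))

  expect_warning(res <- sample_ko_set("g__Nobody", db), "no taxon matched")
  expect_length(as.character(res), 0L)
  expect_identical(attr(res, "match_report")$status, "unmatched")

  # species miss falls back through genus on a full lineage
  lin <- "k__Bacteria; p__P; c__C; o__O; f__Pseudomonadaceae; g__Pseudomonas; s__novel"
  fb <- sample_ko_set(lin, db, rank_fallback = TRUE)
  expect_identical(attr(fb, "match_report")$status, "fallback")
  expect_identical(attr(fb, "match_report")$matched_label, "g__pseudomonas")

  # superset community KO set contains the subset community's
  sub <- sample_ko_set("g__Rhodococcus", db)
  expect_true(all(as.character(sub) %in% as.character(kos)))
})

test_that("pathway completeness is the detected-over-required KO ratio", {
  expect_equal(pathway_completeness(c("K00001", "K00003"),
                                    sprintf("K0000%d", 1:4)), 0.5)
  expect_equal(pathway_completeness("K99999", c("K00001", "K00002")), 0)
  expect_equal(pathway_completeness(sprintf("K0000%d", 1:5),
                                    sprintf("K0000%d", 1:3)), 1)
  expect_error(pathway_completeness("K00001", character()),
               class = "pathpls_validation_error")
})

test_that("completeness values are exact rationals agreeing with set enumeration", {
  set.seed(41)
  universe <- sprintf("K%05d", 1:10)
  for (i in 1:25) {
    n_pw <- sample(1:5, 1)
    cat_kos <- lapply(seq_len(n_pw), function(j)
      sample(universe, sample(1:10, 1)))
    kos <- sample(universe, sample(0:10, 1))
    for (j in seq_len(n_pw)) {
      got <- pathway_completeness(kos, cat_kos[[j]])
      expect_identical(got, oracle_completeness(kos, cat_kos[[j]]))
      n <- length(unique(cat_kos[[j]]))
      expect_equal(got * n, round(got * n), tolerance = 1e-12)  # k/n exactly
    }
  }
})

test_that("completeness is monotone under taxon and KO addition (property)", {
  set.seed(43)
  universe <- sprintf("K%05d", 1:12)
  pw <- sample(universe, 6)
  kos <- character()
  prev <- 0
  for (i in 1:10) {
    kos <- union(kos, sample(universe, 2))
    cur <- pathway_completeness(kos, pw)
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("the completeness matrix is deterministic and order-invariant", {
  tab <- make_counts_table()
  db <- make_demo_db()
  catalog <- make_demo_catalog()
  cm <- completeness_matrix(tab, db, catalog)
  # S1: rhodococcus+pseudomonas KOs = {K00496,K05710,K00022,K18293}
  expect_equal(cm["S1", "map00626"], 0.5)   # 2 of 4
  expect_equal(cm["S1", "map00362"], 1.0)   # both
  expect_true(all(cm >= 0 & cm <= 1))
  expect_identical(attr(cm, "ko_set_size")[["S1"]], 4L)

  # permuting rows and columns of the input changes nothing
  perm <- otu_table(tab$values[c("S2", "S1"), c(3, 1, 2)],
                    unit = "counts", taxonomy = tab$taxonomy)
  cm_perm <- completeness_matrix(perm, db, catalog)
  expect_identical(cm_perm[rownames(cm), colnames(cm)],
                   cm[rownames(cm), colnames(cm)])

  # a sample with no matched taxa yields an all-zero row and a warning
  lonely <- otu_table(
    matrix(c(5L, 5L), 2L, 1L, dimnames = list(c("S1", "S2"), "otuX")),
    taxonomy = c(otuX = "k__Bacteria; p__Z; c__Z; o__Z; f__Z; g__Unknowngenus; s__"))
  warns <- capture_warnings(cm0 <- completeness_matrix(lonely, db, catalog))
  expect_match(warns, "no taxon matched", all = TRUE)
  expect_length(warns, 2L)  # one per sample
  expect_true(all(cm0 == 0))
})

test_that("adding a taxon never decreases a sample's completeness row", {
  tab <- make_counts_table()
  db <- make_demo_db()
  catalog <- make_demo_catalog()
  base <- completeness_matrix(tab, db, catalog, min_rel_abund = 0.5)
  more <- completeness_matrix(tab, db, catalog, min_rel_abund = 0)
  expect_true(all(more >= base))
})

test_that("high-completeness ranking applies the inclusive threshold", {
  cm <- matrix(c(1.0, 0.8, 0.95, 0.3), 2L, 2L,
               dimnames = list(c("S1", "S2"), c("P1", "P2")))
  by_mean <- high_completeness_pathways(cm, threshold = 0.9)
  expect_identical(by_mean$pathway_id, "P1")           # mean 0.9 included
  expect_equal(by_mean$aggregate_completeness, 0.9)
  by_min <- high_completeness_pathways(cm, threshold = 0.9, aggregate = "min")
  expect_identical(nrow(by_min), 0L)                    # min 0.8 excluded
  all_of <- high_completeness_pathways(cm, threshold = 0)
  expect_identical(all_of$pathway_id, c("P1", "P2"))    # sorted descending
  only_full <- high_completeness_pathways(
    matrix(1, 2, 1, dimnames = list(c("a", "b"), "P")), threshold = 1)
  expect_identical(only_full$pathway_id, "P")
})
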