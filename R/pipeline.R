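is_concentration_var <- function(nm) grepl("\\((m|µ|u)?g/l\\)", nm)

#' Pipeline run configuration
#'
#' Either all four input paths (`otu`, `geochem`, `annotations`,
#' `pathways`) or a `simulate` block (a [synthetic_config]) must be
#' given — never both. `seed` is mandatory because the permutation tests
#' (and the generator, when simulating) are stochastic.
#'
#' @param otu,geochem,annotations,pathways input file paths.
#' @param simulate a [synthetic_config] to generate inputs instead.
#' @param min_abundance taxon detection threshold on relative abundance
#'   (default 0.0005, the 0.05% display-cutoff convention).
#' @param completeness_threshold aggregate-completeness cutoff for the
#'   high-completeness pathway list (default 0.9).
#' @param n_perm permutations for both axis tests.
#' @param bdl_policy below-detection-limit policy for reading geochem
#'   tables; defaults to `half_dl` when `dl_map` is given, else `zero`.
#' @param dl_map named detection-limit vector for `half_dl`.
#' @param rank taxonomic matching rank for the annotation database.
#' @param seed RNG seed for the whole run.
#' @param out_dir optional directory for the report bundle files.
#' @return A validated `run_config` list.
#' @export
run_config <- function(otu = NULL, geochem = NULL, annotations = NULL,
                       pathways = NULL, simulate = NULL,
                       min_abundance = 5e-4, completeness_threshold = 0.9,
                       n_perm = 999L, bdl_policy = NULL, dl_map = NULL,
                       rank = "genus", seed, out_dir = NULL) {
  if (missing(seed))
    stop_pathpls("pathpls_config_error", "run_config: seed is mandatory")
  paths <- list(otu = otu, geochem = geochem, annotations = annotations,
                pathways = pathways)
  has_paths <- !vapply(paths, is.null, TRUE)
  if (!is.null(simulate) && any(has_paths))
    stop_pathpls("pathpls_config_error",
                 "config must give either input paths or a simulate block, not both")
  if (is.null(simulate)) {
    if (!all(has_paths))
      stop_pathpls("pathpls_config_error", "missing input path(s): %s",
                   paste(names(paths)[!has_paths], collapse = ", "))
  } else if (!inherits(simulate, "synthetic_config")) {
    stop_pathpls("pathpls_config_error", "simulate must be a synthetic_config")
  }
  if (is.null(bdl_policy)) bdl_policy <- if (is.null(dl_map)) "zero" else "half_dl"
  structure(list(paths = paths, simulate = simulate,
                 min_abundance = min_abundance,
                 completeness_threshold = completeness_threshold,
                 n_perm = as.integer(n_perm), bdl_policy = bdl_policy,
                 dl_map = dl_map, rank = rank, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(config) {
  # rolling polynomial hash of the deparsed config; enough to detect
  # config drift in logs
  bytes <- utf8ToInt(paste(deparse(config), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load (or simulate) inputs; per-sample alpha
#' diversity; pathway-completeness matrix and high-completeness list; two
#' two-block PLS analyses against the prepared geochemical block — taxa
#' (Hellinger, centered) and pathway completeness (centered) — each with
#' an axis-1 permutation test. Geochemistry preparation: log10 on
#' concentration variables (unit strings containing g/l), z-scoring,
#' column-median imputation. All randomness derives from `config$seed`;
#' the output is deterministic given the config. Permutation p-values are
#' reported raw, with `n_perm` stated.
#'
#' @param config a [run_config].
#' @return A `report_bundle` list: `diversity`, `completeness`,
#'   `high_pathways`, `pls_taxa`, `perm_taxa`, `pls_completeness`,
#'   `perm_completeness`, `summary` (every headline number, machine
#'   readable), `log` (stage lines). When `config$out_dir` is set the
#'   bundle is also written there (TSVs + `summary.json` + `run.log`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  log_lines <- character()
  stage <- function(name, ...) {
    line <- sprintf("stage=%s t=%.2fs %s", name,
                    proc.time()[["elapsed"]] - t0,
                    paste(sprintf("%s=%s", names(list(...)),
                                  unlist(list(...))), collapse = " "))
    log_lines <<- c(log_lines, line)
  }
  stage("start", seed = config$seed, config_hash = config_hash(config))

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_pathpls("pathpls_stage_error", "stage '%s' failed: %s",
                   name, conditionMessage(e))
    })
  }

  inputs <- run_stage("load", {
    if (!is.null(config$simulate)) {
      ds <- generate_coupled_dataset(config$simulate)
      dl <- ds$dl_map
      list(otu = ds$otu, geochem = ds$geochem, db = ds$db,
           catalog = ds$catalog, truth = ds$truth)
    } else {
      list(otu = read_otu_table(config$paths$otu),
           geochem = read_geochem_table(config$paths$geochem,
                                        bdl_policy = config$bdl_policy,
                                        dl_map = config$dl_map),
           db = read_annotation_db(config$paths$annotations),
           catalog = read_pathway_catalog(config$paths$pathways),
           truth = NULL)
    }
  })
  stage("load", samples = nrow(inputs$otu$values), otus = ncol(inputs$otu$values),
        pathways = length(inputs$catalog))

  div <- run_stage("diversity", diversity_report(inputs$otu))
  stage("diversity", mean_shannon = sprintf("%.3f", mean(div$shannon)))

  warn_notes <- character()
  comp <- run_stage("completeness", withCallingHandlers(
    completeness_matrix(inputs$otu, inputs$db, inputs$catalog,
                        min_rel_abund = config$min_abundance,
                        rank = config$rank),
    warning = function(w) {
      warn_notes <<- c(warn_notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    }))
  high <- high_completeness_pathways(comp, config$completeness_threshold)
  stage("completeness", high_pathways = nrow(high))

  blocks <- run_stage("blocks", {
    conc <- colnames(inputs$geochem$values)[
      is_concentration_var(colnames(inputs$geochem$values))]
    geo <- suppressWarnings(prepare_block(inputs$geochem, scale = TRUE,
                                          log10_vars = conc,
                                          impute = "column_median"))
    taxa <- prepare_block(hellinger_transform(inputs$otu), center = TRUE)
    cmp <- prepare_block(block(comp[, , drop = FALSE]), center = TRUE)
    list(geochem = geo, taxa = taxa, completeness = cmp)
  })
  stage("blocks", geochem_vars = ncol(blocks$geochem$values))

  pls_taxa <- run_stage("pls_taxa",
                        two_block_pls(blocks$geochem, blocks$taxa, n_axes = 2L))
  perm_taxa <- run_stage("pls_taxa", pls_permutation_test(
    blocks$geochem, blocks$taxa, axis = 1L, n_perm = config$n_perm,
    seed = derive_seed(config$seed, 101L)))
  stage("pls_taxa", r1 = sprintf("%.4f", pls_taxa$r[1L]),
        p = format(perm_taxa$p_value))

  pls_comp <- run_stage("pls_completeness",
                        two_block_pls(blocks$geochem, blocks$completeness,
                                      n_axes = 2L))
  perm_comp <- run_stage("pls_completeness", pls_permutation_test(
    blocks$geochem, blocks$completeness, axis = 1L, n_perm = config$n_perm,
    seed = derive_seed(config$seed, 202L)))
  stage("pls_completeness", r1 = sprintf("%.4f", pls_comp$r[1L]),
        p = format(perm_comp$p_value))

  if (length(warn_notes))
    stage("warnings", n = length(warn_notes))

  summary <- list(
    n_samples = nrow(inputs$otu$values),
    n_otus = ncol(inputs$otu$values),
    n_pathways = length(inputs$catalog),
    seed = config$seed,
    n_perm = config$n_perm,
    min_abundance = config$min_abundance,
    completeness_threshold = config$completeness_threshold,
    mean_shannon = mean(div$shannon),
    mean_inverse_simpson = mean(div$inverse_simpson),
    mean_richness = mean(div$richness),
    n_high_completeness_pathways = nrow(high),
    taxa_geochem_r1 = unname(pls_taxa$r[1L]),
    taxa_geochem_p = perm_taxa$p_value,
    completeness_geochem_r1 = unname(pls_comp$r[1L]),
    completeness_geochem_p = perm_comp$p_value)

  bundle <- structure(list(diversity = div, completeness = comp,
                           high_pathways = high, blocks = blocks,
                           pls_taxa = pls_taxa, perm_taxa = perm_taxa,
                           pls_completeness = pls_comp,
                           perm_completeness = perm_comp,
                           truth = inputs$truth, summary = summary,
                           warnings = warn_notes, log = log_lines),
                      class = "report_bundle")
  if (!is.null(config$out_dir)) write_report_bundle(bundle, config)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "report_bundle: %d samples, %d OTUs, %d pathways\n",
    "  mean Shannon %.2f | mean inverse Simpson %.2f | mean richness %.1f\n",
    "  pathways >= %.0f%% aggregate completeness: %d\n",
    "  taxa~geochem axis-1 r = %.3f (p = %.4g, %d perms)\n",
    "  completeness~geochem axis-1 r = %.3f (p = %.4g, %d perms)\n"),
    s$n_samples, s$n_otus, s$n_pathways, s$mean_shannon,
    s$mean_inverse_simpson, s$mean_richness,
    100 * s$completeness_threshold, s$n_high_completeness_pathways,
    s$taxa_geochem_r1, s$taxa_geochem_p, s$n_perm,
    s$completeness_geochem_r1, s$completeness_geochem_p, s$n_perm))
  invisible(x)
}

write_report_bundle <- function(bundle, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  write_diversity_report(bundle$diversity, p("diversity.tsv"), seed = config$seed)
  write_completeness_matrix(bundle$completeness, p("completeness.tsv"),
                            seed = config$seed)
  utils::write.table(bundle$high_pathways, p("high_completeness_pathways.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(bundle$log, p("run.log"))
  invisible(config$out_dir)
}

#' Diversity under truncated vs pooled-remainder conventions
#'
#' Published relative-abundance tables are often truncated at a display
#' cutoff, so their rows sum to less than 1. Two defensible conventions
#' for alpha diversity then exist: renormalize over the shown OTUs
#' (`*_truncated` — the package's standard convention), or additionally
#' pool the undisplayed mass into a single pseudo-OTU
#' (`*_pooled_remainder` — a bound on the contribution of the hidden
#' tail). This report shows both and their discrepancy.
#'
#' @param table an [otu_table] with `unit = "relative"`.
#' @return data.frame with both variants and delta columns per sample.
#' @export
diversity_variants <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  base <- diversity_report(table)
  pooled <- vapply(sample_ids(table), function(s) {
    p <- table$values[s, ]
    rem <- if (table$unit == "relative") max(0, 1 - sum(p)) else 0
    p2 <- c(p, remainder = rem)
    c(shannon(p2), inverse_simpson(p2))
  }, numeric(2L))
  data.frame(sample_id = base$sample_id,
             shannon_truncated = base$shannon,
             shannon_pooled_remainder = pooled[1L, ],
             inverse_simpson_truncated = base$inverse_simpson,
             inverse_simpson_pooled_remainder = pooled[2L, ],
             delta_shannon = pooled[1L, ] - base$shannon,
             delta_inverse_simpson = pooled[2L, ] - base$inverse_simpson,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Preprocessing sweep for reproducing a published two-block analysis
#'
#' Runs the taxa-vs-geochemistry two-block PLS under a declared grid of
#' preprocessing variants — community transform (Hellinger vs raw
#' relative abundances), geochemistry scaling (log10 + z-score vs z-score
#' only), and missingness policy (column-median imputation vs dropping
#' incomplete variables) — and reports the axis-1 score correlation and
#' permutation p for each. When a `reference_r1` is supplied (e.g. a
#' printed value to 2 decimals), variants whose r1 rounds to it are
#' flagged.
#'
#' Both inputs are transcriptions of supplement-style tables:
#' `s2_path`, the per-sample abundance table (percentages; OTUs/groups in
#' rows, samples in columns); `s1_path`, the geochemistry table (samples
#' in rows, parameters with unit strings in columns, `b.d.l.`/`n.d.`
#' tokens allowed). If either file is missing, an object of class
#' `reproduction_unavailable` is returned carrying instructions — not an
#' error.
#'
#' @param s1_path geochemistry TSV path.
#' @param s2_path abundance TSV path (percent scale).
#' @param n_perm permutations per variant.
#' @param seed RNG seed.
#' @param reference_r1 optional published axis-1 correlation to compare
#'   against at 2-decimal precision.
#' @param bdl_policy,dl_map passed to [read_geochem_table].
#' @return List of class `reproduction_sweep`: `sweep` (one row per grid
#'   combination: variant settings, r1, p_value, and `matches_reference`),
#'   `grid_size`, `n_perm`, `seed`; or a `reproduction_unavailable`
#'   object.
#' @export
reproduce_supplementary <- function(s1_path, s2_path, n_perm = 9999L, seed,
                                    reference_r1 = NULL,
                                    bdl_policy = "zero", dl_map = NULL) {
  if (missing(seed))
    stop_pathpls("pathpls_parameter_error", "seed is mandatory")
  missing_files <- c(s1_path, s2_path)[!file.exists(c(s1_path, s2_path))]
  if (length(missing_files)) {
    msg <- paste0(
      "Supplementary-table transcriptions not found:\n  ",
      paste(missing_files, collapse = "\n  "),
      "\nTranscribe the published geochemistry table (samples in rows, ",
      "parameters in columns, 'b.d.l.'/'n.d.' tokens kept) and the ",
      "per-sample abundance table (percent values, taxa in rows, samples ",
      "in columns) as TSV, then rerun with those paths.")
    message(msg)
    return(structure(list(message = msg, missing = missing_files),
                     class = "reproduction_unavailable"))
  }
  otu <- read_otu_table(s2_path, scale = 0.01)
  geo_raw <- read_geochem_table(s1_path, bdl_policy = bdl_policy,
                                dl_map = dl_map)
  common <- intersect(sample_ids(otu), rownames(geo_raw$values))
  if (length(common) < 3L)
    stop_pathpls("pathpls_validation_error",
                 "fewer than 3 shared samples between the two tables")
  otu <- otu_table(otu$values[common, , drop = FALSE], unit = otu$unit,
                   taxonomy = otu$taxonomy)
  geo_raw <- geochem_table(geo_raw$values[common, , drop = FALSE],
                           geo_raw$mask[common, , drop = FALSE])

  grid <- expand.grid(community = c("hellinger", "raw_relative"),
                      geochem = c("log10_zscore", "zscore"),
                      missingness = c("column_median", "drop_incomplete"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    gv <- geo_raw$values
    if (g$missingness == "drop_incomplete")
      gv <- gv[, colSums(is.na(gv)) == 0L, drop = FALSE]
    conc <- colnames(gv)[is_concentration_var(colnames(gv))]
    geo <- suppressWarnings(prepare_block(
      gv, scale = TRUE,
      log10_vars = if (g$geochem == "log10_zscore") conc else character(),
      impute = "column_median"))
    taxa <- if (g$community == "hellinger") {
      prepare_block(hellinger_transform(otu), center = TRUE)
    } else {
      prepare_block(block(as_relative_values(otu)), center = TRUE)
    }
    fit <- two_block_pls(geo, taxa, n_axes = 1L)
    perm <- pls_permutation_test(geo, taxa, axis = 1L, n_perm = n_perm,
                                 seed = derive_seed(seed, i))
    data.frame(g, r1 = fit$r[1L], p_value = perm$p_value,
               matches_reference = if (is.null(reference_r1)) NA
                                   else round(fit$r[1L], 2) == round(reference_r1, 2),
               stringsAsFactors = FALSE)
  })
  structure(list(sweep = do.call(rbind, rows), grid_size = nrow(grid),
                 n_perm = as.integer(n_perm), seed = seed,
                 reference_r1 = reference_r1),
            class = "reproduction_sweep")
}
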