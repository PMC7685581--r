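GEOCHEM_NAME_POOL <- c(
  "Na (mg/l)", "K (mg/l)", "Ca (mg/l)", "Mg (mg/l)", "Cl (mg/l)",
  "SO4 (mg/l)", "HCO3 (mg/l)",
  "B (µg/l)", "Cu (µg/l)", "Ga (µg/l)", "Ge (µg/l)", "As (µg/l)",
  "Sb (µg/l)", "Hg (µg/l)", "Fe (µg/l)", "Al (µg/l)", "Li (µg/l)",
  "Rb (µg/l)", "Sr (µg/l)", "Cs (µg/l)", "Mo (µg/l)", "W (µg/l)")

DEGRADATION_PATHWAY_NAMES <- c(
  "Naphthalene degradation", "Benzoate degradation",
  "Ethylbenzene degradation", "Xylene degradation",
  "Nitrotoluene degradation", "Dioxin degradation", "Styrene degradation")

HOUSEKEEPING_PATHWAY_NAMES <- c(
  "Peptidoglycan biosynthesis", "Flagellar assembly", "Bacterial chemotaxis",
  "Bacterial secretion system", "Valine, leucine and isoleucine biosynthesis",
  "Lipopolysaccharide biosynthesis", "D-Alanine metabolism",
  "Phosphotransferase system (PTS)")

#' Configuration for the coupled synthetic dataset generator
#'
#' Defaults emulate the study conditions of a 10-sample hot-spring oil-site
#' survey: ~200 OTUs, per-sample read depths drawn from 12,000-29,000, a
#' 20-variable heterogeneous geochemical block (temperature, pH, Eh, TDS,
#' major ions in mg/l, trace elements in µg/l), and a single latent
#' environmental gradient that couples geochemistry, community composition
#' and degradation-pathway content with strength `coupling` (kappa in
#' `[0,1]`). The default coupling of 0.8 emulates the strong
#' community-geochemistry association such systems exhibit.
#'
#' @param n_samples number of samples.
#' @param n_taxa number of OTUs.
#' @param n_geochem_vars number of geochemical variables (>= 5).
#' @param depth_range integer range for per-sample read depth.
#' @param coupling latent-gradient coupling strength kappa in `[0,1]`.
#' @param taxon_response_scale scale of degrader log-abundance responses.
#' @param taxon_noise_sd per-cell log-abundance noise SD.
#' @param geochem_noise_sd base geochemical noise SD (heteroscedastic
#'   per-variable multipliers in [0.5, 1.5] are applied on top).
#' @param n_pathways catalog size (degradation pathways first, then
#'   housekeeping).
#' @param kos_per_pathway KO-set size per pathway.
#' @param degrader_fraction fraction of taxa designated hydrocarbon
#'   degraders (positive gradient response, degradation-pathway KOs).
#' @param trace_dl_ratio detection limit as a fraction of each trace
#'   element's baseline concentration; generated values below it are
#'   censored to "b.d.l." semantics.
#' @param overdispersion Dirichlet-multinomial overdispersion; 0 (default)
#'   gives plain multinomial read sampling.
#' @param seed mandatory RNG seed.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 10L, n_taxa = 200L,
                             n_geochem_vars = 20L,
                             depth_range = c(12000L, 29000L),
                             coupling = 0.8,
                             taxon_response_scale = 1.5,
                             taxon_noise_sd = 0.4,
                             geochem_noise_sd = 0.4,
                             n_pathways = 12L, kos_per_pathway = 10L,
                             degrader_fraction = 0.25,
                             trace_dl_ratio = 0.1,
                             overdispersion = 0,
                             seed) {
  if (missing(seed))
    stop_pathpls("pathpls_config_error", "synthetic_config: seed is mandatory")
  cfg <- list(n_samples = as.integer(n_samples), n_taxa = as.integer(n_taxa),
              n_geochem_vars = as.integer(n_geochem_vars),
              depth_range = as.integer(depth_range), coupling = coupling,
              taxon_response_scale = taxon_response_scale,
              taxon_noise_sd = taxon_noise_sd,
              geochem_noise_sd = geochem_noise_sd,
              n_pathways = as.integer(n_pathways),
              kos_per_pathway = as.integer(kos_per_pathway),
              degrader_fraction = degrader_fraction,
              trace_dl_ratio = trace_dl_ratio,
              overdispersion = overdispersion,
              seed = as.integer(seed))
  for (f in c("n_samples", "n_taxa", "n_geochem_vars", "n_pathways",
              "kos_per_pathway"))
    if (cfg[[f]] < 1L)
      stop_pathpls("pathpls_config_error", "%s must be >= 1", f)
  if (cfg$n_geochem_vars < 5L)
    stop_pathpls("pathpls_config_error", "n_geochem_vars must be >= 5")
  if (any(cfg$depth_range < 1L) || cfg$depth_range[1L] > cfg$depth_range[2L])
    stop_pathpls("pathpls_config_error", "invalid depth_range")
  if (cfg$coupling < 0 || cfg$coupling > 1)
    stop_pathpls("pathpls_config_error", "coupling must be in [0,1]")
  if (cfg$degrader_fraction <= 0 || cfg$degrader_fraction >= 1)
    stop_pathpls("pathpls_config_error", "degrader_fraction must be in (0,1)")
  if (cfg$taxon_noise_sd < 0 || cfg$geochem_noise_sd < 0 ||
      cfg$overdispersion < 0)
    stop_pathpls("pathpls_config_error", "noise parameters must be >= 0")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a coupled synthetic dataset
#'
#' One latent standard-normal gradient `z` per sample drives both blocks
#' (rank-1 coupling — the minimal structure under which both headline
#' associations, taxa-geochemistry and completeness-geochemistry, emerge
#' rather than being hard-coded):
#'
#' * geochemistry: concentration variables are log-normal,
#'   `log x_ij = log(base_j) + a_j * kappa * z_i + noise`; temperature,
#'   pH and Eh respond linearly on their natural scales (pH clipped to
#'   its physical range). Noise SDs are heteroscedastic across variables.
#'   Trace elements falling below a detection limit are censored with
#'   below-detection-limit semantics.
#' * community: taxon log relative abundance
#'   `lambda_ik = mu_k + b_k * kappa * z_i + noise`, softmax per sample,
#'   then multinomial read counts at a depth drawn from `depth_range`
#'   (Dirichlet-multinomial when `overdispersion > 0`).
#' * function: a `degrader_fraction` of taxa get strictly positive
#'   responses `b_k` and KO sets drawn from the degradation pathways of
#'   the catalog, so degradation-pathway completeness co-varies with `z`
#'   through which degraders pass the detection threshold; the remaining
#'   taxa carry housekeeping-pathway KOs.
#'
#' Ground truth (gradient, loadings, responses, degrader flags, and the
#' population axis correlation `rho` from a large-n noise-free
#' construction) is stored alongside the tables.
#'
#' @param cfg a [synthetic_config].
#' @return `synthetic_dataset` list: `otu` ([otu_table], counts with
#'   taxonomy), `geochem` ([geochem_table]), `db` ([annotation_db]),
#'   `catalog` ([pathway_catalog]), `dl_map`, `truth`, `config`.
#' @export
generate_coupled_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_samples
    smp <- sprintf("S%02d", seq_len(n))
    z <- stats::rnorm(n)

    geo <- generate_geochem(cfg, z, smp)
    com <- generate_community(cfg, z, smp)
    fun <- generate_annotation(cfg, com$degraders, com$taxa_labels)

    truth <- list(z = stats::setNames(z, smp),
                  a = geo$loadings, b = com$b, mu = com$mu,
                  degraders = com$degraders,
                  kappa = cfg$coupling, seed = cfg$seed)
    ds <- structure(list(otu = com$otu, geochem = geo$table, db = fun$db,
                         catalog = fun$catalog, dl_map = geo$dl_map,
                         truth = truth, config = cfg),
                    class = "synthetic_dataset")
    ds$truth$rho <- if (cfg$coupling == 0) 0 else population_axis_correlation(ds)
    ds
  })
}

generate_geochem <- function(cfg, z, smp) {
  n <- cfg$n_samples
  k <- cfg$coupling
  n_conc <- cfg$n_geochem_vars - 4L
  pool <- GEOCHEM_NAME_POOL
  if (n_conc > length(pool))
    pool <- c(pool, sprintf("Elem%02d (µg/l)", seq_len(n_conc - length(pool))))
  conc_names <- pool[seq_len(n_conc)]
  vars <- c("Temperature (°C)", "pH", "Eh (mV)", "TDS (g/l)", conc_names)

  vals <- matrix(NA_real_, n, length(vars), dimnames = list(smp, vars))
  mask <- matrix("measured", n, length(vars), dimnames = list(smp, vars))
  sgn <- function() sample(c(-1, 1), 1L, prob = c(0.3, 0.7))
  noise_mult <- stats::runif(length(vars), 0.5, 1.5)  # heteroscedastic
  loadings <- data.frame(variable = vars, loading = NA_real_,
                         scale_type = "log", stringsAsFactors = FALSE)

  # natural-scale variables: T, pH, Eh
  nat <- list(`Temperature (°C)` = c(center = 55, load = 20, sd = 12,
                                     lo = 9, hi = 97),
              pH = c(center = 5.5, load = 1.5, sd = 1.1, lo = 0.1, hi = 13.9),
              `Eh (mV)` = c(center = 80, load = 140, sd = 120,
                            lo = -Inf, hi = Inf))
  for (nm in names(nat)) {
    p <- nat[[nm]]
    a <- sgn() * p[["load"]] * stats::runif(1L, 0.6, 1.4)
    x <- p[["center"]] + a * k * z +
      cfg$geochem_noise_sd * p[["sd"]] * noise_mult[match(nm, vars)] *
        stats::rnorm(n)
    vals[, nm] <- pmin(pmax(x, p[["lo"]]), p[["hi"]])
    loadings$loading[loadings$variable == nm] <- a
    loadings$scale_type[loadings$variable == nm] <- "linear"
  }
  # log-normal concentration variables (TDS + ions + trace elements)
  conc_all <- c("TDS (g/l)", conc_names)
  base <- stats::setNames(
    c(0.4, exp(stats::runif(length(conc_names), log(1), log(300)))), conc_all)
  dl_map <- stats::setNames(numeric(0), character(0))
  for (nm in conc_all) {
    a <- sgn() * stats::runif(1L, 0.6, 1.4)
    lx <- log(base[[nm]]) + a * k * z +
      cfg$geochem_noise_sd * noise_mult[match(nm, vars)] * stats::rnorm(n)
    x <- exp(lx)
    if (grepl("µg/l", nm, fixed = TRUE)) {
      dl <- base[[nm]] * cfg$trace_dl_ratio
      dl_map[nm] <- dl
      cens <- x < dl
      x[cens] <- dl / 2             # half-DL convention for censored cells
      mask[cens, nm] <- "below_detection_limit"
    }
    vals[, nm] <- x
    loadings$loading[loadings$variable == nm] <- a
  }
  list(table = geochem_table(vals, mask), loadings = loadings, dl_map = dl_map)
}

generate_community <- function(cfg, z, smp) {
  n <- cfg$n_samples
  m <- cfg$n_taxa
  k <- cfg$coupling
  taxa <- sprintf("OTU%04d", seq_len(m))
  n_degr <- max(1L, round(cfg$degrader_fraction * m))
  degraders <- stats::setNames(rep(FALSE, m), taxa)
  degraders[sample.int(m, n_degr)] <- TRUE

  # degrader baselines sit just below the 0.05% detection convention, so
  # the latent gradient moves them across it
  mu <- stats::setNames(ifelse(degraders,
                               stats::rnorm(m, -2.2, 1.0),
                               stats::rnorm(m, 0, 1.6)), taxa)
  b <- stats::setNames(ifelse(degraders,
                              stats::runif(m, 0.6, 1.4) * cfg$taxon_response_scale,
                              stats::rnorm(m, 0, 0.5)), taxa)

  lambda <- outer(z * k, b) + matrix(mu, n, m, byrow = TRUE) +
    cfg$taxon_noise_sd * matrix(stats::rnorm(n * m), n, m)
  prob <- exp(lambda - apply(lambda, 1L, max))
  prob <- prob / rowSums(prob)
  depth <- sample(seq(cfg$depth_range[1L], cfg$depth_range[2L]), n,
                  replace = TRUE)
  counts <- matrix(0L, n, m, dimnames = list(smp, taxa))
  for (i in seq_len(n)) {
    p <- prob[i, ]
    if (cfg$overdispersion > 0) {
      g <- stats::rgamma(m, shape = p / cfg$overdispersion)
      p <- g / sum(g)
    }
    counts[i, ] <- stats::rmultinom(1L, depth[i], p)[, 1L]
  }

  phyla <- sprintf("Phylum%02d", sample.int(6L, m, replace = TRUE))
  lineage <- sprintf(
    "k__Bacteria; p__%s; c__Class%s; o__Order%s; f__Family%04d; g__Taxon%04d; s__",
    phyla, phyla, phyla, seq_len(m), seq_len(m))
  taxonomy <- stats::setNames(lineage, taxa)
  labels <- stats::setNames(sprintf("g__taxon%04d", seq_len(m)), taxa)

  list(otu = otu_table(counts, unit = "counts", taxonomy = taxonomy),
       mu = mu, b = b, degraders = degraders, taxa_labels = labels,
       prob = prob)
}

generate_annotation <- function(cfg, degraders, taxa_labels) {
  n_degr_pw <- min(length(DEGRADATION_PATHWAY_NAMES),
                   max(1L, ceiling(cfg$n_pathways * 0.6)))
  n_house <- cfg$n_pathways - n_degr_pw
  pw_names <- c(DEGRADATION_PATHWAY_NAMES[seq_len(n_degr_pw)],
                if (n_house > 0L) {
                  hn <- HOUSEKEEPING_PATHWAY_NAMES
                  if (n_house > length(hn))
                    hn <- c(hn, sprintf("Housekeeping pathway %02d",
                                        seq_len(n_house - length(hn))))
                  hn[seq_len(n_house)]
                })
  pw_ids <- sprintf("map%05d", 600 + seq_len(cfg$n_pathways))
  is_degr_pw <- seq_len(cfg$n_pathways) <= n_degr_pw
  ko_sets <- split(sprintf("K%05d", seq_len(cfg$n_pathways * cfg$kos_per_pathway)),
                   rep(seq_len(cfg$n_pathways), each = cfg$kos_per_pathway))
  catalog <- pathway_catalog(pw_ids, pw_names, ko_sets)

  degr_kos <- unlist(ko_sets[is_degr_pw], use.names = FALSE)
  house_kos <- unlist(ko_sets[!is_degr_pw], use.names = FALSE)
  if (!length(house_kos)) house_kos <- degr_kos
  sets <- lapply(seq_along(taxa_labels), function(i) {
    if (degraders[i]) {
      # one specialist pathway per degrader, sparse KO coverage: community
      # completeness then accumulates with how many degraders are detected
      pw <- sample(which(is_degr_pw), 1L)
      kos <- ko_sets[[pw]][stats::runif(cfg$kos_per_pathway) < 0.35]
      kos <- c(kos, house_kos[stats::runif(length(house_kos)) < 0.15])
    } else {
      pw <- which(!is_degr_pw)
      if (length(pw)) pw <- sample(pw, min(length(pw), sample(1:3, 1L)))
      kos <- unlist(lapply(ko_sets[pw], function(ks)
        ks[stats::runif(length(ks)) < 0.6]), use.names = FALSE)
      if (stats::runif(1L) < 0.05) kos <- c(kos, sample(degr_kos, 1L))
    }
    if (!length(kos)) kos <- sample(house_kos, 1L)
    unique(kos)
  })
  names(sets) <- taxa_labels
  list(db = annotation_db(sets, provenance = sprintf("synthetic seed=%d", cfg$seed)),
       catalog = catalog,
       degradation_pathways = pw_ids[is_degr_pw])
}

#' Population axis correlation of a synthetic dataset
#'
#' Recomputes the ground-truth first-axis correlation `rho` from the
#' stored truth by a large-n noise-free construction: `n_oracle` fresh
#' latent draws are pushed through the structural equations with all noise
#' terms at zero (no geochemical noise, no taxon noise, exact relative
#' abundances instead of multinomial reads), the standard block
#' preparation is applied, and the first two-block PLS axis correlation of
#' the resulting deterministic blocks is returned. Exactly 0 when
#' `kappa = 0`.
#'
#' @param ds a `synthetic_dataset`.
#' @param n_oracle number of latent draws for the construction.
#' @export
population_axis_correlation <- function(ds, n_oracle = 2000L) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  cfg <- ds$config
  if (cfg$coupling == 0) return(0)
  with_seed(derive_seed(cfg$seed, 7L), {
    z <- stats::rnorm(n_oracle)
    smp <- sprintf("Z%05d", seq_len(n_oracle))
    # noise-free geochem on the analysis scale (log for concentrations)
    ld <- ds$truth$a
    X <- vapply(seq_len(nrow(ld)), function(j) ld$loading[j] * cfg$coupling * z,
                numeric(n_oracle))
    dimnames(X) <- list(smp, ld$variable)
    keep <- apply(X, 2L, stats::sd) > 0
    Xb <- prepare_block(X[, keep, drop = FALSE], scale = TRUE)
    # noise-free community: exact softmax abundances, Hellinger
    lambda <- outer(z * cfg$coupling, ds$truth$b) +
      matrix(ds$truth$mu, n_oracle, cfg$n_taxa, byrow = TRUE)
    prob <- exp(lambda - apply(lambda, 1L, max))
    prob <- prob / rowSums(prob)
    dimnames(prob) <- list(smp, names(ds$truth$b))
    Yb <- prepare_block(hellinger_transform(
      otu_table(prob, unit = "relative")), center = TRUE)
    two_block_pls(Xb, Yb, n_axes = 1L)$r[1L]
  })
}

#' Generate a decoupled (null) dataset
#'
#' Same generator with the coupling forced to zero: blocks share no latent
#' structure and the truth correlation is exactly 0. Used for type-I-error
#' suites.
#'
#' @param cfg a [synthetic_config]; its `coupling` is overridden to 0.
#' @export
generate_null_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  cfg$coupling <- 0
  generate_coupled_dataset(cfg)
}

#' Write a synthetic dataset as a reloadable fixture directory
#'
#' Emits every table in its flat-text format (`otu_table.tsv`,
#' `geochem.tsv`, `annotations.tsv`, `pathways.tsv`), the ground truth as
#' `truth.json` (including seed and kappa), and a `manifest.json` listing
#' every file — the directory is self-describing and reloadable through
#' the package's readers.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_fixture <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- ds$config$seed
  files <- c(otu_table = "otu_table.tsv", geochem = "geochem.tsv",
             annotations = "annotations.tsv", pathways = "pathways.tsv",
             truth = "truth.json")
  write_otu_table(ds$otu, file.path(dir, files[["otu_table"]]), seed = seed)
  write_geochem_table(ds$geochem, file.path(dir, files[["geochem"]]), seed = seed)
  write_annotation_db(ds$db, file.path(dir, files[["annotations"]]), seed = seed)
  write_pathway_catalog(ds$catalog, file.path(dir, files[["pathways"]]),
                        seed = seed)
  truth <- ds$truth
  truth$a <- as.list(stats::setNames(truth$a$loading, truth$a$variable))
  jsonlite::write_json(
    c(truth, list(dl_map = as.list(ds$dl_map))),
    file.path(dir, files[["truth"]]), auto_unbox = TRUE, digits = NA)
  manifest <- list(generator = "pathpls synthetic_data",
                   version = as.character(utils::packageVersion("pathpls")),
                   seed = seed, kappa = ds$config$coupling,
                   files = as.list(files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
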