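# Synthetic-data generation with known ground truth for every pipeline
# input: phylogeny, Ames-test records, host-use lists, specimen metal
# concentrations with detection limits, and suitability rasters.
#
# Defaults mirror the scale of the field study the pipeline is designed
# for: 26 butterfly species with ~28 specimens each (~730 samples), four
# metals measured over three instrument runs with distinct detection
# limits, and a literature-style mutagenicity database with at least 56
# plant families reaching the 8-test threshold.

#' Default synthetic-study configuration
#'
#' @param n_species number of butterfly species.
#' @param n_per_species specimens per species and metal.
#' @param metals analyte names.
#' @param censor_targets named per-metal target censoring fractions used
#'   to place detection limits (defaults bracket 0--21%).
#' @param sigma_within within-species SD of log10(concentration + 1).
#' @param mu0 grand mean of species-level log concentrations (kept well
#'  above zero so negative instrument readings are rare, as in real
#'  ICP-MS data).
#' @param beta_range,beta_mut true standardized effects of range size and
#'   mutagenicity index on species mean log concentration.
#' @param sigma2_resid phylogenetic residual variance of species means.
#' @param lambda true Pagel's lambda of the residuals.
#' @param n_families,n_small_families plant families in the Ames table;
#'   `n_small_families` of them get fewer than `min_tests` tests to
#'   exercise the order-level fallback.
#' @param tests_range inclusive range of tests per data-rich family.
#' @param small_tests tests per data-poor family.
#' @param methodology_strength scale of the logit-linear methodology
#'   effects (0 disables them).
#' @param confounding strength of the association between a family's base
#'   mutagenicity and the methodology it tends to be tested with
#'   (0 = none).
#' @param min_tests family-level scoring threshold.
#' @param n_replicates technical replicates per specimen.
#' @param replicate_sd SD of additive instrument noise per replicate, raw
#'   units.
#' @param ensure_detectable keep every species detectable: cap detection
#'   limits below each species' peak concentration, as in the emulated
#'   study where no species fell entirely below detection.  Disable to
#'   allow degenerate all-censored scenarios.
#' @param raster_cellsize,raster_extent raster grid resolution (degrees)
#'   and extent `c(lon_min, lon_max, lat_min, lat_max)`.
#' @return configuration list.
#' @export
synth_config <- function(n_species = 26,
                         n_per_species = 28,
                         metals = c("Mn", "As", "Cd", "Pb"),
                         censor_targets = c(Mn = 0, As = 0.003,
                                            Cd = 0.13, Pb = 0.21),
                         sigma_within = 0.3,
                         mu0 = 1.5,
                         beta_range = 0.3,
                         beta_mut = 0.15,
                         sigma2_resid = 0.09,
                         lambda = 0.5,
                         n_families = 60,
                         n_small_families = 4,
                         tests_range = c(8, 40),
                         small_tests = 5,
                         methodology_strength = 0.8,
                         confounding = 0,
                         min_tests = 8,
                         n_replicates = 3,
                         replicate_sd = 0.005,
                         ensure_detectable = TRUE,
                         raster_cellsize = 1,
                         raster_extent = c(-130, -60, 10, 60)) {
  as.list(environment())
}

#' Simulate a pure-birth phylogeny
#'
#' Yule tree rescaled to unit height (ultrametric, so all root-to-tip
#' distances equal 1).
#'
#' @param n_tips number of tips (>= 2).
#' @param seed RNG seed.
#' @return `phylo` tree with tips `sp01`, `sp02`, ...
#' @export
gen_tree <- function(n_tips, seed = 1) {
  stopifnot(n_tips >= 2)
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  depths <- ape::node.depth.edgelength(tree)
  tree$edge.length <- tree$edge.length / max(depths[seq_len(n_tips)])
  tree$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  tree
}

#' Simulate a response under the PGLS generating model
#'
#' Draws from a multivariate normal with mean `X beta` and covariance
#' `sigma2 * V(lambda)`, `V` being the tree's phylogenetic covariance.
#'
#' @param tree `phylo` tree.
#' @param lambda true Pagel's lambda in `[0, 1]`.
#' @param beta coefficient vector (length `ncol(X)`).
#' @param X design matrix with rows ordered as `tree$tip.label`.
#' @param sigma2 residual variance (0 gives exactly `X beta`).
#' @param seed RNG seed.
#' @return named response vector.
#' @export
gen_traits <- function(tree, lambda, beta, X, sigma2, seed = 1) {
  set.seed(seed)
  X <- as.matrix(X)
  mu <- drop(X %*% beta)
  n <- nrow(X)
  if (sigma2 > 0) {
    V <- lambda_transform(vcv_from_tree(tree), lambda)
    y <- mu + drop(rnorm(n) %*% chol(sigma2 * V))
  } else {
    y <- mu
  }
  names(y) <- tree$tip.label
  y
}

# logit-linear methodology effects used by the Ames generator
ames_effects <- function(strength) {
  list(strain = c(TA98 = 0, TA100 = 0.8 * strength, other = -0.5 * strength),
       solvent_class = c(aqueous = 0, organic = 0.6 * strength),
       metabolic_activation = c(`0` = 0, `1` = 0.7 * strength))
}

#' Simulate a literature Ames-test database
#'
#' Families get true base mutagenicity rates from a Beta distribution;
#' each test's positive probability is the family base rate shifted on
#' the logit scale by methodology effects (strain, solvent class, S9
#' activation).  With `confounding > 0`, more-mutagenic families are
#' preferentially tested under high-positive-rate methodology, biasing
#' raw proportions but not the corrected scores.
#'
#' @param config a [synth_config()] list.
#' @param seed RNG seed.
#' @return list with `records` (an Ames record table) and `truth`
#'   (`base_rate` and `true_score` per family, the latter being the
#'   marginal-standardized positive probability over the realized
#'   covariate distribution).
#' @export
gen_ames <- function(config = synth_config(), seed = 1) {
  set.seed(seed)
  nf <- config$n_families
  families <- sprintf("fam%02d", seq_len(nf))
  orders <- sprintf("ord%02d", ceiling(seq_len(nf) / 3))
  base <- stats::rbeta(nf, 2, 4)
  pool <- seq(config$tests_range[1], config$tests_range[2])
  n_tests <- pool[sample.int(length(pool), nf, replace = TRUE)]
  if (config$n_small_families > 0) {
    small <- sample(nf, config$n_small_families)
    n_tests[small] <- config$small_tests
  }
  eff <- ames_effects(config$methodology_strength)

  rows <- vector("list", nf)
  for (i in seq_len(nf)) {
    m <- n_tests[i]
    # confounding: families with high base rates tend to be tested with
    # the high-positive-rate strain/solvent/activation combination
    p_hot <- stats::plogis(config$confounding * (qlogis_safe(base[i])))
    hot <- stats::runif(m) < p_hot
    strain <- ifelse(hot, "TA100",
                     sample(c("TA98", "other"), m, replace = TRUE))
    solvent <- ifelse(hot, "organic",
                      sample(c("aqueous", "organic"), m, replace = TRUE))
    activation <- ifelse(hot, 1L,
                         sample(c(0L, 1L), m, replace = TRUE))
    eta <- qlogis_safe(base[i]) + eff$strain[strain] +
      eff$solvent_class[solvent] +
      eff$metabolic_activation[as.character(activation)]
    outcome <- as.integer(stats::runif(m) < stats::plogis(eta))
    rows[[i]] <- data.frame(
      study_id = sprintf("study%02d_%02d", i, seq_len(m)),
      plant_species = sprintf("%s_plant%02d", families[i],
                              sample(seq_len(max(2, m %/% 3)), m,
                                     replace = TRUE)),
      plant_family = families[i],
      plant_order = orders[i],
      tissue = "leaf",
      solvent_class = solvent,
      strain = strain,
      metabolic_activation = activation,
      outcome = outcome,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL

  # true corrected score: mean positive probability for the family over
  # the pooled realized covariate distribution
  true_score <- vapply(seq_len(nf), function(i) {
    eta <- qlogis_safe(base[i]) + eff$strain[records$strain] +
      eff$solvent_class[records$solvent_class] +
      eff$metabolic_activation[as.character(records$metabolic_activation)]
    mean(stats::plogis(eta))
  }, numeric(1))

  list(records = records,
       truth = data.frame(family = families, order = orders,
                          n_tests = n_tests, base_rate = base,
                          true_score = true_score,
                          stringsAsFactors = FALSE))
}

qlogis_safe <- function(p) stats::qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6))

#' Simulate butterfly host-plant lists
#'
#' Each butterfly uses one to three plant families (drawn from the
#' data-rich families so the downstream index uses family-level scores),
#' with one to six listed host taxa per family.
#'
#' @param species butterfly species names.
#' @param score_truth the `truth` table from [gen_ames()].
#' @param min_tests family-level threshold; hosts are drawn from families
#'   with at least this many tests.
#' @param seed RNG seed.
#' @return data frame `butterfly_species`, `host_taxon`, `plant_family`.
#' @export
gen_hosts <- function(species, score_truth, min_tests = 8, seed = 1) {
  set.seed(seed)
  rich <- score_truth$family[score_truth$n_tests >= min_tests]
  rows <- lapply(species, function(sp) {
    fams <- sample(rich, sample(1:3, 1))
    do.call(rbind, lapply(fams, function(f) {
      k <- sample(1:6, 1)
      data.frame(butterfly_species = sp,
                 host_taxon = sprintf("%s_host%s_%d", f, sp, seq_len(k)),
                 plant_family = f, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate specimen metal measurements with detection limits
#'
#' Specimen log10(concentration + 1) values are normal around the
#' species mean; raw concentrations are back-transformed and measured as
#' `n_replicates` technical replicates with additive instrument noise.
#' Detection limits per metal are placed at the target censoring
#' fraction's quantile of the realized replicate-averaged concentrations
#' and spread over three runs (x0.9, x1.0, x1.1); bookkeeping records the
#' true censor flag of every replicate-averaged measurement.
#'
#' @param species_means named list: per metal, a named vector of species
#'   mean log concentrations.
#' @param config a [synth_config()] list.
#' @param seed RNG seed.
#' @return list with `raw` (replicate rows), `lods`, and `truth`
#'   (per-measurement censor flags and true specimen values).
#' @export
gen_specimens <- function(species_means, config = synth_config(), seed = 1) {
  set.seed(seed)
  metals <- names(species_means)
  n_rep <- config$n_replicates
  raw_rows <- list()
  truth_rows <- list()
  lod_rows <- list()
  for (m in metals) {
    mu <- species_means[[m]]
    sp <- names(mu)
    n_per <- config$n_per_species
    spec_sp <- rep(sp, each = n_per)
    spec_id <- sprintf("%s_%s_%02d", m, spec_sp,
                       rep(seq_len(n_per), times = length(sp)))
    y_true <- stats::rnorm(length(spec_sp), mu[spec_sp],
                           config$sigma_within)
    raw_true <- 10^y_true - 1
    run_id <- sample(paste0("run", 1:3), length(spec_sp), replace = TRUE)
    reps <- matrix(raw_true, nrow = length(spec_sp), ncol = n_rep) +
      matrix(stats::rnorm(length(spec_sp) * n_rep, 0, config$replicate_sd),
             nrow = length(spec_sp))
    raw_avg <- rowMeans(reps)

    target <- config$censor_targets[[m]]
    base_lod <- if (is.null(target) || target <= 0) {
      1e-9
    } else {
      max(as.numeric(stats::quantile(raw_avg, target)), 1e-9)
    }
    if (isTRUE(config$ensure_detectable)) {
      # detection limits sit well below every species' peak concentration
      # (in the emulated study no species was entirely below detection),
      # so cap the LOD under the smallest per-species maximum
      sp_max <- tapply(raw_avg, spec_sp, max)
      base_lod <- max(min(base_lod, 0.99 * min(sp_max) / 1.1), 1e-9)
    }
    run_mult <- c(run1 = 0.9, run2 = 1.0, run3 = 1.1)
    lods <- base_lod * run_mult
    lod_rows[[m]] <- data.frame(metal = m, run_id = names(run_mult),
                                lod = as.numeric(lods),
                                stringsAsFactors = FALSE)
    censored <- raw_avg < as.numeric(lods[run_id]) | raw_avg < 0

    raw_rows[[m]] <- data.frame(
      specimen_id = rep(spec_id, each = n_rep),
      butterfly_species = rep(spec_sp, each = n_rep),
      site_id = rep(sprintf("site%02d", sample(34, length(spec_sp),
                                               replace = TRUE)),
                    each = n_rep),
      metal = m,
      run_id = rep(run_id, each = n_rep),
      raw_concentration = as.numeric(t(reps)),
      stringsAsFactors = FALSE)
    truth_rows[[m]] <- data.frame(
      specimen_id = spec_id, butterfly_species = spec_sp, metal = m,
      y_true = y_true, raw_avg = raw_avg, censored = censored,
      stringsAsFactors = FALSE)
  }
  list(raw = do.call(rbind, raw_rows),
       lods = do.call(rbind, lod_rows),
       truth = do.call(rbind, truth_rows))
}

#' Simulate a suitability raster with known retained area
#'
#' Fields: `"constant"` (uniform suitability), `"halfplane"` (high
#' suitability west of a longitude split, low east of it), or `"block"`
#' (high inside a lon/lat rectangle, low outside).  The analytic area of
#' cells at or above the threshold is returned alongside.
#'
#' @param field field type.
#' @param extent `c(lon_min, lon_max, lat_min, lat_max)` degrees.
#' @param cellsize cell edge, degrees (must divide the extent evenly).
#' @param value suitability of the high region.
#' @param low suitability of the low region.
#' @param block for `"block"`: rectangle `c(lon_min, lon_max, lat_min,
#'   lat_max)` snapped to the grid; for `"halfplane"`: the split
#'   longitude.
#' @param threshold threshold used for the analytic retained area.
#' @param radius_km sphere radius.
#' @return list `raster` (a `suitability_raster`) and `true_area_km2`.
#' @export
gen_raster <- function(field = c("constant", "halfplane", "block"),
                       extent = c(-130, -60, 10, 60), cellsize = 1,
                       value = 0.8, low = 0.05, block = NULL,
                       threshold = 0.2, radius_km = earth_radius_km()) {
  field <- match.arg(field)
  ncols <- round((extent[2] - extent[1]) / cellsize)
  nrows <- round((extent[4] - extent[3]) / cellsize)
  stopifnot(ncols > 0, nrows > 0)
  lon_left <- extent[1] + (seq_len(ncols) - 1) * cellsize
  lat_top <- extent[4] - (seq_len(nrows) - 1) * cellsize

  m <- matrix(low, nrows, ncols)
  if (field == "constant") {
    m[] <- value
  } else if (field == "halfplane") {
    split <- if (is.null(block)) (extent[1] + extent[2]) / 2 else block[1]
    m[, lon_left < split] <- value
  } else {
    stopifnot(length(block) == 4)
    in_lon <- lon_left >= block[1] & lon_left < block[2]
    in_lat <- lat_top <= block[4] & lat_top > block[3]
    m[in_lat, in_lon] <- value
  }
  r <- suitability_raster(m, extent[1], extent[3], cellsize)
  mask_true <- m >= threshold
  lat_n <- extent[4] - (seq_len(nrows) - 1) * cellsize
  row_area <- cell_area_km2(lat_n - cellsize, lat_n, cellsize, radius_km)
  list(raster = r, true_area_km2 = sum(rowSums(mask_true) * row_area),
       true_n_cells = sum(mask_true))
}

#' Simulate a complete input bundle with ground truth
#'
#' Generates, under one seed, every pipeline input: the phylogeny, the
#' Ames database, host lists, per-species suitability rasters, and
#' specimen metal concentrations whose species means follow the PGLS
#' generating model (standardized true range area and true mutagenicity
#' index as predictors, phylogenetic residuals at the configured lambda).
#'
#' @param config a [synth_config()] list.
#' @param seed master RNG seed; stage seeds are derived from it.
#' @return list with elements `tree`, `ames_records`, `host_records`,
#'   `specimens`, `lods`, `rasters` (named list), `config`, `seed`, and
#'   `truth` (family scores, species index, range areas, species means
#'   per metal, censor flags, generating parameters).
#' @export
simulate_bundle <- function(config = synth_config(), seed = 1) {
  sp_seed <- function(k) (seed * 97 + k) %% .Machine$integer.max
  n <- config$n_species
  tree <- gen_tree(n, seed = sp_seed(1))
  species <- tree$tip.label

  ames <- gen_ames(config, seed = sp_seed(2))
  hosts <- gen_hosts(species, ames$truth, min_tests = config$min_tests,
                     seed = sp_seed(3))

  # true mutagenicity index from true corrected scores and host counts
  w <- weights_from_host_lists(hosts)
  sc <- ames$truth$true_score[match(w$plant_family, ames$truth$family)]
  true_index <- vapply(species, function(s) {
    rows <- w$butterfly_species == s
    sum(w$weight[rows] * sc[rows])
  }, numeric(1))

  # per-species rasters: suitability blocks of varying extent
  set.seed(sp_seed(4))
  ext <- config$raster_extent
  rasters <- list()
  true_area <- numeric(n)
  for (i in seq_len(n)) {
    w_lon <- sample(seq(10, ext[2] - ext[1] - 5, by = 5), 1)
    w_lat <- sample(seq(10, ext[4] - ext[3] - 5, by = 5), 1)
    x0 <- ext[1] + sample(0:(ext[2] - ext[1] - w_lon), 1)
    y0 <- ext[3] + sample(0:(ext[4] - ext[3] - w_lat), 1)
    g <- gen_raster("block", extent = ext, cellsize = config$raster_cellsize,
                    block = c(x0, x0 + w_lon, y0, y0 + w_lat))
    rasters[[species[i]]] <- g$raster
    true_area[i] <- g$true_area_km2
  }
  names(true_area) <- species

  z_range <- standardize(true_area)
  z_mut <- standardize(true_index)
  X <- cbind(intercept = 1, range_z = z_range, mutagenicity_z = z_mut)
  rownames(X) <- species

  species_means <- list()
  for (j in seq_along(config$metals)) {
    m <- config$metals[j]
    species_means[[m]] <- gen_traits(
      tree, lambda = config$lambda,
      beta = c(config$mu0, config$beta_range, config$beta_mut),
      X = X, sigma2 = config$sigma2_resid, seed = sp_seed(10 + j))
  }

  spec <- gen_specimens(species_means, config, seed = sp_seed(30))

  list(tree = tree,
       ames_records = ames$records,
       host_records = hosts,
       specimens = spec$raw,
       lods = spec$lods,
       rasters = rasters,
       config = config,
       seed = seed,
       truth = list(family_scores = ames$truth,
                    true_index = true_index,
                    true_area_km2 = true_area,
                    z_range = z_range, z_mut = z_mut,
                    design = X,
                    species_means = species_means,
                    censoring = spec$truth,
                    lambda = config$lambda,
                    beta = c(config$mu0, config$beta_range,
                             config$beta_mut)))
}

#' Write a synthetic bundle to disk as plain-text files
#'
#' Tables as CSV, the tree as Newick, rasters as ESRI ASCII grids, and a
#' ground-truth manifest as JSON.
#'
#' @param bundle output of [simulate_bundle()].
#' @param outdir directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(bundle$tree, file.path(outdir, "tree.nwk"))
  utils::write.csv(bundle$ames_records,
                   file.path(outdir, "ames_records.csv"), row.names = FALSE)
  utils::write.csv(bundle$host_records,
                   file.path(outdir, "host_records.csv"), row.names = FALSE)
  utils::write.csv(bundle$specimens,
                   file.path(outdir, "specimens.csv"), row.names = FALSE)
  utils::write.csv(bundle$lods, file.path(outdir, "lods.csv"),
                   row.names = FALSE)
  rdir <- file.path(outdir, "rasters")
  dir.create(rdir, showWarnings = FALSE)
  for (sp in names(bundle$rasters)) {
    write_esri_ascii(bundle$rasters[[sp]],
                     file.path(rdir, paste0(sp, ".asc")))
  }
  manifest <- list(seed = bundle$seed,
                   lambda = bundle$truth$lambda,
                   beta = bundle$truth$beta,
                   true_index = as.list(bundle$truth$true_index),
                   true_area_km2 = as.list(bundle$truth$true_area_km2))
  jsonlite::write_json(manifest, file.path(outdir, "truth_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Read a bundle written by [write_bundle()]
#'
#' @param dir bundle directory.
#' @return list with the same data elements as [simulate_bundle()]
#'   (without the in-memory `truth`).
#' @export
read_bundle <- function(dir) {
  rfiles <- list.files(file.path(dir, "rasters"), pattern = "\\.asc$",
                       full.names = TRUE)
  rasters <- lapply(rfiles, read_esri_ascii)
  names(rasters) <- sub("\\.asc$", "", basename(rfiles))
  list(tree = ape::read.tree(file.path(dir, "tree.nwk")),
       ames_records = utils::read.csv(file.path(dir, "ames_records.csv"),
                                      stringsAsFactors = FALSE),
       host_records = utils::read.csv(file.path(dir, "host_records.csv"),
                                      stringsAsFactors = FALSE),
       specimens = utils::read.csv(file.path(dir, "specimens.csv"),
                                   stringsAsFactors = FALSE),
       lods = utils::read.csv(file.path(dir, "lods.csv"),
                              stringsAsFactors = FALSE),
       rasters = rasters)
}

#' Monte-Carlo power for detecting the range-size effect
#'
#' Re-draws species mean log concentrations under the bundle's generating
#' model (same tree, same standardized predictors, same effect sizes),
#' adds the sampling error of a species summary estimated from
#' `n_per_species` specimens, fits the PGLS, and counts replicates where
#' the range-size slope is positive with p below `alpha`.
#'
#' @param bundle output of [simulate_bundle()].
#' @param n_reps Monte-Carlo replicates.
#' @param alpha test level.
#' @param seed RNG seed.
#' @param grid_points lambda profile grid size passed to the PGLS fit.
#' @return detection proportion.
#' @export
estimate_detection_power <- function(bundle, n_reps = 200, alpha = 0.05,
                                     seed = 1, grid_points = 41) {
  cfg <- bundle$config
  X <- bundle$truth$design
  tree <- bundle$tree
  se_summary <- cfg$sigma_within / sqrt(cfg$n_per_species)
  hits <- 0L
  for (r in seq_len(n_reps)) {
    mu <- gen_traits(tree, cfg$lambda,
                     c(cfg$mu0, cfg$beta_range, cfg$beta_mut),
                     X, cfg$sigma2_resid,
                     seed = (seed * 1013 + r) %% .Machine$integer.max)
    set.seed((seed * 2027 + r) %% .Machine$integer.max)
    mu_hat <- mu + stats::rnorm(length(mu), 0, se_summary)
    fit <- fit_pgls_ml_lambda(mu_hat, X, tree = tree,
                              grid_points = grid_points)
    co <- fit$coefficients["range_z", ]
    if (co$estimate > 0 && co$p < alpha) hits <- hits + 1L
  }
  hits / n_reps
}
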