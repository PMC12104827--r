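# End-to-end orchestration: Ames scoring -> host-weighted mutagenicity
# index -> censored species metal summaries -> range areas -> one PGLS
# model per metal x tolerance proxy.

#' Default pipeline configuration
#'
#' @param min_tests family-level Ames scoring threshold.
#' @param covariates methodology covariates corrected for.
#' @param penalty separation ridge penalty for the Ames model.
#' @param lod_averaging `"mean"` or `"run"` censor-bound rule.
#' @param log_offset offset in the log10 transform of concentrations.
#' @param threshold suitability cutoff for range areas.
#' @param radius_km Earth radius for cell areas.
#' @param grid_points lambda profile grid size.
#' @param aliases named list of lumped taxa applied to range estimates
#'   and, by relabeling, to every species column (e.g.
#'   `list(lumped = c("a", "b"))`).
#' @param tree_substitutions named character vector
#'   `c(placeholder = target)` of tip relabelings applied to the tree.
#' @param holm logical; apply a Holm correction across the per-model
#'   overall F p-values in the report (off by default: the models are
#'   reported with raw p values).
#' @return configuration list.
#' @export
pipeline_config <- function(min_tests = 8,
                            covariates = ames_default_covariates(),
                            penalty = 0.5,
                            lod_averaging = "mean",
                            log_offset = 1,
                            threshold = 0.2,
                            radius_km = earth_radius_km(),
                            grid_points = 101,
                            aliases = list(),
                            tree_substitutions = character(0),
                            holm = FALSE) {
  as.list(environment())
}

apply_aliases_vector <- function(x, aliases) {
  for (lumped in names(aliases)) {
    x[x %in% aliases[[lumped]]] <- lumped
  }
  x
}

#' Run the full comparative analysis
#'
#' Stages: (1) methodology-corrected family mutagenicity scores with the
#' order-level fallback; (2) host-weighted species mutagenicity index;
#' (3) replicate averaging, censor encoding, and censored-ML species
#' summaries per metal; (4) thresholded spherical range areas with
#' lumped-taxon averaging; (5) species-name reconciliation against the
#' phylogeny (hard error on any mismatch); (6) for every metal, one PGLS
#' model per tolerance proxy (observed maximum and predicted mean), with
#' standardized range size and mutagenicity index as predictors and
#' maximum-likelihood Pagel's lambda.
#'
#' @param bundle input list with elements `tree`, `ames_records`,
#'   `host_records`, `specimens`, `lods`, `rasters` (as produced by
#'   [simulate_bundle()] or [read_bundle()]).
#' @param config a [pipeline_config()] list.
#' @return list of class `metaltol_run`: `analysis_table` (one row per
#'   species), `fits` (named `pgls_fit` list, `<metal>_max` and
#'   `<metal>_predicted`), `model_table` (per-model coefficients, lambda,
#'   F, adjusted R^2), `family_scores`, `species_index`, `ranges`,
#'   `metal_summary`, `censoring`, and `log`.
#' @export
run_all <- function(bundle, config = pipeline_config()) {
  t0 <- Sys.time()

  # stage 1: Ames family scores
  records <- validate_ames_records(bundle$ames_records)
  model <- fit_methodology_model(records, covariates = config$covariates,
                                 penalty = config$penalty)
  scores <- family_scores(records, model, min_tests = config$min_tests)

  # stage 2: species mutagenicity index
  host_w <- weights_from_host_lists(bundle$host_records)
  host_w$butterfly_species <- apply_aliases_vector(host_w$butterfly_species,
                                                   config$aliases)
  if (length(config$aliases) > 0) {
    # merging host lists of lumped taxa can duplicate family rows;
    # re-aggregate and renormalize
    agg <- stats::aggregate(weight ~ butterfly_species + plant_family,
                            data = host_w, FUN = sum)
    tot <- tapply(agg$weight, agg$butterfly_species, sum)
    agg$weight <- agg$weight / as.numeric(tot[agg$butterfly_species])
    host_w <- agg
  }
  index <- species_mutagenicity_index(host_w, scores)

  # stage 3: censored metal summaries
  meas <- average_replicates(bundle$specimens)
  meas$butterfly_species <- apply_aliases_vector(meas$butterfly_species,
                                                 config$aliases)
  values <- encode_censored(meas, bundle$lods,
                            lod_averaging = config$lod_averaging,
                            log_offset = config$log_offset)
  metal_summary <- summarize_species_metals(values)
  censoring <- censor_report(values)

  # stage 4: range areas
  ranges <- range_table(bundle$rasters, threshold = config$threshold,
                        radius_km = config$radius_km)
  if (length(config$aliases) > 0) {
    ranges <- merge_taxa(ranges, config$aliases)
  }

  # stage 5: reconcile species across inputs and tree
  tree <- bundle$tree
  for (ph in names(config$tree_substitutions)) {
    tree <- substitute_taxon(tree, ph, config$tree_substitutions[[ph]])
  }
  species <- sort(tree$tip.label)
  check_species <- function(found, what) {
    miss <- setdiff(species, found)
    extra <- setdiff(found, species)
    if (length(miss) > 0 || length(extra) > 0) {
      stop("species mismatch in ", what,
           if (length(miss) > 0)
             paste0("; absent: ", paste(miss, collapse = ", ")),
           if (length(extra) > 0)
             paste0("; not in tree: ", paste(extra, collapse = ", ")),
           call. = FALSE)
    }
  }
  check_species(unique(index$butterfly_species), "host records")
  check_species(unique(metal_summary$butterfly_species), "metal data")
  check_species(unique(ranges$species), "range estimates")

  # stage 6: analysis table and PGLS models
  tab <- data.frame(species = species, stringsAsFactors = FALSE)
  tab$mutagenicity_index <- index$index[match(species,
                                              index$butterfly_species)]
  tab$range_area_km2 <- ranges$area_km2[match(species, ranges$species)]
  metals <- sort(unique(metal_summary$metal))
  for (m in metals) {
    sub <- metal_summary[metal_summary$metal == m, , drop = FALSE]
    i <- match(species, sub$butterfly_species)
    tab[[paste0(m, "_max")]] <- sub$max_observed_log[i]
    tab[[paste0(m, "_predicted")]] <- sub$predicted_mean_log[i]
  }

  X <- cbind(intercept = 1,
             range_z = standardize(tab$range_area_km2),
             mutagenicity_z = standardize(tab$mutagenicity_index))
  rownames(X) <- species

  fits <- list()
  for (m in metals) {
    for (kind in c("max", "predicted")) {
      y <- tab[[paste0(m, "_", kind)]]
      names(y) <- species
      if (anyNA(y)) {
        stop("missing ", kind, " tolerance proxy for ", m, " in: ",
             paste(species[is.na(y)], collapse = ", "), call. = FALSE)
      }
      fits[[paste0(m, "_", kind)]] <-
        fit_pgls_ml_lambda(y, X, tree = tree,
                           grid_points = config$grid_points)
    }
  }

  model_table <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(model = nm,
               n = f$n,
               lambda = f$lambda,
               range_estimate = f$coefficients["range_z", "estimate"],
               range_t = f$coefficients["range_z", "t"],
               range_p = f$coefficients["range_z", "p"],
               mutagenicity_estimate =
                 f$coefficients["mutagenicity_z", "estimate"],
               mutagenicity_t = f$coefficients["mutagenicity_z", "t"],
               mutagenicity_p = f$coefficients["mutagenicity_z", "p"],
               f_value = unname(f$fstatistic["value"]),
               f_df1 = unname(f$fstatistic["numdf"]),
               f_df2 = unname(f$fstatistic["dendf"]),
               f_p = f$f_p,
               adj_r_squared = f$adj.r.squared,
               stringsAsFactors = FALSE)
  }))
  if (isTRUE(config$holm)) {
    model_table$f_p_holm <- stats::p.adjust(model_table$f_p,
                                            method = "holm")
  }
  rownames(model_table) <- NULL

  out <- list(analysis_table = tab, fits = fits,
              model_table = model_table,
              family_scores = scores, species_index = index,
              ranges = ranges, metal_summary = metal_summary,
              censoring = censoring,
              log = list(n_species = length(species),
                         metals = metals,
                         n_models = length(fits),
                         config = config,
                         started = t0,
                         finished = Sys.time()))
  class(out) <- "metaltol_run"
  out
}

#' @export
print.metaltol_run <- function(x, ...) {
  cat("metaltol pipeline run:", x$log$n_species, "species,",
      x$log$n_models, "PGLS models (",
      paste(x$log$metals, collapse = ", "), ")\n\n")
  print(x$model_table, digits = 3)
  invisible(x)
}

#' Write pipeline reports as delimited text
#'
#' Writes the species analysis table, the per-model summary table, the
#' family score table and a human-readable per-model summary.
#'
#' @param run a `metaltol_run` object.
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_reports <- function(run, outdir) {
  stopifnot(inherits(run, "metaltol_run"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$analysis_table,
                   file.path(outdir, "analysis_table.csv"),
                   row.names = FALSE)
  utils::write.csv(run$model_table,
                   file.path(outdir, "model_table.csv"), row.names = FALSE)
  utils::write.csv(run$family_scores,
                   file.path(outdir, "family_scores.csv"),
                   row.names = FALSE)
  con <- file(file.path(outdir, "model_summaries.txt"), "w")
  on.exit(close(con))
  for (nm in names(run$fits)) {
    writeLines(paste0("== ", nm, " =="), con)
    writeLines(utils::capture.output(print(run$fits[[nm]])), con)
    writeLines("", con)
  }
  invisible(outdir)
}
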