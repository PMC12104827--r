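# Species metal-tolerance proxies from left-censored tissue concentrations.
#
# Concentrations below an ICP-MS run's limit of detection (LOD), or
# returned as negative, are left-censored: all we know is that the true
# log10(concentration + 1) lies below the (log-transformed) LOD bound.
# Species means are estimated by maximizing the censored-normal
# likelihood; the observed species maximum over uncensored values is kept
# as a second, distribution-free tolerance proxy.

#' Average technical replicates per specimen and metal
#'
#' Each specimen is run several times on the instrument; replicates are
#' collapsed to their arithmetic mean.  Rows must share `specimen_id` and
#' `metal` to be treated as replicates.  Missing replicate values are
#' dropped from the mean and flagged.
#'
#' @param raw data frame with columns `specimen_id`, `butterfly_species`,
#'   `metal`, `run_id`, `raw_concentration` (and optionally `site_id`).
#' @return one row per specimen x metal with the averaged concentration
#'   and a `had_missing` flag.
#' @export
average_replicates <- function(raw) {
  stopifnot(is.data.frame(raw))
  need <- c("specimen_id", "butterfly_species", "metal", "run_id",
            "raw_concentration")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("specimen table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) stop("no replicate rows to average", call. = FALSE)
  key <- interaction(raw$specimen_id, raw$metal, drop = TRUE)
  first <- !duplicated(key)
  out <- raw[first, setdiff(need, "raw_concentration"), drop = FALSE]
  if ("site_id" %in% names(raw)) out$site_id <- raw$site_id[first]
  means <- tapply(raw$raw_concentration, key, mean, na.rm = TRUE)
  nmiss <- tapply(is.na(raw$raw_concentration), key, sum)
  out$raw_concentration <- as.numeric(means[as.character(key[first])])
  out$had_missing <- as.integer(nmiss[as.character(key[first])]) > 0
  out$raw_concentration[is.nan(out$raw_concentration)] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Encode measurements as censored log-scale values
#'
#' A measurement is censored iff its averaged raw concentration is below
#' its run's LOD or is negative.  Uncensored values are transformed to
#' `log10(raw + offset)`; the offset (1 by default) keeps all transformed
#' values nonnegative.  The censor bound is `log10(LOD + offset)` using
#' either the mean LOD across runs per metal (`lod_averaging = "mean"`,
#' the default) or the run-specific LOD (`"run"`).
#'
#' @param measurements output of [average_replicates()].
#' @param lods data frame with columns `metal`, `run_id`, `lod`
#'   (all `lod` > 0).
#' @param lod_averaging `"mean"` or `"run"`.
#' @param log_offset offset added before the log10 transform.
#' @return data frame of class `censored_values` with columns
#'   `specimen_id`, `butterfly_species`, `metal`, `y` (NA when censored),
#'   `censored`, `bound`.
#' @export
encode_censored <- function(measurements, lods,
                            lod_averaging = c("mean", "run"),
                            log_offset = 1) {
  lod_averaging <- match.arg(lod_averaging)
  stopifnot(is.data.frame(measurements), is.data.frame(lods))
  if (any(lods$lod <= 0)) stop("all LODs must be positive", call. = FALSE)
  no_lod <- setdiff(unique(measurements$metal), unique(lods$metal))
  if (length(no_lod) > 0) {
    stop("no detection limit recorded for metal(s): ",
         paste(no_lod, collapse = ", "), call. = FALSE)
  }
  m <- measurements[!is.na(measurements$raw_concentration), , drop = FALSE]
  n_dropped <- nrow(measurements) - nrow(m)
  if (n_dropped > 0) {
    warning(n_dropped, " measurement(s) with missing concentration dropped")
  }
  run_lod <- lods$lod[match(paste(m$metal, m$run_id),
                            paste(lods$metal, lods$run_id))]
  if (anyNA(run_lod)) {
    stop("no detection limit for metal/run pair(s): ",
         paste(unique(paste(m$metal, m$run_id)[is.na(run_lod)]),
               collapse = "; "), call. = FALSE)
  }
  mean_lod <- tapply(lods$lod, lods$metal, mean)
  censored <- m$raw_concentration < run_lod | m$raw_concentration < 0
  bound <- if (lod_averaging == "mean") {
    log10(as.numeric(mean_lod[m$metal]) + log_offset)
  } else {
    log10(run_lod + log_offset)
  }
  out <- data.frame(
    specimen_id = m$specimen_id,
    butterfly_species = m$butterfly_species,
    metal = m$metal,
    y = ifelse(censored, NA_real_, log10(m$raw_concentration + log_offset)),
    censored = censored,
    bound = bound,
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("censored_values", class(out))
  out
}

# Negative log-likelihood, gradient and Hessian for the censored-normal
# species-means model.  theta = (mu_1..mu_S, log sigma); x holds y for
# uncensored rows and the censor bound for censored rows.
censored_negll <- function(theta, s, x, cens) {
  S <- length(theta) - 1L
  mu <- theta[seq_len(S)][s]
  sigma <- exp(theta[S + 1L])
  ll <- numeric(length(x))
  ll[!cens] <- stats::dnorm(x[!cens], mu[!cens], sigma, log = TRUE)
  ll[cens] <- stats::pnorm(x[cens], mu[cens], sigma, log.p = TRUE)
  -sum(ll)
}

censored_negll_grad <- function(theta, s, x, cens) {
  S <- length(theta) - 1L
  mu <- theta[seq_len(S)][s]
  sigma <- exp(theta[S + 1L])
  z <- (x - mu) / sigma
  dmu <- numeric(length(x))
  dls <- numeric(length(x))
  dmu[!cens] <- z[!cens] / sigma
  dls[!cens] <- z[!cens]^2 - 1
  if (any(cens)) {
    zc <- z[cens]
    # inverse Mills ratio for the lower tail, computed on the log scale
    lam <- exp(stats::dnorm(zc, log = TRUE) - stats::pnorm(zc, log.p = TRUE))
    dmu[cens] <- -lam / sigma
    dls[cens] <- -lam * zc
  }
  g_mu <- -as.numeric(rowsum(dmu, s, reorder = TRUE))
  # rowsum orders by sorted unique group; map back to 1..S
  g <- numeric(S + 1L)
  g[sort(unique(s))] <- g_mu
  g[S + 1L] <- -sum(dls)
  g
}

censored_negll_hess <- function(theta, s, x, cens) {
  S <- length(theta) - 1L
  mu <- theta[seq_len(S)][s]
  sigma <- exp(theta[S + 1L])
  z <- (x - mu) / sigma
  h_mm <- numeric(length(x))   # d2 ll / d mu^2
  h_ms <- numeric(length(x))   # d2 ll / d mu d logsigma
  h_ss <- numeric(length(x))   # d2 ll / d logsigma^2
  u <- !cens
  h_mm[u] <- -1 / sigma^2
  h_ms[u] <- -2 * z[u] / sigma
  h_ss[u] <- -2 * z[u]^2
  if (any(cens)) {
    zc <- z[cens]
    lam <- exp(stats::dnorm(zc, log = TRUE) - stats::pnorm(zc, log.p = TRUE))
    h_mm[cens] <- -(zc * lam + lam^2) / sigma^2
    h_ms[cens] <- (lam - zc^2 * lam - zc * lam^2) / sigma
    h_ss[cens] <- lam * zc - zc^3 * lam - zc^2 * lam^2
  }
  H <- matrix(0, S + 1L, S + 1L)
  idx <- sort(unique(s))
  H[cbind(idx, idx)] <- as.numeric(rowsum(h_mm, s, reorder = TRUE))
  ms <- as.numeric(rowsum(h_ms, s, reorder = TRUE))
  H[idx, S + 1L] <- ms
  H[S + 1L, idx] <- ms
  H[S + 1L, S + 1L] <- sum(h_ss)
  H   # Hessian of the LOG-likelihood (not negated)
}

censored_optimize <- function(s, x, cens, S) {
  # naive start: censored values imputed at their bound
  mu0 <- as.numeric(tapply(x, factor(s, levels = seq_len(S)), mean))
  mu0[is.na(mu0)] <- mean(x)
  sd0 <- max(stats::sd(x), 0.05)
  starts <- list(c(mu0, log(sd0)),
                 c(mu0, log(sd0 * 2)),
                 c(mu0, log(pmax(sd0 / 2, 1e-3))))
  best <- NULL
  for (st in starts) {
    opt <- try(stats::optim(st, censored_negll, censored_negll_grad,
                            s = s, x = x, cens = cens,
                            method = "L-BFGS-B",
                            lower = c(rep(-Inf, S), log(1e-8)),
                            upper = c(rep(Inf, S), log(1e8)),
                            control = list(maxit = 1000, factr = 1e4)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value - 1e-10) best <- opt
  }
  if (is.null(best)) {
    stop("censored ML optimization failed for all starts", call. = FALSE)
  }
  best
}

#' Censored-normal maximum likelihood for species means of one metal
#'
#' Fits per-species means and a shared standard deviation on the
#' log10(concentration + offset) scale, with left-censored observations
#' contributing the normal tail probability below their bound.
#' Species with no uncensored observation have an unidentifiable mean on
#' this likelihood's boundary; they are flagged and excluded from the fit
#' and from the species-effect contrast.  A Wald chi-square test of equal
#' means across the fitted species and a likelihood-ratio pseudo-R^2
#' (Cox-Snell, with its Nagelkerke normalization) are reported.
#'
#' @param values a `censored_values` data frame restricted to one metal.
#' @return object of class `censored_fit` with elements `mu` (named per
#'   species), `sigma`, `se_mu`, `loglik`, `wald` (the chi-square
#'   statistic and df, a small-sample F-calibrated `p.value`, and the
#'   asymptotic `p_chisq`), `pseudo_r2`, `n`, `n_censored`,
#'   `dropped_species`, `convergence`.
#' @export
fit_censored_species_model <- function(values) {
  stopifnot(is.data.frame(values))
  if (length(unique(values$metal)) != 1) {
    stop("fit one metal at a time", call. = FALSE)
  }
  has_unc <- tapply(!values$censored, values$butterfly_species, any)
  dropped <- names(has_unc)[!has_unc]
  v <- values[!(values$butterfly_species %in% dropped), , drop = FALSE]
  species <- sort(unique(v$butterfly_species))
  S <- length(species)
  if (S < 1) stop("no species with uncensored observations", call. = FALSE)
  s <- match(v$butterfly_species, species)
  x <- ifelse(v$censored, v$bound, v$y)
  cens <- v$censored

  best <- censored_optimize(s, x, cens, S)
  theta <- best$par
  mu <- theta[seq_len(S)]
  names(mu) <- species
  sigma <- exp(theta[S + 1L])
  loglik <- -best$value

  H <- censored_negll_hess(theta, s, x, cens)
  vc <- try(solve(-H), silent = TRUE)
  if (inherits(vc, "try-error")) {
    vc <- matrix(NA_real_, S + 1L, S + 1L)
  }
  se_mu <- sqrt(pmax(diag(vc)[seq_len(S)], 0))
  names(se_mu) <- species

  # Wald test of H0: mu_1 = ... = mu_S via successive differences.  The
  # raw chi-square statistic uses the plug-in ML covariance, which is
  # biased low in finite samples (the ML scale divides by n, not the
  # residual df), so the reported p value rescales the statistic by
  # (n - S - 1)/n and refers it to an F distribution -- the censored-
  # likelihood analogue of the classical ANOVA F calibration.  The
  # uncorrected chi-square p value is kept as `p_chisq`.
  wald <- list(statistic = NA_real_, df = S - 1L, p.value = NA_real_,
               p_chisq = NA_real_)
  if (S >= 2 && !anyNA(vc)) {
    C <- diff(diag(S))                      # (S-1) x S contrast matrix
    d <- drop(C %*% mu)
    Vd <- C %*% vc[seq_len(S), seq_len(S), drop = FALSE] %*% t(C)
    stat <- try(drop(crossprod(d, solve(Vd, d))), silent = TRUE)
    if (!inherits(stat, "try-error")) {
      n_obs <- length(x)
      df2 <- n_obs - S - 1L
      f_equiv <- (stat * df2 / n_obs) / (S - 1L)
      wald <- list(statistic = stat, df = S - 1L,
                   p.value = stats::pf(f_equiv, S - 1L, df2,
                                       lower.tail = FALSE),
                   p_chisq = stats::pchisq(stat, S - 1L,
                                           lower.tail = FALSE))
    }
  }

  # null model: one common mean
  pseudo_r2 <- list(cox_snell = NA_real_, nagelkerke = NA_real_)
  loglik0 <- NA_real_
  if (S >= 2) {
    null_fit <- censored_optimize(rep(1L, length(x)), x, cens, 1L)
    loglik0 <- -null_fit$value
    n <- length(x)
    r2_cs <- 1 - exp((2 / n) * (loglik0 - loglik))
    denom <- 1 - exp((2 / n) * loglik0)
    pseudo_r2 <- list(cox_snell = r2_cs,
                      nagelkerke = if (denom > 0) r2_cs / denom else NA_real_)
  }

  out <- list(mu = mu, sigma = sigma, se_mu = se_mu,
              loglik = loglik, loglik_null = loglik0,
              wald = wald, pseudo_r2 = pseudo_r2,
              n = length(x), n_censored = sum(cens),
              species = species, dropped_species = dropped,
              convergence = best$convergence)
  class(out) <- "censored_fit"
  out
}

#' @export
print.censored_fit <- function(x, ...) {
  cat("Censored-normal species model:", length(x$species), "species,",
      x$n, "observations (", x$n_censored, "censored )\n")
  cat(sprintf("  shared sigma = %.4f, log-likelihood = %.3f\n",
              x$sigma, x$loglik))
  if (!is.na(x$wald$statistic)) {
    cat(sprintf("  species effect: Wald chi^2 = %.2f, df = %d, p = %.3g\n",
                x$wald$statistic, x$wald$df, x$wald$p.value))
  }
  if (length(x$dropped_species) > 0) {
    cat("  all-censored species excluded:",
        paste(x$dropped_species, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Observed species maxima on the log scale
#'
#' The maximum uncensored log-scale value per species; a censored value
#' can never be a maximum.  Species with every observation censored get an
#' `NA` maximum and `all_censored = TRUE`.
#'
#' @param values a `censored_values` data frame restricted to one metal.
#' @return data frame with `butterfly_species`, `max_observed_log`,
#'   `all_censored`.
#' @export
species_max <- function(values) {
  stopifnot(is.data.frame(values))
  sp <- sort(unique(values$butterfly_species))
  mx <- vapply(sp, function(spp) {
    y <- values$y[values$butterfly_species == spp & !values$censored]
    if (length(y) == 0) NA_real_ else max(y)
  }, numeric(1))
  data.frame(butterfly_species = sp, max_observed_log = mx,
             all_censored = is.na(mx), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Censoring report
#'
#' Counts of censored samples by metal, and by species within metal.
#'
#' @param values a `censored_values` data frame (any number of metals).
#' @return list with `by_metal` and `by_species` count tables.
#' @export
censor_report <- function(values) {
  stopifnot(is.data.frame(values))
  by_metal <- stats::aggregate(
    list(n = values$censored, n_total = rep(1L, nrow(values))),
    by = list(metal = values$metal),
    FUN = sum)
  names(by_metal)[2] <- "n_censored"
  by_species <- stats::aggregate(
    list(n = values$censored, n_total = rep(1L, nrow(values))),
    by = list(metal = values$metal,
              butterfly_species = values$butterfly_species),
    FUN = sum)
  names(by_species)[3] <- "n_censored"
  list(by_metal = by_metal, by_species = by_species)
}

#' Per-species tolerance-proxy summary across metals
#'
#' Combines, for each metal, the observed species maximum and the
#' censored-ML predicted species mean into one table.
#'
#' @param values a `censored_values` data frame covering one or more
#'   metals.
#' @return data frame with columns `butterfly_species`, `metal`, `n`,
#'   `n_censored`, `max_observed_log`, `predicted_mean_log`, `se_mean`;
#'   the per-metal `censored_fit` objects are attached as the `"fits"`
#'   attribute.
#' @export
summarize_species_metals <- function(values) {
  metals <- sort(unique(values$metal))
  fits <- list()
  out <- NULL
  for (m in metals) {
    vm <- values[values$metal == m, , drop = FALSE]
    fit <- fit_censored_species_model(vm)
    fits[[m]] <- fit
    mx <- species_max(vm)
    n <- as.integer(table(factor(vm$butterfly_species,
                                 levels = mx$butterfly_species)))
    ncen <- as.integer(tapply(vm$censored,
                              factor(vm$butterfly_species,
                                     levels = mx$butterfly_species), sum))
    tab <- data.frame(
      butterfly_species = mx$butterfly_species,
      metal = m, n = n, n_censored = ncen,
      max_observed_log = mx$max_observed_log,
      predicted_mean_log = as.numeric(fit$mu[mx$butterfly_species]),
      se_mean = as.numeric(fit$se_mu[mx$butterfly_species]),
      stringsAsFactors = FALSE, row.names = NULL)
    out <- rbind(out, tab)
  }
  attr(out, "fits") <- fits
  out
}
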