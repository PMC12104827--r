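raw_row <- function(id, sp, metal, run, conc) {
  data.frame(specimen_id = id, butterfly_species = sp, metal = metal,
             run_id = run, raw_concentration = conc,
             stringsAsFactors = FALSE)
}

test_that("technical replicates are averaged per specimen and metal", {
  raw <- raw_row(rep("x1", 3), "sp", "Pb", "run1", c(1, 2, 3))
  m <- average_replicates(raw)
  expect_equal(nrow(m), 1)
  expect_equal(m$raw_concentration, 2)
  expect_false(m$had_missing)

  single <- average_replicates(raw_row("x2", "sp", "Pb", "run1", 0.7))
  expect_equal(single$raw_concentration, 0.7)

  with_na <- average_replicates(raw_row(rep("x3", 3), "sp", "Pb", "run1",
                                        c(1, NA, 3)))
  expect_equal(with_na$raw_concentration, 2)
  expect_true(with_na$had_missing)

  expect_error(average_replicates(raw_row(character(0), character(0),
                                          character(0), character(0),
                                          numeric(0))),
               "no replicate rows")
})

test_that("censor encoding follows the LOD and negative-value rules", {
  lods <- data.frame(metal = "Pb", run_id = c("run1", "run2"),
                     lod = c(0.002, 0.002), stringsAsFactors = FALSE)
  m <- average_replicates(raw_row(c("a", "b", "c"), "sp", "Pb",
                                  c("run1", "run1", "run2"),
                                  c(-0.4, 0, 9)))
  v <- encode_censored(m, lods)
  expect_true(v$censored[v$specimen_id == "a"])   # negative reading
  expect_true(v$censored[v$specimen_id == "b"])   # below LOD
  expect_equal(v$bound[v$specimen_id == "b"], log10(1.002))
  expect_false(v$censored[v$specimen_id == "c"])
  expect_equal(v$y[v$specimen_id == "c"], 1)      # log10(9 + 1)

  expect_error(encode_censored(m, data.frame(metal = "Cd", run_id = "run1",
                                             lod = 0.1)),
               "Pb")
})

test_that("censor bound averages LODs across runs, or uses the run LOD on request", {
  lods <- data.frame(metal = "Pb", run_id = c("run1", "run2", "run3"),
                     lod = c(0.1, 0.2, 0.3), stringsAsFactors = FALSE)
  m <- average_replicates(raw_row("a", "sp", "Pb", "run3", 0.05))
  v_mean <- encode_censored(m, lods, lod_averaging = "mean")
  expect_equal(v_mean$bound, log10(1.2))          # mean LOD 0.2
  v_run <- encode_censored(m, lods, lod_averaging = "run")
  expect_equal(v_run$bound, log10(1.3))           # run3 LOD
})

test_that("censored ML reduces exactly to uncensored normal ML without censoring", {
  set.seed(12)
  y <- rnorm(120, c(0.4, 0.9, 1.4), 0.25)
  sp <- rep(c("a", "b", "c"), 40)
  df <- make_censored_df(sp, y, bound = -10)
  expect_equal(sum(df$censored), 0)
  fit <- fit_censored_species_model(df)
  mu_hat <- tapply(y, sp, mean)
  expect_equal(as.numeric(fit$mu), as.numeric(mu_hat), tolerance = 1e-6)
  sigma_ml <- sqrt(mean((y - mu_hat[sp])^2))
  expect_equal(fit$sigma, sigma_ml, tolerance = 1e-6)
})

test_that("censored ML matches an independent left-censored regression oracle", {
  set.seed(13)
  n <- 1000
  y <- rnorm(n, 1, 0.3)
  bnd <- qnorm(0.3, 1, 0.3)
  df <- make_censored_df(rep("a", n), y, bnd)
  fit <- fit_censored_species_model(df)
  expect_lt(abs(fit$mu - 1), 0.03)

  sv <- survival::survreg(
    survival::Surv(ifelse(df$censored, bnd, y), !df$censored,
                   type = "left") ~ 1, dist = "gaussian")
  expect_equal(as.numeric(fit$mu), as.numeric(coef(sv)), tolerance = 1e-5)
  expect_equal(fit$sigma, sv$scale, tolerance = 1e-5)
})

test_that("species means and sigma are recovered at the study scale", {
  # 26 species x 28 specimens, ~20% censoring, averaged over replicates
  set.seed(14)
  reps <- 100
  mu_mae <- numeric(reps)
  sig_err <- numeric(reps)
  bnd <- qnorm(0.2, 0.5, sqrt(0.2^2 + 0.3^2))
  for (r in seq_len(reps)) {
    mu_s <- rnorm(26, 0.5, 0.2)
    sp <- rep(sprintf("s%02d", 1:26), each = 28)
    y <- rnorm(26 * 28, rep(mu_s, each = 28), 0.3)
    fit <- fit_censored_species_model(make_censored_df(sp, y, bnd))
    mu_mae[r] <- mean(abs(as.numeric(fit$mu) - mu_s))
    sig_err[r] <- abs(fit$sigma - 0.3)
  }
  expect_lt(mean(mu_mae), 0.05)
  expect_lt(mean(sig_err), 0.05)
})

test_that("likelihood is invariant to species relabeling and all-censored species are flagged", {
  set.seed(15)
  y <- rnorm(90, rep(c(0.3, 0.8, 1.2), each = 30), 0.3)
  sp <- rep(c("a", "b", "c"), each = 30)
  df <- make_censored_df(sp, y, bound = 0.35)
  f1 <- fit_censored_species_model(df)
  relab <- df
  relab$butterfly_species <- c(a = "zz", b = "mm", c = "aa")[df$butterfly_species]
  f2 <- fit_censored_species_model(relab)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(unname(f1$mu[c("a", "b", "c")]),
               unname(f2$mu[c("zz", "mm", "aa")]), tolerance = 1e-6)

  df_all <- rbind(df, make_censored_df(rep("dead", 5),
                                       rep(-5, 5), bound = 0.35))
  f3 <- fit_censored_species_model(df_all)
  expect_identical(f3$dropped_species, "dead")
  expect_false("dead" %in% names(f3$mu))
  expect_equal(f3$wald$df, 2L)
})

test_that("species maxima use only uncensored values", {
  df <- make_censored_df(rep(c("a", "b"), each = 3),
                         c(0.1, 0.9, 0.4, -1, -2, -3), bound = 0)
  mx <- species_max(df)
  expect_equal(mx$max_observed_log[mx$butterfly_species == "a"], 0.9)
  expect_true(is.na(mx$max_observed_log[mx$butterfly_species == "b"]))
  expect_true(mx$all_censored[mx$butterfly_species == "b"])

  one <- species_max(make_censored_df("a", 0.42, bound = -1))
  expect_equal(one$max_observed_log, 0.42)
})

test_that("censor report counts match generator bookkeeping", {
  b <- simulate_bundle(synth_config(n_species = 6, n_per_species = 10),
                       seed = 3)
  vals <- encode_censored(average_replicates(b$specimens), b$lods)
  rep_tab <- censor_report(vals)

  truth <- b$truth$censoring
  truth_counts <- tapply(truth$censored, truth$metal, sum)
  got <- rep_tab$by_metal$n_censored[match(names(truth_counts),
                                           rep_tab$by_metal$metal)]
  expect_equal(got, as.integer(truth_counts), ignore_attr = TRUE)

  # all-uncensored degenerate case
  v0 <- make_censored_df(rep("a", 10), seq(0.1, 1, 0.1), bound = -1)
  expect_equal(censor_report(v0)$by_metal$n_censored, 0L)

  v3 <- make_censored_df(rep("a", 10), c(rep(-2, 3), seq(0.3, 0.9, 0.1)),
                         bound = 0)
  expect_equal(censor_report(v3)$by_metal$n_censored, 3L)
})

test_that("per-species summary table combines maxima and predicted means", {
  b <- simulate_bundle(synth_config(n_species = 5, n_per_species = 12),
                       seed = 4)
  vals <- encode_censored(average_replicates(b$specimens), b$lods)
  tab <- summarize_species_metals(vals)
  expect_setequal(unique(tab$metal), unique(vals$metal))
  expect_equal(nrow(tab), 5 * 4)
  expect_true(all(tab$n_censored <= tab$n))
  fits <- attr(tab, "fits")
  expect_s3_class(fits$Pb, "censored_fit")
  i <- tab$metal == "Pb"
  expect_equal(tab$predicted_mean_log[i],
               as.numeric(fits$Pb$mu[tab$butterfly_species[i]]))
})
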