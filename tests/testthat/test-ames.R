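test_that("record loading validates schema and binary outcomes", {
  df <- make_ames_df(rep(c("A", "B"), each = 2), rep(c("oA", "oB"), each = 2),
                     c(1L, 0L, 1L, 0L))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  rec <- load_ames_records(path)
  expect_equal(nrow(rec), 4)
  expect_type(rec$outcome, "integer")

  df2 <- df[, setdiff(names(df), "plant_order")]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df2, path2, row.names = FALSE)
  expect_error(load_ames_records(path2), "plant_order")

  df3 <- df
  df3$outcome <- c("1", "maybe", "0", "1")
  path3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df3, path3, row.names = FALSE)
  expect_error(load_ames_records(path3), "row\\(s\\): 2")

  df4 <- df
  df4$plant_order[2] <- "other_order"
  expect_error(validate_ames_records(df4), "more than one order")
})

test_that("corrected scores reduce to raw proportions without methodology variation", {
  # balanced design, 8/10 vs 2/10 positive
  df <- make_ames_df(rep(c("A", "B"), each = 10), rep(c("oA", "oB"), each = 10),
                     c(rep(1L, 8), rep(0L, 2), rep(1L, 2), rep(0L, 8)))
  m <- fit_methodology_model(df)
  expect_identical(m$kind, "proportion")
  sc <- family_scores(df, m, min_tests = 8)
  expect_equal(sc$score[sc$family == "A"], 0.8)
  expect_equal(sc$score[sc$family == "B"], 0.2)
  expect_true(all(sc$level == "family"))
})

test_that("methodology correction matches a brute-force marginal standardization oracle", {
  # family A tested only with a high-positive-rate strain, family B only
  # with a low-rate strain; a pooled set of both-strain families
  # identifies the strain effect
  set.seed(5)
  n <- 60
  strainA <- rep("hot", n)
  strainB <- rep("cold", n)
  strainC <- rep(c("hot", "cold"), n / 2)
  pr <- function(base, strain) plogis(qlogis(base) + ifelse(strain == "hot", 1.2, 0))
  df <- rbind(
    make_ames_df(rep("A", n), rep("oA", n), rbinom(n, 1, pr(0.45, strainA)), strain = strainA),
    make_ames_df(rep("B", n), rep("oB", n), rbinom(n, 1, pr(0.45, strainB)), strain = strainB),
    make_ames_df(rep("C", n), rep("oC", n), rbinom(n, 1, pr(0.30, strainC)), strain = strainC))
  m <- fit_methodology_model(df, covariates = "strain")
  sc <- family_scores(df, m, min_tests = 8)

  # oracle: separately fitted glm, averaging predicted probabilities over
  # the pooled covariate distribution row by row
  g <- glm(outcome ~ plant_family + strain, family = binomial(), data = df)
  oracle <- sapply(c("A", "B", "C"), function(fam) {
    nd <- df
    nd$plant_family <- fam
    mean(predict(g, newdata = nd, type = "response"))
  })
  expect_equal(sc$score[match(c("A", "B", "C"), sc$family)],
               unname(oracle), tolerance = 1e-8)

  raw <- tapply(df$outcome, df$plant_family, mean)
  gap_raw <- abs(raw[["A"]] - raw[["B"]])
  gap_corr <- abs(sc$score[sc$family == "A"] - sc$score[sc$family == "B"])
  expect_lt(gap_corr, gap_raw)
})

test_that("the order-level fallback rule is exact and boundary scores are exact", {
  # 7-test family falls back to its order, which pools 27 tests
  df <- rbind(
    make_ames_df(rep("small", 7), rep("ordX", 7), c(1L, 1L, 0L, 0L, 0L, 0L, 0L)),
    make_ames_df(rep("big", 20), rep("ordX", 20), rep(c(1L, 0L), 10)),
    make_ames_df(rep("neg", 8), rep("ordY", 8), rep(0L, 8)),
    make_ames_df(rep("pos", 8), rep("ordZ", 8), rep(1L, 8)))
  m <- fit_methodology_model(df)
  sc <- family_scores(df, m, min_tests = 8)
  expect_identical(sc$level == "order_fallback", sc$n_tests < 8)
  small <- sc[sc$family == "small", ]
  expect_identical(small$level, "order_fallback")
  expect_equal(small$score, mean(df$outcome[df$plant_order == "ordX"]))
  expect_equal(sc$score[sc$family == "neg"], 0)
  expect_equal(sc$score[sc$family == "pos"], 1)
  expect_true(all(sc$score >= 0 & sc$score <= 1))
})

test_that("scores are invariant to record order and covariate relabeling", {
  cfg <- synth_config(n_families = 10, n_small_families = 0,
                      tests_range = c(12, 25))
  g <- gen_ames(cfg, seed = 21)
  sc1 <- family_scores(g$records, fit_methodology_model(g$records))
  perm <- g$records[sample(nrow(g$records)), ]
  sc2 <- family_scores(perm, fit_methodology_model(perm))
  expect_equal(sc1$score, sc2$score, tolerance = 1e-7)

  relab <- g$records
  relab$strain <- paste0("zz_", relab$strain)  # changes level sort order
  sc3 <- family_scores(relab, fit_methodology_model(relab))
  expect_equal(sc1$score, sc3$score, tolerance = 1e-7)
})

test_that("family effect F matches the closed-form one-way ANOVA", {
  df <- make_ames_df(rep(c("A", "B"), each = 10), rep(c("oA", "oB"), each = 10),
                     c(rep(1L, 9), 0L, 1L, rep(0L, 9)))
  res <- family_effect_test(df, covariates = character(0), min_tests = 8)
  # closed form for two groups of 10 with means 0.9 and 0.1
  y <- df$outcome
  gm <- mean(y)
  ssb <- 10 * ((0.9 - gm)^2 + (0.1 - gm)^2)
  ssw <- sum((y[1:10] - 0.9)^2) + sum((y[11:20] - 0.1)^2)
  f_closed <- (ssb / 1) / (ssw / 18)
  expect_equal(res$statistic, f_closed, tolerance = 1e-10)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 18)
  # cell-means parameterization reported alongside with df = n families
  expect_equal(res$cell_means$df1, 2)
})

test_that("degenerate and under-replicated family tests are flagged", {
  df <- make_ames_df(rep(c("A", "B"), each = 10), rep(c("oA", "oB"), each = 10),
                     rep(1L, 20))
  res <- family_effect_test(df, covariates = character(0))
  expect_true(res$zero_variance)
  expect_true(is.na(res$statistic))

  df2 <- make_ames_df(rep(c("A", "B"), c(10, 3)), rep(c("oA", "oB"), c(10, 3)),
                      c(rep(1L, 10), 0L, 0L, 1L))
  expect_error(family_effect_test(df2), "fewer than two families")
})

test_that("family effect test attains nominal type-I error under the null", {
  set.seed(31)
  reps <- 1000
  rej <- 0L
  for (r in seq_len(reps)) {
    df <- make_ames_df(rep(c("A", "B", "C"), each = 12),
                       rep(c("oA", "oB", "oC"), each = 12),
                       rbinom(36, 1, 0.4))
    res <- family_effect_test(df, covariates = character(0), min_tests = 8)
    if (!res$zero_variance && res$p.value < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / reps, 0.025)
  expect_lt(rej / reps, 0.085)
})
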