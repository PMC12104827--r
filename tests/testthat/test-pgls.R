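test_that("phylogenetic covariances equal shared path lengths", {
  star <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unname(vcv_from_tree(star)),
               matrix(c(1, 0, 0, 1), 2, 2))

  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  V <- vcv_from_tree(tr)
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "C"], 0)
  expect_equal(unname(diag(V)), rep(2, 3))

  # random trees against an explicit path-enumeration oracle
  for (s in 1:5) {
    rt <- gen_tree(6, seed = 100 + s)
    expect_equal(vcv_from_tree(rt)[rt$tip.label, rt$tip.label],
                 vcv_path_oracle(rt), tolerance = 1e-12)
  }

  expect_error(vcv_from_tree(tr, species = c("A", "Zz")), "Zz")
})

test_that("the lambda transform scales only off-diagonal entries", {
  V <- vcv_from_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  expect_equal(lambda_transform(V, 1), V)
  expect_equal(lambda_transform(V, 0), diag(diag(V)), ignore_attr = TRUE)
  V5 <- lambda_transform(V, 0.5)
  expect_equal(V5["A", "B"], 0.5)
  expect_equal(diag(V5), diag(V))
  expect_error(lambda_transform(V, 1.2), "\\[0, 1\\]")
})

test_that("GLS reduces to OLS with identity covariance and recovers noiseless signals", {
  set.seed(41)
  n <- 12
  X <- cbind(1, rnorm(n), runif(n))
  y <- rnorm(n)
  f <- gls_fit(y, X, diag(n))
  expect_equal(as.numeric(f$coefficients), as.numeric(coef(lm(y ~ X - 1))),
               tolerance = 1e-10)

  beta <- c(2, -1, 0.5)
  y0 <- drop(X %*% beta)
  f0 <- gls_fit(y0, X, diag(n))
  expect_equal(as.numeric(f0$coefficients), beta, tolerance = 1e-10)
  expect_lt(f0$sigma2_ml, 1e-20)

  expect_error(gls_fit(y, cbind(X, X[, 2]), diag(n)), "rank deficient")
  expect_error(gls_fit(y, X, matrix(0, n, n)), "positive definite")
})

test_that("GLS matches the dense-matrix oracle on random phylogenetic problems", {
  set.seed(42)
  for (r in 1:100) {
    tr <- gen_tree(5, seed = 2000 + r)
    V <- vcv_from_tree(tr)
    X <- cbind(1, rnorm(5))
    y <- rnorm(5)
    f <- gls_fit(y, X, V)
    expect_equal(as.numeric(f$coefficients),
                 as.numeric(gls_dense_oracle(y, X, V)), tolerance = 1e-10)
  }
})

test_that("PGLS at lambda 0 equals OLS, including t statistics", {
  tr <- gen_tree(26, seed = 51)
  set.seed(52)
  X <- cbind(intercept = 1, x1 = rnorm(26), x2 = rnorm(26))
  rownames(X) <- tr$tip.label
  y <- gen_traits(tr, 0, c(0.5, 0.3, -0.2), X, 0.2, seed = 53)
  fit <- fit_pgls_ml_lambda(y, X, tree = tr, lambda = 0)
  ols <- summary(lm(y ~ X[, 2] + X[, 3]))
  expect_equal(fit$coefficients$estimate, unname(coef(ols)[, 1]),
               tolerance = 1e-8)
  expect_equal(fit$coefficients$t, unname(coef(ols)[, 3]), tolerance = 1e-8)
  expect_equal(unname(fit$fstatistic["value"]), unname(ols$fstatistic[1]),
               tolerance = 1e-8)
  expect_equal(fit$adj.r.squared, ols$adj.r.squared, tolerance = 1e-8)
  expect_equal(unname(fit$fstatistic[c("numdf", "dendf")]), c(2, 23))
})

test_that("the profiled likelihood at the ML lambda dominates a fine grid", {
  tr <- gen_tree(40, seed = 61)
  set.seed(62)
  X <- cbind(intercept = 1, x = rnorm(40))
  rownames(X) <- tr$tip.label
  y <- gen_traits(tr, 0.6, c(0, 0.4), X, 0.15, seed = 63)
  fit <- fit_pgls_ml_lambda(y, X, tree = tr)
  V <- vcv_from_tree(tr)
  grid_ll <- vapply(seq(0, 1, by = 0.01), function(l) {
    gls_fit(y, X, lambda_transform(V, l))$loglik
  }, numeric(1))
  expect_gte(fit$loglik, max(grid_ll) - 1e-6)
  expect_gte(fit$lambda, 0)
  expect_lte(fit$lambda, 1)
})

test_that("PGLS agrees with an independent GLS implementation at fixed lambda", {
  tr <- gen_tree(20, seed = 71)
  set.seed(72)
  x <- rnorm(20)
  X <- cbind(intercept = 1, x = x)
  rownames(X) <- tr$tip.label
  y <- gen_traits(tr, 0.7, c(0.2, 0.5), X, 0.1, seed = 73)
  fit <- fit_pgls_ml_lambda(y, X, tree = tr, lambda = 0.7)

  dat <- data.frame(y = y, x = x, sp = tr$tip.label)
  gfit <- nlme::gls(y ~ x, data = dat,
                    correlation = ape::corPagel(0.7, phy = tr,
                                                form = ~sp, fixed = TRUE),
                    method = "ML")
  expect_equal(fit$coefficients$estimate, unname(coef(gfit)),
               tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(stats::logLik(gfit)),
               tolerance = 1e-5)
})

test_that("estimates are invariant to species ordering", {
  tr <- gen_tree(15, seed = 81)
  set.seed(82)
  X <- cbind(intercept = 1, x = rnorm(15))
  rownames(X) <- tr$tip.label
  y <- gen_traits(tr, 0.5, c(0, 0.3), X, 0.1, seed = 83)
  f1 <- fit_pgls_ml_lambda(y, X, tree = tr)
  perm <- sample(15)
  f2 <- fit_pgls_ml_lambda(y[perm], X[perm, , drop = FALSE], tree = tr)
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-8)
  expect_equal(f1$lambda, f2$lambda, tolerance = 1e-6)
})

test_that("taxon substitution relabels or grafts without distorting covariances", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  rel <- substitute_taxon(tr, "A", "D")
  expect_setequal(rel$tip.label, c("D", "B", "C"))
  expect_equal(rel$edge.length, tr$edge.length)
  Vr <- vcv_from_tree(rel)
  V <- vcv_from_tree(tr)
  expect_equal(Vr["D", "B"], V["A", "B"])
  expect_equal(Vr["D", "D"], V["A", "A"])

  gr <- substitute_taxon(tr, "A", "D", method = "graft")
  Vg <- vcv_from_tree(gr)
  expect_equal(Vg["D", "B"], V["A", "B"])   # same as the sister's
  expect_equal(Vg["D", "C"], V["A", "C"])
  expect_equal(Vg["D", "D"], V["A", "A"])

  expect_error(substitute_taxon(tr, "Zz", "D"), "Zz")
})

test_that("standardize centers and scales with the sample SD", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  z <- standardize(rnorm(50, 10, 3))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_error(standardize(rep(2, 5)), "constant")
})
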