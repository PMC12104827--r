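# Phylogenetic generalized least squares with maximum-likelihood Pagel's
# lambda.  Residual covariance across species is proportional to shared
# root-to-ancestor branch length, attenuated off-diagonal by lambda
# (lambda = 0 recovers ordinary least squares, lambda = 1 Brownian
# motion).

#' Phylogenetic variance-covariance matrix
#'
#' Entry (i, j) is the branch length shared by the root-to-tip paths of
#' tips i and j (root to most recent common ancestor); the diagonal holds
#' root-to-tip distances.
#'
#' @param tree rooted `phylo` tree with nonnegative branch lengths and
#'   unique tip labels.
#' @param species optional character vector; the matrix is restricted to
#'   (and ordered by) these tips, erroring on any that are absent.
#' @return symmetric covariance matrix with tip labels as dimnames.
#' @export
vcv_from_tree <- function(tree, species = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("tree must have nonnegative branch lengths", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("tip labels must be unique", call. = FALSE)
  }
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  V <- ape::vcv.phylo(tree)
  if (!is.null(species)) {
    missing_sp <- setdiff(species, rownames(V))
    if (length(missing_sp) > 0) {
      stop("species missing from tree: ",
           paste(missing_sp, collapse = ", "), call. = FALSE)
    }
    V <- V[species, species, drop = FALSE]
  }
  V
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged.
#'
#' @param V phylogenetic covariance matrix.
#' @param lambda scalar in `[0, 1]`.
#' @return transformed matrix.
#' @export
lambda_transform <- function(V, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 ||
      lambda < 0 || lambda > 1) {
    stop("lambda must be a single value in [0, 1]", call. = FALSE)
  }
  Vl <- V * lambda
  diag(Vl) <- diag(V)
  Vl
}

#' Generalized least squares fit with known covariance structure
#'
#' Solves the GLS normal equations through the Cholesky factor of `V`:
#' `beta = (X' V^-1 X)^-1 X' V^-1 y`, with the maximum-likelihood residual
#' scale and the multivariate-normal log-likelihood.
#'
#' @param y response vector.
#' @param X design matrix (full column rank).
#' @param V positive-definite covariance matrix (up to the residual
#'   scale).
#' @return list with `coefficients`, `rss` (GLS-metric residual sum of
#'   squares), `sigma2_ml`, `loglik`, `cov_unscaled`
#'   (`(X' V^-1 X)^-1`), `n`, `k`.
#' @export
gls_fit <- function(y, X, V) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(V) == n, ncol(V) == n)
  L <- try(chol(V), silent = TRUE)
  if (inherits(L, "try-error")) {
    stop("covariance matrix is not positive definite", call. = FALSE)
  }
  wy <- backsolve(L, y, transpose = TRUE)
  wX <- backsolve(L, X, transpose = TRUE)
  qrX <- qr(wX)
  if (qrX$rank < ncol(X)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  beta <- qr.coef(qrX, wy)
  res <- wy - wX %*% beta
  rss <- sum(res^2)
  sigma2_ml <- rss / n
  logdetV <- 2 * sum(log(diag(L)))
  loglik <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdetV + n)
  R <- qr.R(qrX)
  cov_unscaled <- chol2inv(R)
  dimnames(cov_unscaled) <- list(colnames(X), colnames(X))
  list(coefficients = beta, rss = rss, sigma2_ml = sigma2_ml,
       loglik = loglik, cov_unscaled = cov_unscaled, n = n, k = ncol(X))
}

#' Standardize a numeric vector to z-scores
#'
#' Centers to mean 0 and scales to sample standard deviation 1 (n - 1
#' denominator), so coefficients on different predictors are directly
#' comparable.
#'
#' @param x numeric vector with positive standard deviation.
#' @return standardized vector.
#' @export
standardize <- function(x) {
  if (length(x) < 2) stop("need at least two values", call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize a constant vector", call. = FALSE)
  }
  (x - mean(x)) / s
}

#' PGLS with maximum-likelihood Pagel's lambda
#'
#' Profiles the GLS log-likelihood over lambda in `[0, 1]` (grid search
#' refined by local optimization; boundary values permitted), then fits
#' at the maximizing lambda.  Coefficient t tests use `n - k` residual
#' degrees of freedom (k = number of design columns including the
#' intercept); the overall F tests all non-intercept terms against the
#' intercept-only model under the same lambda-transformed covariance.
#'
#' @param y named response vector (names are species) or unnamed vector
#'   ordered as `X` rows.
#' @param X design matrix including an intercept column; row names are
#'   species when a tree is supplied.
#' @param tree rooted `phylo` tree covering all species (used unless `V`
#'   is given).
#' @param V optionally, a precomputed phylogenetic covariance matrix.
#' @param lambda `"ml"` (default) or a fixed value in `[0, 1]`.
#' @param grid_points number of profile grid points on `[0, 1]`.
#' @return object of class `pgls_fit`: coefficient table, `lambda`,
#'   `loglik`, `fstatistic` (value, numdf, dendf), `f_p`, `r.squared`,
#'   `adj.r.squared`, `sigma2`, `n`, `k`.
#' @export
fit_pgls_ml_lambda <- function(y, X, tree = NULL, V = NULL,
                               lambda = "ml", grid_points = 101) {
  X <- as.matrix(X)
  if (is.null(V)) {
    if (is.null(tree)) stop("supply either a tree or V", call. = FALSE)
    sp <- if (!is.null(names(y))) names(y) else rownames(X)
    if (is.null(sp)) {
      stop("y (or rownames(X)) must carry species names when fitting ",
           "from a tree", call. = FALSE)
    }
    V <- vcv_from_tree(tree, species = sp)
  }
  n <- length(y)
  k <- ncol(X)
  if (n <= k) stop("need more species than coefficients", call. = FALSE)

  profile_ll <- function(lam) gls_fit(y, X, lambda_transform(V, lam))$loglik

  if (identical(lambda, "ml")) {
    grid <- seq(0, 1, length.out = max(5, grid_points))
    ll <- vapply(grid, profile_ll, numeric(1))
    i <- which.max(ll)
    lo <- grid[max(1, i - 1)]
    hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(profile_ll, c(lo, hi), maximum = TRUE,
                           tol = 1e-8)
    cand <- c(grid[i], opt$maximum, 0, 1)
    cand_ll <- c(ll[i], opt$objective, ll[1], ll[length(ll)])
    lambda_hat <- cand[which.max(cand_ll)]
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
      stop("lambda must be \"ml\" or a value in [0, 1]", call. = FALSE)
    }
    lambda_hat <- lambda
  }

  Vl <- lambda_transform(V, lambda_hat)
  fit <- gls_fit(y, X, Vl)
  sigma2 <- fit$rss / (n - k)
  se <- sqrt(diag(fit$cov_unscaled) * sigma2)
  tval <- fit$coefficients / se
  pval <- 2 * stats::pt(abs(tval), n - k, lower.tail = FALSE)

  # intercept-only null fit under the same covariance
  icol <- which(apply(X, 2, function(col) all(col == col[1])))
  X0 <- X[, icol[1], drop = FALSE]
  fit0 <- gls_fit(y, X0, Vl)
  df1 <- k - 1
  df2 <- n - k
  fstat <- ((fit0$rss - fit$rss) / df1) / (fit$rss / df2)
  f_p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  r2 <- 1 - fit$rss / fit0$rss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - k)

  coefs <- data.frame(estimate = as.numeric(fit$coefficients),
                      se = as.numeric(se),
                      t = as.numeric(tval),
                      p = as.numeric(pval),
                      row.names = colnames(X))
  out <- list(coefficients = coefs, lambda = lambda_hat,
              loglik = fit$loglik, sigma2 = sigma2,
              fstatistic = c(value = fstat, numdf = df1, dendf = df2),
              f_p = f_p, r.squared = r2, adj.r.squared = adj_r2,
              n = n, k = k)
  class(out) <- "pgls_fit"
  out
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS fit: n = %d, lambda = %.3f (ML), logLik = %.3f\n",
              x$n, x$lambda, x$loglik))
  printCoefmat(as.matrix(x$coefficients), P.values = TRUE,
               has.Pvalue = TRUE)
  cat(sprintf("F(%d, %d) = %.3f, p = %.4g;  R^2 = %.3f, adj. R^2 = %.3f\n",
              x$fstatistic["numdf"], x$fstatistic["dendf"],
              x$fstatistic["value"], x$f_p, x$r.squared, x$adj.r.squared))
  invisible(x)
}

#' Substitute one taxon for another in a tree
#'
#' Used when an analysis species is absent from the phylogeny but its
#' sister species is present: by default the sister tip is relabeled with
#' the analysis species' name (topology and branch lengths unchanged).
#' With `method = "graft"`, the analysis species is instead added as a
#' zero-length sister of the placeholder (both tips kept), so the new tip
#' has exactly the placeholder's covariances with all other tips.
#'
#' @param tree `phylo` tree.
#' @param placeholder tip label present in the tree.
#' @param target label of the analysis species.
#' @param method `"relabel"` (default) or `"graft"`.
#' @return modified tree.
#' @export
substitute_taxon <- function(tree, placeholder, target,
                             method = c("relabel", "graft")) {
  method <- match.arg(method)
  stopifnot(inherits(tree, "phylo"))
  hit <- which(tree$tip.label == placeholder)
  if (length(hit) != 1) {
    stop("placeholder tip not found in tree: ", placeholder, call. = FALSE)
  }
  if (method == "relabel") {
    tree$tip.label[hit] <- target
    return(tree)
  }
  if (!requireNamespace("phytools", quietly = TRUE)) {
    stop("grafting requires the phytools package", call. = FALSE)
  }
  phytools::bind.tip(tree, target, edge.length = 0, where = hit,
                     position = 0)
}
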