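# Methodology-corrected mutagenicity scores for plant families from
# literature Ames-test records.

#' Required columns of an Ames-test record table
#'
#' One row per published Ames test of a plant extract: plant taxonomy
#' (species, family, order), methodology covariates (tissue, solvent class,
#' bacterial strain, S9 metabolic activation) and the binary outcome
#' (mutagenic or not, i.e. at least a doubling of revertant colonies over
#' control).
#'
#' @export
ames_columns <- function() {
  c("study_id", "plant_species", "plant_family", "plant_order",
    "tissue", "solvent_class", "strain", "metabolic_activation", "outcome")
}

#' Default methodology covariates corrected for in family scores
#' @export
ames_default_covariates <- function() {
  c("solvent_class", "strain", "metabolic_activation")
}

parse_binary <- function(x) {
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) {
    out <- as.integer(x)
    out[!(x %in% c(0, 1))] <- NA_integer_
    return(out)
  }
  key <- tolower(trimws(as.character(x)))
  map <- c("0" = 0L, "1" = 1L, "true" = 1L, "false" = 0L,
           "yes" = 1L, "no" = 0L, "t" = 1L, "f" = 0L)
  unname(map[key])
}

#' Validate a table of Ames-test records
#'
#' Checks the schema (all required columns present), coerces the binary
#' fields, and enforces the record invariants: `outcome` strictly binary,
#' nonempty family and order, and each family mapping to exactly one order.
#' Malformed rows are reported by row number.
#'
#' @param records data frame of Ames-test records (see [ames_columns()]).
#' @return the validated data frame with `outcome` and
#'   `metabolic_activation` as 0/1 integers.
#' @export
validate_ames_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(ames_columns(), names(records))
  if (length(missing_cols) > 0) {
    stop("Ames record table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- parse_binary(records$outcome)
  if (anyNA(out)) {
    stop("non-binary `outcome` value in row(s): ",
         paste(which(is.na(out)), collapse = ", "), call. = FALSE)
  }
  act <- parse_binary(records$metabolic_activation)
  if (anyNA(act)) {
    stop("non-binary `metabolic_activation` value in row(s): ",
         paste(which(is.na(act)), collapse = ", "), call. = FALSE)
  }
  for (col in c("plant_family", "plant_order")) {
    v <- records[[col]]
    bad <- which(is.na(v) | !nzchar(trimws(as.character(v))))
    if (length(bad) > 0) {
      stop("empty `", col, "` in row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  fam_ord <- unique(records[, c("plant_family", "plant_order")])
  dup <- unique(fam_ord$plant_family[duplicated(fam_ord$plant_family)])
  if (length(dup) > 0) {
    stop("plant family mapped to more than one order: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  records$outcome <- out
  records$metabolic_activation <- act
  records
}

#' Read Ames-test records from a delimited text file
#'
#' @param path path to a delimited file with a header row naming all
#'   required columns (see [ames_columns()]).
#' @param sep field separator, comma by default.
#' @return validated data frame of records.
#' @export
load_ames_records <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = TRUE)
  validate_ames_records(df)
}

# Covariates that actually vary in the data; constant covariates carry no
# methodology information and are dropped from the model.
active_covariates <- function(records, covariates) {
  keep <- character(0)
  for (cv in covariates) {
    if (!cv %in% names(records)) {
      stop("unknown covariate column: ", cv, call. = FALSE)
    }
    if (length(unique(records[[cv]])) >= 2) keep <- c(keep, cv)
  }
  keep
}

# Fit a binomial regression of outcome on a grouping factor (plant family
# or plant order) plus methodology covariates.  When a group is perfectly
# separated (all positive or all negative under some covariate pattern),
# the unpenalized MLE is at infinity; a ridge penalty on the non-intercept
# coefficients keeps the corrected scores finite.
fit_outcome_model <- function(records, group, covariates, penalty = 0.5) {
  records <- droplevels(as.data.frame(records))
  records[[group]] <- factor(records[[group]])
  for (cv in covariates) records[[cv]] <- factor(records[[cv]])

  if (length(covariates) == 0) {
    # No methodology variation: the model is saturated in the group factor
    # and the corrected score reduces exactly to the raw proportion.
    props <- tapply(records$outcome, records[[group]], mean)
    obj <- list(kind = "proportion", group = group, covariates = character(0),
                scores = props, data = records,
                loglik = sum(stats::dbinom(records$outcome, 1,
                                           props[as.character(records[[group]])],
                                           log = TRUE)),
                penalty = penalty, separation = FALSE)
    class(obj) <- "mutagenicity_model"
    return(obj)
  }

  rhs <- stats::reformulate(c(group, covariates))
  mm <- stats::model.matrix(rhs, data = records)
  y <- records$outcome

  fit <- suppressWarnings(
    stats::glm.fit(mm, y, family = stats::binomial(), control = stats::glm.control(maxit = 100))
  )
  coefs <- fit$coefficients
  eta <- drop(mm %*% ifelse(is.na(coefs), 0, coefs))
  p <- stats::plogis(eta)
  separated <- !fit$converged || anyNA(coefs) ||
    any(abs(coefs) > 15, na.rm = TRUE) ||
    any(p < 1e-8 | p > 1 - 1e-8)

  if (separated) {
    # ridge-penalized logistic fit: -loglik + penalty/2 * sum(beta_j^2)
    # over non-intercept coefficients
    mask <- as.numeric(colnames(mm) != "(Intercept)")
    f <- function(b) {
      eta <- drop(mm %*% b)
      -sum(y * eta - log1p(exp(eta))) + 0.5 * penalty * sum((b * mask)^2)
    }
    g <- function(b) {
      p <- stats::plogis(drop(mm %*% b))
      -drop(crossprod(mm, y - p)) + penalty * b * mask
    }
    start <- ifelse(is.na(coefs) | abs(coefs) > 15, 0, coefs)
    opt <- stats::optim(start, f, g, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    coefs <- opt$par
    loglik <- {
      eta <- drop(mm %*% coefs)
      sum(y * eta - log1p(exp(eta)))
    }
  } else {
    loglik <- -fit$deviance / 2
  }

  obj <- list(kind = if (separated) "penalized" else "glm",
              group = group, covariates = covariates,
              formula = rhs, coefficients = coefs,
              xlevels = lapply(records[c(group, covariates)], levels),
              data = records, loglik = loglik,
              penalty = penalty, separation = separated)
  class(obj) <- "mutagenicity_model"
  obj
}

#' Fit the methodology-correction model for Ames outcomes
#'
#' Binomial regression of the binary mutagenicity outcome on plant family
#' plus methodology covariates (extraction solvent class, bacterial strain,
#' S9 metabolic activation by default).  Covariates that are constant in
#' the data are dropped, in which case corrected scores reduce exactly to
#' raw per-family proportions.  Perfect separation is detected and handled
#' by a fixed small ridge penalty so fitted probabilities stay away from
#' the 0/1 boundary.
#'
#' @param records validated Ames record table (see
#'   [validate_ames_records()]).
#' @param covariates character vector of methodology covariate columns.
#' @param penalty ridge penalty weight used only when separation is
#'   detected.
#' @return an object of class `mutagenicity_model`.
#' @export
fit_methodology_model <- function(records,
                                  covariates = ames_default_covariates(),
                                  penalty = 0.5) {
  records <- validate_ames_records(records)
  if (length(unique(records$plant_family)) < 2) {
    stop("need records from at least two plant families", call. = FALSE)
  }
  keep <- active_covariates(records, covariates)
  fit_outcome_model(records, group = "plant_family",
                    covariates = keep, penalty = penalty)
}

# Corrected score for one group level by marginal standardization: the
# mean predicted probability with the group set to `level`, averaged over
# the empirical joint distribution of methodology covariates in the full
# dataset.
marginal_score <- function(model, level) {
  stopifnot(inherits(model, "mutagenicity_model"))
  if (model$kind == "proportion") {
    s <- model$scores[[level]]
    if (is.null(s)) stop("no records for group level: ", level, call. = FALSE)
    return(unname(s))
  }
  nd <- model$data
  nd[[model$group]] <- factor(level, levels = model$xlevels[[model$group]])
  mm <- stats::model.matrix(model$formula, data = nd)
  mean(stats::plogis(drop(mm %*% model$coefficients)))
}

#' Methodology-corrected mutagenicity score per plant family
#'
#' Families with at least `min_tests` Ames tests receive a family-level
#' corrected score (marginal standardization over the pooled covariate
#' distribution).  Families with fewer tests fall back to the corrected
#' score of their plant order, computed from all records of that order, and
#' are flagged `level = "order_fallback"`.  A family whose order carries no
#' records at all is flagged `level = "missing"` with an `NA` score rather
#' than a silent zero.
#'
#' @param records validated Ames record table.
#' @param model a `mutagenicity_model` fitted on the same records.
#' @param min_tests minimum number of tests for a family-level score.
#' @return data frame with columns `family`, `order`, `n_tests`, `score`,
#'   `level`.
#' @export
family_scores <- function(records, model = NULL, min_tests = 8) {
  records <- validate_ames_records(records)
  if (is.null(model)) model <- fit_methodology_model(records)
  fam <- sort(unique(records$plant_family))
  ord <- records$plant_order[match(fam, records$plant_family)]
  n_tests <- as.integer(table(factor(records$plant_family, levels = fam)))

  need_fallback <- n_tests < min_tests
  order_model <- NULL
  if (any(need_fallback)) {
    order_model <- fit_outcome_model(records, group = "plant_order",
                                     covariates = model$covariates,
                                     penalty = model$penalty)
  }

  score <- numeric(length(fam))
  level <- character(length(fam))
  for (i in seq_along(fam)) {
    if (!need_fallback[i]) {
      score[i] <- marginal_score(model, fam[i])
      level[i] <- "family"
    } else if (ord[i] %in% order_model$data$plant_order) {
      score[i] <- marginal_score(order_model, ord[i])
      level[i] <- "order_fallback"
    } else {
      score[i] <- NA_real_
      level[i] <- "missing"
    }
  }
  data.frame(family = fam, order = ord, n_tests = n_tests,
             score = score, level = level,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Test for a plant-family effect on Ames outcome
#'
#' F test for the family term in a linear model of the 0/1 outcome on
#' methodology covariates plus family, restricted to families meeting the
#' replicate threshold.  Two parameterizations are reported: the standard
#' partial F comparing the covariate-only model against covariates +
#' family (numerator df = number of families - 1), and the cell-means
#' variant testing all family coefficients jointly in a coding without a
#' separate intercept for family (numerator df = number of families).
#'
#' @param records validated Ames record table.
#' @param covariates methodology covariates adjusted for.
#' @param min_tests minimum tests per family for inclusion.
#' @return list with `statistic`, `df1`, `df2`, `p.value`, `n_families`,
#'   `n_tests`, `zero_variance`, and `cell_means` (the alternative
#'   parameterization).
#' @export
family_effect_test <- function(records,
                               covariates = ames_default_covariates(),
                               min_tests = 8) {
  records <- validate_ames_records(records)
  counts <- table(records$plant_family)
  eligible <- names(counts)[counts >= min_tests]
  if (length(eligible) < 2) {
    stop("fewer than two families with at least ", min_tests,
         " tests", call. = FALSE)
  }
  sub <- droplevels(records[records$plant_family %in% eligible, , drop = FALSE])
  sub$plant_family <- factor(sub$plant_family)
  keep <- active_covariates(sub, covariates)
  for (cv in keep) sub[[cv]] <- factor(sub[[cv]])

  if (stats::var(sub$outcome) == 0) {
    return(list(statistic = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                p.value = NA_real_, n_families = length(eligible),
                n_tests = nrow(sub), zero_variance = TRUE,
                cell_means = NULL))
  }

  f_reduced <- if (length(keep) > 0) stats::reformulate(keep, response = "outcome")
               else outcome ~ 1
  f_full <- stats::reformulate(c(keep, "plant_family"), response = "outcome")
  lm0 <- stats::lm(f_reduced, data = sub)
  lm1 <- stats::lm(f_full, data = sub)
  rss0_f <- sum(stats::residuals(lm0)^2)
  rss1_f <- sum(stats::residuals(lm1)^2)
  df1 <- stats::df.residual(lm0) - stats::df.residual(lm1)
  df2 <- stats::df.residual(lm1)
  # explicit partial F; guards against tiny negative SS differences from
  # floating-point cancellation when group means coincide
  stat <- (max(rss0_f - rss1_f, 0) / df1) / (rss1_f / df2)
  pval <- stats::pf(stat, df1, df2, lower.tail = FALSE)

  # cell-means parameterization: joint test of all family coefficients in
  # outcome ~ 0 + family + covariates
  f_cm <- stats::reformulate(c("0", "plant_family", keep), response = "outcome")
  lm_cm <- stats::lm(f_cm, data = sub)
  f_cm0 <- if (length(keep) > 0) stats::reformulate(c("0", keep), response = "outcome")
           else outcome ~ 0
  lm_cm0 <- stats::lm(f_cm0, data = sub)
  rss1 <- sum(stats::residuals(lm_cm)^2)
  rss0 <- sum(stats::residuals(lm_cm0)^2)
  k_cm <- nlevels(sub$plant_family)
  df2_cm <- stats::df.residual(lm_cm)
  stat_cm <- ((rss0 - rss1) / k_cm) / (rss1 / df2_cm)

  list(statistic = stat, df1 = df1, df2 = df2, p.value = pval,
       n_families = length(eligible), n_tests = nrow(sub),
       zero_variance = FALSE,
       cell_means = list(statistic = stat_cm, df1 = k_cm, df2 = df2_cm,
                         p.value = stats::pf(stat_cm, k_cm, df2_cm,
                                             lower.tail = FALSE)))
}
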