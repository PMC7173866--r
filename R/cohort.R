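#' Generating truth for a synthetic cohort
#'
#' Coefficients of the logistic event model on the standardized scale, split
#' into prognostic main effects (`beta`) and treatment-interacted predictive
#' effects (`gamma`).  Column order is fixed throughout the package:
#' intercept/treatment main effect first, then general health (SF-36 GH),
#' age, sex (1 = male) and HbA1c.
#'
#' Defaults are the posterior means reported for the reference analysis of a
#' large lifestyle-intervention trial in type 2 diabetes, so cohorts generated
#' with them behave like that trial's analysis sample.
#'
#' @param beta length-5 numeric: intercept, GH, age, sex, HbA1c (log-odds).
#' @param gamma length-5 numeric: treatment main effect, GH x treatment,
#'   age x treatment, sex x treatment, HbA1c x treatment (log-odds).
#' @return An object of class `truth_params`.
#' @export
#' @examples
#' truth_params()                       # reference-analysis posterior means
#' truth_params(gamma = rep(0, 5))     # homogeneous null treatment effect
truth_params <- function(beta = c(-2.41, -0.07, 0.43, 0.82, 0.39),
                         gamma = c(-0.22, -0.19, -0.01, -0.07, 0.32)) {
  beta <- as.numeric(beta)
  gamma <- as.numeric(gamma)
  if (length(beta) != 5L || length(gamma) != 5L)
    stop("beta and gamma must each have length 5")
  if (!all(is.finite(beta)) || !all(is.finite(gamma)))
    stop("truth coefficients must be finite")
  structure(list(beta = beta, gamma = gamma), class = "truth_params")
}

#' Configuration of the synthetic cohort generator
#'
#' Marginal covariate moments default to the baseline table of the reference
#' trial (entire-sample column): age 58.9 (6.8) years, 41% male, HbA1c
#' 7.3 (1.2) %, SF-36 general health 47.2 (8.9), ~1:1 allocation.
#'
#' @param n_subjects number of subjects to generate.
#' @param age_mean,age_sd age moments in years.
#' @param male_prob probability a subject is male.
#' @param hba1c_mean,hba1c_sd HbA1c moments in percent.
#' @param sf36_mean,sf36_sd SF-36 general health score moments.
#' @param allocation_prob probability of assignment to the intervention arm.
#' @param truth a [truth_params()] object used to generate events.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param corr optional 3x3 correlation matrix for (sf36_gh, age, hba1c);
#'   the default `NULL` generates them independently.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects,
                          age_mean = 58.9, age_sd = 6.8,
                          male_prob = 0.41,
                          hba1c_mean = 7.3, hba1c_sd = 1.2,
                          sf36_mean = 47.2, sf36_sd = 8.9,
                          allocation_prob = 0.5,
                          truth = truth_params(),
                          seed = NULL,
                          corr = NULL) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L)
    stop("n_subjects must be a positive integer")
  for (s in c(age_sd, hba1c_sd, sf36_sd))
    if (!is.finite(s) || s <= 0) stop("all sd fields must be > 0")
  for (p in c(male_prob, allocation_prob))
    if (!is.finite(p) || p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  stopifnot(inherits(truth, "truth_params"))
  if (!is.null(corr)) {
    corr <- as.matrix(corr)
    if (!identical(dim(corr), c(3L, 3L)) || any(abs(corr - t(corr)) > 1e-8))
      stop("corr must be a symmetric 3x3 matrix ordered (sf36_gh, age, hba1c)")
  }
  structure(list(n_subjects = n_subjects,
                 age_mean = age_mean, age_sd = age_sd,
                 male_prob = male_prob,
                 hba1c_mean = hba1c_mean, hba1c_sd = hba1c_sd,
                 sf36_mean = sf36_mean, sf36_sd = sf36_sd,
                 allocation_prob = allocation_prob,
                 truth = truth, seed = seed, corr = corr),
            class = "cohort_config")
}

# run expr under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic trial cohort
#'
#' Draws baseline covariates from the configured marginal distributions
#' (normals for the continuous covariates, Bernoulli for sex), assigns
#' treatment by Bernoulli(`allocation_prob`), and generates the binary
#' composite CVD event from the logistic model
#' \eqn{Y ~ Bernoulli(logit^{-1}(x'\beta + t z'\gamma))}, where the
#' continuous covariates entering x and z are standardized against the
#' generated sample itself -- the same scale on which the analysis model is
#' fit, so `truth` and fitted coefficients are directly comparable.
#'
#' @param config a [cohort_config()] object.
#' @return A `data.frame` with columns `age`, `sex`, `sf36_gh`, `hba1c`,
#'   `treatment`, `event`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(500, seed = 1))
#' colMeans(cohort)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_subjects
    if (is.null(config$corr)) {
      sf36 <- rnorm(n, config$sf36_mean, config$sf36_sd)
      age <- rnorm(n, config$age_mean, config$age_sd)
      hba1c <- rnorm(n, config$hba1c_mean, config$hba1c_sd)
    } else {
      L <- chol(config$corr)
      zc <- matrix(rnorm(3L * n), n, 3L) %*% L
      sf36 <- config$sf36_mean + config$sf36_sd * zc[, 1L]
      age <- config$age_mean + config$age_sd * zc[, 2L]
      hba1c <- config$hba1c_mean + config$hba1c_sd * zc[, 3L]
    }
    sex <- rbinom(n, 1L, config$male_prob)
    treatment <- rbinom(n, 1L, config$allocation_prob)
    # standardize within the generated sample (guard n = 1, zero-sd edge)
    std1 <- function(v) {
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }
    Z <- cbind(1, std1(sf36), std1(age), sex, std1(hba1c))
    eta <- drop(Z %*% config$truth$beta) +
      treatment * drop(Z %*% config$truth$gamma)
    event <- rbinom(n, 1L, stats::plogis(eta))
    data.frame(age = age, sex = sex, sf36_gh = sf36, hba1c = hba1c,
               treatment = treatment, event = event)
  })
}

#' Set covariate fields missing in a subset of rows
#'
#' Marks exactly `n_incomplete` randomly chosen rows as incomplete by setting
#' one or more of their covariate fields (`age`, `sex`, `sf36_gh`, `hba1c`)
#' to `NA`.  Treatment and event indicators are never blanked.  Used to
#' exercise complete-case filtering.
#'
#' @param cohort a cohort `data.frame`.
#' @param n_incomplete number of rows to render incomplete.
#' @param seed integer seed, or `NULL`.
#' @return The cohort with `NA`s injected.
#' @export
inject_missingness <- function(cohort, n_incomplete, seed = NULL) {
  n <- nrow(cohort)
  n_incomplete <- as.integer(n_incomplete)
  if (is.na(n_incomplete) || n_incomplete < 0L || n_incomplete > n)
    stop("n_incomplete must lie in [0, nrow(cohort)]")
  if (n_incomplete == 0L) return(cohort)
  covars <- c("age", "sex", "sf36_gh", "hba1c")
  with_seed(seed, {
    rows <- sample.int(n, n_incomplete)
    for (r in rows) {
      k <- sample.int(length(covars), 1L)
      cohort[r, sample(covars, k)] <- NA
    }
  })
  cohort
}

#' True benefiting mask on a covariate grid
#'
#' Evaluates, for each grid point z, whether the true benefit-positive
#' personalised treatment effect \eqn{-(\gamma_0 + z'\gamma_{-0})} exceeds
#' `threshold`.  Positive effects mean reduced event odds (the sign is
#' flipped relative to the raw log-odds contrast because the event is
#' harmful).  Depends only on `gamma`: prognostic shifts never change the
#' benefiting set.
#'
#' @param truth a [truth_params()] object.
#' @param grid a [make_grid()] object, or a numeric matrix of predictive
#'   vectors (leading 1, then standardized GH, age, sex, HbA1c).
#' @param threshold log-odds benefit threshold (default 0).
#' @return Logical vector, one entry per grid point.
#' @export
true_benefit_mask <- function(truth, grid, threshold = 0) {
  stopifnot(inherits(truth, "truth_params"))
  pts <- if (inherits(grid, "covariate_grid")) grid$points else as.matrix(grid)
  if (ncol(pts) != 5L)
    stop("grid points must have 5 columns (1, GH, age, sex, HbA1c)")
  drop(-(pts %*% truth$gamma)) > threshold
}

#' Read or write a cohort CSV
#'
#' Headered CSV with columns `age`, `sex`, `sf36_gh`, `hba1c`, `treatment`,
#' `event`; missing values are encoded as empty fields.
#'
#' @param cohort a cohort `data.frame`.
#' @param path file path.
#' @return `read_cohort` returns the cohort `data.frame`; `write_cohort`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, na.strings = "")
  required <- c("age", "sex", "sf36_gh", "hba1c", "treatment", "event")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols))
    stop("cohort CSV is missing columns: ", paste(missing_cols, collapse = ", "))
  cohort[required]
}
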