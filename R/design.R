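#' Drop subjects with any missing field
#'
#' The analysis is complete-case only: any row with a missing covariate,
#' treatment or event value is removed.  Row order is preserved.
#'
#' @param cohort a cohort `data.frame`.
#' @return A list with elements `cohort` (the filtered table) and `removed`
#'   (number of rows dropped).
#' @export
complete_cases <- function(cohort) {
  if (nrow(cohort) == 0L) stop("cohort is empty")
  keep <- stats::complete.cases(cohort)
  if (!any(keep)) stop("no complete cases remain after filtering")
  list(cohort = cohort[keep, , drop = FALSE],
       removed = sum(!keep))
}

std_covariates <- c("sf36_gh", "age", "hba1c")

#' Standardize the continuous covariates of a cohort
#'
#' Centers and scales `sf36_gh`, `age` and `hba1c` to sample mean 0 and
#' sample standard deviation 1 (n - 1 denominator).  Binary fields (sex,
#' treatment, event) are untouched.  The centers and scales are returned so
#' that evaluation grids and new subjects can be mapped onto the same scale
#' as the fitted model.
#'
#' @param cohort a complete-case cohort `data.frame`.
#' @return A list with `cohort` (standardized values) and `params`, an object
#'   of class `standardization_params`: per covariate a `center` and `scale`.
#' @export
standardize_cohort <- function(cohort) {
  if (anyNA(cohort[std_covariates]))
    stop("standardize_cohort requires complete cases; run complete_cases() first")
  params <- lapply(cohort[std_covariates], function(v) {
    ctr <- mean(v)
    scl <- stats::sd(v)
    if (!is.finite(scl) || scl == 0)
      stop("cannot standardize a constant covariate (zero standard deviation)")
    list(center = ctr, scale = scl)
  })
  class(params) <- "standardization_params"
  for (nm in std_covariates)
    cohort[[nm]] <- (cohort[[nm]] - params[[nm]]$center) / params[[nm]]$scale
  list(cohort = cohort, params = params)
}

# map raw covariate values onto the stored standardized scale
apply_standardization <- function(values, params, covariate) {
  p <- params[[covariate]]
  (values - p$center) / p$scale
}

#' Model coefficient labels
#'
#' Row names of the posterior summary, in the fixed model order: five
#' prognostic effects then five treatment-interacted predictive effects.
#' @return Character vector of length 10.
#' @export
coef_labels <- function() {
  c("Intercept", "General Health", "Age", "Sex", "HbA1c",
    "Treatment", "General Health x Treatment", "Age x Treatment",
    "Sex x Treatment", "HbA1c x Treatment")
}

#' Build the design structures of the logistic model
#'
#' Produces the prognostic matrix X = (1, GH, age, sex, HbA1c) and the
#' predictive matrix Z with the identical columns (the same four covariates
#' act as both prognostic and predictive; Z's leading constant column makes
#' the treatment main effect the first predictive coefficient), plus the
#' treatment and event vectors.  Continuous covariates are standardized via
#' [standardize_cohort()] and the parameters stored in the result.
#'
#' @param cohort a complete-case cohort `data.frame`.
#' @return An object of class `design_matrices` with fields `X`, `Z`, `t`,
#'   `y`, `std` and `column_labels`.
#' @export
build_design <- function(cohort) {
  if (anyNA(cohort)) stop("build_design requires complete cases")
  if (!all(cohort$treatment %in% c(0, 1)) || !all(cohort$event %in% c(0, 1)))
    stop("treatment and event must be coded 0/1")
  s <- standardize_cohort(cohort)
  ch <- s$cohort
  X <- cbind(1, ch$sf36_gh, ch$age, ch$sex, ch$hba1c)
  colnames(X) <- coef_labels()[1:5]
  Z <- X
  structure(list(X = X, Z = Z,
                 t = as.numeric(ch$treatment),
                 y = as.numeric(ch$event),
                 std = s$params,
                 column_labels = coef_labels()),
            class = "design_matrices")
}

#' @export
print.design_matrices <- function(x, ...) {
  cat("design_matrices:", nrow(x$X), "subjects,",
      ncol(x$X), "prognostic +", ncol(x$Z), "predictive columns\n")
  cat("  events:", sum(x$y), " treated:", sum(x$t), "\n")
  invisible(x)
}
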