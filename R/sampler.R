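#' Prior specification for the logistic model coefficients
#'
#' Independent mean-zero normal priors: a vague prior (variance 1000) on each
#' prognostic effect preserves the observed covariate-endpoint relationships,
#' while a conservative unit-variance prior on each predictive effect encodes
#' scepticism of large treatment-effect heterogeneity yet still lets strong
#' posterior evidence overwhelm it.
#'
#' @param prognostic_variance prior variance of each prognostic coefficient.
#' @param predictive_variance prior variance of each predictive coefficient.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(prognostic_variance = 1000, predictive_variance = 1) {
  if (!is.finite(prognostic_variance) || prognostic_variance <= 0 ||
      !is.finite(predictive_variance) || predictive_variance <= 0)
    stop("prior variances must be positive and finite")
  structure(list(prognostic_variance = prognostic_variance,
                 predictive_variance = predictive_variance),
            class = "prior_spec")
}

#' MCMC configuration
#'
#' Defaults follow the reference analysis: 10,000 retained Gibbs iterations
#' after 1,000 burn-in iterations, a single chain, coefficients initialized
#' at zero.
#'
#' @param iterations retained draws.
#' @param burn_in discarded initial iterations.
#' @param seed integer seed, or `NULL`.
#' @param init either `"zero"` or a numeric length-10 starting vector.
#' @param method `"gibbs"` for the Polya-Gamma blocked Gibbs sampler
#'   (default), or `"metropolis"` for a random-walk Metropolis fallback
#'   behind the same interface.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 10000, burn_in = 1000, seed = NULL,
                        init = "zero", method = c("gibbs", "metropolis")) {
  iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in)
  if (is.na(iterations) || iterations < 1L) stop("iterations must be >= 1")
  if (is.na(burn_in) || burn_in < 0L) stop("burn_in must be >= 0")
  if (is.numeric(init) && length(init) != 10L)
    stop("numeric init must have length 10")
  structure(list(iterations = iterations, burn_in = burn_in, seed = seed,
                 init = init, method = match.arg(method)),
            class = "mcmc_config")
}

prior_variance_vector <- function(prior) {
  rep(c(prior$prognostic_variance, prior$predictive_variance), each = 5L)
}

#' Sample the posterior of the logistic model coefficients
#'
#' Fits `Y ~ Bernoulli(logit^-1(x'beta + t z'gamma))` with independent normal
#' priors.  The default sampler augments each observation with a
#' Polya-Gamma latent variable, giving a blocked Gibbs sampler whose
#' coefficient update is conjugate multivariate normal; a random-walk
#' Metropolis sampler (proposal calibrated at the penalized mode) is
#' available behind the same interface.  Passing `dm = NULL` draws from the
#' prior (the no-data limit of the posterior), which is also how the
#' sampler's prior handling is tested.
#'
#' @param dm a [build_design()] object, or `NULL` for the no-data limit.
#' @param prior a [prior_spec()].
#' @param cfg an [mcmc_config()].
#' @return An object of class `posterior_draws`: `draws` is an
#'   iterations x 10 matrix ordered as [coef_labels()].
#' @export
sample_posterior <- function(dm, prior = prior_spec(), cfg = mcmc_config()) {
  stopifnot(inherits(prior, "prior_spec"), inherits(cfg, "mcmc_config"))
  pv <- prior_variance_vector(prior)
  if (is.null(dm)) {
    A <- matrix(0, 0L, 10L)
    y <- numeric(0)
  } else {
    stopifnot(inherits(dm, "design_matrices"))
    A <- cbind(dm$X, dm$t * dm$Z)
    y <- dm$y
    if (anyNA(A) || any(!is.finite(A)))
      stop("design matrices contain non-finite values")
  }
  init <- if (is.numeric(cfg$init)) cfg$init else rep(0, 10L)
  draws <- with_seed(cfg$seed, {
    if (cfg$method == "gibbs") {
      gibbs_pg_logistic(A, y, pv, cfg$iterations, cfg$burn_in, init)
    } else {
      rw_metropolis_logistic(A, y, pv, cfg$iterations, cfg$burn_in, init)
    }
  })
  if (any(!is.finite(draws)))
    stop("sampler produced non-finite draws")
  colnames(draws) <- coef_labels()
  structure(list(draws = draws, labels = coef_labels(),
                 prior = prior, config = cfg),
            class = "posterior_draws")
}

# log posterior kernel (used by the Metropolis fallback)
log_posterior <- function(theta, A, y, prior_var) {
  lp <- -0.5 * sum(theta^2 / prior_var)
  if (length(y)) {
    eta <- drop(A %*% theta)
    # Bernoulli log-lik: y*eta - log(1 + exp(eta)), stably
    lp <- lp + sum(y * eta - log1p(exp(-abs(eta))) - pmax(eta, 0))
  }
  lp
}

# random-walk Metropolis with proposal covariance from the penalized mode
rw_metropolis_logistic <- function(A, y, prior_var, n_iter, burn, init) {
  d <- length(prior_var)
  neg <- function(th) -log_posterior(th, A, y, prior_var)
  opt <- stats::optim(init, neg, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500))
  H <- opt$hessian
  # proposal ~ N(0, 2.38^2/d * H^-1); fall back to prior scale if H is bad
  L <- tryCatch(t(chol(solve(H))), error = function(e) diag(sqrt(prior_var)))
  step <- 2.38 / sqrt(d)
  theta <- opt$par
  lp <- log_posterior(theta, A, y, prior_var)
  out <- matrix(NA_real_, n_iter, d)
  for (it in seq_len(n_iter + burn)) {
    prop <- theta + step * drop(L %*% stats::rnorm(d))
    lp_prop <- log_posterior(prop, A, y, prior_var)
    if (log(stats::runif(1)) < lp_prop - lp) {
      theta <- prop
      lp <- lp_prop
    }
    if (it > burn) out[it - burn, ] <- theta
  }
  out
}

#' Posterior summary table
#'
#' Per-coefficient posterior mean, standard deviation and equal-tailed
#' central credible bounds, with a significance flag set when the bounds
#' exclude zero.
#'
#' @param draws a [sample_posterior()] object (or bare draws matrix).
#' @param level credible level in (0, 1); default 0.95.
#' @return A `data.frame` with one row per coefficient: `parameter`, `mean`,
#'   `sd`, `lower`, `upper`, `significant`.
#' @export
posterior_summary <- function(draws, level = 0.95) {
  m <- if (inherits(draws, "posterior_draws")) draws$draws else as.matrix(draws)
  if (nrow(m) < 2L) stop("need at least 2 draws to summarize")
  if (!is.finite(level) || level <= 0 || level >= 1)
    stop("level must lie strictly in (0, 1)")
  alpha <- (1 - level) / 2
  qs <- apply(m, 2L, stats::quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  out <- data.frame(
    parameter = colnames(m) %||% paste0("coef", seq_len(ncol(m))),
    mean = colMeans(m),
    sd = apply(m, 2L, stats::sd),
    lower = qs[1L, ],
    upper = qs[2L, ],
    row.names = NULL
  )
  out$significant <- out$lower > 0 | out$upper < 0
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Chain diagnostics: autocorrelation and effective sample size
#'
#' Sample autocorrelation per coefficient up to `max_lag`, and effective
#' sample size from Geyer's initial-positive-sequence rule (sum of
#' consecutive even/odd autocorrelation pairs truncated at the first
#' non-positive pair), capped at the number of draws.
#'
#' @param draws a [sample_posterior()] object (or bare draws matrix).
#' @param max_lag largest lag reported in the autocorrelation table.
#' @return An object of class `mcmc_diagnostics`: `acf` is a
#'   (max_lag + 1) x p matrix (rows = lags 0..max_lag), `ess` a named vector.
#' @export
diagnostics <- function(draws, max_lag = 50) {
  m <- if (inherits(draws, "posterior_draws")) draws$draws else as.matrix(draws)
  n <- nrow(m)
  if (n < 10L) stop("need at least 10 draws for diagnostics")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("autocorrelation is undefined for a constant chain")
  max_lag <- min(max_lag, n - 1L)
  lag_full <- min(n - 1L, max(max_lag, 1000L))
  ac <- apply(m, 2L, function(v)
    drop(stats::acf(v, lag.max = lag_full, plot = FALSE,
                    demean = TRUE)$acf))
  ess <- apply(ac, 2L, function(rho) {
    # pair sums Gamma_k = rho_{2k} + rho_{2k+1}; keep while positive
    npair <- (length(rho) - 1L) %/% 2L
    tau <- 1
    for (k in seq_len(npair)) {
      g <- rho[2L * k] + rho[2L * k + 1L]
      if (g <= 0) break
      tau <- tau + 2 * g
    }
    min(n, n / tau)
  })
  structure(list(acf = ac[seq_len(max_lag + 1L), , drop = FALSE],
                 ess = ess, n_draws = n),
            class = "mcmc_diagnostics")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("posterior_draws:", nrow(x$draws), "retained draws x",
      ncol(x$draws), "coefficients\n")
  print(posterior_summary(x), digits = 3)
  invisible(x)
}

#' Read or write posterior draws as CSV
#'
#' One column per coefficient (header = [coef_labels()]), one row per
#' retained draw.
#'
#' @param draws a [sample_posterior()] object.
#' @param path file path.
#' @return `read_draws` returns a `posterior_draws` object; `write_draws`
#'   returns `path` invisibly.
#' @export
write_draws <- function(draws, path) {
  stopifnot(inherits(draws, "posterior_draws"))
  utils::write.csv(as.data.frame(draws$draws, check.names = FALSE), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  if (ncol(m) != 10L) stop("draws CSV must have 10 coefficient columns")
  colnames(m) <- coef_labels()
  structure(list(draws = m, labels = coef_labels(),
                 prior = NULL, config = NULL),
            class = "posterior_draws")
}
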