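# Independent brute-force oracles for the band / classification machinery.
# These deliberately use dense matrices and plain loops, never the package's
# streaming code paths.

# wrap a bare coefficient matrix as a posterior_draws object
fake_draws <- function(m) {
  m <- as.matrix(m)
  colnames(m) <- coef_labels()
  structure(list(draws = m, labels = coef_labels(),
                 prior = NULL, config = NULL),
            class = "posterior_draws")
}

# inverted-CDF quantile, spelled out
oracle_quantile1 <- function(x, p) sort(x)[max(1, ceiling(p * length(x)))]

# pointwise moments and per-draw sup deviations by explicit loops
oracle_band <- function(values, level, sd_floor = 1e-12) {
  K <- nrow(values); m <- ncol(values)
  mu <- numeric(m); sdv <- numeric(m)
  for (j in seq_len(m)) {
    mu[j] <- sum(values[, j]) / K
    sdv[j] <- sqrt(sum((values[, j] - mu[j])^2) / (K - 1))
  }
  W <- numeric(K)
  for (k in seq_len(K)) {
    best <- 0
    for (j in seq_len(m)) {
      if (sdv[j] > sd_floor)
        best <- max(best, abs(values[k, j] - mu[j]) / sdv[j])
    }
    W[k] <- best
  }
  cc <- oracle_quantile1(W, level)
  half <- ifelse(sdv > sd_floor, cc * sdv, 0)
  list(mean = mu, sd = sdv, multiplier = cc,
       lower = mu - half, upper = mu + half)
}

oracle_classify <- function(ob, delta) {
  list(D = ob$lower > delta, S = ob$upper > delta)
}

# exact fraction of draws satisfying the bracketing event
oracle_bracket <- function(values, D, S, delta) {
  K <- nrow(values)
  hits <- 0L
  for (k in seq_len(K)) {
    B_k <- values[k, ] > delta
    if (all(B_k[D]) && all(S[B_k])) hits <- hits + 1L
  }
  hits / K
}

# signed max level by sweeping every level in the grid
oracle_max_level <- function(values, delta, level_grid) {
  m <- ncol(values)
  surface <- numeric(m)
  for (lv in sort(level_grid)) {
    ob <- oracle_band(values, lv)
    cl <- oracle_classify(ob, delta)
    surface[cl$D] <- lv
    surface[!cl$S & surface <= 0] <- -lv
  }
  surface
}

# quadrature oracle for the marginal event rate of the generator with
# gamma = 0: continuous covariates standardized => the linear predictor is
# beta0 + beta_sex * sex + s * u with u ~ N(0,1), s the prognostic scale
oracle_event_rate <- function(beta, male_prob) {
  s <- sqrt(beta[2]^2 + beta[3]^2 + beta[5]^2)
  f <- function(u, b0) plogis(b0 + s * u) * dnorm(u)
  rate_given_sex <- function(b0)
    integrate(f, -Inf, Inf, b0 = b0, rel.tol = 1e-10)$value
  (1 - male_prob) * rate_given_sex(beta[1]) +
    male_prob * rate_given_sex(beta[1] + beta[4])
}

# small complete cohort fixture
toy_cohort <- function(n = 60, seed = 42) {
  generate_cohort(cohort_config(n, seed = seed))
}
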