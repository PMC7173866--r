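#' Build a factorial covariate grid on the model's standardized scale
#'
#' Lays `resolution` equally spaced raw values over each continuous
#' covariate range, crosses them with sex in {0, 1}, and maps the continuous
#' axes onto the standardized scale stored from the fitted cohort.  The
#' point matrix carries a leading constant column so each row is a complete
#' predictive vector z = (1, GH, age, sex, HbA1c).
#'
#' @param std a `standardization_params` object from [standardize_cohort()]
#'   (or [build_design()]`$std`).
#' @param ranges named list of length-2 raw intervals for `sf36_gh`, `age`
#'   and `hba1c`.
#' @param resolution points per continuous axis (>= 2).
#' @return An object of class `covariate_grid`: `points` (m x 5 standardized
#'   predictive vectors), `raw` (data.frame of raw covariate values), `axes`
#'   (the raw axis values per covariate), `resolution`.
#' @export
make_grid <- function(std, ranges, resolution = 20) {
  stopifnot(inherits(std, "standardization_params"))
  resolution <- as.integer(resolution)
  if (is.na(resolution) || resolution < 2L) stop("resolution must be >= 2")
  unknown <- setdiff(names(ranges), std_covariates)
  if (length(unknown))
    stop("unknown covariate name(s) in ranges: ", paste(unknown, collapse = ", "))
  if (!all(std_covariates %in% names(ranges)))
    stop("ranges must cover sf36_gh, age and hba1c")
  axes <- lapply(ranges[std_covariates], function(r) {
    if (length(r) != 2L || !all(is.finite(r)) || r[1L] == r[2L])
      stop("each range must be a finite interval with distinct endpoints")
    seq(min(r), max(r), length.out = resolution)
  })
  raw <- expand.grid(sf36_gh = axes$sf36_gh, age = axes$age,
                     sex = c(0, 1), hba1c = axes$hba1c,
                     KEEP.OUT.ATTRS = FALSE)
  points <- cbind(
    1,
    apply_standardization(raw$sf36_gh, std, "sf36_gh"),
    apply_standardization(raw$age, std, "age"),
    raw$sex,
    apply_standardization(raw$hba1c, std, "hba1c")
  )
  colnames(points) <- c("const", "sf36_gh", "age", "sex", "hba1c")
  structure(list(points = points, raw = raw, axes = axes,
                 resolution = resolution, std = std),
            class = "covariate_grid")
}

#' Default grid over a cohort's observed covariate span
#'
#' Convenience wrapper around [make_grid()] using the 1st-99th percentile
#' range of each continuous covariate in the (complete-case) cohort.
#'
#' @param cohort complete-case cohort on the raw scale.
#' @param std standardization parameters of the fitted model.
#' @param resolution points per continuous axis.
#' @return A `covariate_grid`.
#' @export
grid_from_cohort <- function(cohort, std, resolution = 20) {
  ranges <- lapply(cohort[std_covariates], stats::quantile,
                   probs = c(0.01, 0.99), names = FALSE)
  make_grid(std, ranges, resolution)
}

#' Personalised treatment effects per posterior draw
#'
#' For each retained draw k and grid point z, computes the benefit-positive
#' personalised treatment effect.  On the primary log-odds scale this is
#' \eqn{\Delta^{(k)}(z) = -z'\gamma^{(k)}} (constant column included, so the
#' treatment main effect is in play); the sign flip makes positive values
#' mean reduced odds of the harmful event.  On the risk-difference scale it
#' is \eqn{logit^{-1}(z'\beta^{(k)}) - logit^{-1}(z'\beta^{(k)} +
#' z'\gamma^{(k)})}, using the same covariate vector prognostically and
#' predictively.
#'
#' The result is stored in closed form (coefficient draws plus grid), so
#' downstream band construction can stream over draw blocks without ever
#' materializing the full draws x points matrix; [pte_from_matrix()] wraps an
#' explicit matrix instead, which the enumeration oracles in the test suite
#' rely on.
#'
#' @param draws a [sample_posterior()] object.
#' @param grid a [make_grid()] object.
#' @param scale `"log-odds"` (primary) or `"risk-difference"`.
#' @return An object of class `pte_draws`.
#' @export
compute_pte <- function(draws, grid, scale = c("log-odds", "risk-difference")) {
  scale <- match.arg(scale)
  stopifnot(inherits(draws, "posterior_draws"), inherits(grid, "covariate_grid"))
  m <- draws$draws
  if (ncol(m) != 10L) stop("posterior draws must have 10 coefficient columns")
  structure(list(kind = "linear",
                 beta = m[, 1:5, drop = FALSE],
                 gamma = m[, 6:10, drop = FALSE],
                 points = grid$points,
                 grid = grid,
                 scale = scale,
                 n_draws = nrow(m),
                 n_points = nrow(grid$points),
                 cache = new.env(parent = emptyenv())),
            class = "pte_draws")
}

#' Wrap an explicit draws x points effect matrix
#'
#' @param values numeric draws x points matrix of treatment effects.
#' @param grid optional `covariate_grid` the columns refer to.
#' @param scale scale tag.
#' @return A `pte_draws` object.
#' @export
pte_from_matrix <- function(values, grid = NULL, scale = "log-odds") {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("effect values must be finite")
  structure(list(kind = "matrix", values = values, grid = grid,
                 scale = scale, n_draws = nrow(values),
                 n_points = ncol(values),
                 cache = new.env(parent = emptyenv())),
            class = "pte_draws")
}

# materialize a block of draws as a points x draws matrix (grid in rows, so
# pointwise vectors recycle without large temporaries)
pte_block <- function(pte, rows) {
  if (pte$kind == "matrix") return(t(pte$values[rows, , drop = FALSE]))
  if (pte$scale == "log-odds")
    return(-(pte$points %*% t(pte$gamma[rows, , drop = FALSE])))
  eta0 <- pte$points %*% t(pte$beta[rows, , drop = FALSE])
  eta1 <- eta0 + pte$points %*% t(pte$gamma[rows, , drop = FALSE])
  stats::plogis(eta0) - stats::plogis(eta1)
}

# draw-index blocks keeping points x block around 2e7 doubles
pte_block_starts <- function(pte, target = 2e7) {
  size <- max(1L, min(pte$n_draws, floor(target / max(1L, pte$n_points))))
  split(seq_len(pte$n_draws), (seq_len(pte$n_draws) - 1L) %/% size)
}

# floor below which a pointwise sd is treated as exactly zero
SD_FLOOR <- 1e-12

# pointwise mean/sd over draws plus the per-draw sup-standardized deviations
# W^(k) = max_j |Delta^(k)(z_j) - mean_j| / sd_j over non-degenerate points.
# Three streaming passes (mean, then centered two-pass sd, then W) so the
# result agrees with the obvious dense computation to the last bit; cached on
# the pte object because every band level reuses the same statistics.
pte_band_stats <- function(pte) {
  if (!is.null(pte$cache$stats)) return(pte$cache$stats)
  K <- pte$n_draws
  blocks <- pte_block_starts(pte)
  s1 <- numeric(pte$n_points)
  for (rows in blocks) s1 <- s1 + rowSums(pte_block(pte, rows))
  mu <- s1 / K
  ss <- numeric(pte$n_points)
  for (rows in blocks) {
    d <- pte_block(pte, rows) - mu
    ss <- ss + rowSums(d * d)
  }
  sd <- sqrt(ss / max(1L, K - 1L))
  # degenerate points divide by Inf and so contribute 0 to the sup
  sd_safe <- ifelse(sd > SD_FLOOR, sd, Inf)
  W <- numeric(K)
  if (any(is.finite(sd_safe))) {
    for (rows in blocks) {
      b <- pte_block(pte, rows)
      W[rows] <- matrixStats::colMaxs(abs(b - mu) / sd_safe)
    }
  }
  stats <- list(mean = mu, sd = sd, W = W)
  pte$cache$stats <- stats
  stats
}

# inverted-CDF (type 1) empirical quantile
quantile_type1 <- function(x, p) {
  xs <- sort(x)
  xs[pmin(length(xs), pmax(1L, ceiling(p * length(xs))))]
}

#' Simultaneous credible band over the covariate grid
#'
#' Builds the two-sided sup-t band: with pointwise posterior means
#' \eqn{\hat\mu_j} and sds \eqn{\hat\sigma_j}, the per-draw statistic
#' \eqn{W^{(k)} = \max_j |\Delta^{(k)}(z_j) - \hat\mu_j| / \hat\sigma_j}
#' is computed over all non-degenerate grid points, and the band multiplier
#' c is the empirical `level` quantile (inverted-CDF convention) of the
#' W draws.  By construction the whole effect surface lies inside
#' \eqn{[\hat\mu_j - c\hat\sigma_j, \hat\mu_j + c\hat\sigma_j]} for at least
#' `level` of the posterior draws.  Points with sd below 1e-12 get a
#' zero-width band (lower = upper = mean) and are excluded from the sup.
#' Draws are processed in blocks, so grids of 50,000+ points and 10,000
#' draws never require the full matrix in memory.
#'
#' @param pte a [compute_pte()] object.
#' @param level credible level in (0, 1).
#' @return An object of class `simultaneous_band` with `mean`, `sd`,
#'   `multiplier`, `lower`, `upper`, `level`, `degenerate` (mask of floored
#'   points).
#' @export
simultaneous_band <- function(pte, level) {
  stopifnot(inherits(pte, "pte_draws"))
  if (pte$n_draws < 2L) stop("need at least 2 draws")
  if (!is.finite(level) || level <= 0 || level >= 1)
    stop("level must lie strictly in (0, 1)")
  st <- pte_band_stats(pte)
  cc <- quantile_type1(st$W, level)
  degenerate <- st$sd <= SD_FLOOR
  half <- ifelse(degenerate, 0, cc * st$sd)
  structure(list(mean = st$mean, sd = st$sd, multiplier = cc,
                 lower = st$mean - half, upper = st$mean + half,
                 level = level, degenerate = degenerate,
                 sup_draws = st$W),
            class = "simultaneous_band")
}

#' Classify the grid into the credible subgroup pair
#'
#' The exclusive credible subgroup D collects grid points whose band lower
#' bound exceeds the benefit threshold; the inclusive subgroup S those whose
#' upper bound exceeds it.  D contains, with joint posterior probability at
#' least the band level, only points with true effect above the threshold,
#' while S simultaneously contains all of them; the remainder splits into
#' the no-benefit region (S-complement) and the uncertainty region S \\ D.
#'
#' @param band a [simultaneous_band()] object.
#' @param threshold benefit threshold delta on the effect scale (default 0,
#'   capturing benefits of any magnitude).
#' @return An object of class `credible_subgroup_pair` with logical masks
#'   `D` and `S`, the `region` factor (levels `D`, `S\\D`, `Sc`), `level`,
#'   `threshold`.
#' @export
classify <- function(band, threshold = 0) {
  stopifnot(inherits(band, "simultaneous_band"))
  D <- band$lower > threshold
  S <- band$upper > threshold
  region <- factor(ifelse(D, "D", ifelse(S, "S\\D", "Sc")),
                   levels = c("D", "S\\D", "Sc"))
  structure(list(D = D, S = S, region = region,
                 level = band$level, threshold = threshold),
            class = "credible_subgroup_pair")
}

#' Monte-Carlo estimate of the bracketing probability
#'
#' Estimates, over the retained draws, the posterior probability of the
#' defining event of a credible subgroup pair: every point of D has effect
#' above the threshold AND every point with effect above the threshold lies
#' in S (equivalently, no point outside S does).  For a pair built from the
#' same draws at level 1 - alpha this estimate is at least 1 - alpha by
#' construction of the band.
#'
#' @param pte the [compute_pte()] object the pair was derived from.
#' @param pair a [classify()] object.
#' @return A probability in `[0, 1]`.
#' @export
bracket_probability <- function(pte, pair) {
  stopifnot(inherits(pte, "pte_draws"), inherits(pair, "credible_subgroup_pair"))
  if (length(pair$D) != pte$n_points)
    stop("pair and draws refer to different grids")
  delta <- pair$threshold
  idx_D <- which(pair$D)
  idx_notS <- which(!pair$S)
  ok <- logical(pte$n_draws)
  for (rows in pte_block_starts(pte)) {
    b <- pte_block(pte, rows)  # points x draws
    good <- rep(TRUE, length(rows))
    if (length(idx_D))
      good <- good & (matrixStats::colMins(b[idx_D, , drop = FALSE]) > delta)
    if (length(idx_notS))
      good <- good & (matrixStats::colMaxs(b[idx_notS, , drop = FALSE]) <= delta)
    ok[rows] <- good
  }
  mean(ok)
}

#' Signed maximum credible level per grid point
#'
#' For each grid point, the largest level in `level_grid` at which the point
#' belongs to the exclusive subgroup D (positive sign) or, failing that, the
#' largest level at which it belongs to the no-benefit region S-complement
#' (negative sign); zero if it enters neither at any computed level.
#' Because the band multiplier c(level) is non-decreasing in the level,
#' membership thresholds reduce to comparing c(level) against the
#' standardized margin of each point, so the whole surface costs one pass
#' over the draws.
#'
#' @param pte a [compute_pte()] object.
#' @param threshold benefit threshold delta.
#' @param level_grid ascending credible levels inside (0, 1); default
#'   0.001-step grid over (0.001, 0.999).
#' @return An object of class `max_level_surface` with the signed `level`
#'   vector and the `level_grid` used.
#' @export
max_credible_level <- function(pte, threshold = 0,
                               level_grid = seq(0.001, 0.999, by = 0.001)) {
  stopifnot(inherits(pte, "pte_draws"))
  if (!length(level_grid)) stop("level_grid is empty")
  if (any(level_grid <= 0 | level_grid >= 1)) stop("levels must lie in (0, 1)")
  level_grid <- sort(level_grid)
  st <- pte_band_stats(pte)
  c_levels <- quantile_type1(st$W, level_grid)  # non-decreasing
  surface <- numeric(pte$n_points)
  deg <- st$sd <= SD_FLOOR
  top <- length(level_grid)
  for (j in seq_len(pte$n_points)) {
    if (deg[j]) {
      # zero-width band: membership is level-free
      surface[j] <- if (st$mean[j] > threshold) level_grid[top]
                    else -level_grid[top]
      next
    }
    margin_D <- (st$mean[j] - threshold) / st$sd[j]
    iD <- sum(c_levels < margin_D)        # levels form a prefix
    if (iD > 0L) {
      surface[j] <- level_grid[iD]
    } else {
      margin_S <- (threshold - st$mean[j]) / st$sd[j]
      iS <- sum(c_levels <= margin_S)
      surface[j] <- if (iS > 0L) -level_grid[iS] else 0
    }
  }
  structure(list(level = surface, level_grid = level_grid,
                 threshold = threshold),
            class = "max_level_surface")
}

#' Membership fractions of a cohort under a classified grid
#'
#' Maps each subject to its nearest grid point (nearest neighbour along each
#' standardized continuous axis, exact match on sex) and reports the share
#' of subjects falling in D, the uncertainty region S\\D, and the no-benefit
#' region Sc.  Subjects outside the grid's covariate ranges are clamped to
#' the boundary point and counted, with a warning.
#'
#' @param pair a [classify()] object built on `grid`.
#' @param cohort complete-case cohort on the raw scale.
#' @param std standardization parameters of the fitted model.
#' @param grid the `covariate_grid` the pair was built on.
#' @return Named numeric vector of fractions `D`, `S\\D`, `Sc` summing to 1.
#' @export
apply_to_cohort <- function(pair, cohort, std, grid) {
  stopifnot(inherits(pair, "credible_subgroup_pair"),
            inherits(grid, "covariate_grid"))
  if (anyNA(cohort)) stop("cohort must be complete-case")
  if (length(pair$D) != nrow(grid$points))
    stop("pair and grid sizes disagree")
  nearest_axis <- function(values, axis) {
    lo <- axis[1L]; hi <- axis[length(axis)]
    out_of_range <- values < lo | values > hi
    step <- (hi - lo) / (length(axis) - 1L)
    idx <- round((pmin(hi, pmax(lo, values)) - lo) / step) + 1L
    list(idx = pmin(length(axis), pmax(1L, idx)), oor = out_of_range)
  }
  a_gh <- nearest_axis(cohort$sf36_gh, grid$axes$sf36_gh)
  a_age <- nearest_axis(cohort$age, grid$axes$age)
  a_hb <- nearest_axis(cohort$hba1c, grid$axes$hba1c)
  n_oor <- sum(a_gh$oor | a_age$oor | a_hb$oor)
  if (n_oor > 0L)
    warning(n_oor, " subject(s) outside the grid ranges were clamped to the boundary")
  res <- grid$resolution
  # expand.grid order in make_grid: sf36 fastest, then age, then sex, then hba1c
  pos <- a_gh$idx +
    res * (a_age$idx - 1L) +
    res * res * cohort$sex +
    2L * res * res * (a_hb$idx - 1L)
  region <- pair$region[pos]
  counts <- table(region)
  fractions <- as.numeric(counts) / nrow(cohort)
  names(fractions) <- names(counts)
  fractions
}

#' Export a classified grid as a table
#'
#' One row per grid point: raw covariate values, standardized values,
#' posterior mean effect, band lower/upper, region label, and (optionally)
#' the signed maximum credible level.
#'
#' @param grid a `covariate_grid`.
#' @param band the `simultaneous_band` on that grid.
#' @param pair the `credible_subgroup_pair`.
#' @param surface optional `max_level_surface`.
#' @return A `data.frame`.
#' @export
classification_table <- function(grid, band, pair, surface = NULL) {
  out <- data.frame(
    sf36_gh = grid$raw$sf36_gh, age = grid$raw$age,
    sex = grid$raw$sex, hba1c = grid$raw$hba1c,
    sf36_gh_std = grid$points[, "sf36_gh"],
    age_std = grid$points[, "age"],
    hba1c_std = grid$points[, "hba1c"],
    mean_effect = band$mean, sd_effect = band$sd,
    lower = band$lower, upper = band$upper,
    region = as.character(pair$region)
  )
  if (!is.null(surface)) out$max_level <- surface$level
  out
}
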