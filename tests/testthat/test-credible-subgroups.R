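std_toy <- function() {
  co <- toy_cohort(200, seed = 101)
  build_design(co)$std
}

test_that("make_grid lays a factorial grid on the standardized scale", {
  std <- std_toy()
  ranges <- list(sf36_gh = c(30, 60), age = c(45, 75), hba1c = c(5, 10))
  g <- make_grid(std, ranges, resolution = 2)
  expect_equal(nrow(g$points), 16)  # 2 * 2^3
  expect_true(all(g$points[, 1] == 1))
  expect_true(all(g$points[, "sex"] %in% c(0, 1)))
  expect_true(all(g$raw$sf36_gh >= 30 & g$raw$sf36_gh <= 60))

  # grid point at the raw means -> standardized continuous components 0
  centers <- sapply(std, `[[`, "center")
  ranges_c <- list(sf36_gh = centers[["sf36_gh"]] + c(-5, 5),
                   age = centers[["age"]] + c(-5, 5),
                   hba1c = centers[["hba1c"]] + c(-1, 1))
  g3 <- make_grid(std, ranges_c, resolution = 3)
  mid <- g3$points[, c("sf36_gh", "age", "hba1c")]
  at_center <- abs(g3$raw$sf36_gh - centers[["sf36_gh"]]) < 1e-9 &
    abs(g3$raw$age - centers[["age"]]) < 1e-9 &
    abs(g3$raw$hba1c - centers[["hba1c"]]) < 1e-9
  expect_true(any(at_center))
  expect_true(all(abs(mid[at_center, ]) < 1e-9))

  expect_error(make_grid(std, ranges, resolution = 1), "resolution")
  expect_error(make_grid(std, c(ranges, list(bogus = c(0, 1)))), "unknown")
  expect_error(
    make_grid(std, list(sf36_gh = c(30, 30), age = c(45, 75), hba1c = c(5, 10))),
    "distinct")
})

test_that("grid_from_cohort spans the observed 1st-99th percentile range", {
  co <- toy_cohort(500, seed = 11)
  std <- build_design(co)$std
  g <- grid_from_cohort(co, std, resolution = 4)
  expect_equal(nrow(g$points), 2 * 4^3)
  expect_equal(range(g$axes$age),
               unname(quantile(co$age, c(0.01, 0.99))))
})

test_that("compute_pte evaluates the benefit-positive contrast per draw", {
  std <- std_toy()
  g <- make_grid(std, list(sf36_gh = c(30, 60), age = c(45, 75),
                           hba1c = c(5, 10)), resolution = 2)
  # all-zero gamma draws -> effect identically 0 on both scales
  draws0 <- fake_draws(cbind(matrix(rnorm(20), 4), matrix(0, 4, 5)))
  for (sc in c("log-odds", "risk-difference")) {
    pte <- compute_pte(draws0, g, sc)
    expect_true(all(credpair:::pte_block(pte, 1:4) == 0))
  }

  # single reference draw, hand-evaluated at chosen predictive vectors
  gamma <- c(-0.22, -0.19, -0.01, -0.07, 0.32)
  one <- fake_draws(matrix(c(rep(0, 5), gamma), 1))
  pts <- rbind(c(1, 0, 0, 0, 0),   # standardized-origin female
               c(1, 0, 0, 0, 1))   # HbA1c at +1 sd
  pte <- pte_from_matrix(-(matrix(gamma, 1) %*% t(pts)))
  expect_equal(drop(credpair:::pte_block(pte, 1)), c(0.22, -0.10))
  # the linear path agrees
  g$points <- pts
  pte_lin <- compute_pte(one, g, "log-odds")
  expect_equal(drop(credpair:::pte_block(pte_lin, 1)), c(0.22, -0.10))

  expect_error(compute_pte(one, g, "hazard"), "arg")
})

test_that("risk-difference scale uses x = z on both arms", {
  m <- matrix(rnorm(20, sd = 0.3), 2)
  draws <- fake_draws(m)
  pts <- cbind(1, rnorm(3), rnorm(3), c(0, 1, 0), rnorm(3))
  g <- list(points = pts); class(g) <- "covariate_grid"
  pte <- compute_pte(draws, g, "risk-difference")
  vals <- credpair:::pte_block(pte, 1:2)
  for (k in 1:2) for (j in 1:3) {
    e0 <- plogis(sum(pts[j, ] * m[k, 1:5]))
    e1 <- plogis(sum(pts[j, ] * m[k, 1:5]) + sum(pts[j, ] * m[k, 6:10]))
    expect_equal(vals[j, k], e0 - e1)
  }
})

test_that("simultaneous band matches the enumeration oracle on toys", {
  vals <- matrix(c(0.1, 0.5, -0.2, 0.4,
                   0.3, 0.2, 0.0, 0.6), 4, 2)
  pte <- pte_from_matrix(vals)
  for (lv in c(0.25, 0.5, 0.75, 0.95)) {
    b <- simultaneous_band(pte, lv)
    ob <- oracle_band(vals, lv)
    expect_equal(b$multiplier, ob$multiplier)
    expect_equal(b$mean, ob$mean)
    expect_equal(b$sd, ob$sd)
    expect_equal(b$lower, ob$lower)
    expect_equal(b$upper, ob$upper)
  }
  # level -> 1 gives the max sup-deviation and the widest band
  b1 <- simultaneous_band(pte, 0.9999)
  expect_equal(b1$multiplier, max(b1$sup_draws))

  # all draws identical: sd floor collapses the band onto the mean
  flat <- pte_from_matrix(matrix(c(1, 1, 1, -2, -2, -2), 3, 2))
  b <- simultaneous_band(flat, 0.8)
  expect_equal(b$lower, b$upper)
  expect_equal(b$lower, c(1, -2))

  expect_error(simultaneous_band(pte, 1), "level")
  expect_error(simultaneous_band(pte_from_matrix(vals[1, , drop = FALSE]), 0.5),
               "2 draws")
})

test_that("classify applies the band decision rule", {
  band <- structure(list(mean = c(0.3, 0.05, -0.35),
                         sd = c(0.1, 0.125, 0.125), multiplier = 2,
                         lower = c(0.1, -0.2, -0.6),
                         upper = c(0.5, 0.3, -0.1),
                         level = 0.8, degenerate = rep(FALSE, 3)),
                    class = "simultaneous_band")
  pair <- classify(band, 0)
  expect_equal(pair$D, c(TRUE, FALSE, FALSE))
  expect_equal(pair$S, c(TRUE, TRUE, FALSE))
  expect_equal(as.character(pair$region), c("D", "S\\D", "Sc"))
  expect_true(all(pair$D <= pair$S))  # D subset of S always
})

test_that("bracket_probability matches exact enumeration and the guarantee", {
  vals <- matrix(c(0.2, -0.1, 0.4, 0.3,
                   0.1, 0.2, -0.5, 0.0,
                   -0.3, -0.2, -0.1, 0.6), 4, 3)
  pte <- pte_from_matrix(vals)
  for (lv in c(0.5, 0.8)) {
    pair <- classify(simultaneous_band(pte, lv), 0)
    bp <- bracket_probability(pte, pair)
    expect_equal(bp, oracle_bracket(vals, pair$D, pair$S, 0))
    expect_gte(bp, lv)
  }
  # D empty and S the full grid -> vacuously certain
  pair_all <- structure(list(D = rep(FALSE, 3), S = rep(TRUE, 3),
                             level = 0.8, threshold = 0),
                        class = "credible_subgroup_pair")
  expect_equal(bracket_probability(pte, pair_all), 1)
})

test_that("randomized oracle-equivalence suite over small draw matrices", {
  set.seed(314)
  lvls <- seq(0.05, 0.95, by = 0.05)
  for (rep in 1:40) {
    K <- sample(2:10, 1)
    m <- sample(1:5, 1)
    vals <- matrix(round(rnorm(K * m), 2), K, m)  # rounding induces ties
    if (rep %% 4 == 0) vals[, 1] <- 1  # degenerate column
    pte <- pte_from_matrix(vals)
    delta <- sample(c(0, 0.1, -0.2), 1)
    for (lv in sample(lvls, 3)) {
      b <- simultaneous_band(pte, lv)
      ob <- oracle_band(vals, lv)
      expect_equal(b$multiplier, ob$multiplier, tolerance = 1e-12)
      expect_equal(b$lower, ob$lower, tolerance = 1e-12)
      expect_equal(b$upper, ob$upper, tolerance = 1e-12)
      pair <- classify(b, delta)
      ocl <- oracle_classify(ob, delta)
      expect_identical(pair$D, ocl$D)
      expect_identical(pair$S, ocl$S)
      expect_identical(bracket_probability(pte, pair),
                       oracle_bracket(vals, pair$D, pair$S, delta))
    }
    surf <- max_credible_level(pte, 0, level_grid = lvls)
    expect_equal(surf$level, oracle_max_level(vals, 0, lvls))
  }
})

test_that("max_credible_level is signed and consistent with classify", {
  # constant positive effect with a floored sd -> top of the level grid
  flat <- pte_from_matrix(matrix(1, 3, 1))
  surf <- max_credible_level(flat, 0, level_grid = c(0.2, 0.5, 0.9))
  expect_equal(surf$level, 0.9)

  # symmetric two-draw toy straddling the threshold -> small magnitude
  sym <- pte_from_matrix(matrix(c(1, -1), 2, 1))
  surf <- max_credible_level(sym, 0, level_grid = seq(0.05, 0.95, 0.05))
  expect_lte(abs(surf$level), 0.5)

  # consistency: {surface >= level} == D(level) at every grid level
  set.seed(9)
  vals <- matrix(rnorm(8 * 4), 8, 4)
  pte <- pte_from_matrix(vals)
  lvls <- seq(0.1, 0.9, by = 0.1)
  surf <- max_credible_level(pte, 0, level_grid = lvls)
  for (lv in lvls) {
    pair <- classify(simultaneous_band(pte, lv), 0)
    expect_identical(surf$level >= lv, pair$D)
  }
  expect_error(max_credible_level(pte, 0, numeric(0)), "empty")
})

test_that("subgroups are nested across credible levels", {
  set.seed(21)
  dm <- build_design(toy_cohort(400, seed = 22))
  dr <- sample_posterior(dm, cfg = mcmc_config(500, 100, seed = 23))
  g <- grid_from_cohort(toy_cohort(400, seed = 22), dm$std, resolution = 4)
  pte <- compute_pte(dr, g)
  levels <- c(0.5, 0.65, 0.8, 0.95)
  pairs <- lapply(levels, function(lv) classify(simultaneous_band(pte, lv), 0))
  for (i in seq_len(length(levels) - 1)) {
    hi <- pairs[[i + 1]]; lo <- pairs[[i]]
    expect_true(all(hi$D <= lo$D))        # D shrinks as the level rises
    expect_true(all((!hi$S) <= (!lo$S)))  # so does the no-benefit region
    expect_true(all(hi$D <= hi$S))
  }
  # the bracketing guarantee holds at every level by construction
  for (i in seq_along(levels))
    expect_gte(bracket_probability(pte, pairs[[i]]), levels[i])
})

test_that("band and effects are equivariant to shifting the treatment main effect", {
  set.seed(33)
  m <- matrix(rnorm(60, sd = 0.4), 6, 10)
  std <- std_toy()
  g <- make_grid(std, list(sf36_gh = c(30, 60), age = c(45, 75),
                           hba1c = c(5, 10)), resolution = 2)
  shift <- 0.7
  m2 <- m; m2[, 6] <- m2[, 6] + shift
  b1 <- simultaneous_band(compute_pte(fake_draws(m), g), 0.8)
  b2 <- simultaneous_band(compute_pte(fake_draws(m2), g), 0.8)
  expect_equal(b2$mean, b1$mean - shift)
  expect_equal(b2$lower, b1$lower - shift)
  expect_equal(b2$upper, b1$upper - shift)
  expect_equal(b2$multiplier, b1$multiplier)
})

test_that("apply_to_cohort maps subjects to nearest grid points", {
  co <- toy_cohort(300, seed = 41)
  dm <- build_design(co)
  g <- grid_from_cohort(co, dm$std, resolution = 3)
  m <- nrow(g$points)

  # every subject lands in D when D is the whole grid
  pair_allD <- structure(list(D = rep(TRUE, m), S = rep(TRUE, m),
                              region = factor(rep("D", m),
                                              levels = c("D", "S\\D", "Sc")),
                              level = 0.8, threshold = 0),
                         class = "credible_subgroup_pair")
  fr <- suppressWarnings(apply_to_cohort(pair_allD, co, dm$std, g))
  expect_equal(unname(fr), c(1, 0, 0))
  expect_equal(sum(fr), 1)

  # empty D, S = full grid -> everyone uncertain
  pair_unc <- pair_allD
  pair_unc$D <- rep(FALSE, m)
  pair_unc$region <- factor(rep("S\\D", m), levels = c("D", "S\\D", "Sc"))
  fr <- suppressWarnings(apply_to_cohort(pair_unc, co, dm$std, g))
  expect_equal(unname(fr), c(0, 1, 0))

  # hand-mapped toy: region determined solely by sex on a tiny grid
  g2 <- grid_from_cohort(co, dm$std, resolution = 2)
  m2 <- nrow(g2$points)
  sex_col <- g2$points[, "sex"]
  region <- factor(ifelse(sex_col == 1, "Sc", "D"),
                   levels = c("D", "S\\D", "Sc"))
  pair_sex <- structure(list(D = sex_col == 0, S = sex_col == 0,
                             region = region, level = 0.8, threshold = 0),
                        class = "credible_subgroup_pair")
  fr <- suppressWarnings(apply_to_cohort(pair_sex, co, dm$std, g2))
  expect_equal(unname(fr[["D"]]), mean(co$sex == 0))
  expect_equal(unname(fr[["Sc"]]), mean(co$sex == 1))

  # out-of-range subjects are clamped with a warning
  co2 <- co
  co2$age[1] <- 1000
  expect_warning(apply_to_cohort(pair_allD, co2, dm$std, g), "clamped")
})
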