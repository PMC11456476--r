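test_that("Wald ratio is the outcome/exposure effect quotient", {
  est <- wald_ratio(0.1, 0.02, 0.05, 0.01)
  expect_equal(est$theta, 0.5)
  expect_equal(est$se, 0.1)
  expect_equal(wald_ratio(-0.1, 0.02, 0.05, 0.01)$theta, -0.5)
  expect_equal(wald_ratio(0.1, 0.02, 0, 0.01)$theta, 0)
  expect_error(wald_ratio(0, 0.02, 0.05, 0.01), "nonzero")
})

test_that("IVW reproduces the closed-form weighted LS through the origin", {
  set <- harmonized_set(beta_x = c(0.5, 0.2), se_x = c(0.02, 0.02),
                        beta_y = c(0.25, 0.10), se_y = c(0.1, 0.1))
  fixed <- ivw(set, "fixed")
  mre <- ivw(set, "multiplicative_random")
  # homogeneous ratios: both Wald ratios 0.5
  expect_equal(fixed$theta, 0.5, tolerance = 1e-12)
  expect_equal(fixed$extras$Q, 0, tolerance = 1e-12)
  # SE identical under both variance models when Q = 0
  expect_equal(mre$se, fixed$se, tolerance = 1e-12)
  # closed form: sqrt(1 / (100 * 0.29)) = sqrt(1/29)
  expect_equal(fixed$se, sqrt(1 / 29), tolerance = 1e-12)
})

test_that("IVW and Egger match generic weighted least squares oracles", {
  for (seed in 1:20) {
    set <- random_set(j = 20, seed = seed)
    d <- set$data
    w <- 1 / d$se_y^2
    fit0 <- stats::lm(beta_y ~ 0 + beta_x, data = d, weights = w)
    expect_equal(ivw(set, "fixed")$theta, unname(coef(fit0)),
                 tolerance = 1e-10)

    od <- orient_positive_exposure(set)$data
    fit1 <- stats::lm(beta_y ~ beta_x, data = od, weights = 1 / od$se_y^2)
    e <- egger(set)
    expect_equal(e$theta, unname(coef(fit1)["beta_x"]), tolerance = 1e-10)
    expect_equal(e$extras$alpha, unname(coef(fit1)["(Intercept)"]),
                 tolerance = 1e-10)
    # lm scales coefficient SEs by sigma; the Egger convention floors the
    # inflation at 1
    sm <- summary(fit1)
    expect_equal(e$se,
                 sm$coefficients["beta_x", "Std. Error"] / sm$sigma *
                   max(1, sm$sigma), tolerance = 1e-10)
  }
})

test_that("Egger recovers an exact affine relation with zero residual", {
  set <- harmonized_set(beta_x = c(0.2, 0.4, 0.6), se_x = rep(0.02, 3),
                        beta_y = c(0.18, 0.26, 0.34), se_y = c(0.05, 0.07, 0.06))
  e <- egger(set)
  expect_equal(e$theta, 0.4, tolerance = 1e-12)
  expect_equal(e$extras$alpha, 0.1, tolerance = 1e-12)
  expect_equal(e$extras$rss, 0, tolerance = 1e-10)
  expect_error(egger(make_set(c(0.1, 0.2), c(0.05, 0.1))), "at least 3")
})

test_that("weighted median interpolation follows the cumulative-weight rule", {
  wm <- mrflora:::.weighted_median_point
  expect_equal(wm(c(0.2, 0.5, 0.9), rep(1, 3)), 0.5)
  # two equal-weight ratios: midpoint by interpolation
  expect_equal(wm(c(0.2, 0.9), c(1, 1)), 0.55)
  # weights shift the crossing point
  expect_equal(wm(c(0.2, 0.9), c(3, 1)), 0.2 + 0.7 * (0.5 - 3 / 8) / (1 / 2))
  # estimator wrapper agrees on a symmetric set
  set <- make_set(rep(0.2, 3), 0.2 * c(0.2, 0.5, 0.9))
  expect_equal(weighted_median(set, n_boot = 10, seed = 1)$theta, 0.5)
})

test_that("weighted mode locates the dominant ratio cluster", {
  set <- make_set(rep(0.2, 4), 0.2 * c(0.48, 0.50, 0.52, 5.0))
  est <- weighted_mode(set, n_boot = 10, seed = 1)
  expect_gte(est$theta, 0.48)
  expect_lte(est$theta, 0.52)
  # degenerate cluster: all ratios identical
  set2 <- make_set(rep(0.2, 4), rep(0.2 * 0.7, 4))
  expect_equal(weighted_mode(set2, n_boot = 10, seed = 1)$theta, 0.7)
})

test_that("larger mode bandwidth never increases the number of modes", {
  set.seed(5)
  r <- c(rnorm(10, 0, 0.05), rnorm(5, 1, 0.05))
  w <- rep(1 / 15, 15)
  count_modes <- function(phi) {
    h <- max(phi * 0.9 * min(sd(r), mad(r)) * 15^(-1 / 5), 1e-12)
    grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 512)
    dens <- vapply(grid, function(x) sum(w * dnorm(x, r, h)), numeric(1))
    sum(diff(sign(diff(dens))) == -2)
  }
  phis <- c(0.25, 0.5, 1, 2, 4, 8)
  modes <- vapply(phis, count_modes, numeric(1))
  expect_true(all(diff(modes) <= 0))
})

test_that("maximum likelihood profiles to the grid-search optimum", {
  for (seed in 1:5) {
    set <- random_set(j = 20, seed = seed + 100)
    ml <- max_likelihood(set)
    # two-stage independent grid search on the profile log-likelihood
    ll <- function(t) mrflora:::.profile_loglik(t, set$data)
    coarse <- seq(ml$theta - 0.5, ml$theta + 0.5, length.out = 2001)
    t0 <- coarse[which.max(vapply(coarse, ll, numeric(1)))]
    fine <- seq(t0 - 6e-4, t0 + 6e-4, length.out = 2401)
    t1 <- fine[which.max(vapply(fine, ll, numeric(1)))]
    expect_equal(ml$theta, t1, tolerance = 1e-6)
  }
})

test_that("maximum likelihood reduces to fixed IVW with noiseless exposure", {
  set.seed(9)
  set <- harmonized_set(beta_x = runif(10, 0.1, 0.4), se_x = rep(1e-8, 10),
                        beta_y = rnorm(10, 0.1, 0.02), se_y = runif(10, 0.02, 0.05))
  expect_equal(max_likelihood(set)$theta, ivw(set, "fixed")$theta,
               tolerance = 1e-4)
  # single SNP: Wald ratio
  s1 <- harmonized_set(0.2, 0.02, 0.1, 0.05)
  expect_equal(max_likelihood(s1)$theta, 0.5)
  expect_equal(ivw(s1)$theta, 0.5)
})

test_that("all estimators return the common ratio on homogeneous sets", {
  set <- make_set(c(0.2, 0.3, 0.4, 0.5), 0.37 * c(0.2, 0.3, 0.4, 0.5))
  expect_equal(ivw(set, "fixed")$theta, 0.37, tolerance = 1e-10)
  expect_equal(ivw(set, "multiplicative_random")$theta, 0.37,
               tolerance = 1e-10)
  expect_equal(weighted_median(set, n_boot = 10, seed = 1)$theta, 0.37,
               tolerance = 1e-10)
  expect_equal(weighted_mode(set, n_boot = 10, seed = 1)$theta, 0.37,
               tolerance = 1e-3)
  expect_equal(max_likelihood(set)$theta, 0.37, tolerance = 1e-6)
})

test_that("estimators are scale-equivariant in the outcome", {
  set <- random_set(j = 15, seed = 3)
  c_scale <- 2.7
  scaled <- harmonized_set(set$data$beta_x, set$data$se_x,
                           c_scale * set$data$beta_y,
                           c_scale * set$data$se_y)
  expect_equal(ivw(scaled)$theta, c_scale * ivw(set)$theta,
               tolerance = 1e-10)
  expect_equal(egger(scaled)$theta, c_scale * egger(set)$theta,
               tolerance = 1e-10)
  expect_equal(weighted_median(scaled, n_boot = 10, seed = 1)$theta,
               c_scale * weighted_median(set, n_boot = 10, seed = 1)$theta,
               tolerance = 1e-10)
  expect_equal(max_likelihood(scaled)$theta,
               c_scale * max_likelihood(set)$theta, tolerance = 1e-5)
})

test_that("orientation leaves IVW, median, mode and ML unchanged", {
  set <- harmonized_set(beta_x = c(-0.3, 0.2, -0.15, 0.4),
                        se_x = rep(0.02, 4),
                        beta_y = c(-0.12, 0.09, -0.05, 0.18),
                        se_y = rep(0.05, 4))
  oriented <- orient_positive_exposure(set)
  expect_equal(ivw(set)$theta, ivw(oriented)$theta, tolerance = 1e-14)
  expect_equal(weighted_median(set, n_boot = 10, seed = 1)$theta,
               weighted_median(oriented, n_boot = 10, seed = 1)$theta,
               tolerance = 1e-12)
  expect_equal(weighted_mode(set, n_boot = 10, seed = 1)$theta,
               weighted_mode(oriented, n_boot = 10, seed = 1)$theta,
               tolerance = 1e-12)
  expect_equal(max_likelihood(set)$theta, max_likelihood(oriented)$theta,
               tolerance = 1e-8)
})

test_that("odds-ratio conversion and CI inversion are mutually consistent", {
  orc <- to_odds_ratio(0, 0.1)
  expect_equal(orc$or_point, 1)
  expect_equal(orc$or_ci95, c(exp(-0.196), exp(0.196)))
  # published triple: theta = ln(0.40), se chosen to give CI 0.21-0.77
  orc2 <- to_odds_ratio(log(0.40), 0.3315)
  expect_equal(round(orc2$or_ci95, 2), c(0.21, 0.77))
  # monotone in theta
  expect_lt(to_odds_ratio(0.1, 0.1)$or_point,
            to_odds_ratio(0.2, 0.1)$or_point)

  expect_equal(round(p_from_or_ci(0.40, 0.21, 0.77), 3), 0.006)
  expect_equal(round(p_from_or_ci(2.12, 1.10, 4.11), 3), 0.025)
  expect_equal(p_from_or_ci(1.0, 0.5, 2.0), 1)
  expect_error(p_from_or_ci(0.4, 0.5, 0.77), "ci_low")
})
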