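# The five two-sample MR causal estimators: inverse-variance weighted,
# MR-Egger, weighted median, weighted mode, and maximum likelihood; plus
# the single-variant Wald ratio and odds-ratio conversion.

.mr_estimate <- function(method, theta, se, n_snp, extras = list()) {
  pval <- 2 * stats::pnorm(-abs(theta / se))
  orc <- to_odds_ratio(theta, se)
  structure(list(method = method, theta = theta, se = se,
                 pval = max(pval, .Machine$double.xmin), n_snp = n_snp,
                 or_point = orc$or_point, or_ci95 = orc$or_ci95,
                 extras = extras),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (%d SNPs): theta = %.4f (SE %.4f), OR = %.3f [%.3f, %.3f], p = %.3g\n",
              x$method, x$n_snp, x$theta, x$se, x$or_point,
              x$or_ci95[1], x$or_ci95[2], x$pval))
  invisible(x)
}

.set_data <- function(set) {
  stopifnot(inherits(set, "harmonized_set"))
  d <- set$data
  if (nrow(d) == 0) stop("empty harmonized set", call. = FALSE)
  d
}

#' Single-variant Wald ratio estimate
#'
#' theta = beta_y / beta_x with the first-order standard error
#' se_y / |beta_x|.
#'
#' @param beta_x,se_x Exposure effect and SE.
#' @param beta_y,se_y Outcome effect and SE.
#' @return An \code{mr_estimate}.
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y) {
  if (beta_x == 0) stop("beta_x must be nonzero for a Wald ratio",
                        call. = FALSE)
  .mr_estimate("wald_ratio", beta_y / beta_x, se_y / abs(beta_x), 1L)
}

#' Inverse-variance weighted estimate
#'
#' Weighted least squares of the outcome effects on the exposure
#' effects through the origin, with weights 1/se_y^2 — the
#' meta-analysis of per-SNP Wald ratios. Under the default
#' multiplicative random-effects model the fixed-effect SE is inflated
#' by max(1, sqrt(Q/(J-1))) with Cochran's Q, so it is never
#' anti-conservative relative to fixed effects.
#'
#' @param set A \code{harmonized_set} with J >= 2 (J = 1 delegates to
#'   the Wald ratio).
#' @param variance_model "multiplicative_random" (default) or "fixed".
#' @return An \code{mr_estimate}.
#' @export
ivw <- function(set, variance_model = c("multiplicative_random", "fixed")) {
  variance_model <- match.arg(variance_model)
  d <- .set_data(set)
  j <- nrow(d)
  if (j == 1) {
    est <- wald_ratio(d$beta_x, d$se_x, d$beta_y, d$se_y)
    est$method <- "ivw"
    return(est)
  }
  w <- 1 / d$se_y^2
  sxx <- sum(w * d$beta_x^2)
  theta <- sum(w * d$beta_x * d$beta_y) / sxx
  se_fixed <- sqrt(1 / sxx)
  q <- sum(w * (d$beta_y - theta * d$beta_x)^2)
  scale <- if (variance_model == "multiplicative_random" && j > 1) {
    max(1, sqrt(q / (j - 1)))
  } else 1
  .mr_estimate("ivw", theta, se_fixed * scale, j,
               extras = list(Q = q, variance_model = variance_model,
                             se_fixed = se_fixed))
}

#' MR-Egger regression estimate
#'
#' Weighted linear regression beta_y = alpha + theta * beta_x with
#' weights 1/se_y^2 on the positively-oriented set. The intercept alpha
#' measures directional pleiotropy; the slope is the causal estimate
#' under the InSIDE assumption. Coefficient SEs are inflated by
#' max(1, sigma_hat) where sigma_hat^2 is the weighted residual mean
#' square on J - 2 degrees of freedom.
#'
#' @param set A \code{harmonized_set} with J >= 3.
#' @return An \code{mr_estimate} with alpha, se_alpha, pval_alpha,
#'   sigma in \code{extras}.
#' @export
egger <- function(set) {
  set <- orient_positive_exposure(set)
  d <- .set_data(set)
  j <- nrow(d)
  if (j < 3) stop("MR-Egger requires at least 3 instruments", call. = FALSE)
  w <- 1 / d$se_y^2
  x <- d$beta_x; y <- d$beta_y
  sw <- sum(w); swx <- sum(w * x); swx2 <- sum(w * x^2)
  swy <- sum(w * y); swxy <- sum(w * x * y)
  det <- sw * swx2 - swx^2
  theta <- (sw * swxy - swx * swy) / det
  alpha <- (swx2 * swy - swx * swxy) / det
  rss <- sum(w * (y - alpha - theta * x)^2)
  sigma2 <- rss / (j - 2)
  infl <- max(1, sqrt(sigma2))
  se_theta <- sqrt(sw / det) * infl
  se_alpha <- sqrt(swx2 / det) * infl
  pval_alpha <- 2 * stats::pnorm(-abs(alpha / se_alpha))
  .mr_estimate("egger", theta, se_theta, j,
               extras = list(alpha = alpha, se_alpha = se_alpha,
                             pval_alpha = pval_alpha,
                             sigma = sqrt(sigma2), rss = rss))
}

# Per-SNP Wald ratios and normalized first-order inverse-variance
# weights (beta_x^2 / se_y^2) shared by the median and mode estimators.
.ratio_weights <- function(d) {
  r <- d$beta_y / d$beta_x
  w <- d$beta_x^2 / d$se_y^2
  list(r = r, w = w / sum(w))
}

.weighted_median_point <- function(r, w) {
  ord <- order(r)
  r <- r[ord]; w <- w[ord]
  w <- w / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

.mode_point <- function(r, w, phi) {
  w <- w / sum(w)
  if (length(unique(r)) == 1) return(r[1])
  h <- phi * 0.9 * min(stats::sd(r), stats::mad(r)) * length(r)^(-1 / 5)
  h <- max(h, 1e-12)
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 512)
  dens <- vapply(grid, function(x) sum(w * stats::dnorm(x, r, h)),
                 numeric(1))
  grid[which.max(dens)]
}

.parametric_boot_se <- function(d, point_fun, n_boot, seed) {
  if (!is.null(seed)) set.seed(seed)
  j <- nrow(d)
  ests <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(j, d$beta_x, d$se_x)
    by <- stats::rnorm(j, d$beta_y, d$se_y)
    point_fun(bx, by)
  }, numeric(1))
  stats::sd(ests)
}

#' Weighted median estimate
#'
#' The inverse-variance weighted median of the per-SNP Wald ratios,
#' linearly interpolated at cumulative weight 0.5; consistent when up
#' to 50% of the instrument weight is invalid. The SE is a parametric
#' bootstrap over the summary statistics.
#'
#' @param set A \code{harmonized_set} with J >= 3.
#' @param n_boot Bootstrap replicates for the SE (default 1000).
#' @param seed Seed for the bootstrap.
#' @return An \code{mr_estimate}.
#' @export
weighted_median <- function(set, n_boot = 1000L, seed = 1L) {
  d <- .set_data(set)
  if (nrow(d) < 3) stop("weighted median requires at least 3 instruments",
                        call. = FALSE)
  rw <- .ratio_weights(d)
  theta <- .weighted_median_point(rw$r, rw$w)
  se <- .parametric_boot_se(d, function(bx, by) {
    .weighted_median_point(by / bx, bx^2 / d$se_y^2)
  }, n_boot, seed)
  .mr_estimate("weighted_median", theta, se, nrow(d),
               extras = list(n_boot = n_boot))
}

#' Weighted mode estimate
#'
#' The mode of the inverse-variance weighted kernel density of the
#' per-SNP Wald ratios (modified Silverman bandwidth scaled by
#' \code{phi}), targeting the largest cluster of instruments with
#' similar ratio estimates. The SE is a parametric bootstrap.
#'
#' @param set A \code{harmonized_set} with J >= 3.
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap.
#' @return An \code{mr_estimate}.
#' @export
weighted_mode <- function(set, phi = 1, n_boot = 1000L, seed = 1L) {
  d <- .set_data(set)
  if (nrow(d) < 3) stop("weighted mode requires at least 3 instruments",
                        call. = FALSE)
  rw <- .ratio_weights(d)
  theta <- .mode_point(rw$r, rw$w, phi)
  se <- .parametric_boot_se(d, function(bx, by) {
    .mode_point(by / bx, bx^2 / d$se_y^2, phi)
  }, n_boot, seed)
  .mr_estimate("weighted_mode", theta, se, nrow(d),
               extras = list(phi = phi, n_boot = n_boot))
}

.profile_loglik <- function(theta, d) {
  bstar <- (d$beta_x / d$se_x^2 + theta * d$beta_y / d$se_y^2) /
    (1 / d$se_x^2 + theta^2 / d$se_y^2)
  sum(stats::dnorm(d$beta_x, bstar, d$se_x, log = TRUE) +
        stats::dnorm(d$beta_y, theta * bstar, d$se_y, log = TRUE))
}

#' Maximum-likelihood estimate
#'
#' Joint normal likelihood over the true per-SNP exposure effects and
#' the causal parameter theta; the per-SNP effects are profiled out in
#' closed form and theta maximized by one-dimensional optimization
#' started at the IVW estimate. The SE comes from the curvature of the
#' profile log-likelihood at the optimum. Under no heterogeneity or
#' pleiotropy it resembles IVW with slightly smaller SEs.
#'
#' @param set A \code{harmonized_set} with J >= 2 (J = 1 reduces to the
#'   Wald ratio).
#' @return An \code{mr_estimate}.
#' @export
max_likelihood <- function(set) {
  d <- .set_data(set)
  j <- nrow(d)
  if (j == 1) {
    est <- wald_ratio(d$beta_x, d$se_x, d$beta_y, d$se_y)
    est$method <- "max_likelihood"
    return(est)
  }
  init <- ivw(set, variance_model = "fixed")
  half <- max(1, 20 * init$se, abs(init$theta))
  opt <- stats::optimize(function(t) .profile_loglik(t, d),
                         interval = c(init$theta - half, init$theta + half),
                         maximum = TRUE, tol = 1e-10)
  theta <- opt$maximum
  h <- max(1e-6, 1e-4 * abs(theta), 1e-3 * init$se)
  d2 <- (.profile_loglik(theta + h, d) - 2 * opt$objective +
           .profile_loglik(theta - h, d)) / h^2
  if (!is.finite(d2) || d2 >= 0) {
    stop("maximum-likelihood estimation failed: non-concave profile ",
         "log-likelihood at the optimum (d2 = ", format(d2), ")",
         call. = FALSE)
  }
  .mr_estimate("max_likelihood", theta, sqrt(-1 / d2), j,
               extras = list(loglik = opt$objective))
}

#' Convert a log-odds estimate to an odds ratio with 95% CI
#'
#' @param theta Log-odds causal estimate.
#' @param se Its standard error, > 0.
#' @return List with \code{or_point} and \code{or_ci95} (low, high).
#' @export
to_odds_ratio <- function(theta, se) {
  stopifnot(se > 0)
  list(or_point = exp(theta),
       or_ci95 = c(exp(theta - 1.96 * se), exp(theta + 1.96 * se)))
}

#' Recover the p-value implied by an odds ratio and its 95% CI
#'
#' Inverts the reporting convention OR [exp(beta - 1.96 se),
#' exp(beta + 1.96 se)]: the SE is recovered from the CI width on the
#' log scale and the two-sided normal p-value returned. Used to check
#' the internal consistency of published OR/CI/p triples.
#'
#' @param or_point Odds ratio point estimate.
#' @param ci_low,ci_high 95% CI bounds, 0 < ci_low < or_point < ci_high.
#' @return Two-sided p-value.
#' @export
p_from_or_ci <- function(or_point, ci_low, ci_high) {
  if (!(ci_low > 0 && ci_low < or_point && or_point < ci_high)) {
    stop("require 0 < ci_low < or_point < ci_high", call. = FALSE)
  }
  beta <- log(or_point)
  se <- (log(ci_high) - log(ci_low)) / (2 * 1.96)
  2 * (1 - stats::pnorm(abs(beta) / se))
}

#' Run all five MR estimators on a harmonized set
#'
#' @param set A \code{harmonized_set}.
#' @param n_boot Bootstrap replicates for median/mode SEs.
#' @param seed Bootstrap seed.
#' @param variance_model IVW variance model.
#' @return Named list of \code{mr_estimate} objects (those whose
#'   minimum instrument count is not met are omitted).
#' @export
mr_all_methods <- function(set, n_boot = 1000L, seed = 1L,
                           variance_model = "multiplicative_random") {
  d <- .set_data(set)
  j <- nrow(d)
  out <- list()
  if (j >= 1) out$ivw <- ivw(set, variance_model)
  if (j >= 3) {
    out$egger <- egger(set)
    out$weighted_median <- weighted_median(set, n_boot, seed)
    out$weighted_mode <- weighted_mode(set, n_boot = n_boot, seed = seed)
  }
  if (j >= 1) out$max_likelihood <- max_likelihood(set)
  out
}
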