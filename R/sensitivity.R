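# Sensitivity diagnostics: Cochran's Q heterogeneity (IVW and Egger
# reference models), the MR-Egger intercept pleiotropy test,
# leave-one-out influence analysis, and MR-PRESSO (global residual test,
# per-SNP outlier test, distortion test).

#' Cochran's Q heterogeneity statistic
#'
#' Dispersion of the per-SNP Wald ratios about the fixed-effect IVW
#' estimate (df = J - 1) or of the outcome effects about the fitted
#' MR-Egger line (df = J - 2); chi-squared upper-tail p under
#' homogeneity.
#'
#' @param set A \code{harmonized_set}.
#' @param reference "ivw" (default) or "egger".
#' @return List with method, Q, df, pval.
#' @export
cochran_q <- function(set, reference = c("ivw", "egger")) {
  reference <- match.arg(reference)
  d <- .set_data(set)
  j <- nrow(d)
  if (reference == "ivw") {
    if (j < 2) stop("Cochran's Q (IVW) requires at least 2 instruments",
                    call. = FALSE)
    est <- ivw(set, variance_model = "fixed")
    q <- sum((d$beta_y - est$theta * d$beta_x)^2 / d$se_y^2)
    df <- j - 1L
    method <- "ivw_q"
  } else {
    if (j < 3) stop("Cochran's Q (Egger) requires at least 3 instruments",
                    call. = FALSE)
    est <- egger(set)
    q <- est$extras$rss
    df <- j - 2L
    method <- "egger_q"
  }
  list(method = method, Q = q, df = df,
       pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' @param set A \code{harmonized_set} with J >= 3.
#' @return List with alpha, se_alpha, pval.
#' @export
egger_intercept_test <- function(set) {
  est <- egger(set)
  list(alpha = est$extras$alpha, se_alpha = est$extras$se_alpha,
       pval = est$extras$pval_alpha)
}

#' Leave-one-out influence analysis
#'
#' Re-estimates the causal effect J times, each omitting one SNP; the
#' estimate is flagged stable when every leave-one-out estimate shares
#' the sign of the full estimate.
#'
#' @param set A \code{harmonized_set} with J >= 3.
#' @param method Estimator to use, currently "ivw".
#' @return List with \code{rows} (data frame: excluded_snp, theta, se,
#'   pval), \code{full_estimate} and \code{stable}.
#' @export
leave_one_out <- function(set, method = "ivw") {
  stopifnot(method == "ivw")
  d <- .set_data(set)
  j <- nrow(d)
  if (j < 3) stop("leave-one-out requires at least 3 instruments",
                  call. = FALSE)
  full <- ivw(set)
  rows <- do.call(rbind, lapply(seq_len(j), function(i) {
    sub <- harmonized_set(d$beta_x[-i], d$se_x[-i], d$beta_y[-i],
                          d$se_y[-i], d$snp_id[-i])
    est <- ivw(sub)
    data.frame(excluded_snp = d$snp_id[i], theta = est$theta,
               se = est$se, pval = est$pval, stringsAsFactors = FALSE)
  }))
  list(rows = rows, full_estimate = full,
       stable = all(sign(rows$theta) == sign(full$theta)))
}

# Leave-one-out fixed-effect IVW slopes for every SNP at once:
# theta_(-j) = (Sxy - w_j x_j y_j) / (Sxx - w_j x_j^2), weights 1/se_y^2.
.loo_ivw_theta <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' (1) Global test: observed residual sum of squares of each SNP about
#' the leave-one-out IVW prediction, weighted by 1/se_y^2, compared
#' with its parametric simulation distribution.
#' (2) Outlier test: per-SNP squared residuals against their simulated
#' counterparts, Bonferroni-adjusted across SNPs.
#' (3) Distortion test: outlier-corrected IVW versus the raw estimate,
#' with the observed distortion compared against random same-size SNP
#' removals.
#'
#' Empirical p-values use the add-one estimator so they are never
#' exactly zero.
#'
#' @param set A \code{harmonized_set} with J >= 4.
#' @param n_sim Number of parametric simulations (default 1000).
#' @param outlier_alpha Threshold on the Bonferroni-adjusted per-SNP
#'   p-value (default 0.05).
#' @param seed Simulation seed.
#' @return Object of class \code{presso_result}: list with rss_obs,
#'   global_pval, per_snp_pvals, outlier_ids, theta_raw,
#'   theta_corrected, distortion_pct, distortion_pval, n_sim, seed.
#' @export
mr_presso <- function(set, n_sim = 1000L, outlier_alpha = 0.05, seed = 1L) {
  d <- .set_data(set)
  j <- nrow(d)
  if (j < 4) stop("MR-PRESSO requires at least 4 instruments", call. = FALSE)
  # canonical snp_id order so results are invariant to input row order
  input_ids <- d$snp_id
  d <- d[order(d$snp_id), , drop = FALSE]
  set.seed(seed)
  w <- 1 / d$se_y^2

  theta_loo <- .loo_ivw_theta(d$beta_x, d$beta_y, w)
  resid_obs <- d$beta_y - theta_loo * d$beta_x
  d2_obs <- resid_obs^2
  rss_obs <- sum(w * d2_obs)

  # Parametric simulations under the no-pleiotropy model: each SNP's
  # expected outcome effect is its leave-one-out IVW prediction.
  bx_sim <- matrix(stats::rnorm(j * n_sim, d$beta_x, d$se_x), nrow = j)
  by_sim <- matrix(stats::rnorm(j * n_sim, theta_loo * d$beta_x, d$se_y),
                   nrow = j)
  sxy <- colSums(w * bx_sim * by_sim)
  sxx <- colSums(w * bx_sim^2)
  theta_loo_sim <- (rep(sxy, each = j) - w * bx_sim * by_sim) /
    (rep(sxx, each = j) - w * bx_sim^2)
  dim(theta_loo_sim) <- c(j, n_sim)
  resid_sim <- by_sim - theta_loo_sim * bx_sim
  d2_sim <- resid_sim^2
  rss_sim <- colSums(w * d2_sim)

  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  p_raw <- (1 + rowSums(d2_sim >= d2_obs)) / (n_sim + 1)
  per_snp_pvals <- stats::setNames(pmin(1, p_raw * j), d$snp_id)
  outlier_idx <- which(per_snp_pvals < outlier_alpha)
  outlier_ids <- d$snp_id[outlier_idx]

  theta_raw <- .ivw_fixed_theta(d$beta_x, d$beta_y, w)
  theta_corrected <- NA_real_
  distortion_pct <- NA_real_
  distortion_pval <- NA_real_
  n_keep <- j - length(outlier_idx)
  if (length(outlier_idx) > 0 && n_keep >= 2) {
    keep <- setdiff(seq_len(j), outlier_idx)
    theta_corrected <- .ivw_fixed_theta(d$beta_x[keep], d$beta_y[keep],
                                        w[keep])
    distortion_pct <- 100 * (theta_raw - theta_corrected) /
      abs(theta_corrected)
    obs_abs <- abs(distortion_pct)
    dist_sim <- vapply(seq_len(n_sim), function(s) {
      drop_idx <- sample.int(j, length(outlier_idx))
      kp <- setdiff(seq_len(j), drop_idx)
      tc <- .ivw_fixed_theta(d$beta_x[kp], d$beta_y[kp], w[kp])
      100 * (theta_raw - tc) / abs(tc)
    }, numeric(1))
    distortion_pval <- (1 + sum(abs(dist_sim) >= obs_abs)) / (n_sim + 1)
  } else if (length(outlier_idx) > 0 && n_keep < 2) {
    warning("all (or nearly all) SNPs flagged as outliers; ",
            "outlier-corrected estimate skipped", call. = FALSE)
  }

  per_snp_pvals <- per_snp_pvals[input_ids]
  structure(list(rss_obs = rss_obs, global_pval = global_pval,
                 per_snp_pvals = per_snp_pvals, outlier_ids = outlier_ids,
                 theta_raw = theta_raw, theta_corrected = theta_corrected,
                 distortion_pct = distortion_pct,
                 distortion_pval = distortion_pval,
                 n_sim = n_sim, seed = seed),
            class = "presso_result")
}

.ivw_fixed_theta <- function(bx, by, w) {
  sum(w * bx * by) / sum(w * bx^2)
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS = %.3f, global p = %.4g, %d outlier(s)\n",
              x$rss_obs, x$global_pval, length(x$outlier_ids)))
  if (length(x$outlier_ids) > 0 && !is.na(x$theta_corrected)) {
    cat(sprintf("  raw theta %.4f -> corrected %.4f (distortion %.1f%%, p = %.3g)\n",
                x$theta_raw, x$theta_corrected, x$distortion_pct,
                x$distortion_pval))
  }
  invisible(x)
}

#' Run the full sensitivity suite on a harmonized set
#'
#' @param set A \code{harmonized_set}.
#' @param n_sim MR-PRESSO simulation count.
#' @param seed Seed for MR-PRESSO.
#' @return List with q_ivw, q_egger, egger_intercept, loo, presso
#'   (components NULL when the set is too small for them).
#' @export
sensitivity_suite <- function(set, n_sim = 1000L, seed = 1L) {
  j <- nrow(set$data)
  list(
    q_ivw = if (j >= 2) cochran_q(set, "ivw") else NULL,
    q_egger = if (j >= 3) cochran_q(set, "egger") else NULL,
    egger_intercept = if (j >= 3) egger_intercept_test(set) else NULL,
    loo = if (j >= 3) leave_one_out(set) else NULL,
    presso = if (j >= 4) mr_presso(set, n_sim = n_sim, seed = seed) else NULL
  )
}
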