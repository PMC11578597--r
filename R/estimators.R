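## All estimators operate on harmonized instruments and work with the
## per-instrument Wald ratios b_j = beta_outcome_j / beta_exposure_j and
## their first-order (delta-method) standard errors se_outcome_j /
## |beta_exposure_j|; inverse-variance weights are w_j = 1 / ratio_se_j^2.
## Records are put into a canonical order by variant_id on entry so that
## bootstrap draws (and therefore standard errors) are bit-reproducible
## regardless of the row order of the input.

Z95 <- stats::qnorm(0.975)

ratio_estimates <- function(records) {
  records <- as_instruments(records)
  if (nrow(records) == 0) estimation_error("no instruments supplied")
  records <- records[order(records$variant_id), , drop = FALSE]
  if (any(records$beta_exposure == 0))
    estimation_error("zero exposure effect for: %s",
                     paste(records$variant_id[records$beta_exposure == 0],
                           collapse = ", "))
  if (any(records$se_outcome <= 0) || any(records$se_exposure <= 0))
    estimation_error("nonpositive standard error in instrument table")
  list(
    variant_id = records$variant_id,
    b  = records$beta_outcome / records$beta_exposure,
    se = records$se_outcome / abs(records$beta_exposure),
    f  = (records$beta_exposure / records$se_exposure)^2
  )
}

new_mr_estimate <- function(method, beta, se, n_instruments, f_statistic,
                            heterogeneity_q = NA_real_) {
  z <- beta / se
  structure(list(
    method = method,
    beta = beta,
    se = se,
    ci_low  = beta - Z95 * se,
    ci_high = beta + Z95 * se,
    pval = 2 * stats::pnorm(-abs(z)),
    n_instruments = as.integer(n_instruments),
    f_statistic = f_statistic,
    heterogeneity_q = heterogeneity_q
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4g (se %.4g, 95%% CI %.4g to %.4g), p = %.3g, J = %d, mean F = %.1f\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pval,
              x$n_instruments, x$f_statistic))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_instruments = x$n_instruments,
             beta = x$beta, se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
             pval = x$pval, f_statistic = x$f_statistic,
             heterogeneity_q = x$heterogeneity_q, stringsAsFactors = FALSE)
}

#' Wald ratio estimate from a single instrument
#'
#' The causal effect is the ratio of the outcome to the exposure
#' association, `beta_outcome / beta_exposure`, with first-order
#' delta-method standard error `se_outcome / |beta_exposure|`.
#'
#' @param record A one-row harmonized instrument table.
#' @return An `mr_estimate` (method, beta, se, 95% CI, normal p-value,
#'   instrument count, mean F-statistic).
#' @export
mr_wald_ratio <- function(record) {
  r <- ratio_estimates(record)
  if (length(r$b) != 1)
    estimation_error("wald_ratio takes exactly one instrument")
  new_mr_estimate("wald_ratio", r$b, r$se, 1L, r$f)
}

#' Inverse-variance weighted (IVW) estimate
#'
#' Combines per-instrument Wald ratios with inverse-variance weights
#' \eqn{w_j = 1/se_j^2}: \eqn{\hat\theta = \sum w_j b_j / \sum w_j}. The
#' fixed-effect standard error is \eqn{\sqrt{1/\sum w_j}}; under the default
#' multiplicative random-effects model it is inflated by
#' \eqn{\sqrt{Q/(J-1)}} whenever Cochran's
#' \eqn{Q = \sum w_j (b_j - \hat\theta)^2} exceeds its degrees of freedom,
#' so heterogeneity widens the interval but never narrows it. A single
#' instrument delegates to the Wald ratio.
#'
#' @param records Harmonized instrument table with at least one row.
#' @param mode `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_estimate`; `heterogeneity_q` carries Cochran's Q when
#'   two or more instruments are used.
#' @export
mr_ivw <- function(records, mode = c("multiplicative_random", "fixed")) {
  mode <- match.arg(mode)
  r <- ratio_estimates(records)
  J <- length(r$b)
  if (J == 1) {
    est <- new_mr_estimate("ivw", r$b, r$se, 1L, r$f)
    return(est)
  }
  w <- 1 / r$se^2
  beta <- sum(w * r$b) / sum(w)
  q <- sum(w * (r$b - beta)^2)
  se <- sqrt(1 / sum(w))
  if (mode == "multiplicative_random") se <- se * sqrt(max(1, q / (J - 1)))
  new_mr_estimate("ivw", beta, se, J, mean(r$f), heterogeneity_q = q)
}

## Parametric bootstrap shared by the weighted median and mode: resample
## each ratio from Normal(b_j, ratio_se_j), keep the weights, recompute the
## point estimate, and take the standard deviation across replicates.
bootstrap_se <- function(b, se, n_boot, seed, point_fun) {
  J <- length(b)
  reps <- with_seed(seed, {
    draws <- matrix(stats::rnorm(n_boot * J, mean = rep(b, each = n_boot),
                                 sd = rep(se, each = n_boot)),
                    nrow = n_boot, ncol = J)
    vapply(seq_len(n_boot), function(i) point_fun(draws[i, ]), 0)
  })
  stats::sd(reps)
}

#' Weighted median estimate
#'
#' The weighted median of the per-instrument Wald ratios: ratios are sorted
#' ascending, weights `w_j = 1/se_j^2` are standardized, and the estimate
#' linearly interpolates the sorted ratios at cumulative weight one half.
#' It is consistent when at least 50% of the total weight comes from valid
#' instruments. The standard error comes from a seeded parametric
#' bootstrap: each ratio is resampled from `Normal(b_j, se_j)`, the
#' weighted median recomputed, and the standard deviation over replicates
#' taken.
#'
#' @param records Harmonized instrument table.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Bootstrap seed.
#' @param min_instruments Minimum number of instruments (default 3); below
#'   this an estimation error advises the Wald ratio or IVW instead.
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(records, n_boot = 1000, seed = 1,
                               min_instruments = 3) {
  r <- ratio_estimates(records)
  J <- length(r$b)
  if (J < min_instruments)
    estimation_error("weighted median needs >= %d instruments (got %d); use IVW or the Wald ratio",
                     min_instruments, J)
  w <- 1 / r$se^2
  beta <- weighted_median_point(r$b, w)
  se <- bootstrap_se(r$b, r$se, n_boot, seed,
                     function(bs) weighted_median_point(bs, w))
  new_mr_estimate("weighted_median", beta, se, J, mean(r$f))
}

#' Bandwidth for the weighted mode estimator
#'
#' Modified Silverman rule on the weighted ratio distribution:
#' \eqn{h = \phi \cdot 0.9 \cdot \min(s_w, MAD_w/0.6745) \cdot J^{-1/5}},
#' where \eqn{s_w} is the weighted standard deviation of the ratios,
#' \eqn{MAD_w} the weighted median absolute deviation about the weighted
#' median, and \eqn{\phi} the tuning factor `bandwidth_factor`.
#'
#' @param b Numeric vector of ratio estimates.
#' @param w Positive weights.
#' @param bandwidth_factor Multiplier on the rule-of-thumb bandwidth.
#' @return A non-negative bandwidth (zero when the weighted spread is zero;
#'   [mr_weighted_mode()] floors it at a small epsilon).
#' @export
mode_bandwidth <- function(b, w, bandwidth_factor = 1) {
  if (bandwidth_factor <= 0) parameter_error("bandwidth_factor must be positive")
  s <- w / sum(w)
  mu <- sum(s * b)
  wsd <- sqrt(sum(s * (b - mu)^2))
  wmad <- weighted_median_point(abs(b - weighted_median_point(b, w)), w)
  bandwidth_factor * 0.9 * min(wsd, wmad / 0.6745) * length(b)^(-1 / 5)
}

kde_mode <- function(b, w, h, n_grid = 512) {
  grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = n_grid)
  dens <- outer(grid, b, function(g, bb) stats::dnorm(g - bb, sd = h)) %*% w
  ## which.max takes the first maximum; the grid is ascending, so exact
  ## density ties resolve toward the lower mode.
  grid[which.max(dens)]
}

#' Weighted mode estimate
#'
#' The mode of the inverse-variance-weighted kernel density of the
#' per-instrument Wald ratios: a Gaussian kernel of bandwidth
#' [mode_bandwidth()] is placed at each ratio with mass proportional to
#' `w_j = 1/se_j^2`, the density is evaluated on a grid of `n_grid` points
#' spanning `[min(b) - 3h, max(b) + 3h]`, and the estimate is the grid
#' argmax (ties resolve toward the lower mode). Consistent when the largest
#' weight cluster of ratios comes from valid instruments. Standard error by
#' the same parametric bootstrap as the weighted median, with the bandwidth
#' recomputed for each replicate.
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor Multiplier on the modified Silverman bandwidth
#'   (default 1).
#' @param n_grid Number of density grid points (default 512, minimum 512).
#' @return An `mr_estimate`.
#' @export
mr_weighted_mode <- function(records, bandwidth_factor = 1, n_boot = 1000,
                             seed = 1, min_instruments = 3, n_grid = 512) {
  if (n_grid < 512) parameter_error("n_grid must be at least 512")
  r <- ratio_estimates(records)
  J <- length(r$b)
  if (J < min_instruments)
    estimation_error("weighted mode needs >= %d instruments (got %d); use IVW or the Wald ratio",
                     min_instruments, J)
  w <- 1 / r$se^2
  h <- mode_bandwidth(r$b, w, bandwidth_factor)
  if (!is.finite(h) || h <= 0) {
    warning("zero weighted-mode bandwidth; flooring at 1e-8")
    h <- 1e-8
  }
  beta <- kde_mode(r$b, w, h, n_grid)
  se <- bootstrap_se(r$b, r$se, n_boot, seed, function(bs) {
    hb <- mode_bandwidth(bs, w, bandwidth_factor)
    if (!is.finite(hb) || hb <= 0) hb <- 1e-8
    kde_mode(bs, w, hb, n_grid)
  })
  new_mr_estimate("weighted_mode", beta, se, J, mean(r$f))
}

#' Instrument-strength F-statistic of a set of instruments
#'
#' The mean per-instrument F, \eqn{\bar F = J^{-1} \sum_j
#' (\hat\beta_{exp,j} / SE_{exp,j})^2}, used to flag groups at risk of weak
#' instrument bias (values below ~10 are conventionally considered weak).
#'
#' @param records Harmonized instrument table with at least one row.
#' @return A non-negative scalar.
#' @export
mr_f_statistic <- function(records) {
  records <- as_instruments(records)
  if (nrow(records) == 0) estimation_error("no instruments supplied")
  mean((records$beta_exposure / records$se_exposure)^2)
}
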