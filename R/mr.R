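# Two-sample Mendelian randomization estimators for protein exposures on
# heart-failure outcomes: Wald ratio, inverse-variance weighting
# generalized to correlated instruments, MR-Egger, and the weighted
# median, all reported on the log-odds scale per 1-SD higher protein with
# OR and 95% CI. Fixed-effect IVW is the primary estimator; Cochran's Q
# is reported as the heterogeneity diagnostic.

mr_result_row <- function(protein_id, outcome, method, theta, se_theta,
                          n_instruments, egger_intercept = NA_real_,
                          egger_intercept_p = NA_real_,
                          cochran_q = NA_real_, q_df = NA_integer_) {
  tibble(
    protein_id = protein_id, outcome = outcome, method = method,
    theta = theta, se_theta = se_theta,
    or_ = exp(theta),
    ci_low = exp(theta - 1.96 * se_theta),
    ci_high = exp(theta + 1.96 * se_theta),
    pvalue = {
      p <- suppressWarnings(pnorm2(theta, se_theta))
      p[is.na(theta) | is.na(se_theta)] <- NA_real_
      p
    },
    n_instruments = as.integer(n_instruments),
    egger_intercept = egger_intercept,
    egger_intercept_p = egger_intercept_p,
    cochran_q = cochran_q, q_df = as.integer(q_df)
  )
}

#' Wald ratio estimate for a single instrument
#'
#' `theta = by / bx` with first-order delta-method standard error
#' `se = sy / |bx|`; the second-order form adds the exposure-uncertainty
#' term `by^2 sx^2 / bx^4`.
#'
#' @param bx,sx Exposure effect and SE.
#' @param by,sy Outcome effect and SE.
#' @param second_order Use the second-order delta SE? Default `FALSE`.
#' @return One-row tibble with `theta`, `se`.
#' @export
mr_wald <- function(bx, sx, by, sy, second_order = FALSE) {
  if (bx == 0) {
    abort("Wald ratio undefined: exposure effect is zero.",
          class = "proteomr_undefined_ratio_error")
  }
  theta <- by / bx
  se <- if (second_order) {
    sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  } else {
    sy / abs(bx)
  }
  tibble(theta = theta, se = se)
}

ivw_core <- function(bx, by, sy, R) {
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    # singular or indefinite LD (e.g. perfectly duplicated instruments):
    # ridge to |min eigenvalue| + 1e-8, rescaled to unit diagonal
    R <- stats::cov2cor(R + diag(abs(min(ev)) + 1e-8, nrow(R)))
  }
  Omega <- diag(sy, nrow = length(sy)) %*% R %*% diag(sy, nrow = length(sy))
  Oi <- tryCatch(solve(Omega), error = function(e) {
    abort(sprintf(
      "Singular instrument covariance (condition number %.3g).",
      kappa(Omega)), class = "proteomr_numerical_error")
  })
  denom <- drop(t(bx) %*% Oi %*% bx)
  theta <- drop(t(bx) %*% Oi %*% by) / denom
  se <- sqrt(1 / denom)
  resid <- by - theta * bx
  q <- drop(t(resid) %*% Oi %*% resid)
  list(theta = theta, se = se, q = q)
}

#' Correlated-instrument inverse-variance-weighted MR
#'
#' Generalized (GLS) IVW with instrument covariance
#' `Omega = diag(sy) R diag(sy)`:
#' `theta = (bx' Omega^-1 bx)^-1 bx' Omega^-1 by`,
#' `se = sqrt((bx' Omega^-1 bx)^-1)`. With `R = I` this is textbook
#' fixed-effect IVW; with one instrument it reduces to the Wald ratio.
#' Cochran's Q = `(by - theta bx)' Omega^-1 (by - theta bx)` on `n - 1`
#' degrees of freedom. A non-invertible `Omega` is ridge-repaired before
#' the numerical error is raised.
#'
#' @param set An `instrument_set` from [build_instrument_set()].
#' @param outcome Outcome label carried into the result.
#' @return One-row MR-result tibble (see [run_mr()]).
#' @export
mr_ivw <- function(set, outcome = "dhfa") {
  d <- set$data
  fit <- ivw_core(d$bx, d$by, d$sy, set$R)
  mr_result_row(set$protein_id, outcome, "ivw", fit$theta, fit$se,
                nrow(d), cochran_q = fit$q, q_df = nrow(d) - 1L)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with an intercept,
#' weights `1/sy^2`, after orienting all exposure effects non-negative
#' (flipping the paired outcome effect with them). The intercept and its
#' p-value diagnose directional pleiotropy; the slope is the
#' pleiotropy-adjusted causal estimate. Requires at least 3 instruments;
#' with fewer, an all-`NA` "not applicable" row is returned.
#'
#' @inheritParams mr_ivw
#' @return One-row MR-result tibble.
#' @export
mr_egger <- function(set, outcome = "dhfa") {
  d <- set$data
  n <- nrow(d)
  if (n < 3L) {
    return(mr_result_row(set$protein_id, outcome, "egger",
                         NA_real_, NA_real_, n))
  }
  flip <- sign(d$bx)
  flip[flip == 0] <- 1
  bx <- d$bx * flip
  by <- d$by * flip
  w <- 1 / d$sy^2
  fit <- lm(by ~ bx, weights = w)
  cf <- summary(fit)$coefficients
  mr_result_row(set$protein_id, outcome, "egger",
                theta = cf["bx", "Estimate"], se_theta = cf["bx", "Std. Error"],
                n_instruments = n,
                egger_intercept = cf["(Intercept)", "Estimate"],
                egger_intercept_p = pnorm2(cf["(Intercept)", "Estimate"],
                                           cf["(Intercept)", "Std. Error"]))
}

#' Weighted-median MR
#'
#' Per-instrument Wald ratios are sorted; with weights proportional to the
#' inverse ratio variances, the estimate is the value where the cumulative
#' (midpoint-adjusted) weight crosses one half, linearly interpolated.
#' Consistent when instruments carrying at least half the weight are
#' valid. The SE comes from a parametric bootstrap: `bx` and `by` are
#' resampled from normal distributions centered on their estimates with
#' their SEs, under a fixed seed, so repeated calls are identical.
#'
#' @inheritParams mr_ivw
#' @param n_boot Bootstrap resamples for the SE. Default 1000.
#' @param seed Bootstrap seed. Default 1.
#' @return One-row MR-result tibble.
#' @export
mr_weighted_median <- function(set, outcome = "dhfa", n_boot = 1000L,
                               seed = 1L) {
  d <- set$data
  n <- nrow(d)
  if (n < 3L) {
    return(mr_result_row(set$protein_id, outcome, "weighted_median",
                         NA_real_, NA_real_, n))
  }
  est <- weighted_median_estimate(d$bx, d$by, d$sy)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx_b <- rnorm(n, d$bx, d$sx)
      by_b <- rnorm(n, d$by, d$sy)
      weighted_median_estimate(bx_b, by_b, d$sy)
    }, numeric(1))
  })
  mr_result_row(set$protein_id, outcome, "weighted_median",
                est, sd(boots), n)
}

# Interpolated weighted median of the per-instrument ratio estimates.
weighted_median_estimate <- function(bx, by, sy) {
  ok <- bx != 0
  ratio <- by[ok] / bx[ok]
  w <- (abs(bx[ok]) / sy[ok])^2   # 1 / se_ratio^2 with se_ratio = sy/|bx|
  ord <- order(ratio)
  ratio <- ratio[ord]
  w <- w[ord] / sum(w[ord])
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(ratio[1])
  if (cum[length(cum)] <= 0.5) return(ratio[length(cum)])
  stats::approx(cum, ratio, xout = 0.5)$y
}

#' Run all applicable MR methods on an instrument set
#'
#' Applies the Wald ratio (single instrument), correlated-instrument IVW
#' (always), and MR-Egger plus weighted median (3+ instruments). Reported
#' on the log-odds scale with `OR = exp(theta)` and
#' `95% CI = exp(theta +/- 1.96 se)`.
#'
#' @inheritParams mr_ivw
#' @param n_boot,seed Passed to [mr_weighted_median()].
#' @return Tibble with one row per method: `protein_id`, `outcome`,
#'   `method`, `theta`, `se_theta`, `or_`, `ci_low`, `ci_high`, `pvalue`,
#'   `n_instruments`, `egger_intercept`, `egger_intercept_p`, `cochran_q`,
#'   `q_df`.
#' @export
run_mr <- function(set, outcome = "dhfa", n_boot = 1000L, seed = 1L) {
  d <- set$data
  rows <- list()
  if (nrow(d) == 1L) {
    w <- mr_wald(d$bx, d$sx, d$by, d$sy)
    rows$wald <- mr_result_row(set$protein_id, outcome, "wald",
                               w$theta, w$se, 1L)
  }
  rows$ivw <- mr_ivw(set, outcome)
  rows$egger <- mr_egger(set, outcome)
  rows$wm <- mr_weighted_median(set, outcome, n_boot = n_boot, seed = seed)
  bind_rows(rows)
}

#' Forest-plot export for an instrument set and its pooled estimates
#'
#' One row per instrument (Wald ratio and CI) plus one row per pooled
#' method, ready for plotting.
#'
#' @param set An `instrument_set`.
#' @param mr_results Output of [run_mr()] for the same set.
#' @return Tibble with `label`, `kind`, `theta`, `ci_low`, `ci_high` (on
#'   the log-odds scale).
#' @export
forest_table <- function(set, mr_results) {
  d <- set$data
  per <- tibble(
    label = d$variant_id, kind = "instrument",
    theta = d$by / d$bx,
    se = d$sy / abs(d$bx)
  )
  per <- mutate(per, ci_low = .data$theta - 1.96 * .data$se,
                ci_high = .data$theta + 1.96 * .data$se)
  pooled <- tibble(
    label = mr_results$method, kind = "pooled",
    theta = mr_results$theta, se = mr_results$se_theta,
    ci_low = log(mr_results$ci_low), ci_high = log(mr_results$ci_high)
  )
  bind_rows(select(per, -"se"), select(pooled, -"se"))
}

#' Forest plot of per-instrument and pooled MR estimates
#'
#' @inheritParams forest_table
#' @return A ggplot object.
#' @export
plot_forest <- function(set, mr_results) {
  ft <- forest_table(set, mr_results)
  ft$label <- factor(ft$label, levels = rev(ft$label))
  ggplot2::ggplot(ft, ggplot2::aes(x = .data$theta, y = .data$label,
                                   colour = .data$kind)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "log OR per SD protein", y = NULL) +
    ggplot2::theme_minimal()
}
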