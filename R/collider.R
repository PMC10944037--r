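# Index-event (collider) bias correction for case-only outcome GWAS.
#
# Genetic associations with progression measured among cases are
# conditioned on disease liability; variants that raise incidence acquire
# spurious progression effects. The correction fits a two-component
# mixture to (incidence effect, outcome effect) pairs of LD-independent
# variants: an "incidence-only" cluster concentrated on the line
# b_out = slope * b_inc (whose slope IS the collider artefact plus any
# liability-mediated effect) and an unconstrained cluster for variants
# with direct progression effects. The fitted slope is then subtracted
# from every variant's outcome effect.

#' Fit the cluster-then-slope collider-bias correction factor
#'
#' Variants with incidence p-value below `incidence_p_threshold` are
#' modelled as a two-component mixture on the conditional distribution of
#' the outcome effect given the incidence effect: component 1
#' (incidence-only variants) has `b_out ~ N(slope * b_inc, se_out^2 + tau^2)`;
#' component 2 (variants with direct outcome effects) has
#' `b_out ~ N(0, sigma2^2)` independent of `b_inc`. Expectation-maximization
#' with `n_restarts` seeded restarts maximizes the mixture likelihood; the
#' best-likelihood fit is kept, so the result is deterministic given
#' `seed`. The slope is corrected for regression dilution caused by
#' sampling noise in the incidence effects (attenuation factor
#' `var_true / (var_true + mean se_inc^2)` estimated from the cluster-1
#' weighted moments).
#'
#' @param pairs Tibble with columns `variant_id`, `b_inc`, `se_inc`,
#'   `b_out`, `se_out`, and optionally `p_inc` (computed from
#'   `b_inc/se_inc` when absent). Variants must be LD-independent (clump
#'   beforehand).
#' @param incidence_p_threshold Incidence p-value cutoff defining the
#'   clustering subset. Default 1e-3.
#' @param seed Integer seed driving the restart schedule.
#' @param n_restarts Number of EM restarts. Default 10.
#' @param tol Convergence tolerance on the log-likelihood. Default 1e-8.
#' @param max_iter Maximum EM iterations per restart. Default 5000.
#' @param dilution_correction Apply the regression-dilution correction?
#'   Default `TRUE`.
#' @return An object of class `slope_fit`: a list with `slope_b`,
#'   `se_slope`, `mixing_proportion` (cluster-1 weight),
#'   `cluster_assignments` (tibble of per-variant cluster-1 posterior
#'   probabilities), `n_variants_used`, `loglik`, `converged`.
#' @export
fit_collider_slope <- function(pairs, incidence_p_threshold = 1e-3,
                               seed = 1L, n_restarts = 10L, tol = 1e-8,
                               max_iter = 5000L, dilution_correction = TRUE) {
  pairs <- as_tibble(pairs)
  need <- c("variant_id", "b_inc", "se_inc", "b_out", "se_out")
  missing <- setdiff(need, names(pairs))
  if (length(missing) > 0L) {
    abort(sprintf("`pairs` is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "proteomr_config_error")
  }
  if (any(pairs$se_inc <= 0 | pairs$se_out <= 0, na.rm = TRUE)) {
    abort("Standard errors must be positive.",
          class = "proteomr_config_error")
  }
  if (!"p_inc" %in% names(pairs)) {
    pairs$p_inc <- pnorm2(pairs$b_inc, pairs$se_inc)
  }
  sub <- filter(pairs, .data$p_inc < incidence_p_threshold,
                stats::complete.cases(.data$b_inc, .data$b_out))
  if (nrow(sub) < 30L) {
    abort(sprintf(
      "Only %d variant(s) pass the incidence p-value threshold; >= 30 required.",
      nrow(sub)), class = "proteomr_insufficient_instruments_error")
  }
  bx <- sub$b_inc; by <- sub$b_out
  sy2 <- sub$se_out^2
  n <- length(bx)

  em_once <- function(slope0) {
    slope <- slope0
    tau2 <- var(by) / 4 + 1e-12
    sig2 <- var(by) + 1e-12
    pi1 <- 0.7
    ll_old <- -Inf
    converged <- FALSE
    gamma <- rep(pi1, n)
    par_old <- c(slope, tau2, sig2, pi1)
    for (iter in seq_len(max_iter)) {
      v1 <- sy2 + tau2
      d1 <- dnorm(by, mean = slope * bx, sd = sqrt(v1), log = TRUE) + log(pi1)
      d2 <- dnorm(by, mean = 0, sd = sqrt(sig2), log = TRUE) + log(1 - pi1)
      m <- pmax(d1, d2)
      ll <- sum(m + log(exp(d1 - m) + exp(d2 - m)))
      gamma <- 1 / (1 + exp(d2 - d1))
      # M-step
      # the incidence-only cluster is the majority component by
      # assumption; constraining its weight keeps the line identifiable
      pi1 <- min(max(mean(gamma), 0.5), 1 - 1e-6)
      w <- gamma / v1
      sxx <- sum(w * bx^2)
      if (sxx <= 0) break
      slope <- sum(w * bx * by) / sxx
      resid2 <- (by - slope * bx)^2
      tau2 <- max(sum(gamma * (resid2 - sy2)) / max(sum(gamma), 1e-12), 1e-12)
      # the direct-effect component must stay diffuse relative to the
      # line cluster (at least 2x its SD): otherwise it swallows the
      # middle of a single-cluster distribution and biases the slope
      # away from zero
      sig2 <- max(sum((1 - gamma) * by^2) / max(sum(1 - gamma), 1e-12),
                  4 * (tau2 + mean(sy2)), 1e-12)
      # converged when the likelihood stalls or the parameters stop moving
      # (the latter catches the slow boundary crawl when one component
      # empties out)
      par_new <- c(slope, tau2, sig2, pi1)
      par_stable <- iter > 1L &&
        max(abs(par_new - par_old) / (abs(par_old) + 1e-12)) < 1e-8
      par_old <- par_new
      if (is.finite(ll) &&
          (abs(ll - ll_old) < tol * (1 + abs(ll)) || par_stable)) {
        converged <- TRUE
        ll_old <- ll
        break
      }
      ll_old <- ll
    }
    list(slope = slope, tau2 = tau2, sig2 = sig2, pi1 = pi1,
         gamma = gamma, loglik = ll_old, converged = converged)
  }

  # One-component reference fit: iteratively reweighted line-only model.
  single_component_fit <- function(bx, by, sy2) {
    tau2 <- max(var(by) / 2, 1e-12)
    slope <- 0
    for (it in 1:200) {
      w <- 1 / (sy2 + tau2)
      slope_new <- sum(w * bx * by) / sum(w * bx^2)
      tau2_new <- max(mean((by - slope_new * bx)^2 - sy2), 1e-12)
      done <- abs(slope_new - slope) < 1e-12 && abs(tau2_new - tau2) < 1e-12
      slope <- slope_new
      tau2 <- tau2_new
      if (done) break
    }
    ll <- sum(dnorm(by, slope * bx, sqrt(sy2 + tau2), log = TRUE))
    list(slope = slope, tau2 = tau2, sig2 = NA_real_,
         pi1 = 1 - 1e-6, gamma = rep(1, length(bx)), loglik = ll,
         converged = TRUE)
  }

  # Restart schedule: first init from the overall weighted regression,
  # the rest from seeded random slopes spanning the observed ratio range.
  base_slope <- sum(bx * by / sy2) / sum(bx^2 / sy2)
  inits <- withr::with_seed(seed, {
    spread <- stats::mad(by / bx, constant = 1) + abs(base_slope) + 0.1
    c(base_slope, base_slope + stats::rnorm(n_restarts - 1L, 0, spread))
  })
  fits <- map(inits, em_once)
  oks <- keep(fits, ~ .x$converged && is.finite(.x$loglik))
  if (length(oks) == 0L) {
    abort("EM failed to converge in all restarts.",
          class = "proteomr_convergence_error")
  }
  best <- oks[[which.max(map_dbl(oks, "loglik"))]]

  # Guard against spurious splitting when the data are a single cluster
  # (no direct-effect variants): compare by BIC with the one-component
  # fit (every variant on the line; slope + tau2 = 2 parameters vs 4).
  single <- single_component_fit(bx, by, sy2)
  if (2 * single$loglik - 2 * log(n) >= 2 * best$loglik - 4 * log(n)) {
    best <- single
  }

  slope <- best$slope
  gamma <- best$gamma
  v1 <- sy2 + best$tau2
  w <- gamma / v1
  se_slope <- sqrt(1 / sum(w * bx^2))
  attenuation <- 1
  if (dilution_correction) {
    wsum <- sum(gamma)
    var_obs <- sum(gamma * bx^2) / wsum
    mean_sx2 <- sum(gamma * sub$se_inc^2) / wsum
    var_true <- max(var_obs - mean_sx2, 0.05 * var_obs)
    attenuation <- var_true / (var_true + mean_sx2)
    slope <- slope / attenuation
    se_slope <- se_slope / attenuation
  }

  structure(list(
    slope_b = slope,
    se_slope = se_slope,
    mixing_proportion = best$pi1,
    cluster_assignments = tibble(variant_id = sub$variant_id,
                                 prob_cluster1 = gamma),
    n_variants_used = n,
    attenuation = attenuation,
    loglik = best$loglik,
    converged = best$converged,
    incidence_p_threshold = incidence_p_threshold,
    seed = seed
  ), class = "slope_fit")
}

#' Construct a slope_fit manually
#'
#' Useful for applying an externally estimated correction factor (or a
#' fixed slope in tests) with [adjust_collider_bias()].
#' @param slope_b Correction slope.
#' @param se_slope Its standard error (0 for a fixed, known slope).
#' @return A `slope_fit` object.
#' @export
new_slope_fit <- function(slope_b, se_slope = 0) {
  structure(list(slope_b = slope_b, se_slope = se_slope,
                 mixing_proportion = NA_real_,
                 cluster_assignments = tibble(variant_id = character(),
                                              prob_cluster1 = numeric()),
                 n_variants_used = 0L, attenuation = 1,
                 loglik = NA_real_, converged = NA,
                 incidence_p_threshold = NA_real_, seed = NA_integer_),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat("Collider-bias slope fit\n")
  cat(sprintf("  slope: %.4f (SE %.4f)\n", x$slope_b, x$se_slope))
  cat(sprintf("  cluster-1 (incidence-only) weight: %.3f over %d variants\n",
              x$mixing_proportion, x$n_variants_used))
  invisible(x)
}

#' @export
tidy.slope_fit <- function(x, ...) {
  tibble(term = "collider_slope", estimate = x$slope_b,
         std.error = x$se_slope,
         statistic = x$slope_b / x$se_slope,
         p.value = pnorm2(x$slope_b, x$se_slope))
}

#' @export
glance.slope_fit <- function(x, ...) {
  tibble(slope_b = x$slope_b, se_slope = x$se_slope,
         mixing_proportion = x$mixing_proportion,
         n_variants_used = x$n_variants_used,
         logLik = x$loglik, converged = x$converged)
}

#' @export
augment.slope_fit <- function(x, ...) {
  x$cluster_assignments
}

#' Apply a fitted slope correction to outcome summary statistics
#'
#' For every outcome variant with a harmonizable incidence record,
#' `beta_adj = b_out - slope * b_inc` and
#' `se_adj = sqrt(se_out^2 + slope^2 se_inc^2 + b_inc^2 se_slope^2)`
#' (the third term propagates slope uncertainty); the p-value is recomputed
#' from `beta_adj / se_adj` under a normal approximation. Outcome variants
#' with no matching incidence record pass through unmodified with
#' `adjusted = FALSE`.
#'
#' @param outcome Tibble of outcome association records.
#' @param incidence Tibble of incidence (disease-risk) association records.
#' @param fit A `slope_fit` from [fit_collider_slope()].
#' @param palindromic_eaf_band Passed to [harmonize_sumstats()] when
#'   aligning incidence records to the outcome's effect alleles.
#' @return The outcome tibble with `beta`, `se`, `pvalue` replaced by their
#'   adjusted values where possible, plus an `adjusted` logical column.
#' @export
adjust_collider_bias <- function(outcome, incidence, fit,
                                 palindromic_eaf_band = 0.08) {
  if (!inherits(fit, "slope_fit")) {
    abort("`fit` must be a slope_fit object.", class = "proteomr_config_error")
  }
  h <- harmonize_sumstats(outcome, incidence,
                          palindromic_eaf_band = palindromic_eaf_band)
  h <- filter(h, .data$action %in% c("kept", "flipped"))
  inc_se <- select(as_tibble(incidence), variant_id = "variant_id",
                   se_inc = "se")
  h <- left_join(h, inc_se, by = "variant_id")
  out <- as_tibble(outcome)
  m <- match(out$variant_id, h$variant_id)
  b_inc <- h$by[m]
  se_inc <- h$se_inc[m]
  adjusted <- !is.na(b_inc)
  beta_adj <- ifelse(adjusted, out$beta - fit$slope_b * b_inc, out$beta)
  se_adj <- ifelse(adjusted,
                   sqrt(out$se^2 + fit$slope_b^2 * se_inc^2 +
                          b_inc^2 * fit$se_slope^2),
                   out$se)
  out$beta <- beta_adj
  out$se <- se_adj
  out$pvalue <- ifelse(adjusted, pnorm2(beta_adj, se_adj), out$pvalue)
  out$adjusted <- adjusted
  out
}
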