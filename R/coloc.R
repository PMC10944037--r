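# Bayesian colocalization between protein levels and HF outcomes under
# the single-causal-variant-per-trait model: per-SNP approximate Bayes
# factors (Wakefield-style, from beta and SE), posterior probabilities
# for the five sharing hypotheses
#   H0 no causal variant, H1 protein only, H2 outcome only,
#   H3 distinct causal variants, H4 one shared causal variant,
# the conditional posterior PP_H4 / (PP_H3 + PP_H4), and sensitivity to
# the shared-causal prior p12.

#' Log approximate Bayes factor for one association
#'
#' With `V = se^2`, shrinkage `r = W^2 / (W^2 + V)` and `z = beta / se`,
#' `log ABF = 0.5 log(1 - r) + 0.5 r z^2`: the log marginal likelihood
#' ratio of an `N(0, W^2)` causal-effect prior against the point null.
#'
#' @param beta,se Effect estimate and its standard error (`se > 0`).
#' @param prior_sd Prior SD `W` of the true effect under causality.
#' @return Numeric vector of log ABFs (vectorized over `beta`, `se`).
#' @export
log_abf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) {
    abort("`se` must be positive.", class = "proteomr_config_error")
  }
  if (any(prior_sd <= 0)) {
    abort("`prior_sd` must be positive.", class = "proteomr_config_error")
  }
  V <- se^2
  r <- prior_sd^2 / (prior_sd^2 + V)
  z <- beta / se
  0.5 * log(1 - r) + 0.5 * r * z^2
}

#' Bayesian colocalization posteriors for a region
#'
#' Computes PP_H0..PP_H4 for two traits measured at the same harmonized
#' variants. Per-SNP log ABFs for each trait are combined with the
#' configuration priors in log space (log-sum-exp): `H1: p1 * sum BF1_j`,
#' `H2: p2 * sum BF2_j`, `H3: p1 p2 * sum over SNP pairs i != j`, `H4:
#' p12 * sum over shared SNPs`. The H3 sum excludes same-SNP pairs by
#' subtracting the shared-SNP sum from the full product. A region
#' "colocalizes" when PP_H4 exceeds 0.8.
#'
#' @param trait1 Tibble with `variant_id`, `beta`, `se` for the protein
#'   (quantitative) trait.
#' @param trait2 Tibble with `variant_id`, `beta`, `se` for the outcome
#'   (case-control) trait, over the same variants.
#' @param p1,p2 Prior probability a SNP is causal for trait 1 / trait 2.
#'   Default 1e-4 each.
#' @param p12 Prior probability a SNP is causal for both. Default 1e-5.
#'   Must not exceed `min(p1, p2)`.
#' @param prior_sd1 Causal effect-size prior SD for the quantitative
#'   trait. Default 0.15 (per-SD units).
#' @param prior_sd2 Causal effect-size prior SD for the case-control
#'   trait. Default 0.2 (log-odds units).
#' @param coloc_pp4_rule PP_H4 threshold declaring colocalization.
#'   Default 0.8.
#' @return Object of class `coloc_result`: list with `pp` (named
#'   `PP_H0`..`PP_H4`, summing to 1), `n_snps`, `conditional_pp`,
#'   `priors`, `colocalized`, and the cached per-SNP log ABFs.
#' @export
run_coloc <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd1 = 0.15, prior_sd2 = 0.2,
                      coloc_pp4_rule = 0.8) {
  t1 <- as_tibble(trait1)
  t2 <- as_tibble(trait2)
  for (p in c(p1, p2, p12)) stopifnot_scalar_number(p, "prior", 1e-300, 1)
  if (p12 > min(p1, p2) + 1e-15) {
    abort("`p12` must not exceed min(p1, p2).",
          class = "proteomr_config_error")
  }
  if (nrow(t1) < 2L) {
    abort("Colocalization needs at least 2 variants.",
          class = "proteomr_config_error")
  }
  if (nrow(t1) != nrow(t2) ||
      !setequal(t1$variant_id, t2$variant_id)) {
    abort("trait1 and trait2 must cover the same variants.",
          class = "proteomr_config_error")
  }
  t2 <- t2[match(t1$variant_id, t2$variant_id), ]
  l1 <- log_abf(t1$beta, t1$se, prior_sd1)
  l2 <- log_abf(t2$beta, t2$se, prior_sd2)
  res <- coloc_posteriors(l1, l2, p1, p2, p12)
  structure(list(
    pp = res$pp,
    n_snps = nrow(t1),
    conditional_pp = conditional_from_pp(res$pp),
    priors = c(p1 = p1, p2 = p2, p12 = p12,
               prior_sd1 = prior_sd1, prior_sd2 = prior_sd2),
    colocalized = unname(res$pp["PP_H4"] > coloc_pp4_rule),
    coloc_pp4_rule = coloc_pp4_rule,
    abf = tibble(variant_id = t1$variant_id, labf1 = l1, labf2 = l2)
  ), class = "coloc_result")
}

# Hypothesis sums in log space from per-SNP log ABFs.
coloc_posteriors <- function(l1, l2, p1, p2, p12) {
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  s3 <- logdiffexp(s1 + s2, s12)
  lh <- c(
    PP_H0 = 0,
    PP_H1 = log(p1) + s1,
    PP_H2 = log(p2) + s2,
    PP_H3 = log(p1) + log(p2) + s3,
    PP_H4 = log(p12) + s12
  )
  m <- max(lh)
  pp <- exp(lh - m)
  pp <- pp / sum(pp)
  list(pp = pp, log_hyp = lh)
}

conditional_from_pp <- function(pp) {
  denom <- pp[["PP_H3"]] + pp[["PP_H4"]]
  if (denom <= 0) return(NA_real_)
  pp[["PP_H4"]] / denom
}

#' Conditional colocalization posterior
#'
#' `PP_H4 / (PP_H3 + PP_H4)`: the probability of a shared causal variant
#' conditional on both traits having a causal variant in the region.
#' Returns `NA` (with a message) when the denominator is zero.
#'
#' @param result A `coloc_result` from [run_coloc()].
#' @return A number in `[0, 1]`, or `NA`.
#' @export
conditional_coloc <- function(result) {
  out <- conditional_from_pp(result$pp)
  if (is.na(out)) {
    inform("PP_H3 + PP_H4 = 0: conditional posterior undefined.")
  }
  out
}

#' Sensitivity of the colocalization posterior to the shared prior
#'
#' Recomputes the posteriors over a grid of `p12` values, reusing the
#' cached per-SNP ABFs. PP_H4 is monotone non-decreasing in `p12`. The
#' result is flagged prior-sensitive when the colocalization verdict
#' (PP_H4 > rule) differs across the grid.
#'
#' @param result A `coloc_result` from [run_coloc()].
#' @param p12_grid Grid of shared-prior values in `(0, min(p1, p2)]`.
#' @return Tibble with `p12`, `pp_h4`, `conditional_pp`, `colocalized`,
#'   plus a `"prior_sensitive"` attribute.
#' @export
coloc_prior_sensitivity <- function(result,
                                    p12_grid = c(1e-6, 1e-5, 1e-4)) {
  p1 <- result$priors[["p1"]]
  p2 <- result$priors[["p2"]]
  if (any(p12_grid <= 0 | p12_grid > min(p1, p2) + 1e-15)) {
    abort("p12 grid values must lie in (0, min(p1, p2)].",
          class = "proteomr_config_error")
  }
  rows <- map_dfr(sort(p12_grid), function(p12) {
    res <- coloc_posteriors(result$abf$labf1, result$abf$labf2, p1, p2, p12)
    tibble(p12 = p12,
           pp_h4 = unname(res$pp[["PP_H4"]]),
           conditional_pp = conditional_from_pp(res$pp),
           colocalized = res$pp[["PP_H4"]] > result$coloc_pp4_rule)
  })
  attr(rows, "prior_sensitive") <- length(unique(rows$colocalized)) > 1L
  rows
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalization over %d SNPs\n", x$n_snps))
  print(round(x$pp, 4))
  cat(sprintf("  conditional PP_H4/(PP_H3+PP_H4): %s\n",
              ifelse(is.na(x$conditional_pp), "undefined",
                     sprintf("%.4f", x$conditional_pp))))
  cat(sprintf("  colocalized (PP_H4 > %.2f): %s\n", x$coloc_pp4_rule,
              x$colocalized))
  invisible(x)
}

#' @export
tidy.coloc_result <- function(x, ...) {
  tibble(hypothesis = names(x$pp), posterior = unname(x$pp))
}

#' @export
glance.coloc_result <- function(x, ...) {
  tibble(n_snps = x$n_snps,
         pp_h0 = x$pp[["PP_H0"]], pp_h1 = x$pp[["PP_H1"]],
         pp_h2 = x$pp[["PP_H2"]], pp_h3 = x$pp[["PP_H3"]],
         pp_h4 = x$pp[["PP_H4"]],
         conditional_pp = x$conditional_pp,
         colocalized = x$colocalized,
         p12 = x$priors[["p12"]])
}
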