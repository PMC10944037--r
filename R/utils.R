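# Internal numerical helpers shared across modules.

#' Log-sum-exp of a numeric vector
#'
#' Numerically stable `log(sum(exp(x)))`; returns `-Inf` for an empty vector.
#' @param x numeric vector of log-scale terms.
#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, clamped at -Inf when the difference
# underflows; used for the distinct-causal-variant hypothesis sum.
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Two-sided normal p-value from an effect and its standard error
#' @keywords internal
#' @noRd
pnorm2 <- function(beta, se) {
  pmax(2 * pnorm(-abs(beta / se)), 1e-300)
}

#' Repair a correlation matrix to positive semidefiniteness
#'
#' Adds a ridge of `|min eigenvalue| + 1e-8` when the smallest eigenvalue is
#' negative, then rescales to unit diagonal so the result is still a
#' correlation matrix.
#' @param R square symmetric matrix of correlations.
#' @keywords internal
#' @noRd
psd_repair <- function(R) {
  R <- (R + t(R)) / 2
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  min_ev <- min(ev)
  if (min_ev < 0) {
    eps <- abs(min_ev) + 1e-8
    R <- R + diag(eps, nrow(R))
    R <- stats::cov2cor(R)
  }
  R
}

# Consistent column order for association-record tibbles.
assoc_cols <- c(
  "variant_id", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pvalue", "n", "trait_id"
)

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].",
                  name, format(lower), format(upper)),
          class = "proteomr_config_error")
  }
  invisible(x)
}

# Derive a stream of child seeds from one master seed, each below 2^31.
derive_seeds <- function(seed, k) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}
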