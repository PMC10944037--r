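# Fixture builders and independent oracles used across the test files.
# Oracles are deliberately naive (enumeration, grid search, quadrature,
# closed-form normal equations) and never call the implementation paths
# they check.

make_records <- function(variant_id, beta, se,
                         chrom = "1",
                         pos = seq_along(variant_id) * 1000L,
                         effect_allele = "A", other_allele = "G",
                         eaf = 0.3, pvalue = NULL,
                         n = 10000L, trait_id = "trait") {
  if (is.null(pvalue)) pvalue <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  tibble::tibble(
    variant_id = variant_id, chrom = chrom, pos = as.integer(pos),
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta = beta, se = se, pvalue = pvalue,
    n = as.integer(n), trait_id = trait_id
  )
}

make_set <- function(bx, sx, by, sy, R = diag(length(bx)),
                     protein_id = "P", cis = "cis") {
  ids <- paste0("v", seq_along(bx))
  dimnames(R) <- list(ids, ids)
  structure(list(
    protein_id = protein_id,
    data = tibble::tibble(
      variant_id = ids, chrom = "1", pos = seq_along(bx) * 1000L,
      effect_allele = "A", other_allele = "G",
      bx = bx, sx = sx, by = by, sy = sy, cis_trans = cis
    ),
    R = R,
    mean_F = mean((bx / sx)^2),
    weak = mean((bx / sx)^2) <= 10
  ), class = "instrument_set")
}

# --- Cox partial likelihood oracle: direct evaluation of the Efron (or
# Breslow) log partial likelihood, maximized by 1-D grid/optimize. Used
# to cross-check the fitted single-covariate model.
cox_pl <- function(beta, time, event, x, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  eta <- beta * x
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    risk <- which(time >= t)
    d <- length(D)
    ll <- ll + sum(eta[D])
    sum_risk <- sum(exp(eta[risk]))
    sum_tied <- sum(exp(eta[D]))
    for (l in seq_len(d)) {
      if (ties == "efron") {
        ll <- ll - log(sum_risk - (l - 1) / d * sum_tied)
      } else {
        ll <- ll - log(sum_risk)
      }
    }
  }
  ll
}

cox_oracle_beta <- function(time, event, x, ties = "efron",
                            interval = c(-5, 5)) {
  optimize(function(b) cox_pl(b, time, event, x, ties = ties),
           interval = interval, maximum = TRUE, tol = 1e-10)$maximum
}

# --- Colocalization oracle: exhaustive enumeration over all causal
# configurations (SNP for trait 1) x (SNP for trait 2), feasible for
# small n_snps. Returns unnormalized log hypothesis sums.
coloc_enum_oracle <- function(l1, l2, p1, p2, p12) {
  n <- length(l1)
  lh1 <- log(p1) + log(sum(exp(l1)))
  lh2 <- log(p2) + log(sum(exp(l2)))
  s3 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) s3 <- s3 + exp(l1[i] + l2[j])
    }
  }
  lh3 <- log(p1) + log(p2) + log(s3)
  lh4 <- log(p12) + log(sum(exp(l1 + l2)))
  c(PP_H0 = 0, PP_H1 = lh1, PP_H2 = lh2, PP_H3 = lh3, PP_H4 = lh4)
}

coloc_enum_pp <- function(l1, l2, p1, p2, p12) {
  lh <- coloc_enum_oracle(l1, l2, p1, p2, p12)
  w <- exp(lh - max(lh))
  w / sum(w)
}

# --- ABF quadrature oracle: numerical integration of the two-Gaussian
# marginal likelihood ratio N(beta; 0, V + W^2) / N(beta; 0, V) via its
# integral representation over the latent true effect.
abf_quadrature <- function(beta, se, W) {
  num <- integrate(function(b) dnorm(beta, b, se) * dnorm(b, 0, W),
                   -Inf, Inf, rel.tol = 1e-12)$value
  log(num) - dnorm(beta, 0, se, log = TRUE)
}

# --- Weighted least squares through the origin via explicit normal
# equations (oracle for fixed-effect IVW with R = I).
wls_origin_oracle <- function(bx, by, sy) {
  w <- 1 / sy^2
  theta <- sum(w * bx * by) / sum(w * bx^2)
  se <- sqrt(1 / sum(w * bx^2))
  c(theta = theta, se = se)
}

# Weighted regression with intercept via solve() on the normal equations
# (oracle for MR-Egger on exact-fit fixtures).
wls_intercept_oracle <- function(bx, by, w) {
  X <- cbind(1, bx)
  XtWX <- t(X) %*% (w * X)
  XtWy <- t(X) %*% (w * by)
  drop(solve(XtWX, XtWy))
}
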