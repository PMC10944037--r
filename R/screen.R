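# Proteome-wide Cox proportional-hazards screening of standardized protein
# levels against death and the death-or-HF-hospitalization composite (DHFA),
# with a principal-component based effective-number-of-tests alpha
# correction.

#' Validate a cohort table
#'
#' Checks the survival-cohort invariants: positive follow-up times, binary
#' event indicators, and per-subject DHFA time no later than death time
#' (the composite fires at or before death by construction).
#'
#' @param cohort Tibble with columns `subject_id`, `time_death`,
#'   `event_death`, `time_dhfa`, `event_dhfa`, plus covariate columns.
#' @return `cohort`, invisibly; aborts on violation.
#' @export
validate_cohort <- function(cohort) {
  need <- c("subject_id", "time_death", "event_death", "time_dhfa", "event_dhfa")
  missing <- setdiff(need, names(cohort))
  if (length(missing) > 0L) {
    abort(sprintf("Cohort is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "proteomr_config_error")
  }
  if (any(cohort$time_death <= 0, na.rm = TRUE) ||
      any(cohort$time_dhfa <= 0, na.rm = TRUE)) {
    abort("Follow-up times must be positive.", class = "proteomr_config_error")
  }
  if (!all(cohort$event_death %in% c(0, 1)) ||
      !all(cohort$event_dhfa %in% c(0, 1))) {
    abort("Event indicators must be 0/1.", class = "proteomr_config_error")
  }
  if (any(cohort$time_dhfa > cohort$time_death + 1e-9, na.rm = TRUE)) {
    abort("DHFA time must not exceed death time for any subject.",
          class = "proteomr_config_error")
  }
  invisible(cohort)
}

#' Standardize a protein abundance matrix
#'
#' Natural-log-transforms positive abundances (relative fluorescence units
#' are right-skewed, so the log is taken before scaling) and centers/scales
#' each protein to mean 0, SD 1 over its non-missing subjects. Hazard ratios
#' fitted on the result are per-SD (z-score) effects. Zero-variance proteins
#' cannot be standardized and are removed; they are listed in the
#' `"excluded"` attribute with a reason.
#'
#' @param raw Numeric matrix, proteins x subjects, positive abundances;
#'   rownames are protein ids.
#' @param log_transform Log-transform before scaling? Default `TRUE`.
#' @return Matrix of z-scores (proteins x subjects) with attribute
#'   `"excluded"`: a tibble of dropped proteins and reasons.
#' @export
standardize_proteins <- function(raw, log_transform = TRUE) {
  raw <- as.matrix(raw)
  if (is.null(rownames(raw))) {
    rownames(raw) <- paste0("protein_", seq_len(nrow(raw)))
  }
  if (log_transform) {
    if (any(raw <= 0, na.rm = TRUE)) {
      abort("Abundances must be positive for log transformation.",
            class = "proteomr_config_error")
    }
    raw <- log(raw)
  }
  mu <- rowMeans(raw, na.rm = TRUE)
  sdv <- apply(raw, 1, sd, na.rm = TRUE)
  zero_var <- !is.finite(sdv) | sdv == 0
  excluded <- tibble(protein_id = rownames(raw)[zero_var],
                     reason = rep("zero_variance", sum(zero_var)))
  if (any(zero_var)) {
    warn(sprintf("Excluding %d zero-variance protein(s) from screening.",
                 sum(zero_var)))
  }
  z <- (raw[!zero_var, , drop = FALSE] - mu[!zero_var]) / sdv[!zero_var]
  attr(z, "excluded") <- excluded
  z
}

#' Fit a single-protein Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood (Efron tie handling) for one
#' standardized protein, optionally adjusted for covariates. Reported per-SD
#' hazard ratio and Wald 95% CI: `HR = exp(beta)`,
#' `CI = exp(beta +/- 1.96 se)`.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators.
#' @param x Protein z-scores (the coefficient of interest).
#' @param covariates Optional data frame of adjustment covariates.
#' @param ties Tie handling passed to [survival::coxph()]; default
#'   `"efron"`.
#' @return One-row tibble: `beta`, `se`, `hr`, `ci_low`, `ci_high`,
#'   `pvalue`, `n_used`, `n_events`.
#' @export
fit_cox <- function(time, event, x, covariates = NULL, ties = "efron") {
  df <- data.frame(time = time, event = event, x = x)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  df <- df[complete.cases(df), , drop = FALSE]
  if (sum(df$event) < 2) {
    abort("Cox model unidentifiable: fewer than 2 events.",
          class = "proteomr_unidentifiable_error")
  }
  rhs <- paste(setdiff(names(df), c("time", "event")), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- survival::coxph(fml, data = df, ties = ties,
                         control = survival::coxph.control(eps = 1e-11,
                                                           toler.chol = 1e-12,
                                                           iter.max = 100))
  if (!is.null(fit$info) && grepl("did not converge", fit$info %||% "")) {
    abort("Cox model failed to converge.", class = "proteomr_convergence_error")
  }
  beta <- unname(coef(fit)["x"])
  se <- sqrt(diag(fit$var))[match("x", names(coef(fit)))]
  if (!is.finite(beta) || !is.finite(se)) {
    abort("Cox model produced a non-finite estimate (degenerate design).",
          class = "proteomr_convergence_error")
  }
  tibble(
    beta = beta, se = se, hr = exp(beta),
    ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
    pvalue = pnorm2(beta, se),
    n_used = nrow(df), n_events = sum(df$event)
  )
}

#' Proteome-wide Cox screen
#'
#' Fits one Cox model per protein against the chosen outcome, unadjusted or
#' adjusted for the supplied covariates (by default the composite clinical
#' risk score and log natriuretic peptide), with complete-case handling per
#' protein. Per-protein fitting failures are logged and skipped, never
#' fatal.
#'
#' @param cohort Cohort tibble (see [validate_cohort()]) containing the
#'   covariate columns.
#' @param proteins_z Standardized protein matrix (proteins x subjects;
#'   column names matching `cohort$subject_id`), from
#'   [standardize_proteins()].
#' @param outcome `"dhfa"` (death or HF hospitalization) or `"death"`.
#' @param model `"adjusted"` or `"unadjusted"`.
#' @param covariates Covariate column names used when `model = "adjusted"`.
#' @return Tibble of screen results sorted by p-value: `protein_id`,
#'   `outcome`, `model`, `hr_per_sd`, `ci_low`, `ci_high`, `beta`, `se`,
#'   `pvalue`, `n_used`, `n_events`.
#' @export
screen_proteins <- function(cohort, proteins_z,
                            outcome = c("dhfa", "death"),
                            model = c("adjusted", "unadjusted"),
                            covariates = c("maggic", "log_ntprobnp")) {
  outcome <- match.arg(outcome)
  model <- match.arg(model)
  validate_cohort(cohort)
  empty <- tibble(
    protein_id = character(), outcome = character(), model = character(),
    hr_per_sd = numeric(), ci_low = numeric(), ci_high = numeric(),
    beta = numeric(), se = numeric(), pvalue = numeric(),
    n_used = integer(), n_events = integer()
  )
  if (is.null(proteins_z) || nrow(proteins_z) == 0L) {
    warn("Empty protein matrix: nothing to screen.")
    return(empty)
  }
  idx <- match(cohort$subject_id, colnames(proteins_z))
  if (all(is.na(idx))) {
    abort("No cohort subjects found in the protein matrix columns.",
          class = "proteomr_config_error")
  }
  time <- cohort[[paste0("time_", outcome)]]
  event <- cohort[[paste0("event_", outcome)]]
  covs <- if (model == "adjusted") {
    missing_cov <- setdiff(covariates, names(cohort))
    if (length(missing_cov) > 0L) {
      abort(sprintf("Missing covariate column(s): %s",
                    paste(missing_cov, collapse = ", ")),
            class = "proteomr_config_error")
    }
    cohort[covariates]
  } else NULL
  rows <- map(rownames(proteins_z), function(pid) {
    x <- proteins_z[pid, idx]
    res <- tryCatch(fit_cox(time, event, x, covariates = covs),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warn(sprintf("Protein %s skipped: %s", pid, conditionMessage(res)))
      return(NULL)
    }
    tibble(protein_id = pid, outcome = outcome, model = model,
           hr_per_sd = res$hr, ci_low = res$ci_low, ci_high = res$ci_high,
           beta = res$beta, se = res$se, pvalue = res$pvalue,
           n_used = res$n_used, n_events = res$n_events)
  })
  out <- bind_rows(compact(rows))
  if (nrow(out) == 0L) return(empty)
  arrange(out, .data$pvalue)
}

#' Effective number of independent tests from protein correlation
#'
#' The screened proteins are strongly correlated, so a Bonferroni correction
#' over the raw protein count is too severe. The corrected alpha divides by
#' the number of principal components of the protein correlation matrix
#' needed to explain at least `variance_threshold` of the total variance
#' (the effective number of independent tests).
#'
#' @param proteins_z Standardized protein matrix (proteins x subjects), at
#'   least 2 proteins and 3 subjects.
#' @param variance_threshold Fraction of variance the retained components
#'   must explain, in (0, 1]. Default 0.95.
#' @param alpha Family-wise alpha to correct. Default 0.05.
#' @return One-row tibble: `n_proteins`, `n_effective`,
#'   `variance_threshold`, `alpha_corrected` (= `alpha / n_effective`).
#' @export
effective_tests <- function(proteins_z, variance_threshold = 0.95,
                            alpha = 0.05) {
  if (!is.numeric(variance_threshold) || length(variance_threshold) != 1L ||
      is.na(variance_threshold) || variance_threshold <= 0 ||
      variance_threshold > 1) {
    abort("`variance_threshold` must be in (0, 1].",
          class = "proteomr_config_error")
  }
  proteins_z <- as.matrix(proteins_z)
  if (nrow(proteins_z) < 2L || ncol(proteins_z) < 3L) {
    abort("Need at least 2 proteins and 3 subjects.",
          class = "proteomr_config_error")
  }
  C <- suppressWarnings(cor(t(proteins_z), use = "pairwise.complete.obs"))
  C[is.na(C)] <- 0
  diag(C) <- 1
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  cum <- cumsum(ev) / sum(ev)
  n_eff <- which(cum >= variance_threshold - 1e-12)[1]
  tibble(
    n_proteins = nrow(proteins_z),
    n_effective = as.integer(n_eff),
    variance_threshold = variance_threshold,
    alpha_corrected = alpha / n_eff
  )
}

#' Volcano export of screen results
#'
#' Plot-ready table with the log hazard ratio, `-log10(p)`, and significance
#' flags at the nominal and corrected alpha.
#'
#' @param screen_results Output of [screen_proteins()].
#' @param alpha_corrected Corrected alpha from [effective_tests()].
#' @param alpha_nominal Nominal alpha. Default 0.05.
#' @return Tibble with one row per screened protein.
#' @export
volcano_table <- function(screen_results, alpha_corrected,
                          alpha_nominal = 0.05) {
  mutate(screen_results,
         log_hr = log(.data$hr_per_sd),
         neg_log10_p = -log10(.data$pvalue),
         sig_nominal = .data$pvalue < alpha_nominal,
         sig_corrected = .data$pvalue < alpha_corrected)
}

#' Volcano plot of a proteome-wide screen
#'
#' @inheritParams volcano_table
#' @return A ggplot object.
#' @export
plot_volcano <- function(screen_results, alpha_corrected,
                         alpha_nominal = 0.05) {
  vt <- volcano_table(screen_results, alpha_corrected, alpha_nominal)
  ggplot2::ggplot(vt, ggplot2::aes(x = .data$log_hr, y = .data$neg_log10_p,
                                   colour = .data$sig_corrected)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha_corrected),
                        linetype = "dashed") +
    ggplot2::labs(x = "log hazard ratio per SD", y = "-log10 p",
                  colour = "corrected-alpha\nsignificant") +
    ggplot2::theme_minimal()
}
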