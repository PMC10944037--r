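# End-to-end orchestration: proteome-wide Cox screen -> effective-tests
# alpha -> collider-bias adjustment of the case-only outcome GWAS ->
# cis-pQTL instrument selection -> correlated-instrument MR -> Bayesian
# colocalization -> evidence-tier verdicts. Gating follows the study
# design: only corrected-alpha screen hits advance to MR, and only
# nominally MR-significant proteins advance to colocalization.

#' Pipeline configuration
#'
#' All module parameters in one validated list; the resolved config is
#' attached to the pipeline result so every run is self-describing.
#'
#' @param outcome `"dhfa"`, `"death"`, or `"both"`.
#' @param screen_model `"adjusted"` or `"unadjusted"`.
#' @param covariates Adjustment covariate columns for the screen.
#' @param variance_threshold PC variance fraction for the effective
#'   number of tests.
#' @param window_bp Cis window half-width (bp).
#' @param p_threshold Instrument significance cutoff (strict).
#' @param scope Instrument scope: `"cis"`, `"trans"`, or `"both"`.
#' @param r2_clump LD clumping threshold (r^2).
#' @param palindromic_eaf_band Harmonization EAF band.
#' @param incidence_p_threshold Clustering subset cutoff for the
#'   collider slope fit.
#' @param collider_adjust Apply collider-bias adjustment to the outcome
#'   GWAS before MR? Default `TRUE`.
#' @param mr_alpha Nominal MR significance level (the study reports
#'   nominal P < 0.05, justified by the prior screen gating).
#' @param p1,p2,p12,prior_sd1,prior_sd2 Colocalization priors.
#' @param coloc_pp4_rule PP_H4 threshold for a colocalization signal.
#' @param conditional_pp_rule Conditional-PP threshold reported in
#'   verdicts.
#' @param n_boot Weighted-median bootstrap resamples.
#' @param seed Seed for the stochastic steps (EM restarts, bootstrap).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outcome = "dhfa", screen_model = "adjusted",
                            covariates = c("maggic", "log_ntprobnp"),
                            variance_threshold = 0.95, window_bp = 5e5,
                            p_threshold = 5e-8, scope = "cis",
                            r2_clump = 0.1, palindromic_eaf_band = 0.08,
                            incidence_p_threshold = 1e-3,
                            collider_adjust = TRUE, mr_alpha = 0.05,
                            p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                            prior_sd1 = 0.15, prior_sd2 = 0.2,
                            coloc_pp4_rule = 0.8,
                            conditional_pp_rule = 0.9,
                            n_boot = 500L, seed = 1L) {
  outcome <- match.arg(outcome, c("dhfa", "death", "both"))
  screen_model <- match.arg(screen_model, c("adjusted", "unadjusted"))
  scope <- match.arg(scope, c("cis", "trans", "both"))
  stopifnot_scalar_number(variance_threshold, "variance_threshold", 1e-9, 1)
  stopifnot_scalar_number(window_bp, "window_bp", 0)
  stopifnot_scalar_number(p_threshold, "p_threshold", 0, 1)
  stopifnot_scalar_number(r2_clump, "r2_clump", 0, 1)
  stopifnot_scalar_number(mr_alpha, "mr_alpha", 0, 1)
  structure(list(
    outcome = outcome, screen_model = screen_model,
    covariates = covariates, variance_threshold = variance_threshold,
    window_bp = window_bp, p_threshold = p_threshold, scope = scope,
    r2_clump = r2_clump, palindromic_eaf_band = palindromic_eaf_band,
    incidence_p_threshold = incidence_p_threshold,
    collider_adjust = collider_adjust, mr_alpha = mr_alpha,
    p1 = p1, p2 = p2, p12 = p12, prior_sd1 = prior_sd1,
    prior_sd2 = prior_sd2, coloc_pp4_rule = coloc_pp4_rule,
    conditional_pp_rule = conditional_pp_rule,
    n_boot = as.integer(n_boot), seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the full analysis pipeline on a study bundle
#'
#' Stages, in order, per outcome: (1) standardize proteins and screen
#' them with Cox models; (2) compute the PC-based corrected alpha and
#' keep the screen-significant proteins; (3) fit the collider slope on
#' LD-clumped incidence variants and adjust the outcome GWAS; (4) select,
#' clump, and harmonize cis (and/or trans) pQTL instruments for each
#' advanced protein; (5) run MR (Wald/IVW/Egger/weighted median); (6)
#' colocalize every MR-significant protein over its cis region; (7)
#' assign evidence tiers. Per-protein failures are quarantined with a
#' warning; a stage-level failure aborts with that stage's diagnostics.
#'
#' @param bundle A `sim_bundle` from [simulate_study()], or any list with
#'   the same components (`cohort`, `proteins_raw`, `loci`, `exposure`,
#'   `incidence_gwas`, `outcome_gwas`, `ld`).
#' @param config A [pipeline_config()].
#' @return An object of class `pipeline_result`: list of stage tables
#'   (`screen`, `alpha`, `collider`, `instruments`, `mr`, `coloc`,
#'   `verdicts`) plus `config` and a `manifest` of per-stage row counts.
#' @export
run_pipeline <- function(bundle, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  outcomes <- if (config$outcome == "both") c("dhfa", "death") else config$outcome

  proteins_z <- standardize_proteins(bundle$proteins_raw)
  alpha <- effective_tests(proteins_z, config$variance_threshold)

  screen <- map_dfr(outcomes, function(oc) {
    suppressWarnings(screen_proteins(
      bundle$cohort, proteins_z, outcome = oc,
      model = config$screen_model, covariates = config$covariates))
  })
  screen <- mutate(screen, sig_corrected = .data$pvalue < alpha$alpha_corrected)

  # Collider-bias correction of the outcome GWAS, shared across proteins.
  collider_fits <- list()
  adjusted_outcomes <- list()
  for (oc in outcomes) {
    out_gwas <- bundle$outcome_gwas[[oc]]
    if (config$collider_adjust) {
      inc <- bundle$incidence_gwas
      hf_ld <- bundle$ld[["hf"]]
      clump_in <- if (!is.null(hf_ld)) {
        filter(inc, .data$variant_id %in% rownames(hf_ld))
      } else inc
      clumped <- if (!is.null(hf_ld)) {
        clump_instruments(
          mutate(clump_in, pvalue = pmax(.data$pvalue, 1e-300)),
          hf_ld, r2_threshold = config$r2_clump)
      } else clump_in
      h <- harmonize_sumstats(clumped, out_gwas,
                              palindromic_eaf_band = config$palindromic_eaf_band)
      pairs <- filter(h, .data$action %in% c("kept", "flipped"))
      pairs <- tibble(variant_id = pairs$variant_id, b_inc = pairs$bx,
                      se_inc = pairs$sx, b_out = pairs$by,
                      se_out = pairs$sy)
      fit <- fit_collider_slope(
        pairs, incidence_p_threshold = config$incidence_p_threshold,
        seed = config$seed)
      collider_fits[[oc]] <- fit
      adjusted_outcomes[[oc]] <- adjust_collider_bias(
        out_gwas, bundle$incidence_gwas, fit,
        palindromic_eaf_band = config$palindromic_eaf_band)
    } else {
      collider_fits[[oc]] <- NULL
      adjusted_outcomes[[oc]] <- mutate(out_gwas, adjusted = FALSE)
    }
  }
  collider_tbl <- map_dfr(outcomes, function(oc) {
    f <- collider_fits[[oc]]
    if (is.null(f)) return(tibble())
    mutate(glance(f), outcome = oc)
  })

  # MR on screen-significant proteins only (the study's gating)
  advanced <- filter(screen, .data$sig_corrected)
  instrument_rows <- list()
  mr_rows <- list()
  coloc_rows <- list()
  sets <- list()
  for (k in seq_len(nrow(advanced))) {
    pid <- advanced$protein_id[k]
    oc <- advanced$outcome[k]
    locus <- filter(bundle$loci, .data$protein_id == pid)
    if (nrow(locus) == 0L) {
      warn(sprintf("Protein %s: no locus annotation; skipped.", pid))
      next
    }
    pqtls <- filter(bundle$exposure, .data$trait_id == pid)
    cand <- suppressMessages(select_instruments(
      pqtls, locus, window_bp = config$window_bp,
      p_threshold = config$p_threshold, scope = config$scope))
    if (nrow(cand) == 0L) next
    locus_ld <- bundle$ld[[pid]]
    clumped <- clump_instruments(cand, locus_ld,
                                 r2_threshold = config$r2_clump)
    set <- suppressMessages(build_instrument_set(
      pid, clumped, adjusted_outcomes[[oc]], locus_ld,
      palindromic_eaf_band = config$palindromic_eaf_band))
    if (is.null(set)) next
    sets[[paste(pid, oc, sep = ".")]] <- set
    instrument_rows[[paste(pid, oc)]] <- mutate(tidy(set), outcome = oc)
    res <- tryCatch(
      run_mr(set, outcome = oc, n_boot = config$n_boot,
             seed = config$seed),
      error = function(e) {
        warn(sprintf("Protein %s MR failed: %s", pid, conditionMessage(e)))
        NULL
      })
    if (is.null(res)) next
    mr_rows[[paste(pid, oc)]] <- res
    # coloc gate: nominally significant primary (IVW) estimate
    ivw <- filter(res, .data$method == "ivw")
    if (nrow(ivw) == 1L && !is.na(ivw$pvalue) &&
        ivw$pvalue < config$mr_alpha) {
      region <- filter(pqtls,
                       .data$chrom == locus$chrom,
                       .data$pos >= locus$start - config$window_bp,
                       .data$pos <= locus$end + config$window_bp)
      h <- tryCatch(
        harmonize_sumstats(region, adjusted_outcomes[[oc]],
                           palindromic_eaf_band = config$palindromic_eaf_band),
        proteomr_empty_overlap_error = function(e) NULL)
      if (!is.null(h)) h <- filter(h, .data$action %in% c("kept", "flipped"))
      if (!is.null(h) && nrow(h) >= 2L) {
        cres <- run_coloc(
          tibble(variant_id = h$variant_id, beta = h$bx, se = h$sx),
          tibble(variant_id = h$variant_id, beta = h$by, se = h$sy),
          p1 = config$p1, p2 = config$p2, p12 = config$p12,
          prior_sd1 = config$prior_sd1, prior_sd2 = config$prior_sd2,
          coloc_pp4_rule = config$coloc_pp4_rule)
        coloc_rows[[paste(pid, oc)]] <- mutate(glance(cres),
                                               protein_id = pid,
                                               outcome = oc)
      }
    }
  }
  empty_instruments <- tibble(protein_id = character(),
                              variant_id = character(),
                              outcome = character())
  empty_mr <- mr_result_row(character(), character(), character(),
                            numeric(), numeric(), integer())[0, ]
  empty_coloc <- tibble(protein_id = character(), outcome = character(),
                        n_snps = integer(), pp_h0 = numeric(),
                        pp_h1 = numeric(), pp_h2 = numeric(),
                        pp_h3 = numeric(), pp_h4 = numeric(),
                        conditional_pp = numeric(),
                        colocalized = logical(), p12 = numeric())
  instruments <- if (length(instrument_rows)) bind_rows(instrument_rows) else empty_instruments
  mr <- if (length(mr_rows)) bind_rows(mr_rows) else empty_mr
  coloc <- if (length(coloc_rows)) bind_rows(coloc_rows) else empty_coloc

  verdicts <- build_verdicts(screen, mr, coloc, config)

  manifest <- list(
    n_proteins_screened = length(unique(screen$protein_id)),
    n_effective = alpha$n_effective,
    alpha_corrected = alpha$alpha_corrected,
    n_screen_significant = nrow(advanced),
    n_with_instruments = length(sets),
    n_mr_significant = sum(
      mr$method == "ivw" & !is.na(mr$pvalue) & mr$pvalue < config$mr_alpha),
    n_colocalized = sum(coloc$colocalized %||% logical(0)),
    seed = config$seed
  )

  structure(list(
    screen = screen, alpha = alpha, collider = collider_tbl,
    collider_fits = collider_fits, adjusted_outcomes = adjusted_outcomes,
    instruments = instruments, instrument_sets = sets, mr = mr,
    coloc = coloc, verdicts = verdicts, config = config,
    manifest = manifest
  ), class = "pipeline_result")
}

# Evidence tiers: observational-only -> MR-supported -> MR+coloc-supported.
# Monotone by construction: coloc support requires MR support, MR support
# requires a corrected-alpha screen hit.
build_verdicts <- function(screen, mr, coloc, config) {
  base <- filter(screen, .data$sig_corrected)
  if (nrow(base) == 0L) {
    return(tibble(protein_id = character(), outcome = character(),
                  screen_significant = logical(), mr_significant = logical(),
                  pp_h4 = numeric(), conditional_pp = numeric(),
                  colocalized = logical(), coloc_supported = logical(),
                  tier = character()))
  }
  ivw <- filter(mr, .data$method == "ivw")
  ivw <- select(ivw, "protein_id", "outcome", mr_p = "pvalue")
  cl <- select(coloc, "protein_id", "outcome", "pp_h4",
               "conditional_pp", "colocalized")
  out <- left_join(select(base, "protein_id", "outcome",
                          screen_p = "pvalue"),
                   ivw, by = c("protein_id", "outcome"))
  out <- left_join(out, cl, by = c("protein_id", "outcome"))
  # coloc support for the evidence tier keys on the conditional
  # posterior PP_H4/(PP_H3+PP_H4): with a modest case-only outcome GWAS
  # the marginal PP_H4 is limited by power (H1 soaks up posterior mass),
  # which is exactly what conditional colocalization is for; the
  # marginal PP_H4 > 0.8 flag is still reported in the coloc table
  mutate(out,
         screen_significant = TRUE,
         mr_significant = !is.na(.data$mr_p) & .data$mr_p < config$mr_alpha,
         colocalized = !is.na(.data$colocalized) & .data$colocalized,
         coloc_supported = !is.na(.data$conditional_pp) &
           .data$conditional_pp > config$conditional_pp_rule,
         tier = dplyr::case_when(
           .data$mr_significant & .data$coloc_supported ~ "MR+coloc-supported",
           .data$mr_significant ~ "MR-supported",
           TRUE ~ "observational-only"
         ))
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("proteomr pipeline result\n")
  cat(sprintf("  screened: %d proteins (n_eff = %d, corrected alpha = %.2g)\n",
              m$n_proteins_screened, m$n_effective, m$alpha_corrected))
  cat(sprintf("  screen-significant: %d | with instruments: %d | MR-significant: %d | colocalized: %d\n",
              m$n_screen_significant, m$n_with_instruments,
              m$n_mr_significant, m$n_colocalized))
  invisible(x)
}

#' @export
glance.pipeline_result <- function(x, ...) {
  as_tibble(x$manifest)
}

#' Plot-ready report tables from a pipeline result
#'
#' @param result A `pipeline_result`.
#' @return List of tibbles: `volcano` (one row per screened protein),
#'   `forest` (one row per protein x method MR estimate), `verdicts`.
#' @export
make_reports <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  volcano <- volcano_table(result$screen,
                           result$alpha$alpha_corrected)
  forest <- select(result$mr, "protein_id", "outcome", "method", "theta",
                   "se_theta", "or_", "ci_low", "ci_high", "pvalue",
                   "n_instruments")
  list(volcano = volcano, forest = forest, verdicts = result$verdicts)
}

#' Write pipeline result tables to a directory
#'
#' Exports every stage table as TSV plus the manifest (with the resolved
#' configuration) as JSON.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reports <- make_reports(result)
  readr::write_tsv(result$screen, file.path(dir, "screen.tsv"),
                   progress = FALSE)
  readr::write_tsv(result$alpha, file.path(dir, "alpha.tsv"),
                   progress = FALSE)
  if (nrow(result$collider) > 0) {
    readr::write_tsv(result$collider, file.path(dir, "collider.tsv"),
                     progress = FALSE)
  }
  readr::write_tsv(result$instruments, file.path(dir, "instruments.tsv"),
                   progress = FALSE)
  readr::write_tsv(result$mr, file.path(dir, "mr.tsv"), progress = FALSE)
  readr::write_tsv(result$coloc, file.path(dir, "coloc.tsv"),
                   progress = FALSE)
  readr::write_tsv(reports$volcano, file.path(dir, "volcano.tsv"),
                   progress = FALSE)
  readr::write_tsv(reports$forest, file.path(dir, "forest.tsv"),
                   progress = FALSE)
  readr::write_tsv(result$verdicts, file.path(dir, "verdicts.tsv"),
                   progress = FALSE)
  jsonlite::write_json(c(result$manifest,
                         list(config = unclass(result$config))),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
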