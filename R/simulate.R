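# Synthetic-data generator: every input the pipeline consumes, with known
# truth. Emulates (i) a large external pQTL study per protein (the role a
# proteogenomic consortium plays), (ii) a disease-risk GWAS in the full
# population (the role of an HF GWAS consortium),
# (iii) a case-only progression GWAS exhibiting collider bias by
# construction (liability-threshold selection), and (iv) a survival
# cohort of cases with protein-dependent hazards and clinical covariates.
# Everything is deterministic given the config seed (R's default
# Mersenne-Twister RNG; child seeds are derived once from the master
# seed).

#' Simulation configuration
#'
#' Defaults mirror the scale of a single-center heart-failure cohort with
#' aptamer proteomics: a ~2,000-subject case cohort with roughly 50%
#' composite death-or-HF-hospitalization (DHFA) events and 25% deaths, a
#' 30,000-sample external pQTL study, and a 20,000-sample population for
#' the incidence and case-only outcome GWAS. Proteins live on separate
#' chromosomes, each with an LD-structured cis locus; HF-risk variants
#' occupy their own block.
#'
#' @param n_proteins Number of proteins.
#' @param m_cis Variants per cis locus.
#' @param n_causal_cis Causal cis variants per protein.
#' @param n_hf_variants HF-risk variants (incidence-only block).
#' @param n_pop Population size for incidence + case-only outcome GWAS.
#' @param n_pqtl Sample size of the external pQTL study.
#' @param n_ref Reference-panel size for LD matrices.
#' @param n_cohort Cases entering the survival cohort (capped at the
#'   number of selected cases).
#' @param maf Minor-allele-frequency range (uniform per variant).
#' @param ld_decay AR(1) latent-Gaussian LD parameter in `[0, 1)`.
#' @param h2_cis Cis heritability of each protein.
#' @param hf_h2 Liability variance explained by the HF-risk block.
#' @param protein_liability Per-protein effect of the (standardized)
#'   protein on HF liability; recycled to `n_proteins`.
#' @param causal_theta Per-protein log hazard/odds ratio of the
#'   standardized protein on progression; recycled to `n_proteins`.
#' @param selection_strength Weight of liability in the probit case
#'   inclusion score (0 = random sampling, no collider bias).
#' @param case_frac Fraction of the population entering the case pool.
#' @param severity_env_weight Effect of the environmental liability
#'   component on the progression log-odds; this is what turns
#'   liability-threshold selection into collider bias.
#' @param death_rate,dhfa_rate Target crude event fractions in the
#'   cohort.
#' @param followup_days Administrative follow-up horizon.
#' @param pleiotropy `"none"`, `"balanced"`, or `"directional"`: direct
#'   (non-protein-mediated) outcome effects of the cis instruments.
#' @param pleiotropy_delta Log-odds size of the pleiotropic effects.
#' @param seed Master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_proteins = 20L, m_cis = 15L, n_causal_cis = 2L,
                       n_hf_variants = 60L, n_pop = 20000L,
                       n_pqtl = 30000L, n_ref = 2000L, n_cohort = 2000L,
                       maf = c(0.1, 0.5), ld_decay = 0.6, h2_cis = 0.05,
                       hf_h2 = 0.3, protein_liability = 0.1,
                       causal_theta = 0, selection_strength = 2,
                       case_frac = 0.25, severity_env_weight = 0.8,
                       death_rate = 0.25, dhfa_rate = 0.5,
                       followup_days = 1500, pleiotropy = "none",
                       pleiotropy_delta = 0, seed = 1L) {
  cfg <- list(
    n_proteins = as.integer(n_proteins), m_cis = as.integer(m_cis),
    n_causal_cis = as.integer(n_causal_cis),
    n_hf_variants = as.integer(n_hf_variants),
    n_pop = as.integer(n_pop), n_pqtl = as.integer(n_pqtl),
    n_ref = as.integer(n_ref), n_cohort = as.integer(n_cohort),
    maf = maf, ld_decay = ld_decay, h2_cis = h2_cis, hf_h2 = hf_h2,
    protein_liability = rep_len(protein_liability, n_proteins),
    causal_theta = rep_len(causal_theta, n_proteins),
    selection_strength = selection_strength, case_frac = case_frac,
    severity_env_weight = severity_env_weight,
    death_rate = death_rate, dhfa_rate = dhfa_rate,
    followup_days = followup_days,
    pleiotropy = match.arg(pleiotropy,
                           c("none", "balanced", "directional")),
    pleiotropy_delta = pleiotropy_delta,
    seed = as.integer(seed)
  )
  if (any(c(cfg$n_pop, cfg$n_pqtl, cfg$n_ref) <= 0)) {
    abort("Sample sizes must be positive.", class = "proteomr_config_error")
  }
  if (cfg$maf[1] <= 0 || max(cfg$maf) > 0.5) {
    abort("MAF must lie in (0, 0.5].", class = "proteomr_config_error")
  }
  if (cfg$ld_decay < 0 || cfg$ld_decay >= 1) {
    abort("`ld_decay` must be in [0, 1).", class = "proteomr_config_error")
  }
  if (cfg$h2_cis < 0 || cfg$h2_cis >= 1) {
    abort("`h2_cis` must be in [0, 1).", class = "proteomr_config_error")
  }
  protein_var <- sum(cfg$protein_liability^2)
  if (cfg$hf_h2 + protein_var >= 1) {
    abort("hf_h2 + sum(protein_liability^2) must be < 1 so the liability has positive environmental variance.",
          class = "proteomr_config_error")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate LD-structured genotype dosages
#'
#' Variants are drawn from a latent AR(1) Gaussian, thresholded to
#' haplotype alleles at each variant's MAF; dosage = sum of two
#' independent haplotypes, so Hardy-Weinberg holds. Thresholding
#' attenuates latent correlation, so the latent AR(1) parameter is set
#' to `sin(pi/2 * ld_decay)`; the realized adjacent dosage correlation
#' is then approximately `ld_decay` itself (exact under a median split,
#' slightly lower for asymmetric or unequal MAFs). Rare monomorphic
#' columns (possible at
#' small n) are made polymorphic by flipping one genotype so every
#' variant is usable downstream.
#'
#' @param n Number of subjects.
#' @param m Number of variants.
#' @param maf Scalar MAF or range (uniform per variant).
#' @param ld_decay AR(1) latent correlation in `[0, 1)`.
#' @param seed Seed.
#' @param chrom,pos_start,pos_step,variant_prefix Coordinates and naming
#'   for the emitted variant table.
#' @return List with `G` (n x m dosage matrix), `info` (tibble:
#'   `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `maf`, `eaf`), and `R` (empirical LD of the dosages).
#' @export
simulate_genotypes <- function(n, m, maf = c(0.1, 0.5), ld_decay = 0.6,
                               seed = 1L, chrom = "1", pos_start = 1e6,
                               pos_step = 5000,
                               variant_prefix = paste0("rs", chrom, "_")) {
  out <- withr::with_seed(seed, {
    mafs <- if (length(maf) == 2L) runif(m, maf[1], maf[2]) else rep_len(maf, m)
    thresh <- matrix(qnorm(mafs), n, m, byrow = TRUE)
    # the dial targets the *dosage-scale* adjacent correlation; the
    # latent AR(1) parameter is inflated by the inverse of the
    # median-split attenuation (phi = (2/pi) asin(rho)) so thresholding
    # brings it back down to roughly ld_decay
    rho_lat <- sin(pi / 2 * ld_decay)
    hap <- function() {
      Z <- matrix(rnorm(n * m), n, m)
      if (rho_lat > 0 && m > 1L) {
        for (j in 2:m) {
          Z[, j] <- rho_lat * Z[, j - 1] + sqrt(1 - rho_lat^2) * Z[, j]
        }
      }
      (Z < thresh) + 0
    }
    G <- hap() + hap()
    list(G = G, mafs = mafs)
  })
  G <- out$G
  mono <- which(apply(G, 2, var) == 0)
  for (j in mono) G[1, j] <- if (G[1, j] > 0) G[1, j] - 1 else 1
  ids <- paste0(variant_prefix, seq_len(m))
  colnames(G) <- ids
  info <- tibble(
    variant_id = ids, chrom = chrom,
    pos = as.integer(pos_start + (seq_len(m) - 1L) * pos_step),
    effect_allele = "A", other_allele = "G",
    maf = out$mafs, eaf = colMeans(G) / 2
  )
  R <- suppressWarnings(ld_from_genotypes(G, ids))
  list(G = G, info = info, R = R)
}

# Vectorized marginal regression of a quantitative trait on every dosage
# column (simple OLS per variant).
marginal_quant <- function(G, y) {
  n <- nrow(G)
  gc <- scale(G, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(gc^2)
  sxy <- drop(crossprod(gc, yc))
  beta <- unname(sxy / sxx)
  sse <- pmax(sum(yc^2) - beta * unname(sxy), 0)
  se <- unname(sqrt(sse / ((n - 2) * sxx)))
  tibble(beta = beta, se = se, pvalue = pnorm2(beta, se))
}

# Vectorized marginal log-odds association of a binary trait with every
# dosage column: one-step score-test approximation to logistic
# regression, beta = cov(g, y) / (var(g) * pbar (1 - pbar)),
# se = 1 / sqrt(n var(g) pbar (1 - pbar)).
marginal_binary <- function(G, y) {
  n <- nrow(G)
  pbar <- mean(y)
  phi <- pbar * (1 - pbar)
  gc <- scale(G, center = TRUE, scale = FALSE)
  sxx <- colSums(gc^2)
  sxy <- drop(crossprod(gc, y - pbar))
  beta <- unname(sxy / (sxx * phi))
  se <- unname(1 / sqrt(sxx * phi))
  tibble(beta = beta, se = se, pvalue = pnorm2(beta, se))
}

assoc_from_marginal <- function(info, marg, n, trait_id) {
  tibble(
    variant_id = info$variant_id, chrom = info$chrom, pos = info$pos,
    effect_allele = info$effect_allele, other_allele = info$other_allele,
    eaf = info$eaf, beta = marg$beta, se = marg$se,
    pvalue = pmax(marg$pvalue, 1e-300), n = as.integer(n),
    trait_id = trait_id
  )
}

#' Simulate an external pQTL study for one protein
#'
#' The protein is the genetic score of the causal cis variants, scaled to
#' cis heritability `h2`, plus independent noise; per-variant marginal
#' regressions over the locus are emitted as association records.
#'
#' @param G Dosage matrix for the locus (the pQTL sample).
#' @param info Variant table from [simulate_genotypes()].
#' @param effects Per-variant causal effect weights (length `ncol(G)`;
#'   zeros for non-causal variants).
#' @param h2 Cis heritability in `[0, 1)`; `h2 > 0` requires a nonzero
#'   effect vector.
#' @param protein_id Trait label for the emitted records.
#' @param seed Seed for the environmental noise.
#' @return Tibble of association records (validated).
#' @export
simulate_pqtl_study <- function(G, info, effects, h2, protein_id,
                                seed = 1L) {
  if (length(effects) != ncol(G)) {
    abort("`effects` length must match the number of variants.",
          class = "proteomr_config_error")
  }
  g <- drop(G %*% effects)
  vg <- var(g)
  if (h2 > 0 && vg == 0) {
    abort("h2 > 0 but the causal effects give zero genetic variance.",
          class = "proteomr_config_error")
  }
  y <- withr::with_seed(seed, {
    gen <- if (h2 > 0) (g - mean(g)) * sqrt(h2 / vg) else 0
    gen + rnorm(nrow(G), 0, sqrt(1 - h2))
  })
  marg <- marginal_quant(G, y)
  suppressMessages(validate_sumstats(
    assoc_from_marginal(info, marg, nrow(G), protein_id)))
}

#' Simulate the full synthetic study bundle
#'
#' Runs the whole generative model of [sim_config()] and returns every
#' pipeline input: gene loci, per-protein pQTL summary statistics,
#' reference LD, the population incidence GWAS, case-only outcome GWAS
#' for death and DHFA (collider-biased whenever
#' `selection_strength > 0` and the progression outcome depends on the
#' environmental liability component), the case survival cohort with
#' covariates and a positive protein abundance matrix, and a truth list.
#'
#' The selection model is probit: inclusion score
#' `U = selection_strength * L + eps`, `eps ~ N(0, 1)`; the top
#' `case_frac` of `U` become cases. Progression log-odds are
#' `causal_theta' P + severity_env_weight * e` where `e` is the
#' environmental component of liability `L`; survival times are
#' exponential with the same linear predictor and administrative
#' censoring calibrated to the target crude event rates.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_bundle`: list with `config`, `loci`,
#'   `exposure` (pQTL records, all proteins), `ld` (named list of LD
#'   matrices per locus plus `"hf"`), `incidence_gwas`, `outcome_gwas`
#'   (list `death`, `dhfa`), `cohort`, `proteins_raw`, `truth`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  seeds <- derive_seeds(cfg$seed, 8L + 2L * cfg$n_proteins)
  protein_ids <- sprintf("P%02d", seq_len(cfg$n_proteins))

  # --- loci: one chromosome per protein, gene body to the right of the
  # variant run so every locus variant is cis within the default window.
  loci <- tibble(
    gene = paste0("GENE", seq_len(cfg$n_proteins)),
    chrom = as.character(seq_len(cfg$n_proteins)),
    start = 1200000L, end = 1210000L,
    protein_id = protein_ids
  )

  # causal cis variants spread evenly across the locus: independent
  # association signals rather than one LD-shared block
  causal_idx <- unique(round(seq(1, cfg$m_cis,
                                 length.out = min(cfg$n_causal_cis,
                                                  cfg$m_cis))))
  effect_template <- rep(0, cfg$m_cis)
  effect_template[causal_idx] <- 1

  # --- external pQTL study + reference LD, per protein
  exposure <- vector("list", cfg$n_proteins)
  ld <- list()
  ref_geno <- vector("list", cfg$n_proteins)
  for (i in seq_len(cfg$n_proteins)) {
    gp <- simulate_genotypes(cfg$n_pqtl, cfg$m_cis, maf = cfg$maf,
                             ld_decay = cfg$ld_decay,
                             seed = seeds[8L + i], chrom = loci$chrom[i],
                             pos_start = 1e6, pos_step = 10000,
                             variant_prefix = paste0("rs", i, "_"))
    exposure[[i]] <- simulate_pqtl_study(
      gp$G, gp$info, effect_template, cfg$h2_cis, protein_ids[i],
      seed = seeds[8L + cfg$n_proteins + i])
    ref <- simulate_genotypes(cfg$n_ref, cfg$m_cis, maf = cfg$maf,
                              ld_decay = cfg$ld_decay,
                              seed = seeds[8L + i] + 1L,
                              chrom = loci$chrom[i], pos_start = 1e6,
                              pos_step = 10000,
                              variant_prefix = paste0("rs", i, "_"))
    ld[[protein_ids[i]]] <- ref$R
    ref_geno[[i]] <- gp$info
  }
  exposure <- bind_rows(exposure)

  # --- two independent populations with the same architecture: one for
  # the external disease-risk (incidence) GWAS, one whose selected cases
  # supply the outcome GWAS and the survival cohort
  draw_population <- function(seed) {
    withr::with_seed(seed, {
      locus_G <- map(seq_len(cfg$n_proteins), function(i) {
        simulate_genotypes(cfg$n_pop, cfg$m_cis, maf = cfg$maf,
                           ld_decay = cfg$ld_decay,
                           seed = sample.int(.Machine$integer.max - 1L, 1L),
                           chrom = loci$chrom[i], pos_start = 1e6,
                           pos_step = 10000,
                           variant_prefix = paste0("rs", i, "_"))
      })
      hf <- simulate_genotypes(cfg$n_pop, cfg$n_hf_variants, maf = cfg$maf,
                               ld_decay = 0,
                               seed = sample.int(.Machine$integer.max - 1L, 1L),
                               chrom = "hf", pos_start = 5e7,
                               pos_step = 20000, variant_prefix = "rshf_")
      list(locus_G = locus_G, hf = hf)
    })
  }
  pop <- draw_population(seeds[1])
  pop_inc <- draw_population(seeds[4])
  hf_ref <- simulate_genotypes(cfg$n_ref, cfg$n_hf_variants,
                               maf = cfg$maf, ld_decay = 0,
                               seed = seeds[2], chrom = "hf",
                               pos_start = 5e7, pos_step = 20000,
                               variant_prefix = "rshf_")
  ld[["hf"]] <- hf_ref$R

  # equal-magnitude, random-sign liability effects for the HF block: it
  # emulates the clumped genome-wide-significant HF risk loci, which are
  # detectable by construction
  a <- withr::with_seed(seeds[5],
                        sample(c(-1, 1), cfg$n_hf_variants, replace = TRUE))

  # shared generative model: proteins, liability, probit case selection
  liability_model <- function(popX, seed) {
    withr::with_seed(seed, {
      n <- cfg$n_pop
      P <- matrix(0, n, cfg$n_proteins)
      for (i in seq_len(cfg$n_proteins)) {
        g <- drop(popX$locus_G[[i]]$G %*% effect_template)
        gen <- if (cfg$h2_cis > 0) (g - mean(g)) * sqrt(cfg$h2_cis / var(g)) else 0
        P[, i] <- gen + rnorm(n, 0, sqrt(1 - cfg$h2_cis))
      }
      g_hf <- drop(popX$hf$G %*% a)
      g_hf <- (g_hf - mean(g_hf)) * sqrt(cfg$hf_h2 / var(g_hf))
      env_var <- 1 - cfg$hf_h2 - sum(cfg$protein_liability^2)
      e <- rnorm(n, 0, sqrt(env_var))
      L <- g_hf + drop(P %*% cfg$protein_liability) + e
      U <- cfg$selection_strength * L + rnorm(n)
      is_case <- U > quantile(U, 1 - cfg$case_frac)
      list(P = P, e = e, L = L, is_case = is_case)
    })
  }
  inc_model <- liability_model(pop_inc, seeds[6])

  sim <- withr::with_seed(seeds[3], {
    n <- cfg$n_pop
    base <- liability_model(pop, seeds[7])
    P <- base$P; e <- base$e; L <- base$L; is_case <- base$is_case
    # progression among cases
    case_idx <- which(is_case)
    lp <- drop(P[case_idx, , drop = FALSE] %*% cfg$causal_theta) +
      cfg$severity_env_weight * e[case_idx]
    if (cfg$pleiotropy != "none" && cfg$pleiotropy_delta != 0) {
      for (i in seq_len(cfg$n_proteins)) {
        gdir <- drop(pop$locus_G[[i]]$G[case_idx, causal_idx, drop = FALSE] %*%
                       rep(1, length(causal_idx)))
        sgn <- if (cfg$pleiotropy == "balanced") sample(c(-1, 1), 1) else 1
        lp <- lp + sgn * cfg$pleiotropy_delta * scale(gdir)[, 1]
      }
    }
    lp <- lp - mean(lp)
    n_case <- length(case_idx)
    tau <- cfg$followup_days
    lam_death <- -log(1 - cfg$death_rate) / tau
    lam_total <- -log(1 - cfg$dhfa_rate) / tau
    lam_hosp <- max(lam_total - lam_death, 1e-6 / tau)
    t_death <- rexp(n_case, lam_death * exp(lp))
    t_hosp <- rexp(n_case, lam_hosp * exp(lp))
    cens <- runif(n_case, 0.6 * tau, tau)
    time_death <- pmin(t_death, cens)
    event_death <- as.numeric(t_death <= cens)
    t_dhfa <- pmin(t_death, t_hosp)
    time_dhfa <- pmin(t_dhfa, cens)
    event_dhfa <- as.numeric(t_dhfa <= cens)
    # progression outcome for the case-only GWAS: logistic, so the true
    # per-SD-protein effect is causal_theta on the log-odds scale (the
    # scale MR odds ratios are reported on); the survival times above
    # carry the same linear predictor for the cohort screen
    y_death <- rbinom(n_case, 1, stats::plogis(stats::qlogis(cfg$death_rate) + lp))
    y_dhfa <- rbinom(n_case, 1, stats::plogis(stats::qlogis(cfg$dhfa_rate) + lp))
    # covariates: clinical risk score and log natriuretic peptide,
    # correlated with severity but noisy
    maggic <- 25 + 4 * scale(0.7 * L[case_idx] + rnorm(n_case))[, 1]
    log_nt <- 6 + 1.1 * scale(0.6 * lp + 0.8 * rnorm(n_case))[, 1]
    list(P = P, e = e, L = L, is_case = is_case, case_idx = case_idx,
         time_death = time_death, event_death = event_death,
         time_dhfa = time_dhfa, event_dhfa = event_dhfa,
         y_death = y_death, y_dhfa = y_dhfa,
         maggic = maggic, log_nt = log_nt)
  })

  case_idx <- sim$case_idx
  n_case <- length(case_idx)
  if (n_case < 500L) {
    abort(sprintf("Selection left only %d cases (< 500); weaken selection or enlarge n_pop.",
                  n_case), class = "proteomr_config_error")
  }

  all_info <- bind_rows(c(map(pop$locus_G, "info"), list(pop$hf$info)))
  G_all <- do.call(cbind, c(map(pop$locus_G, "G"), list(pop$hf$G)))

  incidence_gwas <- suppressMessages(validate_sumstats(assoc_from_marginal(
    all_info, marginal_binary(G_all, as.numeric(sim$is_case)),
    cfg$n_pop, "hf_incidence")))
  G_case <- G_all[case_idx, , drop = FALSE]
  outcome_gwas <- list(
    death = suppressMessages(validate_sumstats(assoc_from_marginal(
      all_info, marginal_binary(G_case, sim$y_death), n_case, "death"))),
    dhfa = suppressMessages(validate_sumstats(assoc_from_marginal(
      all_info, marginal_binary(G_case, sim$y_dhfa), n_case, "dhfa")))
  )

  # --- survival cohort: first n_cohort cases with proteomics
  n_coh <- min(cfg$n_cohort, n_case)
  coh <- seq_len(n_coh)
  subject_id <- sprintf("S%05d", seq_len(n_coh))
  cohort <- tibble(
    subject_id = subject_id,
    time_death = sim$time_death[coh], event_death = sim$event_death[coh],
    time_dhfa = sim$time_dhfa[coh], event_dhfa = sim$event_dhfa[coh],
    maggic = sim$maggic[coh], log_ntprobnp = sim$log_nt[coh]
  )
  Pz <- t(sim$P[case_idx[coh], , drop = FALSE])
  rownames(Pz) <- protein_ids
  colnames(Pz) <- subject_id
  proteins_raw <- exp(5 + 0.6 * Pz)

  # empirical collider slope among the incidence-only HF variants: the
  # value the cluster-then-slope fit should recover
  hf_ids <- pop$hf$info$variant_id
  b_inc <- incidence_gwas$beta[match(hf_ids, incidence_gwas$variant_id)]
  b_out <- outcome_gwas$dhfa$beta[match(hf_ids, outcome_gwas$dhfa$variant_id)]
  slope_emp <- sum(b_inc * b_out) / sum(b_inc^2)

  structure(list(
    config = cfg, loci = loci, exposure = exposure, ld = ld,
    incidence_gwas = incidence_gwas, outcome_gwas = outcome_gwas,
    cohort = cohort, proteins_raw = proteins_raw,
    truth = list(
      protein_ids = protein_ids,
      causal_theta = setNames(cfg$causal_theta, protein_ids),
      protein_liability = setNames(cfg$protein_liability, protein_ids),
      causal_cis_index = causal_idx,
      n_cases = n_case,
      collider_slope_empirical = slope_emp
    )
  ), class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf(
    "Synthetic study bundle: %d proteins, %d cases (of %d), %d pQTL samples\n",
    x$config$n_proteins, x$truth$n_cases, x$config$n_pop, x$config$n_pqtl))
  invisible(x)
}

#' Write a simulated bundle to plain-text files
#'
#' Writes the cohort (TSV), protein matrix (TSV), pQTL / incidence /
#' outcome summary statistics (TSV), loci (TSV), LD matrices (TSV), and
#' the truth list (JSON) into a directory.
#'
#' @param bundle A `sim_bundle` from [simulate_study()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(bundle$cohort, file.path(dir, "cohort.tsv"),
                   progress = FALSE)
  pm <- as_tibble(as.data.frame(bundle$proteins_raw), rownames = "protein_id")
  readr::write_tsv(pm, file.path(dir, "proteins.tsv"), progress = FALSE)
  write_sumstats(bundle$exposure, file.path(dir, "pqtl.tsv"))
  write_sumstats(bundle$incidence_gwas, file.path(dir, "incidence_gwas.tsv"))
  write_sumstats(bundle$outcome_gwas$death,
                 file.path(dir, "outcome_death.tsv"))
  write_sumstats(bundle$outcome_gwas$dhfa, file.path(dir, "outcome_dhfa.tsv"))
  readr::write_tsv(bundle$loci, file.path(dir, "loci.tsv"), progress = FALSE)
  for (nm in names(bundle$ld)) {
    write_ld_matrix(bundle$ld[[nm]], file.path(dir, paste0("ld_", nm, ".tsv")))
  }
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
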