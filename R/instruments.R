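# Instrument selection for protein exposures: cis/trans classification
# around the protein-encoding gene, genome-wide-significance filtering,
# greedy LD clumping, and instrument-strength diagnostics.

# Extended MHC region (GRCh37 chr6); trans instruments falling here are
# excluded because its extreme LD and pleiotropy make them unreliable.
MHC_REGION <- list(chrom = c("6", "chr6"), start = 25e6, end = 34e6)

#' Select candidate pQTL instruments for a protein
#'
#' Classifies variants as cis (same chromosome as the protein-encoding
#' gene and within `window_bp` of the gene body, inclusive bounds) or
#' trans (everything else), keeps those with association p-value strictly
#' below `p_threshold`, and restricts to the requested scope. Trans
#' variants in the extended MHC region (chr6:25-34 Mb) are excluded.
#'
#' @param pqtls Tibble of pQTL association records for one protein.
#' @param locus One-row tibble/list with `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive), as from [read_gene_loci()].
#' @param window_bp Cis window half-width in base pairs around the gene
#'   body. Default 500,000.
#' @param p_threshold Genome-wide significance cutoff (strict `<`).
#'   Default 5e-8.
#' @param scope `"cis"`, `"trans"`, or `"both"`.
#' @return The retained records with an added `cis_trans` column. Zero
#'   rows (with a message) when the protein has no qualifying pQTLs.
#' @export
select_instruments <- function(pqtls, locus, window_bp = 5e5,
                               p_threshold = 5e-8,
                               scope = c("cis", "trans", "both")) {
  scope <- match.arg(scope)
  stopifnot_scalar_number(window_bp, "window_bp", 0)
  stopifnot_scalar_number(p_threshold, "p_threshold", 0, 1)
  pqtls <- as_tibble(pqtls)
  locus <- as.list(locus)
  if (scope != "trans" && !any(pqtls$chrom == locus$chrom)) {
    inform(sprintf("Locus chromosome %s absent from pQTL records.",
                   locus$chrom))
  }
  lo <- locus$start - window_bp
  hi <- locus$end + window_bp
  is_cis <- pqtls$chrom == locus$chrom & pqtls$pos >= lo & pqtls$pos <= hi
  out <- mutate(pqtls, cis_trans = if_else(is_cis, "cis", "trans"))
  out <- filter(out, .data$pvalue < p_threshold)
  in_mhc <- out$chrom %in% MHC_REGION$chrom &
    out$pos >= MHC_REGION$start & out$pos <= MHC_REGION$end
  out <- filter(out, !(.data$cis_trans == "trans" & in_mhc))
  out <- switch(scope,
                cis = filter(out, .data$cis_trans == "cis"),
                trans = filter(out, .data$cis_trans == "trans"),
                both = out)
  if (nrow(out) == 0L) {
    inform(sprintf("No instruments for locus %s at p < %g (scope %s).",
                   locus$gene %||% "?", p_threshold, scope))
  }
  out
}

#' Greedy LD clumping of candidate instruments
#'
#' Sorts candidates by ascending p-value (variant id as tie-break) and
#' accepts each variant iff its squared correlation with every
#' already-accepted variant is below `r2_threshold`. Deterministic and
#' invariant to input row order.
#'
#' @param candidates Tibble of association records (needs `variant_id`,
#'   `pvalue`).
#' @param ld LD correlation matrix covering all candidate variants
#'   (dimnames = variant ids).
#' @param r2_threshold Squared-correlation cutoff. Default 0.1: correlated
#'   instruments are retained and modelled through the LD matrix
#'   downstream, so clumping is only a light pre-filter for numerical
#'   stability of the GLS inverse.
#' @return The retained rows of `candidates`, in acceptance order.
#' @export
clump_instruments <- function(candidates, ld, r2_threshold = 0.1) {
  stopifnot_scalar_number(r2_threshold, "r2_threshold", 0, 1)
  candidates <- as_tibble(candidates)
  if (nrow(candidates) == 0L) return(candidates)
  missing_ld <- setdiff(candidates$variant_id, rownames(ld))
  if (length(missing_ld) > 0L) {
    abort(sprintf("LD matrix lacks %d candidate variant(s): %s",
                  length(missing_ld),
                  paste(utils::head(missing_ld, 5), collapse = ", ")),
          class = "proteomr_config_error")
  }
  ord <- order(candidates$pvalue, candidates$variant_id)
  sorted <- candidates[ord, ]
  accepted <- character(0)
  for (v in sorted$variant_id) {
    if (length(accepted) == 0L ||
        all(ld[v, accepted]^2 < r2_threshold)) {
      accepted <- c(accepted, v)
    }
  }
  filter(sorted, .data$variant_id %in% accepted)
}

#' Build a harmonized instrument set for one protein
#'
#' Harmonizes the (selected, clumped) exposure records against the outcome
#' records, subsets the LD matrix to the retained variants (the LD matrix
#' is assumed signed with respect to the exposure effect alleles, the
#' convention [ld_from_genotypes()] produces when dosages count the
#' exposure effect allele), and computes the mean F statistic
#' `mean((bx/sx)^2)`. Sets with mean F <= 10 are flagged weak.
#'
#' @param protein_id Protein identifier.
#' @param exposure Selected + clumped exposure records (with `cis_trans`
#'   column when available).
#' @param outcome Outcome association records.
#' @param ld LD correlation matrix covering the exposure variants.
#' @param palindromic_eaf_band Passed to [harmonize_sumstats()].
#' @return An object of class `instrument_set` (list with `protein_id`,
#'   `data` tibble of aligned `bx`, `sx`, `by`, `sy`, `cis_trans`, the LD
#'   submatrix `R`, `mean_F`, `weak`), or `NULL` (with a message) when no
#'   variant harmonizes.
#' @export
build_instrument_set <- function(protein_id, exposure, outcome, ld,
                                 palindromic_eaf_band = 0.08) {
  exposure <- as_tibble(exposure)
  h <- tryCatch(
    harmonize_sumstats(exposure, outcome,
                       palindromic_eaf_band = palindromic_eaf_band),
    proteomr_empty_overlap_error = function(e) NULL
  )
  if (!is.null(h)) h <- filter(h, .data$action %in% c("kept", "flipped"))
  if (is.null(h) || nrow(h) == 0L) {
    inform(sprintf("Protein %s: no harmonized instruments.", protein_id))
    return(NULL)
  }
  ct <- if ("cis_trans" %in% names(exposure)) {
    exposure$cis_trans[match(h$variant_id, exposure$variant_id)]
  } else rep(NA_character_, nrow(h))
  data <- mutate(h, cis_trans = ct)
  R <- if (is.null(ld)) {
    diag(nrow(data))
  } else {
    missing_ld <- setdiff(data$variant_id, rownames(ld))
    if (length(missing_ld) > 0L) {
      abort(sprintf("LD matrix lacks instrument variant(s): %s",
                    paste(missing_ld, collapse = ", ")),
            class = "proteomr_config_error")
    }
    ld[data$variant_id, data$variant_id, drop = FALSE]
  }
  dimnames(R) <- list(data$variant_id, data$variant_id)
  mean_F <- mean((data$bx / data$sx)^2)
  structure(list(
    protein_id = protein_id,
    data = select(data, "variant_id", "chrom", "pos", "effect_allele",
                  "other_allele", "bx", "sx", "by", "sy", "cis_trans"),
    R = R,
    mean_F = mean_F,
    weak = mean_F <= 10
  ), class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set for %s: %d variant(s), mean F = %.1f%s\n",
              x$protein_id, nrow(x$data), x$mean_F,
              if (x$weak) " [weak]" else ""))
  invisible(x)
}

#' @export
tidy.instrument_set <- function(x, ...) {
  mutate(x$data, protein_id = x$protein_id,
         F_stat = (.data$bx / .data$sx)^2)
}

#' @export
glance.instrument_set <- function(x, ...) {
  tibble(protein_id = x$protein_id, n_instruments = nrow(x$data),
         n_cis = sum(x$data$cis_trans == "cis", na.rm = TRUE),
         mean_F = x$mean_F, weak = x$weak)
}
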