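# Reading, validation, harmonization, and LD handling for GWAS/pQTL
# summary statistics. All positions are 1-based inclusive, the usual
# GWAS summary-statistic convention; BED-style locus input is converted
# on read.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Read GWAS or pQTL summary statistics
#'
#' Reads a delimited summary-statistics file into a validated tibble of
#' association records, one row per variant. Each record carries the
#' variant's effect-allele convention: `beta` is the per-allele effect of
#' `effect_allele` (trait units for quantitative traits, log-odds for
#' case-control traits).
#'
#' Rows with a nonpositive standard error or a missing effect estimate are
#' rejected (not an error); the rejected rows and their reasons are attached
#' as the `"rejects"` attribute. Rows whose p-value disagrees with the
#' normal approximation `2 * pnorm(-|beta/se|)` by more than two orders of
#' magnitude trigger a warning but are kept.
#'
#' @param path Path to a tab- or comma-delimited file with a header row.
#' @param trait_id Label stored in the `trait_id` column of the result.
#' @param column_map Named character vector mapping canonical field names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`, `n`) to the file's column names. Fields absent
#'   from the map are looked up under their canonical names; `eaf` and `n`
#'   are optional.
#' @param delim Field delimiter; guessed from the first line when `NULL`.
#'
#' @return A tibble of association records with columns
#'   `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`, `n`, `trait_id`, in file order.
#' @export
read_sumstats <- function(path, trait_id, column_map = NULL, delim = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("Summary-statistics file not found: %s", path),
          class = "proteomr_config_error")
  }
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  canonical <- c("variant_id", "chrom", "pos", "effect_allele",
                 "other_allele", "eaf", "beta", "se", "pvalue", "n")
  map <- setNames(canonical, canonical)
  if (!is.null(column_map)) map[names(column_map)] <- unname(column_map)
  mandatory <- setdiff(canonical, c("eaf", "n"))
  missing_cols <- mandatory[!map[mandatory] %in% names(raw)]
  if (length(missing_cols) > 0L) {
    abort(sprintf("Missing mandatory column(s): %s (file has: %s)",
                  paste(map[missing_cols], collapse = ", "),
                  paste(names(raw), collapse = ", ")),
          class = "proteomr_config_error")
  }
  out <- tibble(
    variant_id   = as.character(raw[[map["variant_id"]]]),
    chrom        = as.character(raw[[map["chrom"]]]),
    pos          = as.integer(raw[[map["pos"]]]),
    effect_allele = toupper(as.character(raw[[map["effect_allele"]]])),
    other_allele  = toupper(as.character(raw[[map["other_allele"]]])),
    eaf    = if (map["eaf"] %in% names(raw)) as.numeric(raw[[map["eaf"]]]) else NA_real_,
    beta   = as.numeric(raw[[map["beta"]]]),
    se     = as.numeric(raw[[map["se"]]]),
    pvalue = as.numeric(raw[[map["pvalue"]]]),
    n      = if (map["n"] %in% names(raw)) as.integer(raw[[map["n"]]]) else NA_integer_,
    trait_id = trait_id
  )
  validate_sumstats(out)
}

#' Validate a tibble of association records
#'
#' Applies the record invariants: positive SE, non-missing effect, p-value in
#' (0, 1]. Invalid rows are removed and returned in the `"rejects"`
#' attribute with a `reject_reason` column. P-values inconsistent with
#' `|beta/se|` under a normal approximation by more than two orders of
#' magnitude raise a warning.
#'
#' @param records Tibble with the association-record columns.
#' @return The validated tibble (row order preserved).
#' @export
validate_sumstats <- function(records) {
  records <- as_tibble(records)
  missing <- setdiff(assoc_cols, names(records))
  if (length(missing) > 0L) {
    abort(sprintf("Records are missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "proteomr_config_error")
  }
  records <- records[assoc_cols]
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(records$beta)] <- "missing_beta"
  reason[is.na(records$se) | records$se <= 0] <- "nonpositive_se"
  bad_p <- !is.na(records$pvalue) & (records$pvalue <= 0 | records$pvalue > 1)
  reason[is.na(reason) & bad_p] <- "pvalue_out_of_range"
  rejects <- records[!is.na(reason), ]
  if (nrow(rejects) > 0L) {
    rejects$reject_reason <- reason[!is.na(reason)]
    inform(sprintf("Rejected %d invalid record(s): %s", nrow(rejects),
                   paste(unique(rejects$reject_reason), collapse = ", ")))
  }
  kept <- records[is.na(reason), ]
  if (nrow(kept) == 0L) {
    abort("No valid summary-statistic records after validation.",
          class = "proteomr_empty_input_error")
  }
  expected_p <- pnorm2(kept$beta, kept$se)
  ok <- is.na(kept$pvalue) | expected_p == 0 | kept$pvalue == 0 |
    abs(log10(kept$pvalue) - log10(pmax(expected_p, 1e-300))) <= 2
  if (any(!ok)) {
    warn(sprintf(
      "%d record(s) have p-values inconsistent with |beta/se| by >2 orders of magnitude.",
      sum(!ok)))
  }
  attr(kept, "rejects") <- rejects
  kept
}

#' Write association records to a tab-delimited file
#'
#' Numeric columns are written with full (round-trip) precision.
#' @param records Tibble of association records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(records, path) {
  readr::write_tsv(records[assoc_cols], path, progress = FALSE)
  invisible(path)
}

#' Read gene/protein locus annotations
#'
#' Reads a BED-like table (`chrom`, `start`, `end`, `gene`, and optionally
#' `protein_id`) with 0-based half-open coordinates, and converts to 1-based
#' inclusive coordinates. Files with a header naming the columns are also
#' accepted, in any order.
#'
#' @param path Path to a tab-delimited locus file.
#' @param zero_based Is the input BED-style 0-based half-open? Default `TRUE`.
#' @return Tibble with columns `gene`, `chrom`, `start`, `end`, `protein_id`
#'   (1-based inclusive).
#' @export
read_gene_loci <- function(path, zero_based = TRUE) {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  # header row iff the second field is not a coordinate
  has_header <- length(first) >= 2L && is.na(suppressWarnings(as.numeric(first[2])))
  if (has_header) {
    raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE)
    names(raw) <- c("chrom", "start", "end", "gene",
                    "protein_id")[seq_len(ncol(raw))]
  }
  if (!"protein_id" %in% names(raw)) raw$protein_id <- raw$gene
  out <- tibble(
    gene = as.character(raw$gene),
    chrom = as.character(raw$chrom),
    start = as.integer(raw$start) + if (zero_based) 1L else 0L,
    end = as.integer(raw$end),
    protein_id = as.character(raw$protein_id)
  )
  bad <- out$start > out$end | !nzchar(out$chrom)
  if (any(bad)) {
    abort(sprintf("%d locus record(s) violate start <= end / nonempty chrom.",
                  sum(bad)), class = "proteomr_config_error")
  }
  out
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome effects to the exposure's effect allele for every variant
#' shared between the two sets. The outcome beta is sign-flipped when the
#' outcome effect allele equals the exposure other allele; a strand flip
#' (A<->T, C<->G) is attempted before a variant is declared an allele
#' mismatch. Palindromic variants (A/T or C/G) are kept only when both
#' allele frequencies are on the same side of 0.5 and outside
#' `[0.5 - palindromic_eaf_band, 0.5 + palindromic_eaf_band]`; otherwise the
#' strand is ambiguous and the variant is dropped. Indels and non-ACGT
#' alleles are dropped.
#'
#' @param exposure,outcome Tibbles of association records
#'   (see [read_sumstats()]).
#' @param palindromic_eaf_band Half-width of the allele-frequency exclusion
#'   band around 0.5 for palindromic variants. Default 0.08, the common
#'   two-sample MR convention.
#' @return A tibble with one row per shared variant: `variant_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele` (exposure convention), `bx`,
#'   `sx`, `by`, `sy`, `eaf_x`, `eaf_y`, `action`
#'   (`kept`/`flipped`/`dropped_palindromic`/`dropped_mismatch`), `reason`.
#'   Rows with a `dropped_*` action have their outcome fields set to `NA`;
#'   the full table doubles as the harmonization audit.
#' @export
harmonize_sumstats <- function(exposure, outcome, palindromic_eaf_band = 0.08) {
  stopifnot_scalar_number(palindromic_eaf_band, "palindromic_eaf_band", 0, 0.5)
  ex <- as_tibble(exposure)
  ou <- as_tibble(outcome)
  shared <- inner_join(
    select(ex, variant_id = "variant_id", chrom = "chrom", pos = "pos",
           xe = "effect_allele", xo = "other_allele",
           bx = "beta", sx = "se", eaf_x = "eaf"),
    select(ou, variant_id = "variant_id", oe = "effect_allele",
           oo = "other_allele", by_raw = "beta", sy = "se", eaf_y = "eaf"),
    by = "variant_id"
  )
  if (nrow(shared) == 0L) {
    abort("No overlapping variants between exposure and outcome.",
          class = "proteomr_empty_overlap_error")
  }
  is_snp <- function(a) !is.na(a) & a %in% names(COMPLEMENT)
  snp_ok <- is_snp(shared$xe) & is_snp(shared$xo) & is_snp(shared$oe) &
    is_snp(shared$oo) & shared$xe != shared$xo & shared$oe != shared$oo
  flip_comp <- function(a) unname(COMPLEMENT[a])
  palindromic <- snp_ok & shared$xo == flip_comp(shared$xe)

  same  <- snp_ok & shared$oe == shared$xe & shared$oo == shared$xo
  flip  <- snp_ok & shared$oe == shared$xo & shared$oo == shared$xe
  # strand-flipped matches (meaningless for palindromic variants, where the
  # strand flip reproduces the same allele pair)
  same_s <- snp_ok & !palindromic &
    flip_comp(shared$oe) == shared$xe & flip_comp(shared$oo) == shared$xo
  flip_s <- snp_ok & !palindromic &
    flip_comp(shared$oe) == shared$xo & flip_comp(shared$oo) == shared$xe

  band_lo <- 0.5 - palindromic_eaf_band
  band_hi <- 0.5 + palindromic_eaf_band
  pal_ok <- palindromic &
    !is.na(shared$eaf_x) & !is.na(shared$eaf_y) &
    (shared$eaf_x < band_lo | shared$eaf_x > band_hi) &
    (shared$eaf_y < band_lo | shared$eaf_y > band_hi) &
    sign(shared$eaf_x - 0.5) == sign(shared$eaf_y - 0.5)

  action <- dplyr::case_when(
    !snp_ok ~ "dropped_mismatch",
    palindromic & !pal_ok ~ "dropped_palindromic",
    same | same_s ~ "kept",
    flip | flip_s ~ "flipped",
    TRUE ~ "dropped_mismatch"
  )
  reason <- dplyr::case_when(
    !snp_ok ~ "indel_or_invalid_alleles",
    palindromic & !pal_ok ~ "palindromic_ambiguous_strand",
    action == "dropped_mismatch" ~ "allele_mismatch",
    action == "kept" & same_s ~ "strand_flip",
    action == "flipped" & flip_s ~ "strand_flip",
    TRUE ~ NA_character_
  )
  retained <- action %in% c("kept", "flipped")
  by <- ifelse(action == "kept", shared$by_raw,
               ifelse(action == "flipped", -shared$by_raw, NA_real_))
  eaf_y <- ifelse(action == "kept", shared$eaf_y,
                  ifelse(action == "flipped", 1 - shared$eaf_y, NA_real_))
  tibble(
    variant_id = shared$variant_id,
    chrom = shared$chrom,
    pos = shared$pos,
    effect_allele = shared$xe,
    other_allele = shared$xo,
    bx = shared$bx,
    sx = shared$sx,
    by = by,
    sy = ifelse(retained, shared$sy, NA_real_),
    eaf_x = shared$eaf_x,
    eaf_y = eaf_y,
    action = action,
    reason = reason
  )
}

#' Compute an LD correlation matrix from genotype dosages
#'
#' Pearson correlation of dosage columns, signed with respect to each
#' variant's counted (effect) allele, followed by a ridge repair to positive
#' semidefiniteness (adds `|min eigenvalue| + 1e-8` to the diagonal when
#' needed and rescales back to unit diagonal). Zero-variance variants cannot
#' be correlated; they are removed from the matrix and listed in the
#' `"excluded"` attribute.
#'
#' @param G Numeric matrix, subjects x variants, dosages in `[0, 2]`.
#' @param variant_ids Variant identifiers; defaults to `colnames(G)`.
#' @return Square correlation matrix with `variant_ids` as dimnames and an
#'   `"excluded"` attribute naming dropped zero-variance variants.
#' @export
ld_from_genotypes <- function(G, variant_ids = colnames(G)) {
  G <- as.matrix(G)
  if (is.null(variant_ids)) {
    variant_ids <- paste0("v", seq_len(ncol(G)))
  }
  if (length(variant_ids) != ncol(G)) {
    abort("`variant_ids` must match the number of genotype columns.",
          class = "proteomr_config_error")
  }
  v <- apply(G, 2, var)
  zero_var <- !is.finite(v) | v == 0
  excluded <- variant_ids[zero_var]
  if (any(zero_var)) {
    warn(sprintf("Excluding %d zero-variance variant(s) from LD: %s",
                 sum(zero_var), paste(excluded, collapse = ", ")))
    G <- G[, !zero_var, drop = FALSE]
    variant_ids <- variant_ids[!zero_var]
  }
  if (ncol(G) == 0L) {
    abort("All variants have zero variance; no LD matrix computable.",
          class = "proteomr_empty_input_error")
  }
  R <- cor(G)
  R <- psd_repair(R)
  diag(R) <- 1
  dimnames(R) <- list(variant_ids, variant_ids)
  attr(R, "excluded") <- excluded
  R
}

#' Validate an LD correlation matrix
#'
#' Checks symmetry, unit diagonal, bounded entries, and positive
#' semidefiniteness (up to a small numerical tolerance).
#' @param R Square correlation matrix.
#' @return `R`, invisibly; aborts on violation.
#' @export
validate_ld <- function(R) {
  if (!is.matrix(R) || nrow(R) != ncol(R)) {
    abort("LD matrix must be square.", class = "proteomr_config_error")
  }
  if (max(abs(R - t(R))) > 1e-8) {
    abort("LD matrix is not symmetric.", class = "proteomr_config_error")
  }
  if (max(abs(diag(R) - 1)) >= 1e-9) {
    abort("LD matrix diagonal is not 1.", class = "proteomr_config_error")
  }
  if (max(abs(R)) > 1 + 1e-9) {
    abort("LD entries must satisfy |r| <= 1.", class = "proteomr_config_error")
  }
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort("LD matrix is not positive semidefinite.",
          class = "proteomr_config_error")
  }
  invisible(R)
}

#' Read / write an LD matrix as a delimited file
#'
#' The file format is a square tab-delimited matrix whose header row (and
#' implied row order) are the variant identifiers.
#' @param path File path.
#' @rdname ld_io
#' @export
read_ld_matrix <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  R <- as.matrix(raw)
  dimnames(R) <- list(colnames(raw), colnames(raw))
  validate_ld(R)
  R
}

#' @param R Square correlation matrix with variant ids as dimnames.
#' @rdname ld_io
#' @export
write_ld_matrix <- function(R, path) {
  readr::write_tsv(as_tibble(as.data.frame(R)), path, progress = FALSE)
  invisible(path)
}
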