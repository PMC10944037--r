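test_that("summary statistics read back from file, with column mapping", {
  recs <- make_records(c("rs1", "rs2", "rs3"), beta = c(0.1, -0.2, 0.05),
                       se = c(0.02, 0.05, 0.01))
  canonical <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(recs, canonical)
  got <- read_sumstats(canonical, trait_id = "trait")
  expect_equal(nrow(got), 3L)
  expect_equal(nrow(attr(got, "rejects")), 0L)
  expect_equal(got$beta, recs$beta, tolerance = 1e-12)
  expect_identical(got$variant_id, recs$variant_id)
  expect_identical(got$pos, recs$pos)

  # same file with a renamed effect column, mapped back via column_map
  renamed <- withr::local_tempfile(fileext = ".tsv")
  tab <- readr::read_tsv(canonical, show_col_types = FALSE)
  names(tab)[names(tab) == "beta"] <- "Effect"
  readr::write_tsv(tab, renamed)
  via_map <- read_sumstats(renamed, trait_id = "trait",
                           column_map = c(beta = "Effect"))
  expect_equal(as.data.frame(via_map), as.data.frame(got))
})

test_that("rows with nonpositive SE or missing beta are rejected with reasons", {
  recs <- make_records(c("rs1", "rs2", "rs3"), beta = c(0.1, NA, 0.05),
                       se = c(0.02, 0.05, 0.01))
  recs$se[3] <- 0
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(recs, path)
  got <- suppressMessages(read_sumstats(path, trait_id = "trait"))
  expect_equal(got$variant_id, "rs1")
  rejects <- attr(got, "rejects")
  expect_setequal(rejects$reject_reason, c("missing_beta", "nonpositive_se"))
})

test_that("missing mandatory columns and empty files raise typed errors", {
  recs <- make_records("rs1", beta = 0.1, se = 0.02)
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(dplyr::select(recs, -"se"), path)
  expect_error(read_sumstats(path, trait_id = "t"),
               class = "proteomr_config_error")
  recs$se <- -1
  readr::write_tsv(recs, path)
  expect_error(suppressMessages(read_sumstats(path, trait_id = "t")),
               class = "proteomr_empty_input_error")
})

test_that("p-values inconsistent with |beta/se| trigger a warning, not a rejection", {
  recs <- make_records("rs1", beta = 0.5, se = 0.02)
  recs$pvalue <- 0.5   # z = 25 implies p ~ 1e-138
  expect_warning(out <- validate_sumstats(recs), "orders of magnitude")
  expect_equal(nrow(out), 1L)
})

test_that("harmonization follows the allele rules variant by variant", {
  # ten-variant fixture exercising every rule; expected actions worked
  # out by hand from the allele table
  ex <- make_records(paste0("rs", 1:10), beta = rep(0.2, 10), se = 0.02,
                     effect_allele = c("A", "A", "A", "A", "A", "C", "A", "A", "ACT", "A"),
                     other_allele  = c("G", "G", "G", "T", "T", "G", "C", "G", "G", "G"),
                     eaf = c(0.3, 0.3, 0.3, 0.3, 0.55, 0.3, 0.3, 0.3, 0.3, 0.3))
  ou <- make_records(paste0("rs", 1:10), beta = rep(0.3, 10), se = 0.03,
                     effect_allele = c("A", "G", "T", "A", "A", "G", "G", "A", "A", "A"),
                     other_allele  = c("G", "A", "C", "T", "T", "C", "T", "C", "G", "G"),
                     eaf = c(0.3, 0.7, 0.3, 0.3, 0.55, 0.7, 0.7, 0.3, 0.3, 0.3),
                     trait_id = "out")
  h <- harmonize_sumstats(ex, ou)
  expected_action <- c(
    "kept",                 # rs1 same alleles
    "flipped",              # rs2 swapped alleles
    "kept",                 # rs3 strand-flipped (T/C -> A-G)
    "kept",                 # rs4 palindromic A/T, both EAF 0.3 same side
    "dropped_palindromic",  # rs5 palindromic, EAF 0.55 inside band
    "flipped",              # rs6 C/G palindromic? no: exposure C/G IS palindromic
    "flipped",              # rs7 strand flip then swap
    "dropped_mismatch",     # rs8 allele mismatch (A/C vs A/G)
    "dropped_mismatch",     # rs9 indel
    "kept"                  # rs10 same alleles again
  )
  # rs6: exposure C/G is palindromic with EAF 0.3 / outcome 0.7 -> opposite
  # sides of 0.5 -> dropped
  expected_action[6] <- "dropped_palindromic"
  expect_equal(h$action, expected_action)
  expect_equal(h$by[1], 0.3)
  expect_equal(h$by[2], -0.3)
  expect_equal(h$by[3], 0.3)
  expect_equal(h$by[7], -0.3)
  expect_true(all(is.na(h$by[h$action %in%
                             c("dropped_palindromic", "dropped_mismatch")])))
})

test_that("palindromic variant with EAF exactly 0.5 is dropped under any band", {
  ex <- make_records("rs1", beta = 0.2, se = 0.02,
                     effect_allele = "A", other_allele = "T", eaf = 0.5)
  ou <- make_records("rs1", beta = 0.3, se = 0.03,
                     effect_allele = "A", other_allele = "T", eaf = 0.5)
  h <- harmonize_sumstats(ex, ou, palindromic_eaf_band = 0)
  expect_equal(h$action, "dropped_palindromic")
})

test_that("harmonization is idempotent on an already-aligned pair set", {
  ex <- make_records(paste0("rs", 1:5), beta = rnorm(5), se = 0.02)
  ou <- make_records(paste0("rs", 1:5), beta = rnorm(5), se = 0.03,
                     trait_id = "out")
  h1 <- harmonize_sumstats(ex, ou)
  ou2 <- make_records(h1$variant_id, beta = h1$by, se = h1$sy,
                      effect_allele = h1$effect_allele,
                      other_allele = h1$other_allele, eaf = h1$eaf_y,
                      trait_id = "out")
  h2 <- harmonize_sumstats(ex, ou2)
  expect_true(all(h2$action == "kept"))
  expect_equal(h2$by, h1$by, tolerance = 1e-15)
})

test_that("disjoint variant sets raise an empty-overlap error", {
  ex <- make_records("rs1", beta = 0.1, se = 0.02)
  ou <- make_records("rs2", beta = 0.1, se = 0.02)
  expect_error(harmonize_sumstats(ex, ou),
               class = "proteomr_empty_overlap_error")
})

test_that("LD from genotypes: duplicates, singletons, zero variance", {
  withr::local_seed(42)
  g <- matrix(rbinom(200, 2, 0.4), ncol = 2)
  G <- cbind(g[, 1], g[, 1], g[, 2])
  R <- ld_from_genotypes(G, c("a", "b", "c"))
  expect_equal(R["a", "b"], 1.0, tolerance = 1e-12)
  expect_equal(unname(diag(R)), rep(1, 3))

  single <- ld_from_genotypes(matrix(rbinom(50, 2, 0.3), ncol = 1), "v1")
  expect_equal(unname(single[1, 1]), 1.0)

  Gz <- cbind(G, 0)
  expect_warning(Rz <- ld_from_genotypes(Gz, c("a", "b", "c", "z")),
                 "zero-variance")
  expect_equal(attr(Rz, "excluded"), "z")
  expect_equal(dim(Rz), c(3L, 3L))
})

test_that("independent columns give near-zero off-diagonal LD", {
  withr::local_seed(7)
  G <- matrix(rbinom(10000 * 6, 2, 0.3), ncol = 6)
  R <- ld_from_genotypes(G)
  off <- R[upper.tri(R)]
  expect_lt(max(abs(off)), 0.05)
})

test_that("LD matrices from random dosage fixtures satisfy the invariants", {
  withr::local_seed(11)
  for (i in 1:100) {
    n <- sample(30:80, 1)
    m <- sample(2:6, 1)
    sim <- simulate_genotypes(n, m, maf = c(0.2, 0.5),
                              ld_decay = runif(1, 0, 0.9), seed = i)
    expect_silent(validate_ld(sim$R))
  }
})

test_that("records round-trip through write/read bit-compatibly", {
  withr::local_seed(3)
  recs <- make_records(paste0("rs", 1:20), beta = rnorm(20) * 1e-3,
                       se = runif(20, 1e-4, 1e-2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(recs, path)
  got <- read_sumstats(path, trait_id = "trait")
  expect_identical(got$variant_id, recs$variant_id)
  expect_identical(got$pos, recs$pos)
  expect_equal(got$beta, recs$beta, tolerance = 1e-12)
  expect_equal(got$se, recs$se, tolerance = 1e-12)
  expect_equal(got$pvalue, recs$pvalue, tolerance = 1e-12)
})

test_that("gene loci convert BED-style 0-based starts to 1-based inclusive", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t999\t2000\tGENE1\tP1", "chr2\t0\t100\tGENE2\tP2"), path)
  loci <- read_gene_loci(path)
  expect_equal(loci$start, c(1000L, 1L))
  expect_equal(loci$end, c(2000L, 100L))
  expect_equal(loci$protein_id, c("P1", "P2"))
})
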