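locus <- tibble::tibble(gene = "GENE", chrom = "1", start = 1000000L,
                        end = 1002000L, protein_id = "P")

test_that("cis/trans boundaries are inclusive at exactly +/- window", {
  recs <- make_records(c("v_low", "v_in_low", "v_in_high", "v_high"),
                       beta = rep(0.2, 4), se = rep(0.01, 4),
                       pos = c(499999L, 500000L, 1502000L, 1502001L))
  out <- select_instruments(recs, locus, window_bp = 5e5,
                            p_threshold = 1e-4, scope = "both")
  ct <- setNames(out$cis_trans, out$variant_id)
  expect_equal(unname(ct[c("v_in_low", "v_in_high")]), c("cis", "cis"))
  expect_equal(unname(ct[c("v_low", "v_high")]), c("trans", "trans"))
})

test_that("the significance threshold is a strict inequality", {
  recs <- make_records(c("at", "below"), beta = c(0.2, 0.2),
                       se = c(0.01, 0.01), pos = c(1000500L, 1000600L),
                       pvalue = c(5e-8, 4.9e-8))
  out <- select_instruments(recs, locus, p_threshold = 5e-8, scope = "cis")
  expect_equal(out$variant_id, "below")
})

test_that("a 20-variant fixture filters exactly as the hand-applied rules", {
  withr::local_seed(3)
  pos <- as.integer(seq(200000, 2200000, length.out = 20))
  pv <- rep(c(1e-10, 1e-3), 10)
  recs <- make_records(paste0("v", 1:20), beta = rep(0.1, 20),
                       se = rep(0.01, 20), pos = pos, pvalue = pv)
  out <- select_instruments(recs, locus, scope = "cis", p_threshold = 5e-8)
  # hand filter: cis means pos in [500000, 1502000]; significant means
  # pv = 1e-10 (odd indices)
  manual <- recs$variant_id[pos >= 500000 & pos <= 1502000 & pv < 5e-8]
  expect_equal(sort(out$variant_id), sort(manual))
})

test_that("trans instruments inside the extended MHC are excluded", {
  recs <- make_records(c("mhc", "okay"), beta = c(0.3, 0.3),
                       se = c(0.01, 0.01), chrom = "6",
                       pos = c(30000000L, 50000000L))
  locus6 <- tibble::tibble(gene = "G", chrom = "2", start = 1L, end = 10L,
                           protein_id = "P")
  out <- suppressMessages(select_instruments(recs, locus6, scope = "trans"))
  expect_equal(out$variant_id, "okay")
})

test_that("greedy clumping keeps the best of a tight LD block and all independents", {
  recs <- make_records(paste0("v", 1:3), beta = rep(0.2, 3),
                       se = rep(0.01, 3), pvalue = c(1e-10, 1e-8, 1e-9))
  R <- matrix(0.995, 3, 3); diag(R) <- 1
  dimnames(R) <- list(recs$variant_id, recs$variant_id)
  out <- clump_instruments(recs, R, r2_threshold = 0.1)
  expect_equal(out$variant_id, "v1")

  R0 <- diag(3); dimnames(R0) <- dimnames(R)
  expect_equal(nrow(clump_instruments(recs, R0, 0.1)), 3L)
})

test_that("clumping matches a brute-force replay and ignores row order", {
  withr::local_seed(7)
  m <- 8
  sim <- simulate_genotypes(400, m, maf = c(0.2, 0.5), ld_decay = 0.8,
                            seed = 99)
  recs <- make_records(sim$info$variant_id, beta = rnorm(m, 0, 0.1),
                       se = rep(0.01, m), pos = sim$info$pos)
  got <- clump_instruments(recs, sim$R, r2_threshold = 0.1)
  # brute-force replay of the stated greedy rule
  ord <- order(recs$pvalue, recs$variant_id)
  kept <- character(0)
  for (v in recs$variant_id[ord]) {
    if (all(sim$R[v, kept]^2 < 0.1)) kept <- c(kept, v)
  }
  expect_equal(got$variant_id, kept)

  shuffled <- recs[sample(m), ]
  expect_equal(clump_instruments(shuffled, sim$R, 0.1)$variant_id,
               got$variant_id)
})

test_that("mean F statistic is the mean of squared per-variant z-scores", {
  ex1 <- make_records("v1", beta = 0.1, se = 0.02, pos = 1000500L)
  ou <- make_records(c("v1", "v2"), beta = c(0.05, 0.02),
                     se = c(0.02, 0.02), pos = c(1000500L, 1000600L),
                     trait_id = "out")
  set1 <- build_instrument_set("P", ex1, ou, NULL)
  expect_equal(set1$mean_F, 25.0)
  expect_false(set1$weak)

  ex2 <- make_records(c("v1", "v2"), beta = c(0.1, 0.05),
                      se = c(0.02, 0.025), pos = c(1000500L, 1000600L))
  set2 <- build_instrument_set("P", ex2, ou, NULL)
  expect_equal(set2$mean_F, 14.5)
})

test_that("simulated cis pQTL studies give strong instruments at scale", {
  withr::local_seed(5)
  strong <- replicate(20, {
    seed <- sample.int(1e6, 1)
    sim <- simulate_genotypes(30000, 5, maf = c(0.2, 0.5), ld_decay = 0.4,
                              seed = seed)
    recs <- simulate_pqtl_study(sim$G, sim$info, c(1, 1, 0, 0, 0),
                                h2 = 0.05, protein_id = "P", seed = seed + 1)
    top <- dplyr::filter(recs, pvalue < 5e-8)
    nrow(top) > 0 && mean((top$beta / top$se)^2) > 10
  })
  expect_gte(mean(strong), 0.95)
})

test_that("cis and trans partition the retained candidates", {
  withr::local_seed(11)
  recs <- make_records(paste0("v", 1:30), beta = rnorm(30, 0, 0.2),
                       se = rep(0.01, 30),
                       pos = as.integer(runif(30, 1, 3e6)))
  out <- select_instruments(recs, locus, scope = "both", p_threshold = 1)
  expect_setequal(out$cis_trans, c("cis", "trans"))
  expect_equal(nrow(out), 30L)
  expect_equal(sum(out$cis_trans == "cis") + sum(out$cis_trans == "trans"),
               nrow(out))
})

test_that("instrument sets pass their own invariants on random fixtures", {
  withr::local_seed(13)
  for (i in 1:50) {
    m <- sample(1:6, 1)
    bx <- rnorm(m, 0, 0.2); bx[bx == 0] <- 0.1
    sx <- runif(m, 0.005, 0.05)
    ex <- make_records(paste0("v", 1:m), beta = bx, se = sx,
                       pos = as.integer(1000000 + seq_len(m) * 100))
    ou <- make_records(paste0("v", 1:m), beta = rnorm(m, 0, 0.1),
                       se = runif(m, 0.01, 0.05),
                       pos = as.integer(1000000 + seq_len(m) * 100),
                       trait_id = "out")
    set <- build_instrument_set("P", ex, ou, NULL)
    d <- set$data
    expect_true(all(lengths(list(d$bx, d$sx, d$by, d$sy)) == nrow(d)))
    expect_equal(dim(set$R), c(nrow(d), nrow(d)))
    expect_equal(set$mean_F, mean((d$bx / d$sx)^2), tolerance = 1e-12)
    expect_silent(validate_ld(unclass(set$R)))
  }
})

test_that("no harmonizable variants yields a NULL set, not an error", {
  ex <- make_records("v1", beta = 0.1, se = 0.02)
  ou <- make_records("v9", beta = 0.1, se = 0.02, trait_id = "out")
  expect_message(set <- build_instrument_set("P", ex, ou, NULL),
                 "no harmonized instruments")
  expect_null(set)
})
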