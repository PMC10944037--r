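test_that("Wald ratio arithmetic and degenerate cases", {
  w <- mr_wald(bx = 0.4, sx = 0.01, by = 0.2, sy = 0.05)
  expect_equal(w$theta, 0.5)
  expect_equal(w$se, 0.125)

  w0 <- mr_wald(bx = 0.4, sx = 0.01, by = 0, sy = 0.05)
  expect_equal(w0$theta, 0)
  expect_equal(w0$se, 0.05 / 0.4)

  expect_error(mr_wald(0, 0.01, 0.1, 0.05),
               class = "proteomr_undefined_ratio_error")
})

test_that("first-order Wald SE is within 10% of second-order when F > 10", {
  withr::local_seed(9)
  for (i in 1:100) {
    sx <- runif(1, 0.01, 0.05)
    bx <- sx * sqrt(runif(1, 25, 200))  # strong instruments
    sy <- runif(1, 0.01, 0.1)
    by <- runif(1, -1.5, 1.5) * sy      # moderate outcome association
    first <- mr_wald(bx, sx, by, sy)$se
    second <- mr_wald(bx, sx, by, sy, second_order = TRUE)$se
    expect_lt(abs(first - second) / second, 0.10)
  }
})

test_that("single-instrument IVW equals the Wald ratio", {
  set <- make_set(bx = 0.12, sx = 0.02, by = 0.05, sy = 0.03)
  ivw <- mr_ivw(set)
  wald <- mr_wald(0.12, 0.02, 0.05, 0.03)
  expect_equal(ivw$theta, wald$theta, tolerance = 1e-12)
  expect_equal(ivw$se_theta, wald$se, tolerance = 1e-12)
})

test_that("IVW with identity LD equals the normal-equations WLS oracle", {
  bx <- c(0.1, 0.2, 0.15); by <- c(0.05, 0.12, 0.09)
  sy <- c(0.02, 0.03, 0.025)
  set <- make_set(bx = bx, sx = rep(0.01, 3), by = by, sy = sy)
  ivw <- mr_ivw(set)
  oracle <- wls_origin_oracle(bx, by, sy)
  expect_equal(ivw$theta, unname(oracle["theta"]), tolerance = 1e-10)
  expect_equal(ivw$se_theta, unname(oracle["se"]), tolerance = 1e-10)
  expect_equal(ivw$q_df, 2L)
})

test_that("a duplicated instrument changes nothing after ridge repair", {
  bx <- c(0.1, 0.2); by <- c(0.05, 0.12); sy <- c(0.02, 0.03)
  base <- mr_ivw(make_set(bx = bx, sx = rep(0.01, 2), by = by, sy = sy))
  R <- rbind(c(1, 0, 1), c(0, 1, 0), c(1, 0, 1))
  dup <- mr_ivw(make_set(bx = c(bx, bx[1]), sx = rep(0.01, 3),
                         by = c(by, by[1]), sy = c(sy, sy[1]), R = R))
  expect_equal(dup$theta, base$theta, tolerance = 1e-6)
})

test_that("MR-Egger reproduces an exact weighted-line fixture", {
  bx <- c(0.1, 0.2, 0.4)
  delta <- 0.03; slope <- 0.5
  by <- delta + slope * bx
  sy <- c(0.02, 0.05, 0.03)
  set <- make_set(bx = bx, sx = rep(0.01, 3), by = by, sy = sy)
  egger <- mr_egger(set)
  oracle <- unname(wls_intercept_oracle(bx, by, 1 / sy^2))
  expect_equal(egger$theta, oracle[2], tolerance = 1e-12)
  expect_equal(egger$egger_intercept, oracle[1], tolerance = 1e-12)
  expect_equal(egger$theta, slope, tolerance = 1e-12)
  expect_equal(egger$egger_intercept, delta, tolerance = 1e-12)
})

test_that("Egger slope is consistent with IVW absent pleiotropy, and recovers a directional intercept", {
  withr::local_seed(31)
  n_inst <- 8
  consistent <- 0; recovered <- 0
  n_rep <- 200
  for (i in 1:n_rep) {
    bx <- runif(n_inst, 0.05, 0.3)
    sy <- runif(n_inst, 0.02, 0.05)
    theta <- 0.3
    by0 <- rnorm(n_inst, theta * bx, sy)
    set0 <- make_set(bx = bx, sx = rep(0.01, n_inst), by = by0, sy = sy)
    e0 <- mr_egger(set0); i0 <- mr_ivw(set0)
    if (abs(e0$theta - i0$theta) < 2 * e0$se_theta) {
      consistent <- consistent + 1
    }
    delta <- 0.05
    by1 <- rnorm(n_inst, delta + theta * bx, sy)
    set1 <- make_set(bx = bx, sx = rep(0.01, n_inst), by = by1, sy = sy)
    e1 <- mr_egger(set1)
    se_int <- abs(e1$egger_intercept /
                    qnorm(e1$egger_intercept_p / 2, lower.tail = FALSE))
    if (abs(e1$egger_intercept - delta) < 2 * se_int) {
      recovered <- recovered + 1
    }
  }
  expect_gte(consistent / n_rep, 0.9)
  expect_gte(recovered / n_rep, 0.9)
})

test_that("Egger and weighted median report not-applicable below 3 instruments", {
  set <- make_set(bx = c(0.1, 0.2), sx = rep(0.01, 2),
                  by = c(0.05, 0.1), sy = rep(0.02, 2))
  expect_true(is.na(mr_egger(set)$theta))
  expect_true(is.na(mr_weighted_median(set)$theta))
})

test_that("weighted median interpolates the 50% weight crossing", {
  # equal weights, ratios 0.1/0.5/0.9 -> median 0.5
  set <- make_set(bx = c(1, 1, 1), sx = rep(0.01, 3),
                  by = c(0.1, 0.5, 0.9), sy = rep(0.1, 3))
  wm <- mr_weighted_median(set, n_boot = 50)
  expect_equal(wm$theta, 0.5)
})

test_that("weighted median bootstrap SE is deterministic under a fixed seed", {
  withr::local_seed(77)
  set <- make_set(bx = runif(5, 0.1, 0.3), sx = rep(0.02, 5),
                  by = rnorm(5, 0.05, 0.02), sy = runif(5, 0.02, 0.05))
  a <- mr_weighted_median(set, n_boot = 200, seed = 11)
  b <- mr_weighted_median(set, n_boot = 200, seed = 11)
  expect_identical(a$se_theta, b$se_theta)
})

test_that("weighted median resists an invalid minority while IVW is dragged", {
  withr::local_seed(41)
  ok <- 0
  n_rep <- 50
  for (i in 1:n_rep) {
    n_inst <- 10
    bx <- runif(n_inst, 0.15, 0.3)
    sy <- rep(0.02, n_inst)
    theta <- 0.2
    by <- rnorm(n_inst, theta * bx, sy)
    by[1] <- by[1] + 0.5  # one wild pleiotropic outlier
    set <- make_set(bx = bx, sx = rep(0.005, n_inst), by = by, sy = sy)
    wm <- mr_weighted_median(set, n_boot = 100, seed = i)
    if (abs(wm$theta - theta) < 2 * wm$se_theta) ok <- ok + 1
  }
  expect_gte(ok / n_rep, 0.9)
})

test_that("estimates are sign-equivariant under allele flips", {
  withr::local_seed(51)
  bx <- runif(4, 0.1, 0.3); sx <- rep(0.01, 4)
  by <- rnorm(4, 0.1, 0.02); sy <- runif(4, 0.02, 0.04)
  base <- mr_ivw(make_set(bx = bx, sx = sx, by = by, sy = sy))
  flip_x <- mr_ivw(make_set(bx = -bx, sx = sx, by = -by, sy = sy))
  neg_y <- mr_ivw(make_set(bx = bx, sx = sx, by = -by, sy = sy))
  expect_equal(flip_x$theta, base$theta, tolerance = 1e-12)
  expect_equal(neg_y$theta, -base$theta, tolerance = 1e-12)
})

test_that("OR and CI always satisfy the exp(theta +/- 1.96 se) construction", {
  withr::local_seed(61)
  set <- make_set(bx = runif(5, 0.1, 0.3), sx = rep(0.02, 5),
                  by = rnorm(5, 0.05, 0.03), sy = runif(5, 0.02, 0.05))
  res <- run_mr(set, n_boot = 100)
  done <- dplyr::filter(res, !is.na(theta))
  expect_equal(done$or_, exp(done$theta), tolerance = 1e-12)
  expect_equal(done$ci_low, exp(done$theta - 1.96 * done$se_theta),
               tolerance = 1e-9)
  expect_equal(done$ci_high, exp(done$theta + 1.96 * done$se_theta),
               tolerance = 1e-9)
})

test_that("IVW calibration and recovery at summary level", {
  withr::local_seed(71)
  n_inst <- 5
  sx <- rep(0.02, n_inst)
  bx_true <- sx * sqrt(30)   # F ~ 30
  sy <- rep(0.05, n_inst)
  null_p <- replicate(500, {
    bx <- rnorm(n_inst, bx_true, sx)
    by <- rnorm(n_inst, 0, sy)
    mr_ivw(make_set(bx = bx, sx = sx, by = by, sy = sy))$pvalue
  })
  expect_gt(mean(null_p < 0.05), 0.02)
  expect_lt(mean(null_p < 0.05), 0.09)

  est <- replicate(200, {
    bx <- rnorm(n_inst, bx_true, sx)
    by <- rnorm(n_inst, 0.3 * bx_true, sy)
    mr_ivw(make_set(bx = bx, sx = sx, by = by, sy = sy))$theta
  })
  expect_lt(abs(median(est) - 0.3), 0.04)
})
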