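test_that("wald_ratio follows the first-order formula", {
  h <- mk_h(bx = 0.1, by = 0.05, sy = 0.01, sx = 0.02)
  r <- wald_ratio(h)
  expect_equal(r$estimate, 0.5)
  expect_equal(r$se, 0.1)
  expect_equal(r$ci_low, 0.5 - qnorm(0.975) * 0.1)
  expect_equal(r$pval, 2 * pnorm(-5))
  # zero outcome effect -> estimate 0, OR 1
  h0 <- mk_h(bx = 0.1, by = 0, sy = 0.01, binary = TRUE)
  r0 <- to_odds_ratio(wald_ratio(h0))
  expect_equal(r0$estimate, 0)
  expect_equal(r0$or, 1.0)
  expect_mr_error(wald_ratio(mk_h(bx = 0, by = 0.1, sy = 0.01)),
                  "mr_degenerate_error")
})

test_that("ivw matches the closed-form weighted least-squares value", {
  # spec'd 3-SNP instance, frozen against the independent lm oracle
  h <- mk_h(bx = c(0.10, 0.20, 0.15), by = c(0.05, 0.08, 0.09),
            sy = c(0.01, 0.01, 0.02))
  r <- ivw(h)
  expect_equal(r$estimate, 243.75 / 556.25, tolerance = 1e-12)
  expect_equal(r$estimate, oracle_ivw(h$beta_exp, h$beta_out, h$se_out),
               tolerance = 1e-12)
  # single SNP delegates to wald_ratio
  h1 <- mk_h(bx = 0.1, by = 0.05, sy = 0.01)
  expect_equal(ivw(h1)$estimate, wald_ratio(h1)$estimate)
  expect_equal(ivw(h1)$method, "wald")
})

test_that("ivw oracle equivalence holds on random instances", {
  set.seed(401)
  for (i in 1:50) {
    J <- 10
    bx <- rnorm(J, 0, 0.1); by <- rnorm(J, 0, 0.05)
    sy <- runif(J, 0.005, 0.05)
    r <- ivw(mk_h(bx, by, sy))
    expect_equal(r$estimate, oracle_ivw(bx, by, sy), tolerance = 1e-10)
  }
})

test_that("exact proportionality gives Q = 0 and the fixed-effect SE floor", {
  bx <- c(0.1, 0.2, 0.3); c <- 0.42
  r <- ivw(mk_h(bx, c * bx, sy = rep(0.01, 3)))
  expect_equal(r$estimate, c, tolerance = 1e-12)
  expect_equal(r$q_stat, 0, tolerance = 1e-20)
  expect_equal(r$phi, 0)
  expect_equal(r$se, r$se_fixed)               # max(1, phi) floor
  # random-effects SE never drops below the fixed-effect SE
  set.seed(402)
  for (i in 1:20) {
    h <- mk_h(rnorm(8, 0, 0.1), rnorm(8, 0, 0.1), runif(8, 0.005, 0.05))
    expect_gte(ivw(h)$se, ivw(h, random_effects = FALSE)$se)
  }
  expect_mr_error(ivw(mk_h(c(0, 0), c(0.1, 0.2), c(0.01, 0.01))),
                  "mr_degenerate_error")
})

test_that("estimators are invariant to joint sign flips of SNP subsets", {
  set.seed(403)
  bx <- runif(10, 0.05, 0.2); by <- 0.3 * bx + rnorm(10, 0, 0.01)
  sy <- runif(10, 0.005, 0.02)
  flip <- sample(c(1, -1), 10, replace = TRUE)
  h0 <- mk_h(bx, by, sy)
  h1 <- mk_h(bx * flip, by * flip, sy)
  expect_equal(ivw(h1)$estimate, ivw(h0)$estimate, tolerance = 1e-12)
  expect_equal(ivw(h1)$se, ivw(h0)$se, tolerance = 1e-12)
  expect_equal(weighted_median(h1, n_boot = 50, seed = 9)$estimate,
               weighted_median(h0, n_boot = 50, seed = 9)$estimate,
               tolerance = 1e-12)
  expect_equal(egger(h1)$slope$estimate, egger(h0)$slope$estimate,
               tolerance = 1e-12)
  expect_equal(egger(h1)$intercept$estimate, egger(h0)$intercept$estimate,
               tolerance = 1e-12)
})

test_that("egger recovers an exact affine relationship", {
  bx <- c(0.05, 0.1, 0.15, 0.2, 0.3)
  by <- 0.02 + 0.3 * bx
  e <- egger(mk_h(bx, by, sy = rep(0.01, 5)))
  expect_equal(e$intercept$estimate, 0.02, tolerance = 1e-10)
  expect_equal(e$slope$estimate, 0.3, tolerance = 1e-10)
  expect_mr_error(egger(mk_h(c(0.1, 0.1, 0.1), c(1, 2, 3), rep(0.1, 3))),
                  "mr_singular_error")
  expect_mr_error(egger(mk_h(c(0.1, 0.2), c(1, 2), c(0.1, 0.1))),
                  "mr_insufficient_instruments_error")
})

test_that("weighted median interpolates the weighted ratio distribution", {
  # symmetric ratios with equal weights -> middle ratio
  h <- mk_h(bx = c(1, 1, 1), by = c(0.4, 0.5, 0.6), sy = rep(0.1, 3))
  expect_equal(weighted_median(h, n_boot = 50, seed = 1)$estimate, 0.5)
  # one wild ratio among nine near 0.5 stays in the central cluster;
  # frozen against the interpolation formula computed independently
  ratios <- c(0.46, 0.48, 0.49, 0.50, 0.51, 0.52, 0.53, 0.54, 10.0)
  h2 <- mk_h(bx = rep(1, 9), by = ratios, sy = rep(0.1, 9))
  est <- weighted_median(h2, n_boot = 50, seed = 1)$estimate
  srt <- sort(ratios); sw <- (seq_len(9) - 0.5) / 9
  expect_equal(est, approx(sw, srt, xout = 0.5)$y, tolerance = 1e-12)
  expect_lt(abs(est - 0.5), 0.05)
  # determinism of the bootstrap SE
  a <- weighted_median(h2, n_boot = 200, seed = 7)
  b <- weighted_median(h2, n_boot = 200, seed = 7)
  expect_identical(a$se, b$se)
  expect_mr_error(weighted_median(mk_h(c(0, 1, 1), 1:3 / 10, rep(0.1, 3))),
                  "mr_degenerate_error")
})

test_that("mr_presso is a no-op without outliers and flags a planted one", {
  set.seed(404)
  bx <- runif(12, 0.05, 0.2); sy <- runif(12, 0.005, 0.02)
  by <- 0.2 * bx + rnorm(12, 0, sy)
  p <- mr_presso(mk_h(bx, by, sy), n_sim = 500, seed = 11)
  expect_equal(nrow(p$outliers), 0)
  expect_equal(p$corrected$estimate, p$raw$estimate)   # exact no-op
  expect_equal(p$corrected$n_snp, 12)
  expect_true(is.na(p$distortion_pval))
  expect_gt(p$global_pval, 1 / 501)

  by2 <- by; by2[5] <- by2[5] + 12 * sy[5]             # gross outlier
  p2 <- mr_presso(mk_h(bx, by2, sy), n_sim = 1000, seed = 11)
  expect_true("rs005" %in% p2$outliers$snp)
  expect_equal(p2$corrected$n_snp, 12 - nrow(p2$outliers))
  expect_lt(p2$global_pval, 0.05)
  # determinism
  p3 <- mr_presso(mk_h(bx, by2, sy), n_sim = 1000, seed = 11)
  expect_identical(p2$global_pval, p3$global_pval)
  expect_mr_error(mr_presso(mk_h(bx[1:3], by[1:3], sy[1:3])),
                  "mr_insufficient_instruments_error")
})

test_that("to_odds_ratio exponentiates and honours per-unit-decrease", {
  r <- ivw(mk_h(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3) * log(2),
                rep(0.01, 3), binary = TRUE))
  o <- to_odds_ratio(r)
  expect_equal(o$or, 2.0, tolerance = 1e-9)
  od <- to_odds_ratio(r, per_unit_decrease = TRUE)
  expect_equal(od$or, 0.5, tolerance = 1e-9)
  expect_equal(od$or_low, exp(-r$ci_high), tolerance = 1e-12)
  expect_equal(od$pval, r$pval)
  # estimate 0 -> OR exactly 1, CI symmetric about 1 on the log scale
  r0 <- mr_result("wald", 0, 0.1, 1, binary = TRUE)
  o0 <- to_odds_ratio(r0)
  expect_equal(o0$or, 1.0)
  expect_equal(o0$or_low * o0$or_high, 1.0, tolerance = 1e-12)
  r_cont <- ivw(mk_h(c(0.1, 0.2), c(0.05, 0.1), c(0.01, 0.01)))
  expect_mr_error(to_odds_ratio(r_cont), "mr_unit_error")
})
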