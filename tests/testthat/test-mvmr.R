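# helper: scenario-based exposure/mediator/outcome triple with strong SNPs
chain_data <- function(seed, delta = 0.5, theta_M = 0.4, theta_direct = 0.1) {
  s <- synthetic_scenario(J = 60, n_exp = 200000, n_out = 200000,
                          gamma_law = list(min = 0.1, max = 0.3),
                          mediator = list(delta = delta, theta_M = theta_M,
                                          theta_direct = theta_direct,
                                          n_med = 200000, J_med = 30),
                          seed = seed)
  generate_gwas(s)
}

test_that("MVMR with a single exposure equals univariable IVW exactly", {
  d <- chain_data(501)
  ins <- select_instruments(d$exposure)
  h <- clump(harmonize(ins, d$outcome), d$ld)
  u <- ivw(h)
  m <- mvmr_ivw(list(exposure = d$exposure), d$outcome, d$ld)
  expect_equal(m$effects$estimate[1], u$estimate, tolerance = 1e-12)
  expect_equal(m$effects$se_fixed[1], u$se_fixed, tolerance = 1e-12)
  expect_equal(m$n_snp, u$n_snp)
})

test_that("an orthogonal null co-exposure leaves the direct effect unchanged", {
  d <- chain_data(502)
  ins <- select_instruments(d$exposure)
  # co-exposure with true zero effects (only estimation noise) on the set
  set.seed(502)
  null_tbl <- gwas_table(data.frame(
    snp = ins$snp, effect_allele = ins$effect_allele,
    other_allele = ins$other_allele, eaf = ins$eaf,
    beta = rnorm(nrow(ins), 0, 0.01), se = 0.01, pval = 1e-10,
    n = ins$n), trait_name = "null_exposure")
  m <- mvmr_ivw(list(exposure = d$exposure, null_exposure = null_tbl),
                d$outcome, d$ld)
  u <- ivw(clump(harmonize(gwas_subset(ins, match(m$snps, ins$snp)),
                           d$outcome), d$ld))
  expect_equal(m$effects$estimate[1], u$estimate, tolerance = 0.02)
  expect_lt(abs(m$effects$estimate[2]), 0.1)
})

test_that("MVMR recovers known direct effects and rejects singular designs", {
  # truth (theta_direct, theta_M) = (0.3, 0): mediator has instruments but
  # transmits nothing to the outcome
  d <- chain_data(503, delta = 0.5, theta_M = 0, theta_direct = 0.3)
  m <- mvmr_ivw(list(exposure = d$exposure, mediator = d$mediator),
                d$outcome, d$ld)
  expect_lt(abs(m$effects$estimate[1] - 0.3), 0.02)
  expect_lt(abs(m$effects$estimate[2] - 0.0), 0.02)
  expect_gt(min(m$conditional_F), 10)
  # duplicated exposure column -> singular
  expect_mr_error(
    mvmr_ivw(list(a = d$exposure, b = d$exposure), d$outcome, d$ld),
    "mr_singular_error")
})

test_that("conditional F follows the projection formula", {
  set.seed(504)
  J <- 40
  bx <- runif(J, 0.05, 0.2); sx <- runif(J, 0.005, 0.02)
  # co-exposure betas all zero: Q_x = sum((bx/sx)^2), F = Q_x/(J - K + 1)
  B <- cbind(bx, rep(0, J)); S <- cbind(sx, rep(0.01, J))
  fs <- conditional_f(B, S)
  expect_equal(fs[1], sum((bx / sx)^2) / (J - 2 + 1), tolerance = 1e-12)
  # exact linear combination -> conditional F ~ 0
  B2 <- cbind(bx, 2 * bx); S2 <- cbind(sx, sx)
  fs2 <- conditional_f(B2, S2)
  expect_lt(fs2[1], 1e-18)
  expect_lt(fs2[2], 1e-18)
  # single exposure: reduces to the mean per-SNP F
  f1 <- conditional_f(matrix(bx, ncol = 1), matrix(sx, ncol = 1))
  expect_equal(f1, mean((bx / sx)^2), tolerance = 1e-12)
})

test_that("conditional F drops below marginal F when instruments are shared", {
  set.seed(505)
  for (i in 1:5) {
    d <- chain_data(520 + i)
    m <- mvmr_ivw(list(exposure = d$exposure, mediator = d$mediator),
                  d$outcome, d$ld)
    idx <- match(m$snps, d$exposure$snp)
    marginal <- mean((d$exposure$beta[idx] / d$exposure$se[idx])^2)
    # the mediator carries delta * gamma: instruments are shared, so the
    # exposure's conditional strength must fall below its marginal strength
    expect_lt(m$conditional_F[1], marginal)
  }
})

test_that("mediate screens pathways and classifies attenuation", {
  d <- chain_data(506)
  reps <- mediate(d$exposure, d$outcome, list(med = d$mediator), d$ld)
  expect_length(reps, 1)
  rp <- reps$med
  expect_s3_class(rp, "mediation_report")
  expect_lt(abs(rp$total$estimate - 0.3), 0.05)
  expect_lt(abs(rp$direct$estimate - 0.1), 0.05)
  expect_true(rp$attenuation %in% c("partially_attenuated", "attenuated_to_null"))
  # gate conditions: both screens were significant by construction
  expect_lt(rp$total$pval, 0.05)
  expect_lt(rp$exposure_to_mediator$pval, 0.05)

  # a mediator unrelated to the exposure is dropped at step 2
  set.seed(506)
  noise_med <- gwas_table(data.frame(
    snp = d$exposure$snp, effect_allele = d$exposure$effect_allele,
    other_allele = d$exposure$other_allele, eaf = d$exposure$eaf,
    beta = rnorm(nrow(d$exposure), 0, 0.003), se = 0.003, pval = 0.5,
    n = 200000), trait_name = "noise")
  reps2 <- mediate(d$exposure, d$outcome, list(noise = noise_med), d$ld)
  expect_length(reps2, 0)

  # null total effect -> empty report list at step 1
  s0 <- synthetic_scenario(J = 30, theta = 0, seed = 507)
  d0 <- generate_gwas(s0)
  reps3 <- mediate(d0$exposure, d0$outcome, list(med = d$mediator), d0$ld)
  expect_length(reps3, 0)
})
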