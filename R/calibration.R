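#' Simulation-based calibration suite
#'
#' Recomputes, from scratch and under a single seed, the package's standing
#' battery of correctness and calibration checks: oracle equivalence of the
#' IVW estimator, the instrument-strength identity, type-I error and CI
#' coverage of IVW, MR-Egger intercept recovery under InSIDE, weighted-median
#' robustness to invalid instruments, MR-PRESSO outlier detection and null
#' calibration, harmonization round-trips under injected corruption, the
#' clumping oracle, and mediation-chain recovery. Each component simulates
#' its own stated world with the synthetic generator; the worlds and their
#' rationale are documented in the methods vignette and are not tuning
#' knobs.
#'
#' @param seed master seed; every replicate seed derives from it.
#' @param reps named list overriding replicate counts (`type1`, `recovery`,
#'   `egger`, `wm`, `presso`, `clump`, `mediation`), e.g. for quick looks.
#' @return named list of numeric metrics, each with an `n` attribute giving
#'   the problem size (replicates or instances) behind it.
#' @export
mr_calibration <- function(seed = 1, reps = list()) {
  R <- utils::modifyList(list(type1 = 1000, recovery = 1000, egger = 500,
                              wm = 200, presso = 200, clump = 200,
                              mediation = 500), reps)
  base <- with_seed(seed, sample.int(2^20, 12))
  out <- list()
  met <- function(value, n) structure(value, n = n)

  sim_ivw <- function(s) {
    d <- generate_gwas(s)
    ivw(harmonize(d$exposure, d$outcome))
  }

  ## 1. IVW vs independent weighted-least-squares oracle (lm route)
  devs <- with_seed(base[1], {
    vapply(seq_len(50), function(i) {
      bx <- stats::rnorm(10, 0, 0.1); by <- stats::rnorm(10, 0, 0.05)
      sy <- stats::runif(10, 0.005, 0.05)
      fit <- stats::lm(by ~ 0 + bx, weights = 1 / sy^2)
      h <- data.frame(snp = sprintf("s%d", 1:10), beta_exp = bx, se_exp = 0.01,
                      beta_out = by, se_out = sy)
      abs(ivw(h)$estimate - unname(stats::coef(fit)))
    }, numeric(1))
  })
  out$ivw_oracle_max_dev <- met(max(devs), 50)

  ## 2. strength identity: k = 1 overall F equals (beta/se)^2; spot value
  g <- gwas_table(data.frame(snp = "s", effect_allele = "A", other_allele = "G",
                             eaf = 0.3, beta = 0.1, se = 0.01, pval = 1e-10,
                             n = 102))
  st <- overall_strength(g)
  out$f_spot <- met(st$f_overall, 1)
  out$r2_spot <- met(st$r2_total, 1)

  ## 3. type-I error of IVW at the null
  rej <- with_seed(base[2], {
    vapply(seq_len(R$type1), function(i) {
      s <- synthetic_scenario(J = 50, theta = 0, seed = base[2] + i)
      sim_ivw(s)$pval < 0.05
    }, logical(1))
  })
  out$type1_rate <- met(mean(rej), R$type1)

  ## 4. parameter recovery: bias and 95% CI coverage at theta = 0.2
  rec <- with_seed(base[3], {
    t(vapply(seq_len(R$recovery), function(i) {
      s <- synthetic_scenario(J = 100, theta = 0.2, seed = base[3] + i)
      r <- sim_ivw(s)
      c(r$estimate, r$ci_low <= 0.2 && 0.2 <= r$ci_high)
    }, numeric(2)))
  })
  out$recovery_bias <- met(mean(rec[, 1]) - 0.2, R$recovery)
  out$recovery_coverage <- met(mean(rec[, 2]), R$recovery)

  ## 5. MR-Egger: intercept recovery under InSIDE, slope bias vs IVW's
  ## no-pleiotropy bias in the same world (moderate instrument strength so
  ## both dilution biases are measurable; see vignette)
  egger_world <- function(i, pleio) {
    synthetic_scenario(J = 50, theta = 0.5,
                       gamma_law = list(min = 0.02, max = 0.1, sign_prob = 0),
                       n_exp = 8000, n_out = 100000,
                       pleiotropy = if (pleio)
                         list(fraction_invalid = 1, mu_alpha = 0.05,
                              tau_alpha = 0.03, inside = TRUE)
                       else list(fraction_invalid = 0),
                       seed = i)
  }
  eg <- with_seed(base[4], {
    t(vapply(seq_len(R$egger), function(i) {
      d <- generate_gwas(egger_world(base[4] + i, TRUE))
      e <- egger(harmonize(d$exposure, d$outcome))
      np <- sim_ivw(egger_world(base[5] + i, FALSE))
      c(e$intercept$estimate, e$slope$estimate, np$estimate)
    }, numeric(3)))
  })
  out$egger_intercept_err <- met(mean(eg[, 1]) - 0.05, R$egger)
  out$egger_intercept_3mcse <- met(3 * stats::sd(eg[, 1]) / sqrt(R$egger), R$egger)
  out$egger_slope_bias <- met(abs(mean(eg[, 2]) - 0.5), R$egger)
  out$ivw_nopleio_bias <- met(abs(mean(eg[, 3]) - 0.5), R$egger)

  ## 6. weighted median robustness at 40% / 60% invalid instruments
  wm_world <- function(i, frac) {
    synthetic_scenario(J = 50, theta = 0.2,
                       gamma_law = list(min = 0.05, max = 0.15, sign_prob = 0),
                       n_exp = 300000, n_out = 1500000,
                       pleiotropy = list(fraction_invalid = frac,
                                         mu_alpha = 0.03, tau_alpha = 0.005),
                       seed = i)
  }
  wm <- with_seed(base[6], {
    t(vapply(seq_len(R$wm), function(i) {
      d40 <- generate_gwas(wm_world(base[6] + i, 0.4))
      h40 <- harmonize(d40$exposure, d40$outcome)
      d60 <- generate_gwas(wm_world(base[7] + i, 0.6))
      h60 <- harmonize(d60$exposure, d60$outcome)
      c(weighted_median(h40, n_boot = 10, seed = i)$estimate,
        ivw(h40)$estimate,
        weighted_median(h60, n_boot = 10, seed = i)$estimate)
    }, numeric(3)))
  })
  out$wm_bias_40 <- met(abs(mean(wm[, 1]) - 0.2), R$wm)
  out$ivw_bias_40 <- met(abs(mean(wm[, 2]) - 0.2), R$wm)
  out$wm_bias_60 <- met(abs(mean(wm[, 3]) - 0.2), R$wm)

  ## 7. MR-PRESSO: planted 10-sigma outlier; null global-test calibration
  pres <- with_seed(base[8], {
    t(vapply(seq_len(R$presso), function(i) {
      s <- synthetic_scenario(J = 10, theta = 0.1,
                              gamma_law = list(min = 0.05, max = 0.12),
                              maf_range = c(0.1, 0.5), seed = base[8] + i)
      d <- generate_gwas(s)
      h <- harmonize(d$exposure, d$outcome)
      j <- ((i - 1) %% nrow(h)) + 1
      h$beta_out[j] <- h$beta_out[j] + 10 * h$se_out[j]
      p <- mr_presso(h, n_sim = 1000, seed = base[8] + i)
      c(h$snp[j] %in% p$outliers$snp,
        abs(p$corrected$estimate - 0.1) < abs(p$raw$estimate - 0.1))
    }, numeric(2)))
  })
  out$presso_outlier_rate <- met(mean(pres[, 1]), R$presso)
  out$presso_closer_rate <- met(mean(pres[, 2]), R$presso)
  nullrej <- with_seed(base[9], {
    vapply(seq_len(R$presso), function(i) {
      s <- synthetic_scenario(J = 20, theta = 0.1, seed = base[9] + i)
      d <- generate_gwas(s)
      mr_presso(harmonize(d$exposure, d$outcome), n_sim = 1000,
                seed = base[9] + i)$global_pval < 0.05
    }, logical(1))
  })
  out$presso_null_rate <- met(mean(nullrej), R$presso)

  ## 8. harmonization round-trip under corruption; palindrome window rule
  s8 <- synthetic_scenario(J = 60, theta = 0.2,
                           corruption = list(strand_flip = 0.3, allele_swap = 0.3),
                           seed = base[10])
  d8 <- generate_gwas(s8)
  r_corrupt <- ivw(harmonize(d8$exposure, d8$outcome))
  r_clean <- ivw(harmonize(d8$exposure, d8$truth$outcome_clean))
  out$harmonize_roundtrip_dev <- met(abs(r_corrupt$estimate - r_clean$estimate), 60)
  s8b <- synthetic_scenario(J = 200, theta = 0.2,
                            corruption = list(palindrome = 1), seed = base[10] + 1)
  d8b <- generate_gwas(s8b)
  h8b <- harmonize(d8b$exposure, d8b$outcome)
  ambiguous <- d8b$truth$snp[d8b$truth$maf >= 0.42 & d8b$truth$maf <= 0.58]
  out$palindrome_window_violations <-
    met(sum(ambiguous %in% h8b$snp), length(ambiguous))

  ## 9. clumping vs brute-force greedy oracle
  mism <- with_seed(base[11], {
    vapply(seq_len(R$clump), function(i) {
      snps <- sprintf("rs%02d", 1:20)
      pv <- 10^stats::runif(20, -12, -4)
      pairs <- t(utils::combn(snps, 2))
      pick <- stats::runif(nrow(pairs)) < 0.3
      ld <- if (any(pick)) {
        r2 <- ifelse(stats::runif(sum(pick)) < 0.5,
                     stats::runif(sum(pick), 0, 0.001),
                     stats::runif(sum(pick), 0.001, 1))
        ld_matrix(pairs[pick, 1], pairs[pick, 2], r2)
      } else ld_matrix()
      g <- data.frame(snp = snps, pval = pv)
      kept <- clump(g, ld)$snp
      # independent oracle: sequential greedy with full pair re-checks
      ord <- order(pv, snps)
      keep <- character(0)
      for (s in snps[ord]) {
        if (!length(keep) ||
            all(ld_r2(ld, rep(s, length(keep)), keep) < 0.001)) {
          keep <- c(keep, s)
        }
      }
      ok <- setequal(kept, keep)
      if (ok && length(kept) > 1) {
        prs <- t(utils::combn(kept, 2))
        ok <- all(ld_r2(ld, prs[, 1], prs[, 2]) < 0.001)
      }
      if (ok) {
        for (s in setdiff(snps, kept)) {
          culp <- kept[ld_r2(ld, rep(s, length(kept)), kept) >= 0.001]
          ok <- ok && any(pv[match(culp, snps)] <= pv[match(s, snps)])
        }
      }
      !ok
    }, logical(1))
  })
  out$clump_oracle_mismatches <- met(sum(mism), R$clump)

  ## 10. mediation chain recovery; MVMR single-exposure identity
  medn <- with_seed(base[12], {
    t(vapply(seq_len(R$mediation), function(i) {
      s <- synthetic_scenario(J = 100, n_exp = 200000, n_out = 200000,
                              gamma_law = list(min = 0.1, max = 0.3),
                              mediator = list(delta = 0.5, theta_M = 0.4,
                                              theta_direct = 0.1,
                                              n_med = 200000, J_med = 50),
                              seed = base[12] + i)
      d <- generate_gwas(s)
      rp <- mediate(d$exposure, d$outcome, list(m = d$mediator), d$ld)
      c(attr(rp, "total")$estimate,
        if (length(rp)) rp[[1]]$direct$estimate else NA_real_)
    }, numeric(2)))
  })
  out$mediation_total_mean <- met(mean(medn[, 1]), R$mediation)
  out$mediation_direct_mean <- met(mean(medn[, 2], na.rm = TRUE), R$mediation)
  out$mediation_total_3mcse <-
    met(3 * stats::sd(medn[, 1]) / sqrt(R$mediation), R$mediation)
  out$mediation_direct_3mcse <-
    met(3 * stats::sd(medn[, 2], na.rm = TRUE) / sqrt(R$mediation), R$mediation)
  d10 <- generate_gwas(synthetic_scenario(J = 40, theta = 0.2,
                                          gamma_law = list(min = 0.1, max = 0.3),
                                          seed = base[12]))
  u10 <- ivw(clump(harmonize(select_instruments(d10$exposure), d10$outcome),
                   d10$ld))
  m10 <- mvmr_ivw(list(exposure = d10$exposure), d10$outcome, d10$ld)
  out$mvmr_univariable_dev <- met(abs(m10$effects$estimate[1] - u10$estimate), 40)

  out
}
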