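NONPAL_PAIRS <- rbind(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
                      c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))
PAL_PAIRS <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Define a synthetic two-sample GWAS scenario
#'
#' Describes the generative world for [generate_gwas()]: the number of
#' instruments, the true causal effect, the law of SNP-exposure effects and
#' allele frequencies, sample sizes, pleiotropy (invalid-instrument fraction,
#' mean and SD of direct effects, InSIDE on/off), an optional mediator path,
#' an optional reverse (outcome-to-exposure) path, harmonization corruption
#' rates, and optional exchangeable LD blocks.
#'
#' @param J number of exposure-associated SNPs.
#' @param theta true causal effect of the exposure on the outcome per
#'   exposure unit (log-OR per unit when the outcome is binary). Ignored when
#'   `mediator` is supplied (the mediated decomposition defines the total).
#' @param gamma_law list `min`, `max`, `sign_prob`: SNP-exposure effect
#'   magnitudes are uniform on `[min, max]`, negated with probability
#'   `sign_prob`.
#' @param maf_range range of the minor-allele-frequency distribution.
#' @param n_exp,n_out exposure and outcome GWAS sample sizes (>= 100).
#' @param outcome_binary logical; with `n_case`/`n_control` the outcome SEs
#'   use the case-control log-OR approximation.
#' @param n_case,n_control case/control counts for a binary outcome.
#' @param pleiotropy list `fraction_invalid`, `mu_alpha`, `tau_alpha`,
#'   `inside`. Invalid SNPs receive a direct effect `alpha ~ N(mu_alpha,
#'   tau_alpha^2)`, independent of the SNP-exposure effect when `inside` is
#'   `TRUE`, correlated with it otherwise.
#' @param mediator optional list `delta` (exposure to mediator), `theta_M`
#'   (mediator to outcome), `theta_direct` (residual direct effect), `n_med`
#'   (mediator GWAS size), `J_med` (mediator-specific instruments). The
#'   implied total effect is `theta_direct + delta * theta_M`.
#' @param feedback optional list `J_out`, `theta_rev`: outcome-specific
#'   instruments with a reverse effect `theta_rev` on the exposure, enabling
#'   bidirectional analyses.
#' @param corruption list `strand_flip`, `allele_swap`, `palindrome`:
#'   fractions of outcome records reported on the complementary strand, with
#'   swapped effect/other alleles, and of SNPs given palindromic allele pairs.
#' @param ld_blocks optional list `n_blocks`, `block_size`, `r2`:
#'   exchangeable within-block LD among the first SNPs.
#' @param seed integer RNG seed; generation is fully reproducible.
#' @return a validated `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(J = 50, theta = 0,
                               gamma_law = list(min = 0.02, max = 0.10, sign_prob = 0.5),
                               maf_range = c(0.01, 0.5),
                               n_exp = 130000, n_out = 130000,
                               outcome_binary = FALSE,
                               n_case = NULL, n_control = NULL,
                               pleiotropy = list(fraction_invalid = 0, mu_alpha = 0,
                                                 tau_alpha = 0, inside = TRUE),
                               mediator = NULL, feedback = NULL,
                               corruption = list(strand_flip = 0, allele_swap = 0,
                                                 palindrome = 0),
                               ld_blocks = NULL, seed = 1) {
  defaults <- list(fraction_invalid = 0, mu_alpha = 0, tau_alpha = 0, inside = TRUE)
  pleiotropy <- utils::modifyList(defaults, pleiotropy)
  corruption <- utils::modifyList(list(strand_flip = 0, allele_swap = 0,
                                       palindrome = 0), corruption)
  gamma_law <- utils::modifyList(list(min = 0.02, max = 0.10, sign_prob = 0.5),
                                 gamma_law)
  s <- list(J = as.integer(J), theta = theta, gamma_law = gamma_law,
            maf_range = maf_range, n_exp = n_exp, n_out = n_out,
            outcome_binary = isTRUE(outcome_binary),
            n_case = n_case, n_control = n_control,
            pleiotropy = pleiotropy, mediator = mediator,
            feedback = feedback, corruption = corruption,
            ld_blocks = ld_blocks, seed = as.integer(seed))
  frac <- c(pleiotropy$fraction_invalid, unlist(corruption))
  if (any(frac < 0 | frac > 1)) {
    stop_mr("mr_validation_error", "fractions must lie in [0, 1]")
  }
  if (n_exp < 100 || n_out < 100) {
    stop_mr("mr_validation_error", "sample sizes must be at least 100")
  }
  if (s$outcome_binary && (is.null(n_case) || is.null(n_control))) {
    stop_mr("mr_validation_error", "binary outcome requires n_case and n_control")
  }
  if (!is.null(mediator)) {
    need <- c("delta", "theta_M", "theta_direct")
    if (!all(need %in% names(mediator))) {
      stop_mr("mr_validation_error", "mediator needs delta, theta_M, theta_direct")
    }
    s$mediator$n_med <- mediator$n_med %||% n_exp
    s$mediator$J_med <- as.integer(mediator$J_med %||% max(10L, J %/% 2L))
  }
  if (!is.null(feedback)) {
    s$feedback$J_out <- as.integer(feedback$J_out %||% 20L)
    s$feedback$theta_rev <- feedback$theta_rev %||% 0
  }
  if (s$J < 1) stop_mr("mr_validation_error", "J must be positive")
  structure(s, class = "synthetic_scenario")
}

draw_gamma <- function(n, law) {
  mag <- stats::runif(n, law$min, law$max)
  sgn <- ifelse(stats::runif(n) < law$sign_prob, -1, 1)
  mag * sgn
}

# per-SNP standard error under the standardized-trait approximation
se_from_n <- function(n, maf) 1 / sqrt(2 * n * maf * (1 - maf))

assoc_frame <- function(snp, ea, oa, eaf, true_beta, se) {
  beta_hat <- true_beta + stats::rnorm(length(se), 0, se)
  data.frame(snp = snp, effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta_hat, se = se,
             pval = pmax(2 * stats::pnorm(-abs(beta_hat / se)), 1e-300),
             stringsAsFactors = FALSE)
}

#' Generate synthetic two-sample GWAS summary statistics
#'
#' Realizes a [synthetic_scenario()]: draws allele frequencies and true
#' SNP-exposure effects, adds estimation noise with standard errors scaled by
#' sample size and allele frequency (`se = 1/sqrt(2 n maf (1-maf))`; binary
#' outcomes use the case-control log-OR scaling
#' `sqrt(1/n_case + 1/n_control)`), injects pleiotropic direct effects for
#' the invalid fraction, builds mediator and reverse-path tables when
#' requested, and finally corrupts outcome records (strand complements,
#' effect/other allele swaps) and converts a fraction of SNPs to palindromic
#' allele pairs so that harmonization has real work to do. Exposure and
#' outcome noise are independent (two-sample regime). Everything is
#' reproducible from the scenario seed.
#'
#' @param s a `synthetic_scenario`.
#' @return list with `exposure`, `outcome`, optional `mediator`
#'   `gwas_table`s, `ld` (`ld_matrix`), and `truth` (a `truth_record`:
#'   realized `theta_total`, `theta_direct`, per-SNP `gamma` and `alpha`,
#'   invalid mask, corruption log, and uncorrupted copies of the tables).
#' @export
generate_gwas <- function(s) {
  stopifnot(inherits(s, "synthetic_scenario"))
  with_seed(s$seed, generate_gwas_impl(s))
}

generate_gwas_impl <- function(s) {
  J <- s$J
  med <- s$mediator
  fb <- s$feedback
  J_med <- if (is.null(med)) 0L else med$J_med
  J_out <- if (is.null(fb)) 0L else fb$J_out
  J_all <- J + J_med + J_out
  snp <- sprintf("rs%06d", seq_len(J_all))
  role <- rep(c("exposure", "mediator", "outcome"), c(J, J_med, J_out))

  maf <- stats::runif(J_all, s$maf_range[1], s$maf_range[2])
  pal <- stats::runif(J_all) < s$corruption$palindrome
  ea <- oa <- character(J_all)
  if (any(pal)) {
    idx <- sample.int(nrow(PAL_PAIRS), sum(pal), replace = TRUE)
    ea[pal] <- PAL_PAIRS[idx, 1]; oa[pal] <- PAL_PAIRS[idx, 2]
  }
  if (any(!pal)) {
    idx <- sample.int(nrow(NONPAL_PAIRS), sum(!pal), replace = TRUE)
    ea[!pal] <- NONPAL_PAIRS[idx, 1]; oa[!pal] <- NONPAL_PAIRS[idx, 2]
  }

  # true per-SNP effects on the exposure
  gamma <- numeric(J_all)
  gamma[role == "exposure"] <- draw_gamma(J, s$gamma_law)
  eta <- numeric(J_all)          # mediator-specific effects on the mediator
  if (J_med > 0) eta[role == "mediator"] <- draw_gamma(J_med, s$gamma_law)
  gout <- numeric(J_all)         # outcome-specific effects (feedback block)
  if (J_out > 0) gout[role == "outcome"] <- draw_gamma(J_out, s$gamma_law)
  theta_rev <- if (is.null(fb)) 0 else fb$theta_rev
  gamma_exp_true <- gamma + theta_rev * gout

  # pleiotropic direct effects on the outcome for the invalid fraction
  pl <- s$pleiotropy
  n_invalid <- round(pl$fraction_invalid * J)
  invalid <- rep(FALSE, J_all)
  if (n_invalid > 0) {
    pick <- sample(which(role == "exposure"), n_invalid)
    invalid[pick] <- TRUE
  }
  alpha <- numeric(J_all)
  if (any(invalid)) {
    z <- stats::rnorm(sum(invalid))
    if (isTRUE(pl$inside)) {
      alpha[invalid] <- pl$mu_alpha + pl$tau_alpha * z
    } else {
      g <- gamma[invalid]
      gs <- if (stats::sd(g) > 0) (g - mean(g)) / stats::sd(g) else rep(0, length(g))
      rho <- 0.7
      alpha[invalid] <- pl$mu_alpha + pl$tau_alpha * (rho * gs + sqrt(1 - rho^2) * z)
    }
  }

  if (is.null(med)) {
    theta_direct <- s$theta
    theta_total <- s$theta
    med_true <- NULL
    out_true <- s$theta * gamma + alpha + gout
  } else {
    theta_direct <- med$theta_direct
    theta_total <- med$theta_direct + med$delta * med$theta_M
    med_true <- med$delta * gamma + eta
    out_true <- med$theta_direct * gamma + med$theta_M * med_true + alpha + gout
  }

  se_exp <- se_from_n(s$n_exp, maf)
  exposure_df <- assoc_frame(snp, ea, oa, maf, gamma_exp_true, se_exp)
  exposure_df$n <- s$n_exp
  exposure <- gwas_table(exposure_df, trait_name = "exposure",
                         trait_units = "unit", is_binary = FALSE, sex = "both")

  if (s$outcome_binary) {
    se_out <- sqrt(1 / s$n_case + 1 / s$n_control) / sqrt(2 * maf * (1 - maf))
    n_out_col <- s$n_case + s$n_control
  } else {
    se_out <- se_from_n(s$n_out, maf)
    n_out_col <- s$n_out
  }
  outcome_df <- assoc_frame(snp, ea, oa, maf, out_true, se_out)
  outcome_df$n <- n_out_col
  if (s$outcome_binary) {
    outcome_df$n_case <- s$n_case
    outcome_df$n_control <- s$n_control
  }
  outcome_clean <- gwas_table(outcome_df, trait_name = "outcome",
                              trait_units = if (s$outcome_binary) "log(OR)" else "unit",
                              is_binary = s$outcome_binary, sex = "both")

  mediator_tbl <- NULL
  if (!is.null(med)) {
    se_med <- se_from_n(med$n_med, maf)
    mediator_df <- assoc_frame(snp, ea, oa, maf, med_true, se_med)
    mediator_df$n <- med$n_med
    mediator_tbl <- gwas_table(mediator_df, trait_name = "mediator",
                               trait_units = "unit", is_binary = FALSE)
  }

  # corruption of the outcome records: strand complements and allele swaps
  strand <- stats::runif(J_all) < s$corruption$strand_flip
  strand[pal] <- FALSE                     # complementing a palindrome is a no-op
  swap <- stats::runif(J_all) < s$corruption$allele_swap
  corrupted <- as.data.frame(outcome_clean)
  ci <- match(snp, corrupted$snp)
  for (j in seq_len(J_all)) {
    i <- ci[j]
    if (is.na(i)) next
    if (strand[j]) {
      corrupted$effect_allele[i] <- unname(COMPLEMENT[corrupted$effect_allele[i]])
      corrupted$other_allele[i] <- unname(COMPLEMENT[corrupted$other_allele[i]])
    }
    if (swap[j]) {
      tmp <- corrupted$effect_allele[i]
      corrupted$effect_allele[i] <- corrupted$other_allele[i]
      corrupted$other_allele[i] <- tmp
      corrupted$beta[i] <- -corrupted$beta[i]
      corrupted$eaf[i] <- 1 - corrupted$eaf[i]
    }
  }
  outcome <- gwas_table(corrupted, trait_name = "outcome",
                        trait_units = attr(outcome_clean, "trait_units"),
                        is_binary = s$outcome_binary, sex = "both")

  # exchangeable LD blocks among the leading exposure SNPs
  ld_a <- ld_b <- character(0); ld_v <- numeric(0)
  lb <- s$ld_blocks
  if (!is.null(lb) && lb$n_blocks > 0 && lb$block_size > 1) {
    for (b in seq_len(lb$n_blocks)) {
      ids <- snp[((b - 1) * lb$block_size + 1):min(b * lb$block_size, J)]
      if (length(ids) < 2) break
      cmb <- utils::combn(ids, 2)
      ld_a <- c(ld_a, cmb[1, ]); ld_b <- c(ld_b, cmb[2, ])
      ld_v <- c(ld_v, rep(lb$r2, ncol(cmb)))
    }
  }
  ld <- ld_matrix(ld_a, ld_b, ld_v)

  truth <- structure(list(
    theta_total = theta_total, theta_direct = theta_direct,
    delta = if (is.null(med)) NA_real_ else med$delta,
    theta_M = if (is.null(med)) NA_real_ else med$theta_M,
    theta_rev = theta_rev,
    snp = snp, role = role, gamma = gamma, eta = eta, gamma_out = gout,
    alpha = alpha, invalid = invalid, maf = maf,
    corruption_log = data.frame(snp = snp, strand_flipped = strand,
                                swapped = swap, palindromic = pal,
                                stringsAsFactors = FALSE),
    exposure_clean = exposure, outcome_clean = outcome_clean,
    scenario = s), class = "truth_record")

  list(exposure = exposure, outcome = outcome, mediator = mediator_tbl,
       ld = ld, truth = truth)
}

#' Named scenario presets
#'
#' Ready-made scenarios sized like the study designs the package targets:
#' `afb_like` (18 instruments, binary outcome, adverse effect of an earlier
#' exposure), `births_like` (9 instruments), `menarche_like` (208
#' instruments), `menopause_like` (154 instruments, null effect),
#' `mediation_chain` (direct 0.1, delta 0.5, theta_M 0.4, so total 0.3), and
#' `null` (theta 0, no pleiotropy).
#'
#' @param seed base seed stored in every preset.
#' @return named list of `synthetic_scenario` objects.
#' @export
scenario_presets <- function(seed = 1) {
  list(
    afb_like = synthetic_scenario(
      J = 18, theta = -0.40, n_exp = 131987, outcome_binary = TRUE,
      n_case = 60000, n_control = 120000,
      pleiotropy = list(fraction_invalid = 0.1, mu_alpha = 0, tau_alpha = 0.02),
      seed = seed),
    births_like = synthetic_scenario(
      J = 9, theta = 0.55, n_exp = 193953, outcome_binary = TRUE,
      n_case = 60000, n_control = 970000, seed = seed),
    menarche_like = synthetic_scenario(
      J = 208, theta = -0.095, n_exp = 329345, outcome_binary = TRUE,
      n_case = 60000, n_control = 120000,
      pleiotropy = list(fraction_invalid = 0.1, mu_alpha = 0, tau_alpha = 0.02),
      seed = seed),
    menopause_like = synthetic_scenario(
      J = 154, theta = 0, n_exp = 106048, outcome_binary = TRUE,
      n_case = 60000, n_control = 120000, seed = seed),
    mediation_chain = synthetic_scenario(
      J = 100, n_exp = 200000, n_out = 200000,
      gamma_law = list(min = 0.1, max = 0.3),
      mediator = list(delta = 0.5, theta_M = 0.4, theta_direct = 0.1,
                      n_med = 200000, J_med = 50),
      seed = seed),
    null = synthetic_scenario(J = 50, theta = 0, seed = seed)
  )
}

#' Write a generated scenario to TSV files
#'
#' Emits `exposure.tsv`, `outcome.tsv`, optionally `mediator.tsv`, `ld.tsv`,
#' `truth_global.tsv` (key-value) and `truth_snp.tsv` (per-SNP truth).
#'
#' @param data list returned by [generate_gwas()].
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_scenario <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gwas(data$exposure, file.path(dir, "exposure.tsv"))
  write_gwas(data$outcome, file.path(dir, "outcome.tsv"))
  if (!is.null(data$mediator)) {
    write_gwas(data$mediator, file.path(dir, "mediator.tsv"))
  }
  write_ld(data$ld, file.path(dir, "ld.tsv"))
  tr <- data$truth
  glob <- data.frame(
    param = c("theta_total", "theta_direct", "delta", "theta_M", "theta_rev"),
    value = c(tr$theta_total, tr$theta_direct, tr$delta, tr$theta_M, tr$theta_rev))
  write_tsv_full(glob, file.path(dir, "truth_global.tsv"))
  per <- data.frame(snp = tr$snp, role = tr$role, gamma = tr$gamma,
                    eta = tr$eta, gamma_out = tr$gamma_out, alpha = tr$alpha,
                    invalid = tr$invalid, maf = tr$maf,
                    stringsAsFactors = FALSE)
  write_tsv_full(per, file.path(dir, "truth_snp.tsv"))
  invisible(dir)
}
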