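#' Construct an MR result
#'
#' Normalizes an estimate/SE pair into the common result container: 95%
#' normal-theory confidence bounds, two-sided normal p-value, and (for binary
#' outcomes) exponentiated odds-ratio copies.
#'
#' @param method method tag.
#' @param estimate,se point estimate (log-OR scale for binary outcomes) and SE.
#' @param n_snp number of instruments used.
#' @param binary whether the outcome is binary (populates `or` fields).
#' @param ... extra fields stored verbatim (e.g. `q_stat`, `phi`, `exposure`).
#' @return an `mr_result` list.
#' @export
mr_result <- function(method, estimate, se, n_snp, binary = FALSE, ...) {
  estimate <- unname(estimate); se <- unname(se)
  stopifnot(is.finite(estimate), is.finite(se), se > 0)
  z <- z975()
  out <- list(method = method, n_snp = as.integer(n_snp),
              estimate = estimate, se = se,
              ci_low = estimate - z * se, ci_high = estimate + z * se,
              pval = norm_pval(estimate, se),
              or = if (binary) exp(estimate) else NULL,
              or_low = if (binary) exp(estimate - z * se) else NULL,
              or_high = if (binary) exp(estimate + z * se) else NULL,
              ...)
  structure(out, class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %s (%d SNPs): estimate=%.4g se=%.4g [%.4g, %.4g] p=%.3g\n",
              x$method, x$n_snp, x$estimate, x$se, x$ci_low, x$ci_high, x$pval))
  if (!is.null(x$or)) {
    cat(sprintf("  OR=%.3f [%.3f, %.3f]\n", x$or, x$or_low, x$or_high))
  }
  if (!is.null(x$q_stat)) {
    cat(sprintf("  Q=%.3f (p=%.3g), phi=%.3f\n", x$q_stat, x$q_pval, x$phi))
  }
  invisible(x)
}

h_meta <- function(h) {
  list(exposure = attr(h, "exposure_name"),
       outcome = attr(h, "outcome_name"),
       binary = isTRUE(attr(h, "outcome_binary")))
}

check_harmonized <- function(h, min_snps, method) {
  stopifnot(is.data.frame(h))
  need <- c("snp", "beta_exp", "se_exp", "beta_out", "se_out")
  stopifnot(all(need %in% names(h)))
  if (nrow(h) < min_snps) {
    stop_mr("mr_insufficient_instruments_error",
            "%s requires at least %d SNPs, got %d", method, min_snps, nrow(h))
  }
  invisible(h)
}

#' Wald ratio estimate from a single instrument
#'
#' `estimate = beta_out / beta_exp` with the first-order standard error
#' `se_out / |beta_exp|`.
#'
#' @param h a `harmonized_set` with exactly one retained SNP.
#' @return an `mr_result` with method `"wald"`.
#' @export
wald_ratio <- function(h) {
  check_harmonized(h, 1, "wald_ratio")
  if (nrow(h) != 1) {
    stop_mr("mr_insufficient_instruments_error",
            "wald_ratio requires exactly 1 SNP, got %d", nrow(h))
  }
  if (h$beta_exp == 0) {
    stop_mr("mr_degenerate_error", "degenerate instrument: beta_exp = 0")
  }
  m <- h_meta(h)
  mr_result("wald", h$beta_out / h$beta_exp, h$se_out / abs(h$beta_exp),
            n_snp = 1, binary = m$binary,
            exposure = m$exposure, outcome = m$outcome)
}

# closed-form inverse-variance weighted fit; shared by ivw() and mr_presso()
ivw_fit <- function(bx, by, sy) {
  w <- 1 / sy^2
  sxx <- sum(w * bx^2)
  est <- sum(w * bx * by) / sxx
  se_fixed <- 1 / sqrt(sxx)
  q <- sum(w * (by - est * bx)^2)
  list(estimate = est, se_fixed = se_fixed, q = q)
}

#' Inverse-variance weighted MR with multiplicative random effects
#'
#' Weighted regression of the SNP-outcome effects on the SNP-exposure effects
#' through the origin with weights `1/se_out^2`. Cochran's Q on the weighted
#' residuals yields the overdispersion factor `phi = Q/(J-1)`; under the
#' multiplicative random-effects model (the default) the fixed-effect SE is
#' inflated by `sqrt(max(1, phi))`, so the SE never drops below the
#' fixed-effect value. A single-SNP set delegates to [wald_ratio()].
#'
#' @param h a `harmonized_set`.
#' @param random_effects apply the multiplicative SE inflation (default TRUE).
#' @return an `mr_result` with method `"ivw_mre"` (or `"ivw_fe"`), including
#'   `q_stat`, `q_pval` and `phi`.
#' @export
ivw <- function(h, random_effects = TRUE) {
  check_harmonized(h, 1, "ivw")
  if (nrow(h) == 1) return(wald_ratio(h))
  if (all(h$beta_exp == 0)) {
    stop_mr("mr_degenerate_error", "degenerate instruments: all beta_exp = 0")
  }
  J <- nrow(h)
  fit <- ivw_fit(h$beta_exp, h$beta_out, h$se_out)
  phi <- fit$q / (J - 1)
  se <- if (random_effects) fit$se_fixed * sqrt(max(1, phi)) else fit$se_fixed
  m <- h_meta(h)
  mr_result(if (random_effects) "ivw_mre" else "ivw_fe",
            fit$estimate, se, n_snp = J, binary = m$binary,
            q_stat = fit$q,
            q_pval = stats::pchisq(fit$q, df = J - 1, lower.tail = FALSE),
            phi = phi, se_fixed = fit$se_fixed,
            exposure = m$exposure, outcome = m$outcome)
}

#' MR-Egger regression
#'
#' SNPs are first oriented so every SNP-exposure effect is non-negative (both
#' betas flipped together), then SNP-outcome effects are regressed on
#' SNP-exposure effects with an intercept, weighted by `1/se_out^2`. The
#' intercept estimates the average directional pleiotropic effect under the
#' InSIDE assumption; the slope is the pleiotropy-adjusted causal estimate.
#' Both standard errors carry the multiplicative overdispersion inflation
#' `sqrt(max(1, Q/(J-2)))`.
#'
#' @param h a `harmonized_set` with at least 3 SNPs and non-constant
#'   SNP-exposure effects.
#' @return an `egger_result`: `slope` (an `mr_result`, method
#'   `"egger_slope"`) and `intercept` (list with `estimate`, `se`, `ci_low`,
#'   `ci_high`, `pval`).
#' @export
egger <- function(h) {
  check_harmonized(h, 3, "egger")
  flip <- sign(h$beta_exp)
  flip[flip == 0] <- 1
  bx <- h$beta_exp * flip
  by <- h$beta_out * flip
  if (diff(range(bx)) < .Machine$double.eps^0.5 * max(1, max(abs(bx)))) {
    stop_mr("mr_singular_error", "all beta_exp identical: Egger design singular")
  }
  w <- 1 / h$se_out^2
  X <- cbind(intercept = 1, slope = bx)
  xtwx <- crossprod(X, w * X)
  if (abs(det(xtwx)) < .Machine$double.eps) {
    stop_mr("mr_singular_error", "singular Egger design")
  }
  coefs <- solve(xtwx, crossprod(X, w * by))
  resid <- by - X %*% coefs
  J <- nrow(h)
  q <- sum(w * resid^2)
  phi <- q / (J - 2)
  covb <- solve(xtwx) * max(1, phi)
  se <- sqrt(diag(covb))
  m <- h_meta(h)
  slope <- mr_result("egger_slope", coefs["slope", 1], se["slope"],
                     n_snp = J, binary = m$binary,
                     q_stat = q,
                     q_pval = stats::pchisq(q, df = J - 2, lower.tail = FALSE),
                     phi = phi,
                     exposure = m$exposure, outcome = m$outcome)
  ic_est <- unname(coefs["intercept", 1])
  ic_se <- unname(se["intercept"])
  intercept <- list(estimate = ic_est, se = ic_se,
                    ci_low = ic_est - z975() * ic_se,
                    ci_high = ic_est + z975() * ic_se,
                    pval = norm_pval(ic_est, ic_se))
  structure(list(slope = slope, intercept = intercept), class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept=%.4g se=%.4g p=%.3g\n",
              x$intercept$estimate, x$intercept$se, x$intercept$pval))
  invisible(x)
}

# interpolated weighted median of ratios r with weights w
weighted_median_point <- function(r, w) {
  ord <- order(r)
  r <- r[ord]; w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median MR estimator
#'
#' The per-SNP Wald ratios `beta_out/beta_exp`, weighted by the inverse
#' variance of the first-order ratio SE (`se_out/|beta_exp|`), are combined
#' by an interpolated weighted median: ratios are sorted, standardized
#' cumulative weights `(cumsum(w) - w/2)/sum(w)` formed, and the ratio at
#' cumulative weight 0.5 interpolated linearly. The estimate is consistent
#' when at least half the total weight comes from valid instruments. The SE
#' is the standard deviation over `n_boot` parametric bootstrap replicates
#' (both betas perturbed by their SEs), seeded for exact reproducibility.
#'
#' @param h a `harmonized_set` with at least 3 SNPs, none with `beta_exp = 0`.
#' @param n_boot bootstrap replicates for the SE (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return an `mr_result` with method `"weighted_median"`.
#' @export
weighted_median <- function(h, n_boot = 1000, seed = 1) {
  check_harmonized(h, 3, "weighted_median")
  if (any(h$beta_exp == 0)) {
    stop_mr("mr_degenerate_error", "beta_exp = 0 gives a degenerate ratio")
  }
  r <- h$beta_out / h$beta_exp
  se_ratio <- h$se_out / abs(h$beta_exp)
  w <- 1 / se_ratio^2
  est <- weighted_median_point(r, w)
  J <- nrow(h)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- h$beta_exp + stats::rnorm(J, 0, h$se_exp)
      by <- h$beta_out + stats::rnorm(J, 0, h$se_out)
      ok <- bx != 0
      rb <- by[ok] / bx[ok]
      wb <- (abs(bx[ok]) / h$se_out[ok])^2
      weighted_median_point(rb, wb)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  m <- h_meta(h)
  mr_result("weighted_median", est, se, n_snp = J, binary = m$binary,
            exposure = m$exposure, outcome = m$outcome)
}

# leave-one-out IVW estimates for all SNPs at once (closed form)
loo_ivw <- function(bx, by, sy) {
  w <- 1 / sy^2
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' Three linked tests built on leave-one-out IVW residuals. (1) Global test:
#' the observed residual sum of squares `RSS = sum_j (beta_out_j -
#' theta_(-j) * beta_exp_j)^2` is compared against `n_sim` parametric
#' simulations of the outcome betas under the leave-one-out fitted model with
#' variances `se_out^2`; the empirical p uses the `(r+1)/(n+1)` estimator.
#' (2) Outlier test: each SNP's observed squared residual gets an empirical p
#' against its simulated distribution, Bonferroni-adjusted by the number of
#' SNPs; SNPs below `outlier_alpha` are flagged. (3) The corrected estimate
#' is IVW on the unflagged SNPs, and a distortion test compares the raw vs
#' corrected difference against differences from random same-size subsets.
#'
#' @param h a `harmonized_set` with at least 4 SNPs.
#' @param n_sim simulation replicates (default 1000).
#' @param outlier_alpha significance level for the Bonferroni-adjusted
#'   per-SNP outlier test (default 0.05).
#' @param seed RNG seed.
#' @return a `presso_result`: `global_rss`, `global_pval`, `outliers` (data
#'   frame of flagged SNPs with adjusted p), `raw` and `corrected`
#'   `mr_result`s, `distortion_pval` (NA when nothing is flagged).
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed = 1) {
  check_harmonized(h, 4, "mr_presso")
  J <- nrow(h)
  bx <- h$beta_exp; by <- h$beta_out; sy <- h$se_out
  theta_loo <- loo_ivw(bx, by, sy)
  obs_res2 <- (by - theta_loo * bx)^2
  obs_rss <- sum(obs_res2)

  sim <- with_seed(seed, {
    # simulate outcome betas under the LOO fitted model, then recompute the
    # LOO residual statistic on each simulated dataset
    sim_by <- matrix(stats::rnorm(n_sim * J, mean = rep(theta_loo * bx, each = n_sim),
                                  sd = rep(sy, each = n_sim)), nrow = n_sim)
    w <- 1 / sy^2
    sxx <- sum(w * bx^2)
    sxy_all <- sim_by %*% (w * bx)                       # n_sim x 1
    num <- matrix(sxy_all, n_sim, J) -
      sweep(sim_by, 2, w * bx, `*`)                      # leave-one-out Sxy
    den <- matrix(sxx - w * bx^2, n_sim, J, byrow = TRUE)
    theta_sim <- num / den
    res2 <- (sim_by - theta_sim * matrix(bx, n_sim, J, byrow = TRUE))^2
    list(res2 = res2, rss = rowSums(res2))
  })
  global_pval <- (sum(sim$rss >= obs_rss) + 1) / (n_sim + 1)

  p_snp <- (colSums(sim$res2 >= matrix(obs_res2, n_sim, J, byrow = TRUE)) + 1) /
    (n_sim + 1)
  p_adj <- pmin(1, p_snp * J)
  flagged <- which(p_adj < outlier_alpha)

  m <- h_meta(h)
  raw_fit <- ivw_fit(bx, by, sy)
  phi_raw <- raw_fit$q / (J - 1)
  raw <- mr_result("presso_raw", raw_fit$estimate,
                   raw_fit$se_fixed * sqrt(max(1, phi_raw)),
                   n_snp = J, binary = m$binary,
                   exposure = m$exposure, outcome = m$outcome)

  if (length(flagged) == 0) {
    corrected <- raw
    corrected$method <- "presso_corrected"
    distortion_pval <- NA_real_
  } else {
    keep <- setdiff(seq_len(J), flagged)
    if (length(keep) < 2) {
      stop_mr("mr_degenerate_error",
              "MR-PRESSO flagged all but %d SNP(s); corrected IVW undefined",
              length(keep))
    }
    cor_fit <- ivw_fit(bx[keep], by[keep], sy[keep])
    phi_c <- cor_fit$q / (length(keep) - 1)
    corrected <- mr_result("presso_corrected", cor_fit$estimate,
                           cor_fit$se_fixed * sqrt(max(1, phi_c)),
                           n_snp = length(keep), binary = m$binary,
                           exposure = m$exposure, outcome = m$outcome)
    obs_diff <- abs(raw$estimate - corrected$estimate)
    sim_diff <- with_seed(seed + 1L, {
      vapply(seq_len(n_sim), function(i) {
        idx <- sample.int(J, length(keep))
        abs(raw$estimate - ivw_fit(bx[idx], by[idx], sy[idx])$estimate)
      }, numeric(1))
    })
    distortion_pval <- (sum(sim_diff >= obs_diff) + 1) / (n_sim + 1)
  }
  structure(list(global_rss = obs_rss, global_pval = global_pval,
                 outliers = data.frame(snp = h$snp[flagged],
                                       p_adjusted = p_adj[flagged],
                                       stringsAsFactors = FALSE),
                 raw = raw, corrected = corrected,
                 distortion_pval = distortion_pval,
                 n_sim = n_sim),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("<presso_result> global RSS=%.4g, p=%.3g; %d outlier(s)\n",
              x$global_rss, x$global_pval, nrow(x$outliers)))
  if (nrow(x$outliers)) print(x$outliers)
  print(x$raw); print(x$corrected)
  if (!is.na(x$distortion_pval)) {
    cat(sprintf("  distortion p=%.3g\n", x$distortion_pval))
  }
  invisible(x)
}

#' Convert a log-odds-ratio result to the odds-ratio reporting scale
#'
#' Exponentiates the estimate and CI bounds of a binary-outcome result. With
#' `per_unit_decrease = TRUE` the estimate is sign-inverted first (and the CI
#' bounds swapped), reporting the OR per one-unit reduction of the exposure.
#' The p-value is unchanged.
#'
#' @param r an `mr_result` whose outcome is binary.
#' @param per_unit_decrease report per one-unit decrease of the exposure.
#' @return the modified `mr_result` with `or`, `or_low`, `or_high` set.
#' @export
to_odds_ratio <- function(r, per_unit_decrease = FALSE) {
  stopifnot(inherits(r, "mr_result"))
  if (is.null(r$or)) {
    stop_mr("mr_unit_error", "outcome is not binary: no odds-ratio scale")
  }
  if (per_unit_decrease) {
    est <- -r$estimate
    ci <- c(-r$ci_high, -r$ci_low)
    r$estimate <- est
    r$ci_low <- ci[1]; r$ci_high <- ci[2]
  }
  r$or <- exp(r$estimate)
  r$or_low <- exp(r$ci_low)
  r$or_high <- exp(r$ci_high)
  r
}
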