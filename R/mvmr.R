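# Align several exposure tables and the outcome to a common per-SNP
# orientation. The reference record for each SNP comes from the first
# exposure table that carries it. Returns NULL rows for SNPs dropped in any
# table (palindrome ambiguity, incompatible alleles, absence).
mvmr_align <- function(tables, outcome, snps, palindrome_window = 0.08) {
  ref_rows <- lapply(snps, function(s) {
    for (tb in tables) {
      i <- match(s, tb$snp)
      if (!is.na(i)) return(as.data.frame(tb)[i, , drop = FALSE])
    }
    NULL
  })
  ref <- do.call(rbind, ref_rows)
  K <- length(tables)
  J <- length(snps)
  B <- matrix(NA_real_, J, K)
  S <- matrix(NA_real_, J, K)
  P <- matrix(NA_real_, J, K)
  keep <- rep(TRUE, J)
  for (k in seq_len(K)) {
    tb <- tables[[k]]
    idx <- match(snps, tb$snp)
    present <- !is.na(idx)
    keep <- keep & present
    sub_ref <- ref[present, , drop = FALSE]
    rec <- as.data.frame(tb)[idx[present], , drop = FALSE]
    al <- align_records(sub_ref, rec, palindrome_window)
    ok <- !al$action %in% c("dropped_palindrome", "dropped_incompatible")
    rows <- which(present)
    keep[rows[!ok]] <- FALSE
    B[rows, k] <- al$beta
    S[rows, k] <- rec$se
    P[rows, k] <- rec$pval
  }
  idx_out <- match(snps, outcome$snp)
  present <- !is.na(idx_out)
  keep <- keep & present
  beta_out <- se_out <- rep(NA_real_, J)
  if (any(present)) {
    sub_ref <- ref[present, , drop = FALSE]
    rec <- as.data.frame(outcome)[idx_out[present], , drop = FALSE]
    al <- align_records(sub_ref, rec, palindrome_window)
    ok <- !al$action %in% c("dropped_palindrome", "dropped_incompatible")
    rows <- which(present)
    keep[rows[!ok]] <- FALSE
    beta_out[rows] <- al$beta
    se_out[rows] <- rec$se
  }
  list(snp = snps[keep],
       B = B[keep, , drop = FALSE], S = S[keep, , drop = FALSE],
       P = P[keep, , drop = FALSE],
       beta_out = beta_out[keep], se_out = se_out[keep])
}

#' Multivariable IVW Mendelian randomization
#'
#' Estimates the direct effect of each exposure on the outcome conditional on
#' the co-exposures. The instrument set is the union of each exposure's
#' genome-wide-significant SNPs; all tables are harmonized to a common
#' per-SNP allele orientation, the union is clumped ranking each SNP by its
#' best (minimum) p-value across exposures, and the SNP-outcome effects are
#' regressed on the matrix of SNP-exposure effects without intercept,
#' weighted by `1/se_out^2`. Standard errors carry the multiplicative
#' overdispersion inflation `sqrt(max(1, Q/(J-K)))`. Conditional
#' F-statistics (see [conditional_f()]) quantify per-exposure instrument
#' strength after projecting out co-exposures.
#'
#' @param exposure_tables named list of 2+ `gwas_table`s (exposure first,
#'   then putative mediators/covariates).
#' @param outcome outcome `gwas_table`.
#' @param ld an `ld_matrix` (`NULL` means no LD: nothing is clumped away).
#' @param p_threshold instrument-selection threshold (default 5e-8).
#' @param r2_clump clumping threshold (default 0.001).
#' @param palindrome_window see [harmonize()].
#' @return an `mvmr_result`: `exposures`, `effects` (data frame with one row
#'   per exposure: `estimate`, `se`, `ci_low`, `ci_high`, `pval`, plus
#'   `or`/`or_low`/`or_high` for binary outcomes), `n_snp`,
#'   `conditional_F`, `q_stat`, `phi`.
#' @export
mvmr_ivw <- function(exposure_tables, outcome, ld = NULL,
                     p_threshold = 5e-8, r2_clump = 0.001,
                     palindrome_window = 0.08) {
  stopifnot(is.list(exposure_tables), length(exposure_tables) >= 1)
  if (is.null(names(exposure_tables)) || any(!nzchar(names(exposure_tables)))) {
    names(exposure_tables) <- vapply(exposure_tables, trait_name, character(1))
  }
  K <- length(exposure_tables)
  sel <- lapply(exposure_tables, function(tb) {
    tryCatch(select_instruments(tb, p_threshold)$snp, error = function(e) character(0))
  })
  union_snps <- sort(unique(unlist(sel)))
  if (length(union_snps) == 0) {
    stop_mr("mr_empty_instruments_error",
            "no exposure has instruments at p < %g", p_threshold)
  }
  al <- mvmr_align(exposure_tables, outcome, union_snps, palindrome_window)
  if (length(al$snp) == 0) {
    stop_mr("mr_harmonize_error", "no SNPs retained after MVMR harmonization")
  }
  # clump on the best p across exposures
  pmin_exp <- apply(al$P, 1, min)
  frame <- data.frame(snp = al$snp, pval = pmin_exp, stringsAsFactors = FALSE)
  kept <- if (is.null(ld)) frame$snp else clump(frame, ld, r2_clump)$snp
  idx <- match(kept, al$snp)
  B <- al$B[idx, , drop = FALSE]
  S <- al$S[idx, , drop = FALSE]
  y <- al$beta_out[idx]
  sy <- al$se_out[idx]
  J <- length(y)
  if (J <= K) {
    stop_mr("mr_underdetermined_error",
            "MVMR needs more SNPs (%d) than exposures (%d)", J, K)
  }
  if (qr(B)$rank < K) {
    stop_mr("mr_singular_error", "rank-deficient exposure effect matrix")
  }
  w <- 1 / sy^2
  xtwx <- crossprod(B, w * B)
  est <- solve(xtwx, crossprod(B, w * y))[, 1]
  resid <- y - B %*% est
  q <- sum(w * resid^2)
  phi <- q / (J - K)
  covb <- solve(xtwx) * max(1, phi)
  covb_fixed <- solve(xtwx)
  se <- sqrt(diag(covb))
  z <- z975()
  binary <- is_binary_trait(outcome)
  effects <- data.frame(exposure = names(exposure_tables),
                        estimate = est, se = se,
                        se_fixed = sqrt(diag(covb_fixed)),
                        ci_low = est - z * se, ci_high = est + z * se,
                        pval = norm_pval(est, se),
                        stringsAsFactors = FALSE)
  if (binary) {
    effects$or <- exp(effects$estimate)
    effects$or_low <- exp(effects$ci_low)
    effects$or_high <- exp(effects$ci_high)
  }
  rownames(effects) <- NULL
  structure(list(exposures = names(exposure_tables),
                 outcome = trait_name(outcome),
                 effects = effects, n_snp = J,
                 conditional_F = conditional_f(B, S),
                 q_stat = q, phi = phi, snps = kept,
                 outcome_binary = binary),
            class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("<mvmr_result> %d exposures -> %s, %d SNPs\n",
              length(x$exposures), x$outcome, x$n_snp))
  print(x$effects)
  cat("  conditional F: ",
      paste(sprintf("%s=%.3g", x$exposures, x$conditional_F), collapse = ", "), "\n")
  invisible(x)
}

#' Conditional F-statistics for multivariable MR
#'
#' For each target exposure, its SNP effects are regressed (weights
#' `1/se_x^2`, no intercept) on the co-exposures' SNP effects; the weighted
#' residual sum of squares `Q_x` measures the instrument strength left after
#' projecting out the co-exposures, and the conditional F is
#' `Q_x / (J - K + 1)`. Cross-trait covariance of estimation errors is
#' assumed zero (summary data carry no overlap information). With a single
#' exposure this reduces to the mean per-SNP F.
#'
#' @param beta_matrix J x K matrix (or list of `gwas_table`s sharing a SNP
#'   set) of SNP-exposure effects.
#' @param se_matrix matching matrix of standard errors (ignored when tables
#'   are supplied).
#' @return numeric vector of per-exposure conditional F-statistics.
#' @export
conditional_f <- function(beta_matrix, se_matrix = NULL) {
  if (is.list(beta_matrix) && !is.matrix(beta_matrix)) {
    tables <- beta_matrix
    snps <- Reduce(intersect, lapply(tables, `[[`, "snp"))
    if (length(snps) == 0) stop_mr("mr_empty_error", "tables share no SNPs")
    beta_matrix <- vapply(tables, function(tb) tb$beta[match(snps, tb$snp)],
                          numeric(length(snps)))
    se_matrix <- vapply(tables, function(tb) tb$se[match(snps, tb$snp)],
                        numeric(length(snps)))
    beta_matrix <- matrix(beta_matrix, ncol = length(tables))
    se_matrix <- matrix(se_matrix, ncol = length(tables))
  }
  stopifnot(is.matrix(beta_matrix), is.matrix(se_matrix),
            all(dim(beta_matrix) == dim(se_matrix)))
  J <- nrow(beta_matrix); K <- ncol(beta_matrix)
  if (J <= K - 1) stop_mr("mr_underdetermined_error", "too few SNPs")
  vapply(seq_len(K), function(k) {
    bx <- beta_matrix[, k]
    w <- 1 / se_matrix[, k]^2
    Z <- beta_matrix[, -k, drop = FALSE]
    if (ncol(Z) == 0 || all(Z == 0)) {
      qx <- sum(w * bx^2)
    } else {
      ztwz <- crossprod(Z, w * Z)
      if (abs(det(ztwz)) < .Machine$double.eps) {
        qx <- sum(w * bx^2)
      } else {
        g <- solve(ztwz, crossprod(Z, w * bx))
        qx <- sum(w * (bx - Z %*% g)^2)
      }
    }
    qx / (J - K + 1)
  }, numeric(1))
}

#' Step-wise mediation analysis on summary statistics
#'
#' Implements the three-step screen: (1) the total effect is the univariable
#' IVW estimate of exposure on outcome; pathways continue only when it is
#' nominally significant. (2) Each exposure-mediator association is tested
#' with univariable IVW; only significant pairs are carried forward. (3)
#' Multivariable IVW of exposure plus mediator on the outcome yields the
#' exposure's direct effect conditional on the mediator. The direct effect is
#' compared qualitatively with the total effect — the indirect effect and
#' proportion mediated are deliberately not computed, because with a common
#' binary outcome on the OR scale their usual decomposition does not hold.
#' Attenuation classes: `attenuated_to_null` (direct CI spans zero and
#' `|direct| < |total|`), `partially_attenuated` (`|direct| < |total|`, CI
#' excludes zero), otherwise `unchanged`.
#'
#' @param exposure,outcome `gwas_table`s.
#' @param mediators named list of mediator `gwas_table`s.
#' @param ld an `ld_matrix` (or `NULL`).
#' @param screen_alpha nominal significance gate for steps 1-2 (default 0.05).
#' @param p_threshold,r2_clump,palindrome_window pipeline thresholds.
#' @return list of `mediation_report` objects (one per carried-forward
#'   mediator; empty when the total effect fails the gate), with per-pathway
#'   failures in `attr(, "failures")`.
#' @export
mediate <- function(exposure, outcome, mediators, ld = NULL,
                    screen_alpha = 0.05, p_threshold = 5e-8,
                    r2_clump = 0.001, palindrome_window = 0.08) {
  stopifnot(is.list(mediators))
  if (is.null(names(mediators)) || any(!nzchar(names(mediators)))) {
    names(mediators) <- vapply(mediators, trait_name, character(1))
  }
  uni <- function(exp_tb, out_tb) {
    ins <- select_instruments(exp_tb, p_threshold)
    h <- harmonize(ins, out_tb, palindrome_window)
    if (!is.null(ld)) h <- clump(h, ld, r2_clump)
    ivw(h)
  }
  failures <- character(0)
  total <- uni(exposure, outcome)
  reports <- list()
  if (total$pval < screen_alpha) {
    for (med_name in names(mediators)) {
      rep_i <- tryCatch({
        em <- uni(exposure, mediators[[med_name]])
        if (em$pval >= screen_alpha) NULL else {
          mv <- mvmr_ivw(stats::setNames(list(exposure, mediators[[med_name]]),
                                         c(trait_name(exposure), med_name)),
                         outcome, ld, p_threshold, r2_clump, palindrome_window)
          direct <- mv$effects[1, ]
          spans_zero <- direct$ci_low <= 0 && direct$ci_high >= 0
          attenuation <- if (abs(direct$estimate) < abs(total$estimate)) {
            if (spans_zero) "attenuated_to_null" else "partially_attenuated"
          } else "unchanged"
          structure(list(exposure = trait_name(exposure),
                         outcome = trait_name(outcome),
                         mediator = med_name,
                         total = total, exposure_to_mediator = em,
                         direct = direct, mvmr = mv,
                         attenuation = attenuation),
                    class = "mediation_report")
        }
      }, error = function(e) {
        failures[[med_name]] <<- conditionMessage(e)
        NULL
      })
      if (!is.null(rep_i)) reports[[med_name]] <- rep_i
    }
  }
  attr(reports, "failures") <- failures
  attr(reports, "total") <- total
  reports
}

#' @export
print.mediation_report <- function(x, ...) {
  cat(sprintf("<mediation_report> %s -> %s via %s: %s\n",
              x$exposure, x$outcome, x$mediator, x$attenuation))
  cat(sprintf("  total  = %.4g [%.4g, %.4g] p=%.3g (%d SNPs)\n",
              x$total$estimate, x$total$ci_low, x$total$ci_high,
              x$total$pval, x$total$n_snp))
  cat(sprintf("  direct = %.4g [%.4g, %.4g] p=%.3g (%d SNPs)\n",
              x$direct$estimate, x$direct$ci_low, x$direct$ci_high,
              x$direct$pval, x$mvmr$n_snp))
  invisible(x)
}
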