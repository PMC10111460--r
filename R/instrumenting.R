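COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

HARMONIZE_ACTIONS <- c("unchanged", "sign_flipped", "strand_flipped",
                       "palindrome_inferred", "dropped_palindrome",
                       "dropped_incompatible")

#' Select instruments at a significance threshold
#'
#' Keeps SNPs with `pval` strictly below `p_threshold` (default genome-wide
#' significance, 5e-8).
#'
#' @param g a `gwas_table`.
#' @param p_threshold strict upper bound on the association p-value.
#' @return a `gwas_table` subset.
#' @export
select_instruments <- function(g, p_threshold = 5e-8) {
  stopifnot(inherits(g, "gwas_table"))
  keep <- g$pval < p_threshold
  if (!any(keep)) {
    stop_mr("mr_empty_instruments_error",
            "no instruments for trait '%s' at p < %g", trait_name(g), p_threshold)
  }
  gwas_subset(g, keep)
}

# Align one record set to a reference orientation, SNP by SNP.
# ref and rec are data.frames with canonical gwas columns, matched row-wise.
# Returns rec with beta/eaf aligned to ref's effect allele plus an action code.
align_records <- function(ref, rec, palindrome_window = 0.08) {
  n <- nrow(ref)
  action <- character(n)
  beta <- rec$beta
  eaf <- rec$eaf
  lo <- 0.5 - palindrome_window
  hi <- 0.5 + palindrome_window
  for (i in seq_len(n)) {
    ea_r <- ref$effect_allele[i]; oa_r <- ref$other_allele[i]
    ea <- rec$effect_allele[i]; oa <- rec$other_allele[i]
    pal <- is_palindromic(ea_r, oa_r)
    if (pal) {
      if (!is_palindromic(ea, oa) ||
          !(ea %in% c(ea_r, oa_r))) {
        action[i] <- "dropped_incompatible"
        next
      }
      # textual orientation first (same letters under swap for palindromes)
      if (ea == oa_r) {
        beta[i] <- -beta[i]
        if (!is.na(eaf[i])) eaf[i] <- 1 - eaf[i]
      }
      f_ref <- ref$eaf[i]; f <- eaf[i]
      if (is.na(f_ref) || is.na(f) ||
          (f_ref >= lo && f_ref <= hi) || (f >= lo && f <= hi)) {
        action[i] <- "dropped_palindrome"
        next
      }
      # strand ambiguity resolved by minor/major concordance
      if ((f_ref < 0.5) != (f < 0.5)) {
        beta[i] <- -beta[i]
        eaf[i] <- 1 - eaf[i]
      }
      action[i] <- "palindrome_inferred"
      next
    }
    flipped <- FALSE
    if (!setequal(c(ea, oa), c(ea_r, oa_r))) {
      ea_c <- unname(COMPLEMENT[ea]); oa_c <- unname(COMPLEMENT[oa])
      if (setequal(c(ea_c, oa_c), c(ea_r, oa_r))) {
        ea <- ea_c; oa <- oa_c; flipped <- TRUE
      } else {
        action[i] <- "dropped_incompatible"
        next
      }
    }
    if (ea == ea_r) {
      action[i] <- if (flipped) "strand_flipped" else "unchanged"
    } else {
      beta[i] <- -beta[i]
      if (!is.na(eaf[i])) eaf[i] <- 1 - eaf[i]
      action[i] <- if (flipped) "strand_flipped" else "sign_flipped"
    }
  }
  data.frame(beta = beta, eaf = eaf, action = action, stringsAsFactors = FALSE)
}

#' Harmonize exposure and outcome association records
#'
#' Aligns every shared SNP to the exposure's effect-allele orientation:
#' identical allele pairs are kept (swapped listings get a beta sign flip and
#' `eaf -> 1 - eaf`), complementary-strand pairs are complemented first, and
#' palindromic SNPs (A/T, G/C) are oriented from allele frequencies — both
#' frequencies must be present and outside `0.5 +/- palindrome_window`, and a
#' minor/major mismatch flips the outcome beta. Unresolvable palindromes are
#' dropped (`dropped_palindrome`), irreconcilable allele pairs too
#' (`dropped_incompatible`). SNPs absent from the outcome table are excluded
#' and counted.
#'
#' @param exposure,outcome `gwas_table`s sharing SNP ids.
#' @param palindrome_window half-width of the ambiguity window around an
#'   allele frequency of 0.5 (default 0.08: drop when any eaf is in
#'   `[0.42, 0.58]`).
#' @return a `harmonized_set`: data frame with columns `snp`,
#'   `effect_allele`, `other_allele`, `beta_exp`, `se_exp`, `eaf_exp`,
#'   `pval_exp`, `n_exp`, `beta_out`, `se_out`, `eaf_out`, `action`, with
#'   per-action counts and trait metadata in attributes.
#' @export
harmonize <- function(exposure, outcome, palindrome_window = 0.08) {
  stopifnot(inherits(exposure, "gwas_table"), inherits(outcome, "gwas_table"))
  shared <- intersect(exposure$snp, outcome$snp)
  n_absent <- nrow(exposure) - length(shared)
  if (length(shared) == 0) {
    stop_mr("mr_harmonize_error",
            "no shared SNPs between '%s' and '%s'",
            trait_name(exposure), trait_name(outcome))
  }
  e <- as.data.frame(exposure)[match(shared, exposure$snp), ]
  o <- as.data.frame(outcome)[match(shared, outcome$snp), ]
  al <- align_records(e, o, palindrome_window)
  h <- data.frame(snp = e$snp,
                  effect_allele = e$effect_allele,
                  other_allele = e$other_allele,
                  beta_exp = e$beta, se_exp = e$se, eaf_exp = e$eaf,
                  pval_exp = e$pval, n_exp = e$n,
                  beta_out = al$beta, se_out = o$se, eaf_out = al$eaf,
                  action = al$action, stringsAsFactors = FALSE)
  counts <- table(factor(h$action, levels = HARMONIZE_ACTIONS))
  counts <- c(as.list(counts), absent_in_outcome = n_absent)
  keep <- !h$action %in% c("dropped_palindrome", "dropped_incompatible")
  if (!any(keep)) {
    stop_mr("mr_harmonize_error",
            "harmonization retained 0 SNPs (%s)",
            paste(sprintf("%s=%d", names(counts), unlist(counts)), collapse = ", "))
  }
  h <- h[keep, , drop = FALSE]
  rownames(h) <- NULL
  structure(h,
            exposure_name = trait_name(exposure),
            outcome_name = trait_name(outcome),
            exposure_units = attr(exposure, "trait_units"),
            outcome_binary = is_binary_trait(outcome),
            counts = counts,
            class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s, %d SNPs retained\n",
              attr(x, "exposure_name") %||% "exposure",
              attr(x, "outcome_name") %||% "outcome", nrow(x)))
  cts <- attr(x, "counts")
  if (!is.null(cts)) {
    cat("  ", paste(sprintf("%s=%d", names(cts), unlist(cts)), collapse = ", "), "\n")
  }
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Greedy LD clumping
#'
#' Orders SNPs by ascending p-value (ties broken lexicographically by SNP id),
#' repeatedly retains the best remaining SNP and discards all remaining SNPs
#' with r-squared at or above `r2_threshold` against it. Every retained pair
#' therefore has pairwise r-squared strictly below the threshold.
#'
#' @param g a `gwas_table` or `harmonized_set` (needs `snp` and a p-value
#'   column: `pval` or `pval_exp`).
#' @param ld an `ld_matrix`.
#' @param r2_threshold retention threshold (default 0.001).
#' @return object of the same class restricted to the retained SNPs.
#' @export
clump <- function(g, ld, r2_threshold = 0.001) {
  pcol <- if ("pval" %in% names(g)) "pval" else "pval_exp"
  if (nrow(g) == 0) stop_mr("mr_empty_error", "cannot clump an empty table")
  ord <- order(g[[pcol]], g$snp)
  snps <- g$snp[ord]
  keep <- character(0)
  remaining <- snps
  while (length(remaining)) {
    top <- remaining[1]
    keep <- c(keep, top)
    remaining <- remaining[-1]
    if (length(remaining)) {
      r2 <- ld_r2(ld, rep(top, length(remaining)), remaining)
      remaining <- remaining[r2 < r2_threshold]
    }
  }
  idx <- which(g$snp %in% keep)
  if (inherits(g, "gwas_table")) return(gwas_subset(g, idx))
  out <- g[idx, , drop = FALSE]
  rownames(out) <- NULL
  for (a in setdiff(names(attributes(g)), c("row.names", "names"))) {
    attr(out, a) <- attr(g, a)
  }
  out
}

#' Per-SNP instrument strength
#'
#' For a single variant, `F = (beta / se)^2` and the explained variance is
#' `r2 = F / (n - 2 + F)`.
#'
#' @param beta,se SNP-exposure effect and its standard error (vectorized).
#' @param n exposure GWAS sample size (> 2).
#' @return data frame with columns `F_snp` and `r2_snp`.
#' @export
snp_strength <- function(beta, se, n) {
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop_mr("mr_domain_error", "se must be positive")
  }
  if (any(n <= 2)) stop_mr("mr_domain_error", "sample size must exceed 2")
  F_snp <- (beta / se)^2
  data.frame(F_snp = F_snp, r2_snp = F_snp / (n - 2 + F_snp))
}

#' Overall instrument strength report
#'
#' Sums per-SNP explained variances to `R2` and computes the k-instrument
#' F-statistic `F = ((n - k - 1) / k) * (R2 / (1 - R2))`. When instruments
#' report different sample sizes the minimum is used with a warning.
#'
#' @param instruments a `gwas_table` of selected instruments (needs `beta`,
#'   `se`, `n`).
#' @return a `strength_report` list: `per_snp` (data frame), `r2_total`,
#'   `f_overall`, `n`, `k`.
#' @export
overall_strength <- function(instruments) {
  b <- instruments$beta
  s <- instruments$se
  n_all <- instruments$n
  if (any(is.na(n_all))) stop_mr("mr_domain_error", "instrument sample sizes missing")
  n <- min(n_all)
  if (length(unique(n_all)) > 1) {
    warning("instruments report differing sample sizes; using the minimum")
  }
  k <- length(b)
  per <- snp_strength(b, s, n)
  r2 <- sum(per$r2_snp)
  if (r2 >= 1) stop_mr("mr_domain_error", "total R2 >= 1 (degenerate)")
  f <- ((n - k - 1) / k) * (r2 / (1 - r2))
  structure(list(per_snp = cbind(snp = instruments$snp, per),
                 r2_total = r2, f_overall = f, n = n, k = k),
            class = "strength_report")
}

#' @export
print.strength_report <- function(x, ...) {
  cat(sprintf("<strength_report> k=%d instruments, n=%d, R2=%.4g, F=%.4g\n",
              x$k, x$n, x$r2_total, x$f_overall))
  invisible(x)
}
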