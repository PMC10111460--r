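# fixture builders shared across the suite (everything generated in code)

# minimal association frame with sensible defaults, overridable per column
mk_frame <- function(snp, beta, se, pval = NULL,
                     ea = "A", oa = "G", eaf = 0.3, n = 10000) {
  J <- length(snp)
  data.frame(snp = snp,
             effect_allele = rep_len(ea, J), other_allele = rep_len(oa, J),
             eaf = rep_len(eaf, J), beta = beta, se = se,
             pval = pval %||% pmax(2 * pnorm(-abs(beta / se)), 1e-300),
             n = rep_len(n, J), stringsAsFactors = FALSE)
}

mk_gwas <- function(snp, beta, se, pval = NULL, ea = "A", oa = "G",
                    eaf = 0.3, n = 10000, trait = "trait", binary = FALSE) {
  gwas_table(mk_frame(snp, beta, se, pval, ea, oa, eaf, n),
             trait_name = trait, is_binary = binary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# harmonized set built directly from effect vectors (documented df contract)
mk_h <- function(bx, by, sy, sx = rep(0.01, length(bx)),
                 snp = sprintf("rs%03d", seq_along(bx)), binary = FALSE) {
  h <- data.frame(snp = snp, effect_allele = "A", other_allele = "G",
                  beta_exp = bx, se_exp = sx, eaf_exp = 0.3,
                  pval_exp = pmax(2 * pnorm(-abs(bx / sx)), 1e-300),
                  n_exp = 10000, beta_out = by, se_out = sy, eaf_out = 0.3,
                  action = "unchanged", stringsAsFactors = FALSE)
  structure(h, exposure_name = "exposure", outcome_name = "outcome",
            outcome_binary = binary, class = c("harmonized_set", "data.frame"))
}

# independent closed-form IVW oracle (weighted least squares through origin)
oracle_ivw <- function(bx, by, sy) {
  unname(coef(lm(by ~ 0 + bx, weights = 1 / sy^2)))
}

# independent greedy clumping oracle, re-deriving the postconditions
oracle_clump <- function(snp, pval, ld, r2_threshold) {
  ord <- order(pval, snp)
  keep <- character(0)
  for (s in snp[ord]) {
    if (all(ld_r2(ld, rep(s, length(keep)), keep) < r2_threshold) || !length(keep)) {
      keep <- c(keep, s)
    }
  }
  keep
}

# random LD structure over J snps: a mix of absent, weak and strong pairs
random_ld <- function(snps, p_edge = 0.3) {
  pairs <- t(combn(snps, 2))
  pick <- runif(nrow(pairs)) < p_edge
  if (!any(pick)) return(ld_matrix())
  r2 <- ifelse(runif(sum(pick)) < 0.5, runif(sum(pick), 0, 0.001),
               runif(sum(pick), 0.001, 1))
  ld_matrix(pairs[pick, 1], pairs[pick, 2], r2)
}

expect_mr_error <- function(expr, class) expect_error(expr, class = class)
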