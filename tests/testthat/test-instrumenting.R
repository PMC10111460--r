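test_that("select_instruments applies a strict threshold", {
  g <- mk_gwas(c("a", "b", "c"), beta = c(1, 1, 1), se = rep(0.1, 3),
               pval = c(1e-9, 5e-8, 1e-7))
  expect_equal(select_instruments(g)$snp, "a")          # strict <
  expect_equal(nrow(select_instruments(g, 1.0)), 3)
  expect_mr_error(select_instruments(g, 1e-20), "mr_empty_instruments_error")
})

test_that("harmonize resolves orientation, strand and palindromes", {
  exp <- gwas_table(data.frame(
    snp = c("s1", "s2", "s3", "s4", "s5"),
    effect_allele = c("A", "A", "G", "A", "A"),
    other_allele  = c("G", "T", "C", "G", "G"),
    eaf = c(0.3, 0.12, 0.51, 0.3, 0.3),
    beta = c(0.10, 0.10, 0.10, 0.10, 0.10), se = 0.02,
    pval = 1e-10, n = 1000), trait_name = "exp")
  out <- gwas_table(data.frame(
    snp = c("s1", "s2", "s3", "s4", "s5"),
    effect_allele = c("G", "A", "G", "A", "T"),
    other_allele  = c("A", "T", "C", "C", "C"),
    eaf = c(0.7, 0.88, 0.49, 0.3, 0.3),
    beta = c(-0.05, 0.04, 0.02, 0.01, 0.03), se = 0.01,
    pval = 0.5, n = 1000), trait_name = "out")
  h <- harmonize(exp, out)
  # s1: swapped listing -> sign flip
  expect_equal(h$beta_out[h$snp == "s1"], 0.05)
  expect_equal(h$action[h$snp == "s1"], "sign_flipped")
  expect_equal(h$eaf_out[h$snp == "s1"], 0.3)
  # s2: palindrome, eafs on opposite sides of 0.5 -> flipped
  expect_equal(h$beta_out[h$snp == "s2"], -0.04)
  expect_equal(h$action[h$snp == "s2"], "palindrome_inferred")
  # s3: palindrome with eaf inside the default [0.42, 0.58] window -> dropped
  expect_false("s3" %in% h$snp)
  expect_equal(attr(h, "counts")$dropped_palindrome, 1)
  # s4: A/G vs A/C -> incompatible
  expect_false("s4" %in% h$snp)
  expect_equal(attr(h, "counts")$dropped_incompatible, 1)
  # s5: complementary strand T/C == A/G -> strand_flipped, same orientation
  expect_equal(h$beta_out[h$snp == "s5"], 0.03)
  expect_equal(h$action[h$snp == "s5"], "strand_flipped")
})

test_that("harmonize counts absent SNPs and errors when nothing is retained", {
  exp <- mk_gwas(c("a", "b"), beta = c(0.1, 0.2), se = 0.01)
  out <- mk_gwas("a", beta = 0.05, se = 0.01)
  h <- harmonize(exp, out)
  expect_equal(attr(h, "counts")$absent_in_outcome, 1)
  # palindromic with missing eaf -> dropped; zero retained -> typed failure
  exp_p <- mk_gwas("p", beta = 0.1, se = 0.01, ea = "A", oa = "T", eaf = NA)
  out_p <- mk_gwas("p", beta = 0.1, se = 0.01, ea = "A", oa = "T", eaf = 0.2)
  expect_mr_error(harmonize(exp_p, out_p), "mr_harmonize_error")
})

test_that("harmonization is idempotent", {
  s <- synthetic_scenario(J = 40, theta = 0.1,
                          corruption = list(strand_flip = 0.4, allele_swap = 0.4,
                                            palindrome = 0.2),
                          seed = 301)
  d <- generate_gwas(s)
  h1 <- harmonize(d$exposure, d$outcome)
  # reconstitute the harmonized output as a pair of tables and redo
  exp2 <- gwas_table(data.frame(
    snp = h1$snp, effect_allele = h1$effect_allele, other_allele = h1$other_allele,
    eaf = h1$eaf_exp, beta = h1$beta_exp, se = h1$se_exp, pval = h1$pval_exp,
    n = h1$n_exp), trait_name = "exp")
  out2 <- gwas_table(data.frame(
    snp = h1$snp, effect_allele = h1$effect_allele, other_allele = h1$other_allele,
    eaf = h1$eaf_out, beta = h1$beta_out, se = h1$se_out, pval = 0.5,
    n = 1000), trait_name = "out")
  h2 <- harmonize(exp2, out2)
  expect_equal(nrow(h2), nrow(h1))
  expect_equal(h2$beta_out[match(h1$snp, h2$snp)], h1$beta_out)
  expect_true(all(h2$action %in% c("unchanged", "palindrome_inferred")))
})

test_that("clump keeps the best SNP and removes correlated ones", {
  g <- mk_gwas(c("A", "B"), beta = c(1, 1), se = 0.1, pval = c(1e-10, 1e-9))
  expect_equal(clump(g, ld_matrix("A", "B", 0.5))$snp, "A")
  expect_equal(sort(clump(g, ld_matrix("A", "B", 0.0005))$snp), c("A", "B"))
})

test_that("clump matches the brute-force greedy oracle on random instances", {
  set.seed(302)
  for (i in 1:25) {
    snps <- sprintf("rs%02d", 1:20)
    pv <- 10^runif(20, -12, -4)
    g <- mk_gwas(snps, beta = rep(1, 20), se = 0.1, pval = pv)
    ld <- random_ld(snps)
    kept <- clump(g, ld)$snp
    expect_setequal(kept, oracle_clump(snps, pv, ld, 0.001))
    # postcondition 1: retained pairs pairwise independent at the threshold
    if (length(kept) > 1) {
      prs <- t(combn(kept, 2))
      expect_true(all(ld_r2(ld, prs[, 1], prs[, 2]) < 0.001))
    }
    # postcondition 2: every removed SNP is explained by a better-p retained SNP
    for (s in setdiff(snps, kept)) {
      culprits <- kept[ld_r2(ld, rep(s, length(kept)), kept) >= 0.001]
      expect_true(any(pv[match(culprits, snps)] <= pv[match(s, snps)]))
    }
  }
})

test_that("snp_strength computes F and per-SNP R2", {
  st <- snp_strength(0.1, 0.01, 102)
  expect_equal(st$F_snp, 100)
  expect_equal(st$r2_snp, 0.5)
  expect_equal(snp_strength(0, 0.01, 100)$F_snp, 0)
  expect_equal(snp_strength(-0.1, 0.01, 102), snp_strength(0.1, 0.01, 102))
  expect_mr_error(snp_strength(0.1, 0.01, 2), "mr_domain_error")
})

test_that("overall_strength sums R2 and reduces to per-SNP F at k = 1", {
  # k = 1 identity over random draws
  set.seed(303)
  for (i in 1:20) {
    b <- rnorm(1); s <- runif(1, 0.005, 0.1); n <- sample(10:100000, 1)
    g <- mk_gwas("x", beta = b, se = s, n = n)
    rep <- suppressWarnings(overall_strength(g))
    expect_equal(rep$f_overall, (b / s)^2, tolerance = 1e-12)
  }
  # two SNPs each r2 = 0.1, n = 1003 -> F = 125
  # r2 = F/(n-2+F) = 0.1  <=>  F = (n-2)/9
  f1 <- (1003 - 2) / 9
  g2 <- mk_gwas(c("a", "b"), beta = sqrt(f1) * 0.01, se = 0.01, n = 1003)
  rep2 <- overall_strength(g2)
  expect_equal(rep2$r2_total, 0.2, tolerance = 1e-12)
  expect_equal(rep2$f_overall, ((1003 - 2 - 1) / 2) * (0.2 / 0.8), tolerance = 1e-9)
  expect_equal(rep2$f_overall, 125, tolerance = 1e-9)
  # zero effects -> F = 0
  g0 <- mk_gwas(c("a", "b"), beta = 0, se = 0.01, n = 1000)
  expect_equal(overall_strength(g0)$f_overall, 0)
  # differing n: warning, minimum used
  g3 <- gwas_table(mk_frame(c("a", "b"), beta = 0.1, se = 0.01,
                            n = c(1000, 2000)))
  expect_warning(rep3 <- overall_strength(g3), "minimum")
  expect_equal(rep3$n, 1000)
})
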