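---
title: "Methods: models, conventions and design choices in mrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in mrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistics it implements:
the estimators and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator emulates (and
does not), the numerical conventions, and the places where the design was
genuinely open and a choice had to be made. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The inferential setting

Two-sample Mendelian randomization treats genetic variants as instrumental
variables for a modifiable exposure. For SNP $j$ we observe
$(\hat\beta_{Xj}, \sigma_{Xj})$ from an exposure GWAS and
$(\hat\beta_{Yj}, \sigma_{Yj})$ from an outcome GWAS in a non-overlapping
sample of the same ancestry. Under the three core instrument assumptions
(association with the exposure; independence from confounders; no effect on
the outcome except through the exposure), each Wald ratio
$\hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the causal effect $\theta$, and
estimators differ in how they pool ratios and in which violations they
tolerate. For binary outcomes all effects are on the log odds-ratio scale,
and reporting may invert the sign first ("per one-unit *decrease*") before
exponentiating — a pure relabelling that leaves p-values untouched.

## 2. Instrument processing

**Selection** keeps SNPs with exposure $p$ strictly below `p_instrument`
(default $5\times10^{-8}$). Both this and the clumping threshold are strict
inequalities; the sources the package follows print only the inequality
direction, so the boundary convention had to be fixed and is stated here.

**Harmonization** aligns every shared SNP to the exposure's effect allele:
swapped listings flip the outcome beta and its allele frequency;
complementary-strand listings are complemented first. Palindromic SNPs (A/T,
G/C) are strand-ambiguous, so orientation is inferred from allele
frequencies: both frequencies must be present and outside
$0.5 \pm w$, and discordant minor/major status flips the sign. The window
half-width `palindrome_window` defaults to $w = 0.08$ (drop when any
frequency lies in $[0.42, 0.58]$), matching the default of the tooling
ecosystem this workflow comes from; near 0.5 the minor allele is not
identifiable from frequency and inference would be a coin flip. A
palindromic SNP with a missing frequency is dropped — there is nothing to
infer from. Missing frequencies on non-palindromic SNPs are harmless.

**Clumping** is greedy: order by ascending $p$ (ties broken
lexicographically by SNP id, for determinism), keep the best remaining SNP,
discard all remaining SNPs with $r^2 \ge$ `r2_clump` (default 0.001) against
it. Every retained pair is therefore below threshold, and every discarded
SNP is "explained" by a retained SNP with no worse $p$ — both postconditions
are re-checked against a brute-force oracle in the tests. Distance (kb)
windows are not used: the LD table abstraction subsumes locality, and only
the $r^2$ criterion is specified by the design this package follows. The
pipeline order is select → harmonize → clump, mirroring the practice of
harmonizing before clumping so that SNPs lost to harmonization cannot shield
correlated neighbours from removal.

**Instrument strength.** Per SNP, $F_j = (\beta_j/\sigma_j)^2$ and
$R^2_j = F_j/(n - 2 + F_j)$; overall, $R^2 = \sum_j R^2_j$ and
$F = \frac{n-k-1}{k}\,\frac{R^2}{1-R^2}$ with $k$ instruments and the
exposure sample size $n$ (the minimum across instruments, with a warning,
if they disagree). With $k = 1$ this collapses exactly to the per-SNP $F$ —
a useful algebraic identity that the acceptance suite checks.

## 3. Estimators

**IVW with multiplicative random effects** (the primary method) is the
weighted regression of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ through the
origin with weights $w_j = \sigma_{Yj}^{-2}$; in closed form
$\hat\theta = \sum w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum w_j
\hat\beta_{Xj}^2$. Cochran's $Q = \sum w_j(\hat\beta_{Yj} -
\hat\theta\hat\beta_{Xj})^2$ yields the overdispersion $\phi = Q/(J-1)$, and
the multiplicative model scales the fixed-effect SE by
$\sqrt{\max(1,\phi)}$. The floor at 1 means heterogeneity can only widen
intervals — the model names the multiplicative structure but not the floor
convention, so the package fixes it explicitly (and tests that the
random-effects SE never undercuts the fixed-effect SE). One SNP delegates to
the Wald ratio with the first-order SE $\sigma_{Y}/|\hat\beta_{X}|$.

**MR-Egger** adds an intercept: under InSIDE (instrument strength
independent of direct effects), the intercept estimates the average
directional pleiotropic effect and the slope is a pleiotropy-adjusted causal
estimate. Because the intercept's meaning depends on the sign convention of
the exposure effects, every SNP is first oriented so $\hat\beta_{Xj} \ge 0$
(both betas flipped together — an operation all estimators here are
invariant to, for the slope). Slope *and* intercept SEs carry the same
$\sqrt{\max(1, Q/(J-2))}$ inflation; the shared residual overdispersion
factor is the standard weighted-regression treatment, extended to the
intercept for coherence.

**Weighted median.** Ratios $r_j$ are weighted by the inverse variance of
the first-order ratio SE $\sigma_{Yj}/|\hat\beta_{Xj}|$ (the delta
approximation ignoring $\sigma_{Xj}$; a second-order option was considered
and left out of the default because it changes weights only at weak
instruments, where the median's validity is already marginal). The estimate
interpolates the sorted ratios at standardized cumulative weight 0.5, and is
consistent while at least half the total weight comes from valid SNPs. Its
SE is the standard deviation over `n_boot` (default 1000) parametric
bootstrap replicates, perturbing both betas by their SEs under an explicit
seed — bit-identical across runs by contract.

**MR-PRESSO.** The global statistic is the unweighted leave-one-out residual
sum of squares $\sum_j (\hat\beta_{Yj} - \hat\theta_{(-j)}
\hat\beta_{Xj})^2$; its null distribution comes from `n_sim` (default 1000)
parametric re-simulations of the outcome betas under the leave-one-out
fitted model with variances $\sigma_{Yj}^2$, re-computing the same statistic
on each. Per-SNP outlier p-values compare each observed squared residual to
its simulated distribution, Bonferroni-adjusted by $J$, flagging below
`outlier_alpha` (default 0.05). The corrected estimate is IVW on the
unflagged SNPs; the distortion test compares the raw-vs-corrected difference
to differences over random same-size subsets. All empirical p-values use the
$(r+1)/(n+1)$ estimator, so none is exactly zero and the null global test is
slightly conservative by construction.

**Multivariable MR** regresses outcome effects on the $J \times K$ matrix of
exposure effects (no intercept, weights $\sigma_{Yj}^{-2}$), with SE
inflation $\sqrt{\max(1, Q/(J-K))}$. The instrument set is the union of each
exposure's genome-wide-significant SNPs, harmonized to a common per-SNP
orientation (reference: the first exposure table carrying the SNP) and
clumped ranking each SNP by its best p-value across exposures — the ranking
rule is this package's choice, since "clumping the union" does not by itself
say how to rank. Conditional instrument strength for exposure $x$ projects
its SNP effects on the co-exposures' (weights $\sigma_{xj}^{-2}$) and takes
$F_x = Q_x/(J-K+1)$ from the weighted residual sum of squares. Cross-trait
covariance of estimation errors is assumed zero — summary tables carry no
sample-overlap information — and this is a documented limitation, not a
claim about how any external implementation handles it. With one exposure
the formula reduces to the mean per-SNP $F$.

**Mediation** is step-wise: (1) total effect by univariable IVW, gated at
nominal $p <$ 0.05; (2) exposure→mediator IVW, same gate; (3) multivariable
IVW of exposure + mediator on the outcome for the direct effect. The
indirect effect and proportion mediated are *not* computed: with a common
binary outcome on the OR scale, the linear product/difference decomposition
does not hold, so the direct effect is compared qualitatively with the
total. The comparison rule is concrete and recorded with each report:
`attenuated_to_null` when the direct CI spans zero and |direct| < |total|;
`partially_attenuated` when |direct| < |total| with CI excluding zero;
`unchanged` otherwise.

## 4. The study pipeline

`run_study()` executes primary IVW per exposure×outcome pair (Wald fallback
at one SNP), flags significance at `alpha_primary` (default 0.0125 — a
Bonferroni correction for four exposures per outcome, fixed as a config
value rather than recomputed from the config's exposure count, so that a
study with a different design must change it consciously) and at
`alpha_nominal` (0.05); then the sensitivity suite (weighted median, Egger,
PRESSO, skipping with logged reasons when preconditions fail), bidirectional
MR (roles reversed, beta/SE reporting — never an OR, since the reversed
outcome is the original continuous exposure), covariate adjustment
(multivariable MR with the covariate as co-exposure, e.g. educational
attainment), and mediation. Bidirectional and adjusted analyses run for
pairs passing the nominal gate. Failures are isolated per pair; a run never
aborts wholesale. Outputs are TSV fragments plus a manifest (config hash,
seed, versions); identical config and seed give byte-identical files.

The config is JSON. The design called for a flat INI/YAML-style file, but no
YAML parser is available in the supported dependency set, and `jsonlite` is;
the schema is unchanged and the choice is isolated at the serialization
boundary.

## 5. The synthetic generator: what it emulates, what it does not

For SNP $j$: $\mathrm{maf}_j \sim U(0.01, 0.5)$ by default; true exposure
effects $\gamma_j$ have uniform magnitudes on $[0.02, 0.10]$, negated with
probability 0.5 — sized so that instruments at biobank-scale sample sizes
have $F$ in the tens-to-hundreds, like the reproductive-trait GWAS the
presets mirror. Standard errors use the standardized-trait approximation
$\sigma = 1/\sqrt{2n\,\mathrm{maf}(1-\mathrm{maf})}$; binary outcomes use
the case-control log-OR scaling
$\sqrt{1/n_\mathrm{case} + 1/n_\mathrm{control}}$ in place of $1/\sqrt{n}$
(a full liability-threshold simulation is deliberately out of scope).
Estimated betas add independent Gaussian noise in the two samples (the
two-sample regime: no overlap correlation). An invalid fraction receives
direct effects $\alpha_j \sim N(\mu_\alpha, \tau_\alpha^2)$, independent of
$\gamma_j$ under InSIDE or correlated (rho 0.7) otherwise. A mediator block
adds mediator-specific instruments: a pure chain (mediator effects exactly
$\delta\gamma_j$) would make the multivariable design matrix collinear and
the direct effect unidentifiable, so identifiability *requires* SNPs acting
on the mediator alone — the generator makes this structural fact explicit.
The truth record always satisfies
$\theta_\mathrm{total} = \theta_\mathrm{direct} + \delta\,\theta_M$ exactly.
An optional feedback block (outcome-specific instruments with a reverse
effect on the exposure) exists so bidirectional analysis has something real
to find. Corruption — strand complements, effect/other swaps with sign and
frequency flips, palindromic allele pairs — is applied last, to the outcome
records, with a log.

Not emulated: winner's curse (instruments are drawn as truly associated,
matching externally discovered instrument lists; an analysis selecting
instruments in-sample would need it), population stratification, imputation
error, sample overlap, and realistic recombination (LD blocks are
exchangeable with constant within-block $r^2$ — enough to exercise clumping,
nothing more). A green simulation test therefore establishes algorithmic
correctness and statistical calibration *under the stated generative model*,
not robustness to these unmodelled features.

Preset scenarios mirror the instrument counts of the motivating study
designs (18, 9, 208 and 154 instruments; a mediation chain with direct
effect 0.1, exposure→mediator 0.5, mediator→outcome 0.4, hence total 0.3;
and a null).

## 6. Calibration worlds and their rationale

`mr_calibration()` fixes one simulated world per acceptance check. Two
choices deserve explanation, both made at design time from power
considerations (not adjusted afterwards):

- *MR-Egger world*: all-positive $\gamma_j$ (with mixed signs, orientation
  to non-negative exposure effects negates half the $\alpha_j$ and the
  intercept's target would be a sign-mangled average — the intercept
  criterion is only meaningful with a sign-coherent pleiotropy target), and
  a deliberately moderate exposure GWAS ($n = 8000$) so that
  regression-dilution bias is measurable above Monte-Carlo noise in *both*
  the Egger slope and the no-pleiotropy IVW it is compared against. With
  very strong instruments both biases are statistically indistinguishable
  from zero and their ratio is an uninformative noise quotient.
- *MR-PRESSO planted-outlier world*: ten homogeneous instruments
  ($\gamma \in [0.05, 0.12]$, maf $\ge 0.1$) and a direct effect of exactly
  ten times the planted SNP's own outcome SE. The "corrected estimate closer
  to truth" event is governed by the outlier's leverage relative to
  estimator noise, $\approx 10 z_j / 2\sqrt{\sum_k z_k^2}$ standard normal
  units; many weak or heterogeneous instruments dilute it below any reliable
  detection rate regardless of implementation quality.

The weighted-median world uses a large outcome GWAS (n = 1.5M) because the
interpolated median's finite-sample bias scales with the ratio noise
$\sigma_Y/|\gamma|$, and the 40%-invalid criterion bounds bias at 0.03 —
about one ratio-noise quantile step at smaller sample sizes. The mediation
world uses strong instruments ($\gamma \in [0.1, 0.3]$) because the
criterion's tolerance is three Monte-Carlo SEs of the mean, which at 500
replicates is well below the regression-dilution bias weaker instruments
would induce.

## 7. Numerical conventions and degenerate inputs

- All p-values and CIs use the two-sided normal reference (1.96-SE
  intervals); consistent with symmetric reported CIs on the log-OR scale.
- Input p-values of exactly 0 (file dialects print 0 for underflow) are
  floored to $10^{-300}$ with a warning; computed p-values are floored the
  same way.
- Alleles are restricted to single bases A/C/G/T; indel or multiallelic rows
  are dropped with a logged count.
- Degenerate inputs raise typed errors, not NA results: zero exposure beta
  for a Wald ratio, all-zero exposure betas for IVW, constant exposure betas
  for Egger (singular design), rank-deficient multivariable designs, $J \le
  K$ in multivariable MR, $R^2 \ge 1$ in the strength report.
- Every Monte-Carlo procedure takes an explicit seed, runs under a
  save/restore of the caller's RNG state, and is bit-reproducible.
- TSV serialization keeps 17 significant digits, so write/read round-trips
  hold to $10^{-12}$ or better.

## 8. Known limitations

No proxy-SNP search for instruments absent from the outcome GWAS (they are
dropped and counted); no Steiger filtering, MR-RAPS, or mode-based
estimators; no LD computation from reference panels; conditional
F-statistics assume zero cross-trait estimation covariance; the bidirectional
analysis inherits the usual caveat that a true forward effect contaminates
the reverse instrument set with exposure SNPs — visible directly in the
generator's feedback worlds.
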