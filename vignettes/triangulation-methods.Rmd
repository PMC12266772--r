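---
title: "Methods: triangulating drug targets from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triangulating drug targets from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(TriangulateMR)
```

# Scope

TriangulateMR prioritizes molecular drug targets — plasma proteins and
tissue gene transcripts — for a downstream outcome such as lifespan, using
nothing but GWAS/QTL summary statistics and per-locus LD matrices. This
vignette records the statistical models, the default parameters and the
design decisions made where published practice leaves the choice open. The
worked numbers in the README and the quantities written by
`scripts/acceptance.R` are computed by the package at run time; nothing here
asserts an empirical result the tests do not themselves produce.

# Data model and harmonization

A `SumStats` object holds per-variant marginal estimates: effect allele,
other allele, effect-allele frequency (EAF), beta (trait units, or log-odds
for case-control traits), SE, p, and sample size. Validity enforces SE > 0,
EAF in (0,1), p in (0,1], unique variant ids and the case/control/total
consistency n_case + n_control = n.

Two-sample MR requires both tables oriented to the same effect allele.
`harmonize()` applies, per shared variant:

* identical alleles: kept unchanged;
* swapped alleles: outcome beta negated, EAF complemented (`flipped`);
* non-matching single-base alleles: retried after strand complementation
  (A/G vs T/C inference) before being declared incompatible;
* palindromic SNPs (A/T, C/G): usable only when both EAFs are present,
  outside the ambiguity window 0.5 ± 0.08 (the common 0.42–0.58 band; the
  half-width is the `palindromeEafWindow` argument), *and* consistent with
  the nominal allele alignment; anything else is `dropped_palindromic`;
* indels and multi-base alleles: matched directly or swapped, never through
  strand or palindrome logic.

Exactly one action is recorded per shared variant (conservation), the
transform is idempotent, and flipping is an involution — all three are
property-tested. The palindrome policy is a declared default, not something
recoverable from published analyses, which typically do not state it.

Coordinates are 1-based and cis windows are closed intervals anchored on the
gene body (start − w, end + w), with w = 500 kb by default.

# Instruments

`buildInstruments()` composes: cis-window restriction → significance filter
(default p < 5×10⁻⁸; `pThresholdSparse = 1e-5` for sparse tissue panels where
genome-wide significance is unattainable at the panel's sample size) → greedy
LD clumping → F filter.

Clumping is greedy index selection: sort significant variants by ascending p
(ties broken lexicographically by variant id, making the output
deterministic), take the best remaining variant, remove everything with
r² ≥ 0.01 to it, repeat. "LD pruning" is often reported without an
algorithm; greedy index clumping is the standard tool behaviour and is what
we implement, with a property test that no two retained variants exceed the
threshold and every removed variant is tagged by an earlier index.

Instrument strength uses the single-variant approximation F = (β/SE)²,
because per-variant R² and exact n are not always available in public
summary statistics; the alternative (n−2)R²/(1−R²) with R² = z²/(z²+n) is
available via `fStatistic(..., form = "r2")`. Instruments with F < 10 are
removed (the conventional weak-instrument bound).

# MR estimators and the sensitivity battery

Single instrument: Wald ratio β_out/β_exp with first-order delta SE
se_out/|β_exp| and a two-sided normal p. Two or more: fixed-effect IVW over
per-variant ratios with weights 1/se(r)². Fixed-effect is the default
because it is reproducible and the common first-line choice;
multiplicative random effects (SE × max(1, √(Q/df))) sit behind
`randomEffects = TRUE`.

Sensitivity tests activate by instrument count, and report NA below it —
single-instrument targets legitimately carry no pleiotropy or heterogeneity
diagnostics:

* **Cochran's Q** (≥ 2): Q = Σwᵢ(rᵢ − β̂)², chi-square with k−1 df.
* **MR-Egger** (≥ 3): weighted regression of outcome on exposure effects with
  a free intercept, weights 1/se_out², after flipping instruments so all
  exposure effects are non-negative (the orientation the InSIDE framing
  assumes). Intercept and slope p-values use a t distribution with k−2 df.
* **MR-PRESSO** (≥ 4): the observed statistic is the residual sum of squares
  of leave-one-out IVW predictions of the outcome effects; the null
  distribution redraws each outcome effect from N(leave-one-out prediction,
  se_out²) `nSim = 1000` times, recomputing the leave-one-out residuals per
  draw. Per-variant outlier p-values come from the same simulations,
  Bonferroni-adjusted. Seeded and deterministic.
* **Steiger** (always, when sample sizes are known): per-variant trait
  correlations approximated by r = z/√(z²+n), for quantitative and binary
  traits alike (the binary case is not standardized in the literature; we
  declare the same approximation for both). The tie resolves to FALSE —
  when instruments explain no more outcome than exposure variance the
  direction is not defensible.

p-values are two-sided normal for Wald/IVW and t for Egger — stated
explicitly because reporting conventions vary.

# Meta-analysis, FDR and concordance rules

Proteins measured by several studies are pooled with DerSimonian–Laird:
τ² = max(0, (Q−(k−1))/(Σw − Σw²/Σw)) from fixed weights w = 1/se², then
random weights 1/(se²+τ²). A single study passes through unchanged with
τ² = 0. The implementation follows these exact expressions (and is
cross-checked against `metafor::rma(method = "DL")` in the tests) because
the funnel's behaviour, including the k = 1 passthrough, is pinned to them.

FDR control is Benjamini–Hochberg, one family per outcome across all targets
of an omic layer; the family is whatever p-vector the caller assembles, so
other family definitions are possible. `bhFdr()` delegates to
`stats::p.adjust(method = "BH")`.

Replication (cis+trans instruments, or an external cohort) is
operationalized as same-sign with nominal p < 0.05 in the validation
analysis — a declared rule; published analyses state the requirement but
rarely the criterion. Tissue concordance requires at least one
tissue-specific transcript MR that is nominally significant with the same
sign as the plasma-protein effect.

# Colocalization

Per-variant evidence is the Wakefield approximate Bayes factor: with
V = se², W = priorSd² and shrinkage r = W/(W+V),
log ABF = ½log(1−r) + z²r/2. Prior effect scales default to 0.2 for
quantitative and 0.15 for case-control traits (the conventional defaults of
the ABF framework); both are arguments.

**Two traits** (`colocAbf`): the standard single-causal-variant enumeration
over the five hypotheses, with per-variant priors p1 = p2 = 10⁻⁴ and
p12 = 10⁻⁵. H3's sum over ordered distinct pairs is computed as
exp(L1+L2) − exp(L4) in log space. `regionalProbability()` returns
PP.H3 + PP.H4.

**Three traits** (`moloc`): all 15 sharing configurations of traits a, b, c
(commas separate distinct causal variants, juxtaposition means shared), with
per-variant priors 10⁻⁴/10⁻⁶/10⁻⁷ by the number of layers sharing a
variant. Distinct-variant sums exclude coincident assignments by
inclusion–exclusion: for two groups S_G1·S_G2 − S_G1∪G2; for three
singletons S_aS_bS_c − S_abS_c − S_acS_b − S_bcS_a + 2S_abc. The two
regional summaries are P_abc (one shared causal variant) and
P_a,b,c + P_a,bc + P_ab,c + P_ac,b + P_abc (one causal region).

All Bayes-factor algebra runs in log space: each trait's ABF vector is
rescaled by its maximum before any sum or product, so arbitrarily strong
signals (log ABF in the hundreds) cannot overflow; both enumerations are
verified against brute-force linear-space enumeration on small loci to
1×10⁻¹⁰.

Threshold semantics are strictly greater than 0.70 for "colocalized", in
both the two- and three-trait analyses. Two posterior criteria are in
circulation — PP.H4 alone, and the regional PP.H3 + PP.H4 — and different
arms of a published analysis can use different ones; both are implemented,
and the funnel's criterion is an explicit configuration choice
(`colocCriterion = "h4"` or `"regional"`), not a hidden default.

The single-causal-variant assumption is the model's known limitation: loci
with multiple independent signals per trait are outside its guarantees.

# Phenome-wide scan and mediation

`phewasScan()` runs `runMR()` of one target's instruments against each
phenotype of a panel and applies BH FDR across the scan (one family per
target). Phenotypes sharing no usable instruments are reported with NA
fields and excluded from the family. Mediation is product-of-coefficients:
indirect = β₁β₂ with delta-method SE √(β₁²se₂² + β₂²se₁²) and proportion
mediated indirect/total (undefined at total = 0). This is a declared
operationalization — mediation can also be read as a directional chain, and
both the step estimates and the product are reported. Curated mediator lists
are the caller's responsibility (an allow-list), never encoded knowledge.

# Genetic correlation

`bivariateRg()` is a deliberately simplified bivariate LD score regression:
univariate regressions of z² on the LD score ℓ_j = Σ_k r²_jk give
h² = slope·M/n, the cross regression of z₁z₂ on ℓ gives
gencov·√(n₁n₂)/M, rg = gencov/√(h²₁h²₂), and the SE comes from a
delete-one-block jackknife over 20 contiguous blocks. Simplifications, both
deliberate: unweighted least squares (no iterative heteroskedasticity
weights) and free intercepts (no sample-overlap constraint). These are
adequate at simulation scale; |rg| may slightly exceed 1 through estimation
noise, which the class documents rather than truncates. The rg ratio is
mildly heavy-tailed at M = 2000, so 2-SE intervals cover a little under
their nominal 95% — the calibration test asserts the SE's scale, not exact
normal coverage. A panel with constant LD scores leaves the slope
unidentifiable and is rejected.

# The synthetic-data generator

`simulateTraitSumstats()` draws marginal z-scores from the RSS model
z ~ N(√n·R·λ, R) given the LD matrix R and standardized causal effects λ,
converting to beta = z/√n, se = 1/√n. LD structures are AR(1)
(r_jk = ρ^|j−k|), constant-correlation blocks, and identity. Effects live on
the standardized-genotype scale; MR ratios are scale-invariant, so no
allele-frequency conversion is applied by default. Case-control traits are
simulated on the log-odds scale with an effective n, without
individual-level sampling. Local heritability λ'Rλ is capped at 0.5; the
two-sided p is floored at 10⁻³⁰⁰ to stay within its (0,1] domain for extreme
signals.

Scenario generators place causal variants by sharing configuration
(two-trait H0–H4, or any of the 15 three-trait configurations): shared
groups get one variant at the panel centre; distinct groups get variants
satisfying a pairwise r² cap (default 0.05) or matching a requested r²
(`r2Target`, used for the hard LD-confounding case r² = 0.5). Multi-study
protein panels draw each study's causal effect θ_j ~ N(baseEffect, τ²) and
pair every study with its own outcome draw whose local effect is θ_j times
the protein effect — between-study heterogeneity in MR estimates is thereby
generated directly on the causal-effect scale. The bivariate polygenic
generator uses constant-correlation blocks whose ρ cycles through
{0, 0.3, 0.5, 0.7} so that LD scores vary across variants, which the rg
regression requires.

What the generator emulates: LD-correlated marginal statistics, shared vs
distinct causal variants across omic layers, study duplication with
heterogeneity, mediator chains, weak and strong instruments. What it does
not: allele-frequency-dependent power, imputation error, sample overlap
between exposure and outcome GWAS, population stratification, and
multi-causal-variant loci. Passing tests therefore demonstrate correctness
of the machinery under the stated models, not robustness to those
real-data complications.

## Study conditions used by the tests and acceptance script

Simulation sizes were fixed once, at values a practitioner would call
realistic for this setting: exposure QTL studies n = 30,000 (protein GWAS
scale; 100,000 for the bias grid), outcome GWAS n = 300,000–500,000
(lifespan meta-analysis scale), locus heritability 1–2% for a strong cis
signal, 500-variant AR(1) ρ = 0.9 panels for colocalization (150 for the
funnel fixture), M = 2000 variants for the polygenic rg simulation with
true rg = 0.8 and h² = 0.4 per trait, and a 10-target funnel fixture
(3 shared-variant targets with protein-on-outcome effect −0.15, 3
LD-confounded at r² = 0.5, 4 exposure-only nulls; 2 studies per target plus
an external validation study).

# The filtration funnel

`runFunnel()` fixes the stage order: (1) per-study MR with sensitivity
exclusions — a study's result is dropped on Egger intercept p < 0.05,
Cochran Q p < 0.05, or Steiger FALSE, and a target is dropped when no study
survives; (2) DerSimonian–Laird pooling with BH FDR, keep q ≤ 0.05;
(3) colocalization above the 70% criterion; (4) validation: MR-PRESSO,
cis+trans replication, external replication. Every criterion is
individually toggleable (different arms of an analysis legitimately use
different coloc criteria), and disabling one can only enlarge the final set
— a tested superset property. Funnel flowcharts sometimes describe stage 1
as excluding on the estimate's own p-value; the methods-level description —
exclusion on the pleiotropy and heterogeneity diagnostics — is what we
implement.

Design choices worth recording:

* **MR-PRESSO rule.** A target fails validation when the global test is
  significant *and* at least one outlier is flagged. Requiring an identified
  outlier matches how the test is used in practice (detect, remove, refit)
  and avoids discarding clean targets at the test's alpha level.
* **Single-instrument fixture targets.** The bundled funnel fixture plants
  one causal cis variant per target, so its targets are Wald-ratio targets
  with NA Egger/Q/PRESSO — the same pattern single-SNP genes show in real
  target tables. This respects the colocalization model's single-signal
  assumption at stage 3; the multi-instrument sensitivity battery is
  exercised by its own instrument-level simulations instead.
* **Determinism.** The seed is recorded in the report; MR-PRESSO streams are
  derived per target and study, so a rerun with the same configuration is
  byte-identical, which the tests assert on the rendered files.

`renderReport()` writes per-stage counts, removals with reason codes and the
final-target table as TSVs plus a JSON summary; the two views are
cross-checked for equality in the tests.

# Numerical choices

* Log-sum-exp for all posterior normalizations; per-trait maximum rescaling
  before any inclusion–exclusion difference; a non-positive scaled
  difference (numerically empty assignment set) maps to −Inf rather than a
  negative likelihood.
* Degenerate inputs fail loudly and specifically: missing mandatory columns
  name the column, variants missing from an LD matrix name the variant,
  empty intersections and undersized shared panels are hard errors, and an
  empty funnel input completes with all-zero stages rather than erroring.
* Ties: clumping breaks p-ties lexicographically; Steiger ties are FALSE.
* The `pval` slot domain (0,1] is enforced by validity; simulated p-values
  are floored at 10⁻³⁰⁰.

# Known limitations

Single-causal-variant colocalization only (no multi-signal extension); no
GWAS-VCF parsing, liftover or reference-panel LD computation; no
weighted-median/mode MR estimators or multivariable MR; the LDSC
implementation is the simplified unweighted form and is not a drop-in for
genome-scale analyses with reference LD scores; mediator curation is manual
by design.
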