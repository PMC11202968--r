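---
title: "Methods: from haplotype blocks to body composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from haplotype blocks to body composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapbiva)
```

hapbiva chains five analysis stages that are usually scattered across
separate tools: population-genetic screening of a biallelic variant
panel, diplotype calling at named haplotype blocks, specific
bioelectrical impedance vector analysis (specific BIVA), sensory
scoring, and covariate-adjusted association between diplotypes and
bioelectrical phenotypes. A synthetic-cohort generator with a full
ground-truth record makes every stage testable end to end. This
vignette explains the models, the defaults, and the choices made where
the design was genuinely open.

## Coordinates and genotype containers

All genomic coordinates are 1-based with closed intervals, so an
amplicon at 17:3596108-3596806 spans `699` bp (`interval_length()`),
and VCF positions are used as-is. Genotypes are stored as alt-allele
dosages (0/1/2, `NA` for missing) regardless of the phase separator in
the input; phase enters the analysis only through the same-phase
assumption of the diplotype caller. A self-describing genotype TSV
dialect (`##variant=` header lines plus one `G/C`-style column per
variant) is provided for per-amplicon Sanger-style genotype tables,
which are not naturally VCF-shaped. Round-tripping through either
format reproduces dosages exactly.

## Screening statistics

**MAF** is computed per site over non-missing alleles. **Fst** between
two labelled groups is offered in two flavours: the Weir–Cockerham
variance-components estimator (default, the estimator behind the
`--fst` option of the common genotype-analysis toolchain) and the plain
frequency-based Hudson form `1 - Hw/Hb`. The Hudson form is exactly 0
for identical group frequencies and exactly 1 for a fixed difference,
which makes it the cleaner didactic reference; the Weir–Cockerham form
is approximately unbiased around zero under no structure and may go
negative — negative estimates are reported as computed and flagged,
never clipped. Descriptive thresholds of 0.15 (moderately high) and
0.25 (high) are applied only downstream, as labels.

**Pairwise LD** estimates the alt–alt haplotype frequency by
expectation–maximisation over the double-heterozygote ambiguity, with
allele frequencies fixed at their observed values (they are the MLE
regardless of phase). From the converged `p_ab`: `D = p_ab − p_a p_b`,
`D' = |D|/Dmax`, `r² = D²/(p_a(1−p_a)p_b(1−p_b))`. The tests verify the
EM against a grid-search maximiser of the same likelihood, and against
directly countable haplotypes when no double heterozygotes exist.

**LD blocks**: the source toolchain's block rule is not documented at
the level needed for reimplementation, so the simplest rule that
reproduces the intended behaviour on matched synthetic data is used: a
block is a maximal run of consecutive position-sorted variants in which
*every* within-run pair exceeds both thresholds (`D' > 0.75` and
`r² > 0.75`, strict); singletons are not blocks. A consequence worth
knowing: on the default synthetic panel, two genuinely unlinked
variants fall *inside* the H1 positional span, so the contiguous-run
rule reports H1 as two sub-runs there — exactly what a run-based rule
does on the real positional layout. Tests that assert exact block
recovery therefore use panels whose unlinked variants lie outside the
block spans.

**Tajima's D** follows the standard constants
(`a1 = Σ 1/i`, …, `e2 = c2/(a1² + a2)`), with
`D = (π − S/a1)/sqrt(e1 S + e2 S(S−1))`; `S = 0` yields an explicitly
undefined result, never a silent zero. π uses the unbiased
frequency-based estimator `Σ 2k(n−k)/(n(n−1))`, which equals the mean
over all sequence pairs; for unphased diploid input each individual
contributes two sequences — a documented approximation that is exact
for π but blind to phase. Haplotype input is used throughout the tests,
where the implementation is checked against exhaustive pairwise
enumeration to 1e−9 on all matrices with n ≤ 8, S ≤ 10.

## Diplotype calling

Haplotypes are named allele-state vectors over a block's tag SNPs (the
bundled defaults: three states a/b/c over five tag SNPs for H1, two
states over three tag SNPs for H2; the exonic rs877610 lies within the
H2 span but is not in linkage with it and is excluded from calling).
A call is the unordered pair of defined haplotypes whose allele union
reproduces the observed genotype at every site. Genotypes fitting no
pair are `INCONSISTENT`; genotypes fitting several pairs, or with any
missing tag SNP, are `AMBIGUOUS` — the caller never frequency-weights
its way out of ambiguity, because silently picking the likelier pair
would fabricate data. Grouping schemes mirror the analysis
conventions: `merge_c_into_b` (the rare c haplotype differs from b at a
single site and is pooled with it), and `carrier_vs_aa` for the binary
contrast used in the stratified tests.

One encoding subtlety: the printed c-state allele at rs73303325 (G) is
a third allele relative to the a/b states (C/T), so a strictly
biallelic dosage matrix cannot carry it. The generator therefore emits
genotypes both as an allele-pair table (used for calling; carries all
three alleles) and as a biallelic matrix in which third-allele
genotypes are recorded as missing — the same behaviour a biallelic
importer shows on a real triallelic record.

## Specific BIVA

Bioimpedance measures a resistance/reactance vector (R, Xc) in ohms.
Specific BIVA rescales both coordinates by A/L, where
`A = 0.45·arm + 0.10·waist + 0.45·calf` (each area from its
circumference via the circle model `C²/4π`, in cm²) and
`L = height × 1.1` cm approximates the hand-to-foot electrode path.
The result (Rsp, Xcsp) in ohm·cm removes body-size effects, leaving
composition: vector length (Zsp) tracks relative fat mass, the phase
angle `PhA = atan(Xc/R)·180/π` tracks cell mass and the
extracellular-to-intracellular water ratio. PhA is identical for raw
and specific coordinates (A/L cancels) — an invariant the tests
exercise. The circle model is the convention of the specific-BIVA
method; it is the only closed form consistent with circumference
inputs.

Two ellipse families serve different questions. The **tolerance
ellipse** describes a reference *population*: center at the reference
means, covariance from its SDs and correlation, squared radius the
χ²(2 df) quantile at 50/75/95% coverage (a fixed menu, matching BIVA
practice). The **confidence ellipse** describes a *sample mean*:
covariance S/n and the exact small-sample radius
`2(n−1)/(n−2)·F(2, n−2; 0.95)`; it needs n ≥ 4 and a non-singular
covariance, otherwise it reports "sample too small" rather than a
number. Containment uses a closed boundary.

Group comparison uses the two-sample **Hotelling T²**
(`T² = (n1 n2/(n1+n2)) d' S_pooled⁻¹ d`), converted to
`F = T²(n1+n2−3)/(2(n1+n2−2))` on (2, n1+n2−3) df, with the
pooled-covariance **Mahalanobis distance**
`D = sqrt(T²(n1+n2)/(n1 n2))`. These identities are frozen in the
tests against a published table of (T², F, D) triples: all
non-duplicated rows reproduce F from T² at printed precision. Rows
whose small samples were duplicated before analysis use an effective n
that the table does not print; their consistency cannot be checked
without guessing, so they are excluded rather than reinterpreted.

## Perception scoring

The capsaicin threshold design is ten consecutive 1:2 dilutions of a
2.243 µg/mL stock; swab 1 is the most dilute (0.004 µg/mL), swab 10
the stock, so `concentration[k] = stock/2^(10−k)` (swab 5 ≈ 0.07,
swab 9 ≈ 1.12 µg/mL). The threshold phenotype is the ordinal swab
index of the lowest concentration perceived, kept as a 10-category
variable. PROP intensity on the 0–100 labelled magnitude scale is cut
at 50 (closed lower bound → taster); `molar_to_mass_conc()` documents
the 50 mM ↔ 8.51 mg/mL correspondence for PROP (170.23 g/mol).

## Association

Phenotypes analysed across sexes are first standardised *within* sex
(z-scores), which removes the sex main effect exactly. The pooled
regression of a bioelectrical phenotype on diplotype uses OLS with an
additive genotype code (0/1/2 copies of the b haplotype — the
conventional additive coding) plus a sex indicator; carrier coding
(0/1) is exposed because the stratified contrasts are aa vs b-carrier.
Carrier-coded regression on a two-group design reproduces the pooled
two-sample t test exactly, and the two-group ANOVA F equals t² — both
identities are tested. t tests are classical pooled-variance Student
tests. p-values are reported raw with α = 0.05; a Bonferroni column
across the four phenotypes is available but clearly an extension, off
by default. Missing values are deleted listwise per model with the
used n reported.

## The synthetic cohort

`cohort_spec()` defaults encode the emulated study conditions: 46
donors of sub-Saharan ancestry (34 M, 12 F) and 46 Italian donors
(21 M, 25 F); H1 haplotype frequencies 0.545/0.433/0.022 (a/b/c) in
the African-like group and fixed a in the European-like group; H2
0.556/0.444 vs fixed a; six unlinked variants at their
ancestry-specific frequencies. Bivariate (Rsp, Xcsp) strata use the
published female group statistics (converted from Zsp/PhA means and
SDs: SSA F ≈ (499, 54), ITA F ≈ (405, 40) ohm·cm); male strata are not
published at that granularity, so shorter vectors with wider phase
angles — the documented qualitative sex pattern — were chosen once:
SSA M (370, 45), ITA M (350, 42), SDs 55–105/6.5–11, correlation
0.70–0.75. The injected female-restricted effect defaults to
+50 ohm·cm Rsp and +1.5 ohm·cm Xcsp per H2-b copy, which lengthens Zsp
and lowers PhA in female carriers — the reported direction; the
magnitude is a configuration choice, not an empirical claim.
Anthropometry comes from sex-specific normals (height 176±7/163±6 cm,
weight 75±10/60±8 kg, arm 30±3/27±2.5, waist 85±9/75±8, calf
37±3/35±2.5 cm) purely to exercise the A/L pipeline; no anthropometric
realism is claimed. Capsaicin thresholds follow a categorical
distribution massed below swab 6 and zero above swab 8; PROP scores
are N(62, 16) truncated to [0, 100], giving ≈22% non-tasters.

(R, Xc) are produced by *inverting* the specific standardisation from
the sampled (Rsp, Xcsp) and the sampled anthropometry, so a synthetic
subject CSV is indistinguishable from a real one at the interface.
One seeded stream drives the whole study; two calls with the same spec
are byte-identical.

What the generator does *not* emulate: linkage between blocks,
recombination, genotype–anthropometry correlation, measurement error
in R/Xc beyond 0.01-ohm rounding, and realistic demography. Passing
tests therefore demonstrate the correctness of the statistical
machinery under the stated model, not robustness to the full
messiness of field data.

`generate_neutral_region()` provides three stylised scenarios for the
Tajima statistic: `singleton_excess` (every derived allele private to
one sequence; forces D < 0), `balanced_two_class` (two haplotype
classes differing at every site; forces D > 0, the signature the
screening stage is meant to flag), and `binomial_neutral` (derived
counts drawn ∝ 1/i, under which E[π] = E[θ_W] exactly and D centres
on zero).

## Numerical choices and problem sizes

EM convergence: 1e−12 on the haplotype-frequency max-change, capped at
1000 iterations. Ellipse containment uses a 1e−12 slack so boundary
points are inside. Simulation-based checks use fixed seeds and these
replicate counts: 10⁵ draws for tolerance-ellipse coverage, 1000
replicates (n = 30) for confidence-ellipse coverage, 2000 null
replicates (n = 20 per group) for Hotelling type-I error, 500
replicates (200 subjects) for regression effect recovery, 200
replicates for block-detection reliability and neutral-spectrum
calibration, and an exhaustive oracle sweep over 150 random matrices
for Tajima's D. These sizes keep each suite within a few minutes on a
single core while leaving Monte-Carlo error well inside the asserted
bands.

## Known limitations

- The block rule is contiguity-based; interleaved unlinked variants
  split a block, as discussed above. Tools with gap-tolerant block
  definitions will disagree on such panels.
- Tajima's D on unphased dosage input cannot see phase; use haplotype
  input where available.
- The caller requires every tag SNP; block-level imputation is out of
  scope by design.
- Reference-population parameters for tolerance ellipses ship only as
  a file format plus synthetic examples — real reference values are
  not redistributable here, and all bundled references are labelled
  synthetic.
- No multiple-testing correction is applied by default at either the
  screening or the association stage, mirroring the descriptive
  reporting convention the pipeline implements; the Bonferroni column
  is available for stricter use.
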