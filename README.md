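# hapbiva

Haplotype-block diplotypes, population-genetic screening, and specific
bioelectrical impedance vector analysis (BIVA) in one tested R
pipeline.

## The problem

Candidate-gene studies of body composition often need a chain of
analyses that no single tool covers: screen a panel of biallelic
variants for population differentiation and selection signals (minor
allele frequency, Fst, linkage-disequilibrium blocks, Tajima's D);
call each subject's *diplotype* — the pair of block haplotypes carried
— from unphased genotypes; quantify body composition from whole-body
bioimpedance with *specific BIVA*; and test diplotype–phenotype
association with sex as a covariate. hapbiva implements that chain for
researchers working on haplotype-block associations with bioelectrical
phenotypes, with a synthetic-cohort generator so every stage can be
validated against known ground truth.

## The core statistics

- **Tajima's D** over a region with n sequences, S segregating sites
  and mean pairwise differences π:
  `D = (π − S/a₁) / sqrt(e₁S + e₂S(S−1))` with the standard constants
  `a₁ = Σ 1/i`, …, `e₂ = c₂/(a₁² + a₂)`. Strongly positive D flags an
  excess of intermediate-frequency variants (balancing selection or
  contraction).
- **Fst** per SNP between two groups: Weir–Cockerham
  variance-components estimator (default) or the frequency-based
  Hudson form `1 − Hw/Hb`.
- **LD**: two-locus EM over the double-heterozygote ambiguity gives
  `p_AB`, hence `D' = |D|/Dmax` and `r²`; blocks are maximal runs of
  consecutive variants with every pair above `D' > 0.75` and
  `r² > 0.75`.
- **Specific BIVA**: `Rsp = R·A/L`, `Xcsp = Xc·A/L` (ohm·cm) with
  `A = 0.45·arm + 0.10·waist + 0.45·calf` areas (`C²/4π`) and
  `L = 1.1·height`; vector length `Zsp = sqrt(Rsp² + Xcsp²)` and phase
  angle `PhA = atan(Xc/R)·180/π`. Tolerance ellipses (χ²₂ radius) and
  95% confidence ellipses (`2(n−1)/(n−2)·F(2, n−2)` radius) on the
  (Rsp, Xcsp) plane.
- **Hotelling T²** between two bivariate mean vectors, with
  `F = T²(n₁+n₂−3)/(2(n₁+n₂−2))` on (2, n₁+n₂−3) df and Mahalanobis
  `D = sqrt(T²(n₁+n₂)/(n₁n₂))`.
- **Association**: OLS of each bioelectrical phenotype on haplotype
  copy number (additive 0/1/2 or carrier 0/1) plus a sex indicator;
  pooled Student t tests under the aa vs b-carrier grouping; within-sex
  z-score standardisation.

## Worked example

Simulate a two-ancestry cohort of 92 subjects, write it through the
standard formats, and run the full pipeline:

```r
library(hapbiva)

# relocate the unlinked variants outside the block spans so the
# contiguous-run block rule can see both blocks whole
panel <- default_unlinked_snps()
panel$pos <- c(3590000, 3591000, 3610000, 3571000, 3580000, 3581000)

study <- generate_study(cohort_spec(seed = 42, unlinked_snps = panel))
paths <- write_study(study, "demo", format = "vcf")
summary <- run_pipeline(pipeline_config(
  genotypes = paths[["genotypes"]], subjects = paths[["subjects"]],
  out_dir = "demo/out", seed = 42))
str(summary$counts)
#> List of 5
#>  $ samples        : int 92
#>  $ variants       : int 14
#>  $ skipped_records: int 0
#>  $ blocks_detected: int 2
#>  $ resolved_calls : int 89
```

Both planted LD blocks are detected; 89 of 92 subjects get fully
resolved diplotypes (the three others carry the rare H1-c haplotype,
whose third allele cannot be encoded in a biallelic dosage matrix and
is recorded as missing — see the methods vignette). The association
table (`demo/out/association.tsv`) for the H2 block:

```
phenotype        beta     t_stat    p_value n_used
      rsp 36.91289523  2.4311344 0.01705647     92
     xcsp  3.01711938  1.7870718 0.07733035     92
      zsp 37.02813876  2.4294806 0.01712949     92
      pha -0.08320451 -0.5326817 0.59558144     92
```

The generator injected a female-restricted +50 ohm·cm Rsp shift per
H2-b copy; the pooled sex-adjusted regression recovers a positive Rsp
and Zsp association (p ≈ 0.017) with essentially no phase-angle
signal — the expected dilution of a female-only effect in a pooled
additive model. Screening output ranks the H1/H2 tag SNPs at the top
of the Fst table (`fst ≈ 0.48, class "high"`).

Single statistics work standalone:

```r
hotelling_from_t2(13.5, 46, 45)
#> <hotelling_result> T2 = 13.500, F(2, 88) = 6.674, p = 0.002001, D = 0.770 (n1 = 46, n2 = 45)
tajimas_d(generate_neutral_region(40, 20, "balanced_two_class"))
#> <tajima> n = 40 sequences, S = 20, pi = 10.2564, theta_w = 4.7020, D = 3.9071
```

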