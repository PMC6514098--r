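# azfcnv

Copy-number variant detection, classification and case-control association
for the azoospermia factor (AZF) regions of the human Y chromosome, from
multiplex ligation-dependent probe amplification (MLPA) peak areas.

## The problem

Microdeletions of the AZFa, AZFb and AZFc regions are a leading genetic
cause of spermatogenic failure.  Conventional screening amplifies ten
presence/absence STS markers and therefore sees only deletions.  MLPA peak
areas are proportional to target copy number, so a single assay can also
reveal duplications and complex deletion+duplication rearrangements — but
turning 40-odd noisy peak areas into a named rearrangement class, and a
cohort of such calls into odds ratios, takes a defined calling rule, a class
catalogue and some statistics.  `azfcnv` packages that workflow for
geneticists analysing MLPA screens of infertility cohorts, together with a
seeded simulator so the whole pipeline is testable without raw capillary
data.

## The method in brief

For probe *i* with baseline copy number *n₀ᵢ* (the family total for
multicopy targets such as DAZ), the relative peak area is

    rᵢ = (areaᵢ / mean reference-probe area of the sample)
         ÷ (mean of the same quantity over 5 copy-normal reference samples)

so that *rᵢ ≈ nᵢ / n₀ᵢ*.  A probe is called *duplicated* when *rᵢ ≥ 1.30*,
*deleted* when *rᵢ ≤ 0.70* (the 30 % rule, inclusive).  Samples are matched
against a catalogue of 24 AZF rearrangement classes (8 deletions, 11
duplications, 5 complex) by per-locus dosage, with DAZ1/2 vs DAZ3/4
composition resolved from sY587 restriction-digest band intensities and
de novo status determined against paternal genotypes.  Association uses 2×2
tables per class and per composite: OR = (a·d)/(b·c) with the Wald interval
exp(ln OR ± 1.96·√(1/a+1/b+1/c+1/d)), Pearson's χ² and Fisher's exact test.
ΔΔCt qPCR (rq = 2^−ΔΔCT, ACTB reference, triplicates) provides orthogonal
dosage validation.  The methods vignette
(`vignettes/azfcnv-methods.Rmd`) documents every rule and default.

## Worked example

Simulate the default study design — 402 fertile controls, 197 azoospermic
and 226 oligozoospermic patients carrying the 24 classes at the reference
cohort's frequencies, with 5 % multiplicative peak noise — and run the full
pipeline:

```r
library(azfcnv)
library(dplyr)

cohort <- simulate_cohort(simulation_config(seed = 1))
res <- run_azf_pipeline(cohort = cohort)

glance(res$classification)
#> # A tibble: 1 × 5
#>   n_samples n_no_cnv n_carriers n_unclassified n_ambiguous
#> 1       867      646        221              0           0

render_association(res$association) |>
  filter(case_group == "spermatogenic_failure",
         label %in% c("gr/gr del", "b2/b3 del + DAZ1/2 dup",
                      "any_cnv", "any_deletion", "any_duplication_azfc"))
#>   label                  n_case n_control OR   CI95         P        test_used
#> 1 gr/gr del                  32        20 1.56 (0.88–2.78)  0.126    chi2
#> 2 b2/b3 del + DAZ1/2 dup     11         2 5.34 (1.18–24.24) 0.0153   chi2
#> 3 any_cnv                   145        76 2.24 (1.62–3.08)  6.23e-07 chi2
#> 4 any_deletion              115        60 2.13 (1.50–3.01)  1.66e-05 chi2
#> 5 any_duplication_azfc       27        12 2.22 (1.11–4.44)  0.0215   chi2

glance(res$sts)
#> # A tibble: 1 × 7
#>   n_classes n_identified n_missed n_misclassified pct_identified pct_missed pct_misclassified
#> 1        24            7       12               5           29.2         50              20.8

table(res$inheritance$status)
#> de_novo
#>      42
```

Reading the output: at this noise level every simulated carrier is
recovered (221 carriers, none unclassified).  Carrying *any* AZF CNV is
about twice as common among patients as controls (OR 2.24), the complex
"b2/b3 del + DAZ1/2 dup" class shows the strongest class-level signal
(OR 5.34), while the gr/gr deletion alone does not separate cases from
controls (CI spans 1).  The STS comparison quantifies why MLPA is needed:
conventional STS-PCR identifies only 7 of the 24 classes (29.2 %), misses
all 11 duplications plus the RBMY1J deletion, and reads all 5 complex
classes as simple deletions (20.8 %).  All 42 novel-class carriers check
out as de novo against their simulated fathers.

Per-sample dosage profiles and forest plots come from `autoplot()`:

```r
calls <- call_samples(cohort$peaks, cohort$references, azf_panel())
plot_probe_ratios(calls, samples = cohort$samples$sample_id[1:4])
autoplot(res$association)
```

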