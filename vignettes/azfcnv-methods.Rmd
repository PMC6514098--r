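---
title: "Methods: MLPA copy-number calling and association in the AZF regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MLPA copy-number calling and association in the AZF regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(azfcnv)
library(dplyr)
```

## The measurement model

Multiplex ligation-dependent probe amplification (MLPA) quantifies the copy
number of dozens of loci at once: each probe's amplified peak area is, up to
per-sample amplification scale and measurement noise, proportional to the
number of target copies in the sample.  For the Y-chromosome azoospermia
factor regions (AZFa, AZFb, AZFc) this turns structural rearrangements --
deletions, duplications and combined deletion+duplication events generated by
non-allelic homologous recombination between the region's amplicons -- into
characteristic dosage patterns across the probe panel.

The package's calling chain makes the proportionality usable:

1. **Intra-sample normalization.** Each sample's areas are divided by the
   mean of its autosomal reference-probe areas.  This removes per-sample
   amplification scale, so calls are invariant to multiplying all of a
   sample's areas by any positive constant (a tested property).  A `"none"`
   option skips the step for data that is already block-normalized.
2. **Relative peak area.** Each normalized area is divided by the mean of
   the corresponding areas in a set of copy-normal reference samples
   (five by default).  The resulting ratio `r` estimates
   `copies / baseline copies` for the probe's target.
3. **The 30 % rule.** A probe is called `duplicated` when `r >= 1.30` and
   `deleted` when `r <= 0.70`, otherwise `normal`.  The thresholds are
   inclusive so that the rule is honored exactly at the boundary; `delta`
   is configurable in `calling_config()`.  An advisory integer copy
   estimate `round(r * baseline)` is attached, with ties rounded half away
   from zero (plain `round()` would round half to even).

An important consequence of the ±30 % band is that per-probe *states* are
not trustworthy for multicopy families: a 2-of-3-copy dosage sits at
`r = 0.67`, less than one noise standard deviation from the 0.70 boundary at
realistic noise levels.  Classification therefore never requires exact
per-probe state agreement (next section).

## Class assignment

The catalogue (`azf_catalogue()`) enumerates 24 named rearrangement classes
-- 8 deletions, 11 duplications and 5 complex deletion+duplication events --
each as an expected integer copy number for every probe, together with its
category, region scope, ten-marker STS pattern, and expected DAZ1/2 vs
DAZ3/4 doublet composition where AZFc is involved.

Assignment works at the *target-locus (family) level*: the observed dosage
of a family is the mean ratio over its probes, which suppresses per-probe
noise by the square root of the probe count.  A class is **compatible** with
a sample when, for every family, the observed dosage lies within a band
around the class expectation of half a copy (`0.5 / baseline`) or 20 % of
the expected ratio, whichever is wider.  The half-copy term keeps
single-copy loci sharp (their integer dosages are a full copy apart); the
20 % term keeps high-copy states (e.g. 8 or 10 DAZ copies) from being
rejected by a band that shrinks relative to the noise.  Among compatible
classes -- the copy-normal state participates as one -- the class minimizing
the probe-count-weighted squared dosage distance is assigned.  The bands are
deliberately generous (robustness) while the nearest-signature rule does the
discrimination (sharpness): a misassignment requires noise to cross half the
distance between two class signatures, the narrowest such gap in the default
catalogue being one BPY2 copy step.

Sentinels, in decreasing order of information:

* `NO_CNV` -- the copy-normal pseudo-class wins.
* `AMBIGUOUS` -- two or more compatible classes tie in distance and, if a
  digest is available, it does not separate them.  Ties are never silently
  broken.
* `UNCLASSIFIED` -- no class is compatible (e.g. a compound event touching
  two regions at once, which the catalogue deliberately does not invent a
  class for); the top candidates by per-family state agreement are reported.

**DAZ-subset resolution.**  The DAZ family occurs as two doublets, DAZ1/2
and DAZ3/4, distinguishable by a sequence variant at sY587 that creates a
restriction site in one of them.  MLPA sees only the family total, so the
class "b2/b3 del + DAZ1/2 dup" -- a b2/b3 deletion whose lost DAZ dosage is
restored by a DAZ1/2 duplication (expected composition 4 + 0) -- carries
`digest_needed = TRUE`: the total of four copies cannot by itself prove
*which* doublet was duplicated.  `resolve_daz_subsets()` allocates the total
copy number to the doublets proportionally to the two digest band
intensities, with a largest-remainder rounding that always conserves the
total (ties favor DAZ1/2).  With a digest table supplied, the classifier
reports `digest_consistent`; without one it still reports the
dosage-equivalent class but flags it unconfirmed.

**De novo checks.** `inheritance_status()` compares a proband's class with
his father's: the same class is `inherited`, a class the father lacks is
`de_novo`, and any UNCLASSIFIED/AMBIGUOUS input (or a copy-normal proband)
is `indeterminate`.

## The virtual STS-PCR comparison

Conventional screening amplifies ten presence/absence sequence-tagged sites
(sY84/sY86 for AZFa, sY127/sY134 for AZFb, six markers for AZFc).  Each
catalogue class stores the pattern its deletion component leaves on those
markers; duplications leave all ten present.  `compare_sts_mlpa()` scores
each class as:

* `identified` -- non-trivial pattern, unique among the deletion classes;
* `missed` -- a CNV whose pattern is all-present (all 11 duplications, and
  the RBMY1J deletion, whose single-gene target carries no marker);
* `misclassified_as_simple_deletion` -- a complex class whose pattern
  equals a simple deletion's (all 5 complex classes collapse onto the
  gr/gr or b2/b3 deletion patterns).

The patterns are class-level fixture data rather than being recomputed from
genomic coordinates: marker positions inside the amplicon structure are
beyond the package's scope, and fixing the patterns keeps the comparison
exact and auditable.  The three outcomes partition the catalogue; the
summary fractions (7/24 identified, 12/24 missed, 5/24 misclassified) are
what `scripts/acceptance.R` recomputes after first verifying, through a
seeded simulate-call-classify round trip, that the pipeline actually
recovers every scored class.

## qPCR validation

`ddct_quantify()` implements ΔΔCt relative quantification with a reference
gene (ACTB in the simulated tables), triplicate aggregation by mean (SD of
the replicate-wise ΔCt reported, no outlier rejection), and a fixed
amplification base of 2 -- the classic assumption of perfect doubling; the
base is configurable but no efficiency correction is applied.
`qpcr_concordance()` compares the observed relative quantity against the
MLPA dosage expectation `copies / baseline` with a ±30 % relative band,
chosen to mirror the MLPA call band.  A fully deleted target (expected
quantity 0) uses the absolute band `rq <= 0.3`, since a relative band
around zero would be empty.

## Association statistics

`association_report()` builds one 2×2 table per class and per composite
(any CNV; any deletion, which includes the complex classes since they carry
a deletion component; duplication-only; AZFc duplication-only) against the
control group, for the pooled patient group and the azoospermia and
oligozoospermia strata separately.  For each table it reports:

* the odds ratio `(a·d)/(b·c)` with the 95 % Wald interval on the log scale
  -- any zero cell renders both undefined (an en dash in reports), with no
  continuity correction;
* Pearson's χ² (df = 1) with and without Yates correction, from the closed
  form `N(ad−bc)² / ((a+b)(c+d)(a+c)(b+d))`;
* the two-sided Fisher exact p, summing hypergeometric probabilities no
  larger than the observed table's (with the customary `1 + 1e-7` relative
  guard against floating-point ties; the test suite verifies equality with
  an exhaustive factorial enumeration to 1e-10 on every table of size up to
  40).

`test_used` selects Fisher when any expected cell count is below 5 and χ²
otherwise; this is the package's own convention -- both p-values are always
emitted so any other convention can be audited.  No multiple-testing
adjustment is applied, matching the design being emulated; the report is a
screen, not a confirmatory analysis.  `covariate_balance()` applies
equal-variance t-tests (age, BMI) and an uncorrected χ² (smoking).

## The synthetic cohort

`simulate_cohort()` generates a complete study: 402 controls, 197
azoospermic and 226 oligozoospermic patients, carrying the 24 classes at
the per-class carrier counts of the reference case-control survey shipped
as `azf_class_counts()` (`exact_counts = TRUE` assigns exactly those
counts; the probability mode draws independently at the implied rates).
Peak areas follow `base_area × copies/baseline × exp(ε)`, `ε ~ N(0, σ²)`
with σ = 0.05 by default -- multiplicative log-normal noise is the standard
choice for fluorescence intensities and keeps areas positive; the reference
survey publishes no noise model, and 5 % relative noise is a realistic
capillary-electrophoresis figure that still leaves the ±30 % rule ample
margin.  Per-probe nominal areas vary deterministically over a modest range
so that the scale-invariance of the calling chain is actually exercised.
Five copy-normal reference samples are drawn alongside; sY587 digest tables
are produced for carriers of digest-dependent classes; triplicate Ct tables
(σ_Ct = 0.1 cycles) are produced for one carrier of every class STS-PCR
cannot confirm plus two copy-normal calibrators; covariates are drawn at
the reference demographics (`azf_covariate_params()`).  Fathers -- always
copy-normal -- are generated for every carrier of a novel class, so the de
novo checks have material to work on.  Every stage derives its own child
seed from the config seed: identical configs give identical cohorts,
byte-for-byte through the TSV writers.

What the generator does *not* emulate: per-probe variance heterogeneity and
GC-dependent amplification bias, reference-sample batch effects, Y-haplogroup
structure in class frequencies, mosaicism, and partial-breakpoint variation
within a named class.  Passing tests therefore demonstrate that the
*algorithms* are correct under a clean noise model, not that the pipeline is
robust to every artifact of real capillary data.

One bookkeeping caveat of the reference counts themselves: the published
summary (composite) counts for the oligozoospermia stratum are internally
inconsistent with the per-class counts (82 vs a class-count sum of 83 for
any CNV, 65 vs 66 for any deletion; the other strata agree).  The package
ships both: `azf_class_counts()` drives the simulator, so simulated
oligozoospermia composites sum to 83/66, while `azf_composite_counts()`
reports the published summary verbatim for desk-scale recomputation of the
summary odds ratios.

## Numerical choices and problem sizes

* Thresholds inclusive at 0.70 / 1.30; ties in copy estimation rounded half
  away from zero; compatibility band `max(0.5/baseline, 0.2 × expected)`;
  distance ties (within 1e-9) are AMBIGUOUS rather than broken by order.
* Degenerate inputs fail loudly and early: zero reference-probe means,
  missing probes, incomplete qPCR triplicates, Ct outside (0, 45),
  both digest bands zero with DAZ copies present, carrier counts exceeding
  a group size.
* Empty inputs (zero samples, empty catalogue) flow through and produce
  empty, well-formed outputs.
* The test suite simulates cohorts of up to 1 000 copy-normal samples for
  the miscall-rate bound, 200 carriers per class for the per-class accuracy
  bound at σ = 0.05, and the full 825-subject design for the end-to-end
  association checks -- sizes chosen to give the binomial bounds real teeth
  while keeping a complete run comfortably on a single CPU.

## Known limitations

* The probe identities, positions and partial-duplication signatures are a
  synthesized stand-in for a commercial kit's probe list, which is not
  public in the text this design follows; both panel and catalogue are
  ordinary files, so a user with the real probe list can substitute it
  without touching code.  Class-level results (counts, fractions, odds
  ratios) do not depend on the stand-in identities.
* "Type I/II" partial-duplication subtypes and the compound
  "two gr/gr dels + b2/b4 dup" event are encoded schematically -- their
  dosage signatures are chosen to be mutually distinguishable, not
  reconstructed from breakpoints.
* gr/gr deletions are classified without digest confirmation of which DAZ
  doublet was lost; only classes whose *name* asserts a doublet carry
  `digest_needed`.
* Printed p-values of the reference survey are not reproduction targets:
  several are internally inconsistent with their own printed counts, so the
  package asserts odds ratios and intervals instead and always emits both
  test p-values.
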