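---
title: "Models and methods: somatic mtDNA mutation analysis from duplex consensus data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: somatic mtDNA mutation analysis from duplex consensus data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexmt)
```

## What the package models

Duplex sequencing resolves somatic mitochondrial heteroplasmies far below
1% variant allele fraction (VAF) by demanding that a variant appear on the
consensus of *both* strands of one original DNA fragment. `duplexmt`
implements the downstream analysis of such data — frequency and spectrum
estimation, somatic filtering, heteroplasmic-clone analysis and the group
statistics used to report it — together with a synthetic data generator
rich enough to exercise every stage without any external download.

The package treats three error strata explicitly:

1. **Sequencer errors** are independent per read and per base; they are
   removed by the single-strand consensus (SSCS), which requires a
   configurable majority among the reads of one strand family.
2. **PCR errors and DNA-damage miscoding** are fixed into all copies of one
   strand before clustering; they survive SSCS but are removed by the
   duplex consensus (DCS), which requires agreement between the two strand
   families of a fragment. Oxidative lesions on guanine (8-oxo-dG-like)
   miscode as G>T, so a positive SSCS-minus-DCS excess concentrated in the
   G>T/C>A class is the fingerprint of DNA damage rather than true
   mutation.
3. **True mutations** sit on the source molecule and therefore appear on
   both strands; they survive both consensus layers.

## The synthetic data generator

`build_reference()` emits a circular A/C/G/T sequence (default 16,299 bp,
G+C 0.37, matching mouse mtDNA scale and composition) with a feature
layout: a ~900 bp control region ending at the last base, OriL at
5160–5191, seven short masked intervals standing in for the polynucleotide
repeats that are masked in real data, and a coarse gene map. Coordinates
are 1-based closed on the circle; only the control region may wrap the
origin.

`tissue_profile()` fixes the per-base, per-molecule de novo event rates.
The presets in `preset_tissue_profiles()` emulate an aged mouse cohort:
overall SNV frequencies of order 10⁻⁶ (kidney highest at ~6.6×10⁻⁶, heart
lowest at ~1.7×10⁻⁶), spectra dominated by G>A/C>T transitions, ROS-linked
transversion shares elevated in heart (~34% combined) and muscle (~25%),
In/Del rates one tenth of the SNV rate, and per-tissue clonality anchored
at kidney ≈ 10.4%, liver/retina ≈ 5.6% and 2–3% elsewhere. Because the
anchors are *observed* frequencies, which include clonal amplification, the
preset rates divide the anchor by the expected molecule multiplicity
`E[k] = (1 − f_clonal)(1 + p_double) + f_clonal · m_clone` so that the
recovered frequency, not the seeding rate, matches the anchor.

`simulate_sample()` seeds events onto a pool of `N` molecules: per class
the event count is Poisson with mean `rate × L × N`; non-clonal events land
on one molecule (two with probability `p_double = 0.05`); with probability
`clonal_fraction` an event is a heteroplasmic clone on `k = 3 + Pois(m − 3)`
molecules (default mean 5), placed with weight `cr_enrichment` inside the
control region. Events merged onto three or more molecules by coincidental
duplication are reclassified as clonal. All rates of order 10⁻⁷–10⁻⁶ give
VAFs of 10⁻⁴–10⁻³ at `N = 10,000`, safely below the 1% somatic cutoff.

`simulate_read_families()` fragments molecules uniformly around the circle
at a fixed fragment length (default 300 bp; real libraries are mechanically
sheared to roughly this scale and the exact size distribution does not
matter to any downstream statistic), tags each fragment with an ordered
UMI pair from a 96-tag alphabet (pairs are re-drawn on key collisions so
that family identity is `(UMI pair, strand, start, end)`), and emits a
top- and bottom-strand family with truncated-at-1 Poisson sizes (default
mean 3; the empirical duplex family-size distribution is not published, so
this is exposed as configuration). Damage is modelled minimally: each
fragment picks one lesion strand, each eligible site (G on the top strand,
C on the bottom, i.e. the guanine of that strand) carries a lesion with
probability `damage_rate`, and a lesion miscodes as T in every copy of
that strand. This is the simplest mechanism that reproduces the
SSCS-only artifact signature. Reads carry their true mapping coordinates
in the tag table — no aligner is run, which isolates the pipeline's own
computations from third-party mapping behaviour — and a provenance channel
tags every non-reference base with the event or error process that caused
it, so tests can assert that nothing appears from nowhere.

### The depth-level sampling shortcut

Full read simulation at the study's scale (10,000× over 16.3 kb, two
strands, family size 3) would mean ~10⁹ simulated bases per sample. The
recovery experiments therefore use `sample_pileup()`, which draws the
duplex pileup directly: constant depth `d` per position, each seeded event
receiving `Binomial(d, k/N)` supporting reads. When per-read error rates
are zero, the full route and the shortcut have the same distribution of
supporting-read counts, because each of the `d` consensus fragments
covering a position descends from a uniformly chosen molecule. The full
read route is exercised at region scale (1–3 kb, depth 20–40) in the
consensus and damage tests. One consequence worth knowing: at `d = N` a
single-molecule mutation yields Poisson-like support with mean 1, so ~8%
of detected singletons reach the 3-read clone threshold through sampling
alone; measured clonality percentages in the simulation are therefore
higher than the seeded clonal fraction. This mirrors the fact that clone
counting in real data also cannot distinguish three fragments of one
molecule from three molecules, only there the molecule pool vastly exceeds
the sampled depth.

## Consensus calling

Defaults `min_reads = 3`, `agreement = 0.7` and `clip_len = 10` follow
common duplex practice; the published pipeline this emulates does not print
its thresholds, so all three are exposed as configuration. Per position the
SSCS base is the unique majority base if its fraction reaches the
agreement threshold, else `N`; exact ties are `N` (conservative). The DCS
emits a base only where both strands agree and neither is `N`. End
clipping masks the first and last `clip_len` bases of each duplex
consensus, where shearing-induced damage concentrates in real libraries.
`N` bases contribute to neither depth nor allele counts, so total emitted
DCS bases always equal summed DCS depth. In/Dels are carried as
length-typed allele annotations rather than resolved sequences (no
realignment is attempted): an In/Del allele needs the agreement fraction
within a strand family and presence on both strands to reach the duplex
layer, and In/Dels of different lengths at one position are distinct
alleles.

## Somatic filtering

Calls are one row per `(position, non-reference allele)` — each mutation
type is scored once per genome position. The filters set flags rather than
deleting rows, so they are idempotent and commute; the somatic subset is
the flag-free complement, and call counts are conserved:

* **Masked regions** — calls inside any masked interval or OriL are
  excluded, and masked positions are removed from every frequency
  denominator. Intervals are closed; position 5159 survives an OriL of
  5160–5191.
* **NUMT reads** — a read is dropped if and only if some non-mitochondrial
  candidate alignment has a strictly lower e-score than its mitochondrial
  alignment; exact ties keep the read. Dropped reads decrement both
  supporting reads and depth, so this runs before VAF computation (the
  pipeline enforces the ordering). Running the aligner itself is out of
  scope; the decision contract is what is implemented and tested.
* **Inherited variants** — a `(position, alt)` present in every sequenced
  sample of one animal is flagged in all of them; single-sample animals
  warn and pass through.
* **Somatic cutoff** — VAF strictly above 1% or position depth strictly
  below 100 excludes a call; both boundaries are retained. The depth rule
  is applied per position (whether the published rule is per position or
  per region is not stated; per position is the stricter reading).
* **In/Del length** — events above 15 bp are flagged and excluded.

## Frequencies, spectra and the clone model

The mutation frequency is pooled: summed supporting reads over summed
duplex depth at unmasked positions ("variant bases among sequenced
bases"). Per-position allele fractions are retained separately for the VAF
cutoff. The six-class spectrum collapses the 12 ordered substitutions by
strand complementarity; labels are printed reference-strand first
(`G>A/C>T`), and the per-class frequencies sum exactly to the total SNV
frequency.

A heteroplasmic clone is a somatic variant with ≥3 supporting duplex
reads; variants seen once or twice are "unique". The expected-clone model
computes, per class, `lambda_c = sum_t N_t p_t s_tc` with `N_t` the
tissue's SNV count, `p_t` its mean clonality fraction, and `s_tc` its
spectral fractions. The spectral fractions default to the *unique*
(support ≤ 2) variants: the observed side of the comparison counts clones,
so the expectation should be built from the non-clonal complement;
building it from all SNVs would let large clone classes predict
themselves. `clone_model_inputs()` exposes `spectral_source = "total"` as
the alternative reading. A clone contributes 1 to its class count
regardless of read support — clones are counted as variants, not reads.

Observed and expected counts are compared per class with an exact
two-sided Poisson test: twice the smaller of `P(X ≤ O)` and `P(X ≥ O)`
under mean `lambda_c`, capped at 1, with no normal approximation. Folds
are reported as `lambda/O` (under-representation) or `O/lambda`
(over-representation); `O = 0` with positive expectation reports an
infinite fold while the p-value stays defined.

## Statistics

Welch's t-test, one-way ANOVA with Tukey HSD and Dunnett contrasts
delegate to `stats` and `multcomp`; constant-input edge cases return
p = 1 (equal means) or 0 by convention rather than erroring. The Fieller
interval for a ratio of two independent Gaussian means is implemented
in-package (it is not in base R): with the default pooled variance it is
exact under equal variances, and when the denominator mean is not
significantly nonzero at the chosen level the bounded interval does not
exist and the result is flagged unbounded instead of raising an error.
Significance conventions follow common reporting practice: adjusted
p < 0.05 significant, p < 0.15 a trend. The frequency-vs-age regression is
ordinary least squares with a pointwise confidence band.

## Problem sizes and numerical choices

The test and acceptance workloads are sized for a laptop-class single
core: parameter recovery runs 8 tissues at 10,000× over the full 16,299 bp
circle through the sampling shortcut (seconds); read-level suites use
1–3 kb references at depth 20–40; the clone-model calibration uses 500
null replicates at ~1,300 clones and 200 suppressed replicates; Fieller
coverage uses 10⁴ replicates. Recovery tests compare against the
closed-form expectation `rate × E[k]` within three analytic standard
errors of the compound-Poisson/binomial sampling model, plus a 1% slack
for the masked-denominator second-order effect. Determinism is strict:
every simulation takes an explicit seed and restores the caller's RNG
state.

## What passing tests do and do not show

The generator reproduces the *structure* of duplex data — strand-resolved
families, the three error strata, clone multiplicity, control-region
clustering — not its full texture: no base-quality variation, no mapping
ambiguity, no indel realignment, no trinucleotide context, no
strand-asymmetric replication gradient, uniform fragment starts and a
fixed fragment length, and a constant per-position depth in the sampling
shortcut. Tests passing on this synthetic data validate the pipeline's
arithmetic and its filtering/consensus logic under known truth; they do
not validate alignment, library-preparation chemistry, or any biological
conclusion about real tissues. The packaged aged-cohort table is
synthetic (built from coarse published anchors) and is labelled as such in
its filename; quantities computed from it characterise the model, not the
original measurements.
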