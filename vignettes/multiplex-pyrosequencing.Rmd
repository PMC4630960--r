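---
title: "Multiplex pyrosequencing genotyping: model, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplex pyrosequencing genotyping: model, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyromux)
```

## The problem

Pyrosequencing reads a short template by dispensing nucleotides one at a
time in a fixed *dispensation order*; each dispensation produces a
chemiluminescent peak whose height is proportional to the number of bases
incorporated. Genotyping one SNP per well (uniplex) is reliable but slow and
expensive when a risk panel spans many SNPs per patient. Running several
sequencing primers in a single well (multiplex) superimposes their
pyrograms into a signal that is visually uninterpretable — but still linear:
the multiplex signal is the sum of the uniplex signals of whatever templates
are present.

`pyromux` implements the full stack needed to exploit that linearity for a
panel of bi-allelic SNPs:

1. a deterministic pyrogram simulator (template + dispensation order →
   theoretical peak vector);
2. a standardized *dictionary* of per-allele "atom" signals;
3. a beam search for dispensation orders that keep atoms de-correlated;
4. a sparse non-negative decomposition of observed multiplex signals with a
   heterozygote correction and a per-well confidence index;
5. a synthetic-signal generator so the whole pipeline can be validated
   without instrument data;
6. turnaround-time, reagent-cost and waste comparators for the uniplex
   versus multiplex workflows.

The built-in fixture is a nine-SNP prostate-cancer risk panel split into a
quadruplex assay (rs1016343, rs10993994, rs16901979, X-linked rs5945619;
order `CTGCATGACTCGAT`) and a quintuplex assay (rs10896449, rs1859962,
rs4242382, rs4430796, rs6983267; order `AGATCGCTACGACTG`), with a ten-patient
genotype table used as decoding truth.

## The pyrogram model

`simulate_pyrogram()` applies the standard incorporation model: a read
pointer walks the template; each dispensed base incorporates the whole
homopolymer run at the pointer (possibly length 0) and the peak records the
run length. Theoretical signals are therefore integer-valued with first
unitary peak height (FUPH) 1. Experimental signals are mapped onto the same
scale by dividing every peak by a known single-incorporation peak
(`fuph_standardize()`). No chemistry artefacts (incomplete extension,
plus/minus shift, dATPαS background) are modelled: dictionaries use clean
theoretical signals, and departures from them are the business of the noise
model below.

```{r}
simulate_pyrogram("TTCCCTCCCA", "CTGCATGACTCGAT")
```

## Dictionary, heterozygote correction and genotype signals

Each SNP contributes two atoms, one per allele UNS (the 10-nt unique
nucleotide sequence read downstream of its sequencing primer). A
heterozygote carries one template copy of each allele, so its uniplex signal
is the superposition of the two homozygote signals at **half height**;
`genotype_signal()` composes `0.5 * (atom_ref + atom_alt)` for hets and the
plain atom for homo-/hemizygotes. Multiplex combination signals are sums of
per-SNP genotype signals at equal weight (`enumerate_combination_signals()`),
and the *ambiguity index* (`ambiguity_index()`) is the maximum pairwise
Pearson correlation over all of them — the single number that tells you how
close the worst pair of genotype combinations is to being confused.

### Orientation calibration

Four of the nine SNPs are assayed with reverse primers, and a stored UNS can
be recorded either in reporting (genomic) sense or as read. The fixture
resolves this with a per-SNP `as_read` flag, calibrated as follows. If the
reverse-orientation strings are simulated exactly as stored
(`as_read = TRUE` everywhere), the quadruplex dictionary collapses to **7**
distinct theoretical atoms out of 8: the two rs5945619 alleles produce
identical pyrograms because order `CTGCATGACTCGAT` never reaches their
variant base at UNS position 9. That convention makes the X-linked SNP
uncallable and drives the ambiguity index to exactly 1 — inconsistent with
an assay that demonstrably genotypes rs5945619 and yields unique
combination signals. Reverse-complementing the reverse-orientation UNS
before simulation (`as_read = FALSE`, the shipped setting) makes every
allele pair distinguishable, keeps all 8/10 atoms distinct, and gives
ambiguity indices below 1. Allele labels always refer to the stored
reporting-sense strings, so calls are reported in the conventional letters.

### Ambiguity conventions and sensitivity

Two enumeration knobs matter at the margin:

* **Ploidy of the X-linked SNP.** Order-design scoring
  (`force_diploid = TRUE`) enumerates every SNP with three states, the way a
  generic bi-allelic enumeration treats a panel before sex is known;
  genotype calling and simulation always respect true ploidy (two states
  for rs5945619).
* **Heterozygote weight.** Hets enter at half height (0.5/0.5); this is
  forced by the template model, not tunable.

Under the shipped convention the indices are:

| panel | enumeration | max pairwise correlation |
|---|---|---|
| quadruplex | all-diploid (81 combos) | 0.9885 |
| quadruplex | hemizygous X (54 combos) | 0.9863 |
| quintuplex | 243 combos | 0.9878 |

Reference values reported for this assay are 0.9891 (quadruplex) and 0.9892
(quintuplex); the residual gap of 0.0006–0.0014 is attributable to an
enumeration convention of the original implementation that is not public.
The package reports what its own documented convention computes rather than
targeting those constants, and `tests/testthat/test-acceptance.R` asserts
the reference values at four decimal places so the discrepancy stays
visible.

## Dispensation-order design

`select_dispensation_order()` runs a breadth-first beam search, extending
candidate orders one dispensation at a time. Conventions:

* consecutive identical dispensations are never generated (the second one
  can only produce a zero peak);
* feasibility means every allele's **variant base is read**
  (`coverage = "variant"`). Full consumption of every 10-nt UNS
  (`coverage = "full"`) is stricter than what working assays satisfy: both
  shipped orders leave several UNS partially read (e.g. rs10993994's
  reference UNS stops after 6 of 10 bases) while reading every variant —
  which is what allele discrimination actually requires. The validation
  report (`validate_dispensation_order()`) shows both notions per UNS;
* partial candidates are ranked by (uncovered bases, partial max atom
  correlation); feasible candidates are compared lexicographically on
  (max atom correlation, length, alphabetical order string), so the search
  is deterministic. The `seed` argument is accepted for interface stability
  but the default search consumes no randomness;
* with a beam at least as wide as the (pruned) candidate space, the search
  is exhaustive; the tests verify exact agreement with brute-force
  enumeration on toy panels.

The objective is the maximum pairwise atom correlation; mean correlation or
a dictionary condition number would also be defensible, but the maximum
directly bounds the worst confusable pair and is what the validation report
tracks.

## Sparse non-negative decomposition

An observed multiplex signal `y` is fitted as `y ≈ D x`, `x ≥ 0`, where `D`
is the atom matrix. The default solver is plain non-negative least squares
(Lawson–Hanson, `lambda = 0`), which is naturally sparse because atoms
compete for the same peaks; an optional L1 penalty
(`0.5 ||y − Dx||² + λ Σx`) is available through `glmnet`, and
`lambda = "auto"` picks the smallest grid value at which every retained atom
clears the `min_rel_contribution` floor. For both shipped panels the atom
matrices have full column rank, so noiseless signals decompose uniquely —
the suite checks that all 54 + 243 combination signals decode back to their
generating genotypes exactly.

The **confidence index R** is the Pearson correlation between observed and
fitted signal; `R = 1` exactly for any signal inside the dictionary's
non-negative cone. Decoding is scale invariant: multiplying a signal by
`c > 0` multiplies coefficients by `c` and changes neither allele fractions,
relative contributions, calls nor `R`. Observed signals therefore need no
FUPH standardization before decoding; supplying a FUPH merely puts
coefficients in single-incorporation units.

### Genotype calling

Per SNP, allele weights are coefficient sums over that SNP's atoms and the
alt fraction is `f = w_alt / (w_ref + w_alt)`:

| parameter | default | meaning |
|---|---|---|
| `hom_fraction_max` | 0.20 | `f` at or below → hom ref; at or above `1 − 0.20` → hom alt |
| `het_fraction_lo/hi` | 0.30 / 0.70 | het window (diploid only) |
| `min_rel_contribution` | 1 % | below → `low_contribution` flag |
| `min_confidence_r` | 0.95 | well below → every call flagged `low_confidence` |

Fractions falling between the windows are no-calls with an
`ambiguous_fraction` flag; haploid SNPs are called by majority allele with
the same homozygote threshold. The windows follow common pyrosequencing
allele-quantification practice and are deliberately conservative; no
reference cutoffs exist for this assay, so all are configurable.
"Absolute contribution" is the per-SNP coefficient sum by default; a
`contribution = "light"` option weights each coefficient by its atom's
total light instead, which changes relative shares when atoms differ in
total peak mass. Absolute coefficient units depend on each instrument's
arbitrary light scale, so they are reported uncalibrated.

## The synthetic generator

`simulate_multiplex_well()` builds
`fuph_scale × Σ_s eff_s × genotype_signal(s) + background + noise`, with
Gaussian peak noise of standard deviation `sd_base + sd_prop × height`,
truncated at zero. Defaults (`sd_base = 0.03`, `sd_prop = 0.02`,
`background = 0`, `fuph_scale = 7`) put raw peaks in typical instrument
magnitudes with sub-percent relative noise, consistent with the very high
confidence indices real wells of this assay attain; `fuph_scale` is
irrelevant to calls by scale invariance and simply documents that absolute
scale is free. Per-SNP `efficiency` weights emulate PCR amplification
imbalance — the phenomenon that primer-concentration adjustment corrects.
`sample_cohort()` draws diploid genotypes under Hardy–Weinberg equilibrium
with the panel's `maf` interpreted as the alt-allele frequency (which
physical allele is minor varies by SNP and is not modelled), and haploid
genotypes as Bernoulli draws.

What the generator does **not** emulate: incomplete extension and
minus/plus shift artefacts, read-length decay, apyrase kinetics,
between-run drift, or correlated noise across peaks. Passing the synthetic
end-to-end tests therefore demonstrates correctness of the linear model and
the decoder under the stated noise structure, not robustness to every
instrument pathology; the dictionary's support for FUPH-standardized
experimental atoms is the intended mitigation on real data.

## Numerical conventions and degenerate inputs

* Pearson correlation with a zero-variance vector is defined as 0 (and can
  never attain an ambiguity maximum); this cannot occur for the shipped
  panels but keeps toy panels well-defined.
* All-zero observed signals are rejected as degenerate rather than decoded.
* Zero allele mass (`w_ref + w_alt = 0`) yields a no-call with
  `low_contribution`, never a division by zero.
* Ties in the order search are broken alphabetically; all pipelines are
  bit-reproducible under a fixed seed.
* Clipping at zero biases only zero-height peaks (by
  `sd_base/√(2π) ≈ 0.012` units at defaults); positive peaks are unbiased
  to Monte-Carlo precision.

## Problem sizes used in the checks

The test-suite and the acceptance script run at the natural size of the
assay: 81 and 243 enumerated combinations for the ambiguity indices, all
54 + 243 noiseless combination signals for identifiability, ten patients ×
two multiplex wells (90 calls) for cohort concordance, cohorts of 15–100
synthetic patients for contribution and noise-degradation properties, and
n = 1000 patients for the Hardy–Weinberg checks. These sizes keep every run
in seconds while leaving the binomial standard errors small enough for
3-SE assertions.

## Known limitations

* Bi-allelic SNPs only; indels and tri-allelic sites are out of scope.
* The decoder treats supplied peak heights as final (any instrument
  background subtraction is assumed already applied).
* Primer-concentration suggestions use a first-order inverse-proportional
  rule; real PCR competition is nonlinear, so they are starting points for
  titration, not predictions.
* Cost/TAT/waste comparators are bookkeeping over a user-supplied model;
  they contain assay-specific defaults, not general economics.
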