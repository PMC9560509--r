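---
title: "OmpA allelic variation: typing, surface-property prediction and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{OmpA allelic variation: typing, surface-property prediction and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ompalleles)
```

## The problem

Outer membrane protein A (OmpA) is among the most abundant proteins in the
*E. coli* outer membrane: a 325-residue mature chain (preceded by a
21-residue signal peptide) whose N-terminal domain crosses the membrane as
an eight-strand beta barrel with four surface-exposed loops, and whose
C-terminal domain sits in the periplasm (with a minority 16-strand "large
pore" conformation in which it too is membrane-integrated). Natural isolates
carry recurring sequence patterns — alleles — at the four outer loops and at
three C-terminal positions (mature coordinates 175, 203 and 251). An allele
is written as a pair: an N-terminal pattern I–VII and a C-terminal pattern
$\alpha$–$\delta$; K-12 strains carry (I, $\alpha$).

This package implements the computational chain for studying those alleles:

1. **Typing** protein sequences into (I–VII, $\alpha$–$\delta$) bins;
2. **Physicochemical prediction** of per-segment net charge and
   hydrophobicity;
3. **Assay metrics**: MATH hydrophobicity, crystal-violet biofilm index,
   neutrophil-elastase survival;
4. **Growth kinetics**: log-phase detection and specific growth rate from
   OD time series;
5. **Cohort statistics**: ANOVA, compact letter displays, slope-CI
   correlation calls, exact-test enrichment of allele counts;
6. **Synthetic data** generators with known ground truth for all of the
   above.

## The classification scheme is data

The scheme (reference sequence, segment boundaries, classification sites,
pattern residue runs) lives in a YAML file
(`inst/extdata/ompa_scheme_synthetic.yaml`) loaded by `load_scheme()`.
Residues 93, 129 and 161 also vary in nature but are recorded without
contributing to the classification.

The bundled scheme is a **synthetic transcription**. The reference backbone
is the K-12-style mature OmpA chain; the residue runs that define the
non-reference patterns are package-defined stand-ins chosen to satisfy the
full set of constraints the naming convention documents in prose: patterns
I, IV, V and VII carry SVE at the loop-2 site while II, III and VI carry
DNI; only VI and VII carry the D variation at loop 1 and a 7-residue loop-3
run (all others carry the 9-residue run); $\alpha$ equals the K-12 reference
at 175/203/251; $\delta$ differs from $\alpha$ at exactly 203 and 251;
$\gamma$ carries the position-175 variation; I and II differ at all four
loops; IV and VII differ by a single loop-1 residue. Anyone holding the
authoritative residue table can drop it into the YAML without touching
code. Two further constraints are structural: the SVE/DNI variants carry
equal acidic-residue counts, and so do all loop-4 variants, which makes the
loop-2 and loop-4 charge rows of the property table allele-invariant — the
equality pattern the published table shows.

A note on numbering: position 175 has also been reported as "position 200"
in another group's convention. Neither mature (175) nor naive precursor
numbering (175 + 21 = 196) yields 200, so the offset convention of that
report cannot be reconstructed from the text; this package uses mature
coordinates everywhere and treats the correspondence as documented but
unresolved.

## Typing

`align_to_reference()` performs a global pairwise alignment against the
mature reference (match +1, mismatch −1, affine gaps costing 5 for the
first gapped residue and 1 per further residue) and returns a position map
covering every reference coordinate. Precursor inputs (length ≥ 340 with a
recognizable signal peptide) are trimmed and flagged. Inputs under 70%
identity are rejected as "not OmpA-like" — this is deliberate: OmpA from
*Klebsiella*, *Yersinia* or *Salmonella* cannot be described by this
classification system and must fail loudly rather than be force-binned.

`extract_variant_profile()` reads the residue run at each classification
site through the position map (spanning the outermost mapped positions, so
loop indels appear as length changes); `call_allele()` assigns each domain
independently by exact match, counting loop runs of unequal length as one
mismatch. Without an exact match the domain is "novel" and *all* nearest
patterns are reported; equidistant ties set an `ambiguous-tie` flag rather
than silently picking one. `map_to_power_alleles()` collapses the N-terminal
patterns onto the older two-allele system (*ompA1* = I/IV/VII, *ompA2* =
II/III).

```{r typing}
scheme <- load_scheme()
type_sequence(scheme$reference$mature, scheme, id = "K-12")
```

## Segment charge and hydrophobicity

Net charge at pH $p$ uses Henderson–Hasselbalch partial charges,

$$Q = \sum_{\text{basic}} \frac{1}{1 + 10^{\,p - pK_a}}
    - \sum_{\text{acidic}} \frac{1}{1 + 10^{\,pK_a - p}},$$

with a Protein-Calculator-style pKa set (D 4.05, E 4.45, H 5.98, C 9.0,
Y 10.0, K 10.0, R 12.0; termini 8.0/3.1) stored as swappable data. Termini
are off by default because barrel loops are internal peptide stretches.
Hydrophobicity uses the Kyte–Doolittle scale in mean (GRAVY) mode by
default, likewise swappable. The published property table names the tools
it used but not their constants or the exact loop boundaries, so exact
numeric reproduction is a calibration exercise; what **is** reproducible —
and tested — is the equality structure: C-terminal loop rows identical
across all alleles (the classification sites 175/203/251 fall between, not
inside, loops 5–8), loop-2 and loop-4 charge rows shared, and rows equal
exactly where segment sequences are equal.

## Assay metrics

The MATH (microbial adhesion to hydrocarbons) statistic is implemented as
printed: $100\,(OD_i - OD_a)/OD_a$ with the *aqueous* OD in the
denominator. The conventional MATH formula divides by the *initial* OD
instead; whether the printed denominator is intentional cannot be decided
from the text, so both are provided (`conventional = TRUE`) and the printed
form is the default. The biofilm index is $OD_{570}/OD_{620}$; replicate
SDs propagate to first order in quadrature,
$\sigma_I = I\sqrt{(\sigma_{570}/OD_{570})^2 + (\sigma_{620}/OD_{620})^2}$.
Neutrophil-elastase survival is the treated/control mean CFU ratio with a
kill flag requiring a two-tailed pooled t-test below the severe fixed
cutoff (p < 0.005) *and* a decrease.

## Growth kinetics

Curves are linearized as $\ln(OD_t/OD_0)$; the specific growth rate $\mu$
is the least-squares slope over the detected log phase and `mu_sd` the
standard error of that slope — the uncertainty convention used for these
measurements.

The underlying rule — "a decrease in slope ends log phase" — leaves the
noise handling open, so the detector is an explicit, documented choice:

* point-to-point slopes are smoothed with a centered 3-point mean;
* the reference slope $\mu_{\max}$ is the **maximum rolling 8-point
  least-squares slope**, not the raw maximum of noisy point slopes.
  At 1% multiplicative OD noise and 10-minute sampling, point slopes carry
  an SD of ≈ 0.085 h⁻¹ and their extreme statistic would bias any
  threshold anchored to it; the 8-point regression slope has SD
  ≈ 0.008 h⁻¹.
* the log phase is the longest contiguous run of intervals with smoothed
  slope ≥ $(1 - f)\,\mu_{\max}$ (drop fraction $f = 0.10$), tolerating
  interior dips of at most `window` = 3 intervals — one outlying reading
  contaminates exactly three smoothed slopes, so only a longer sustained
  decrease counts as the end of log phase;
* a curve whose $\mu_{\max}$ never reaches the floor (0.05 h⁻¹, above
  plate-reader noise slopes, below any growth rate of interest) raises
  "no growth detected". A naive floor of 0.01 h⁻¹ on raw point slopes
  would be noise-dominated at the study's own noise level, which is why
  the package anchors the floor to the low-noise reference slope instead.

All parameters are explicit arguments and are returned with every fit.

```{r growth}
g <- gen_growth_curves(n_curves = 1, seed = 1)
fit <- fit_growth_curves(g$curves, curve_id)
fit
```

## Cohort statistics

* t-tests are **pooled-variance Student's** (switchable to Welch), matching
  the study's stated test.
* `pairwise_letter_groups()` builds a compact letter display by
  insert-and-absorb, guaranteeing the invariant *two groups share a letter
  iff their pairwise p ≥ α*; the suite checks this biconditional
  exhaustively on random inputs. Zero-variance pairs with equal means count
  as non-significant (p = 1).
* `slope_ci_association()` implements the correlation criterion: OLS slope
  with a t confidence interval; significant iff the interval excludes zero.
* `fisher_2x2()` computes the exact two-tailed p as the sum of
  hypergeometric outcomes at most as probable as the observed table (the
  common implementation convention; others exist), and the conditional-MLE
  odds ratio. `chi_square_homogeneity()` covers the r×c comparisons made in
  earlier work, with an adequacy flag when > 20% of expected counts fall
  below 5.
* **No multiple-testing correction is applied anywhere** — the study
  instead uses severe fixed cutoffs (0.005 for phenotypes, 10⁻⁵ for
  enrichments), and the package mirrors that exactly.

### Count-table reconstruction

`build_count_table()` rebuilds integer counts from printed percentages
(half-away-from-zero rounding) and applies the lump-below-10 rule. The
published summary table mixes two percentage conventions, and the package
supports both explicitly: the environmental/ExPEC row gives fractions *of
the cohort* (22% of 412 → 91 carriers), while phylotype and ExPEC-subtype
rows give fractions *of the allele's n* (for (II, $\alpha$), n = 53, "B1
91%" → 48 of the 83 B1 isolates; the cohort-fraction reading would give 76
carriers of a 53-member allele, which is impossible). Two documented
inconsistencies are surfaced rather than hidden: the same allele is printed
with n = 14 in the table but n = 36 in the text (the text value is used),
and the listed allele counts (382 + 40 "other") exceed the trimmed pool of
400; reconstructed tables carry a `reconstructed` attribute and warn when a
group's counts exceed its stated size.

```{r enrichment}
reconstructed_enrichments()
```

## Synthetic data: what it emulates, and what it does not

All generators are pure functions of (configuration, seed); a single seed
feeds a hierarchical stream split per generator, so adding one generator
call never perturbs another's draws.

* `gen_sequences()` edits the reference to each target allele, optionally
  adding loop-3 indels (insertions upstream of the variant run, deletions
  downstream — adjacent net-zero edits would be genuinely indistinguishable
  from substitutions for *any* aligner), site noise and background
  mutations. Site noise plants a designated novel residue (W, unused by any
  pattern at the variant sites), so the expected novel-call fraction has
  the exact closed form $1-(1-r)^7$.
* `gen_phenotypes()` draws Gaussian replicates around per-allele means;
  `fig2_biofilm_means()` encodes the observed tenfold biofilm split between
  $\alpha$ and $\beta/\gamma$ C-terminal alleles (means 2.0 vs 0.2,
  replicate CV 5%, three replicates — the study's replicate structure).
* `gen_growth_curves()` produces lag/exponential/plateau curves on the
  study's grid (15 h at 10-minute spacing, 91 points) with defaults
  $\mu = 0.6$ h⁻¹, 1 h lag, plateau at 6 h, OD₀ = 0.05 and 1%
  multiplicative noise — a realistic minimal-medium profile.
* `gen_count_table()` draws multinomial counts per group with planted odds
  multipliers.

What the generators do **not** emulate: phylogenetic correlation among
sequences, plate-position and batch effects, non-Gaussian assay error,
heteroscedastic growth noise, and any coupling between sequence and
phenotype beyond the planted means. Passing tests therefore demonstrate
that the algorithms recover *planted* structure under the study's nominal
noise; they do not validate the biological models on real data.

## Calibration design

Two calibration checks deserve their rationale spelled out:

* The slope-CI criterion is checked for ~5% type-I error on null
  simulations at the 95% level (n = 7 pairs, 1000 runs).
* The letter display's family-wise error grows with the number of pairwise
  tests as $1-(1-\alpha)^{C}$. At the seven-allele layout ($C = 21$,
  $\alpha = 0.005$) that is ≈ 10% *by construction* — not a defect — and a
  property test checks the seven-group empirical rate against this closed
  form. The single-letter-on-null calibration therefore uses a four-group
  null ($C = 6$, family-wise error ≈ 3%), where the ≥ 95% single-letter
  expectation is mathematically attainable.

## Numerical choices

* Percentage→count rounding is half-away-from-zero.
* The two-tailed Fisher sum uses a relative tolerance of 10⁻⁷ when
  comparing outcome probabilities to the observed one (guarding ties
  against floating-point noise); the test suite verifies agreement with an
  independent factorial enumeration to 10⁻¹² over every 2×2 table with
  margins ≤ 15.
* The conditional odds ratio solves $E_\psi[X] = a$ by bisection on the
  noncentral hypergeometric mean; boundary tables return 0 or ∞.
* Degenerate inputs are contracts, not surprises: zero Fisher margins give
  p = 1 with a flag; zero-variance equal-mean pairs give p = 1; non-positive
  ODs, empty schemes and missing profile sites raise errors naming the
  offender.

## Problem sizes

The test suite and acceptance script use: 100 growth curves for recovery
checks, 500–1000 runs for type-I calibrations, 70 sequences for typing
round trips, 280 for the site-noise binomial check, and the full
12,376-table grid for the Fisher oracle. These sizes put Monte-Carlo error
well inside each asserted tolerance while keeping the default run fast.

## Known limitations

* The scheme's non-reference residue runs are synthetic stand-ins (above);
  typing real GenBank sequences requires transcribing the authoritative
  residue table into the YAML first.
* Charge/hydrophobicity prediction ignores conformational exposure — the
  monomer/dimer/large-pore distribution — which the study itself flags as a
  likely reason sequence-based predictions align poorly with measured
  surface properties.
* The replicate-level published p-values (e.g. the zeta-potential ANOVA)
  are reproducible only with the study's raw replicate data, which is not
  redistributed here; the pipeline is exercised on synthetic data with the
  same design instead.
* Exact r×c tests are out of scope; the r×c case uses the chi-square
  homogeneity test or pairwise 2×2 comparisons, as in the source analyses.
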