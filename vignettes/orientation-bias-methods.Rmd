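---
title: "Methods: orientation-bias analysis of mutation accumulation catalogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orientation-bias analysis of mutation accumulation catalogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oriconflict)
```

## The question and the geometry

On a circular bacterial chromosome, bidirectional replication proceeds from
the origin to a terminus on the opposite side, defining two replichores. A
gene transcribed in the same direction as the fork that traverses it is
*codirectional* (CD); one transcribed against the fork is *head-on* (HO).
Equivalently, the transcribed (template) strand of a CD gene is the
leading-strand template (LDST) and that of an HO gene the lagging-strand
template (LGST). If replication–transcription conflicts were mutagenic, HO
genes should accumulate more spontaneous mutations than CD genes in a
mutation accumulation (MA) experiment, where serial single-cell bottlenecks
let mutations accrue nearly free of selection. In mismatch-repair-deficient
(MMR^-^) strains those mutations are, to good approximation, raw replication
errors.

`oriconflict` implements the full analysis chain for that question:
geometric classification, catalog validation, feature mapping, conditional
rates, and the comparison/correlation statistics — plus a synthetic MA
generator so every stage can be exercised and calibrated without any
external data.

## Orientation model

* **Replichores.** A position is *right* if it lies on the arc walked from
  the origin in the direction of increasing coordinates up to (but not
  including) the terminus, *left* otherwise; the origin is right and the
  terminus left, so the two arcs partition the circle. When no terminus is
  supplied it defaults to the point halfway around the circle from the
  origin, the usual stand-in for the terC region; an explicit coordinate
  can override it.
* **Orientation.** CD ⇔ (forward strand ∧ right replichore) ∨ (reverse
  strand ∧ left replichore). A gene's replichore is decided by its circular
  CDS midpoint; the orientation definition leaves boundary-spanning genes
  unspecified, and the midpoint rule is deterministic and
  order-independent. Both choices are surfaced as arguments.
* **Strand templates.** On the right replichore the fork moves with
  increasing coordinates, so the reverse strand templates the leading
  strand: forward = LGST, reverse = LDST, mirrored on the left replichore.
  This is the unique assignment consistent with "CD gene ⇒ template strand
  is LDST", and the package asserts that consistency exhaustively in its
  tests.
* **Transition placement.** For an A·T transition the informative base is
  the A; for G·C it is the C. Its placement (`A_on_LGST`, …) is the
  template role of whichever strand carries it. Replication errors are
  known to be asymmetric in exactly this labeling, which is why an apparent
  CD/HO difference can be a strand-placement effect in disguise.

## Catalog conventions

Mutations are stored on the forward strand only; strand interpretation is
always derived. Indels are restricted to ≤ 4 bp (larger events are
rejected and counted — typical short-read MA pipelines cannot call them
reliably) and left-normalized against the genome in the VCF sense, which
pins an indel inside a homopolymer to the run start and makes run
attribution deterministic. The primary exchange format is TSV with explicit
line/experiment provenance; a minimal VCF 4.2 export is provided for
interoperability.

## Statistics

The toolkit mirrors the tests such studies report, built on the standard
base-R machinery behind a typed interface:

* Pearson and Spearman correlations with two-tailed t-distribution
  p-values (n − 2 df); Spearman uses midranks.
* Two-sample comparisons: pooled-variance Student's t by default (Welch by
  flag) and Mann-Whitney. The Mann-Whitney p is computed by complete
  enumeration of the rank-sum null distribution — correct under ties —
  whenever `choose(n_a + n_b, n_a)` ≤ 1e5 labelings, and otherwise by the
  normal approximation with tie correction and continuity correction. The
  enumeration budget is a determinism/feasibility trade-off: enumerating,
  say, two samples of 20 would require ~1.4 × 10^11 labelings.
* Least-squares regression with slope standard errors, regression F tests,
  and a slope-equality t test with Welch–Satterthwaite degrees of freedom.
* One Benjamini-Hochberg pass per report run across *all* emitted
  p-values (t, Mann-Whitney, Pearson, Spearman, F), approximating the
  "one family per study" ledger; Holm is available as an option, and the
  family scoping is configurable by adjusting tables yourself with
  `adjust_report()`.
* Histogram diagnostics: a Gaussian curve fit (`a·exp(−(x−μ)²/2σ²)`,
  Levenberg-Marquardt, initialized at the modal count, weighted mean and
  SD, with the fit R² reported) against a Poisson reference histogram at
  the sample mean — over-dispersion of mutations per CDS relative to
  Poisson is what length heterogeneity produces.
* Box statistics with type-7 (linear interpolation) quartiles and the
  1.5 × IQR outlier rule, inclusive at the fence. When the IQR is zero the
  inclusive rule would flag every value at the median, so the degenerate
  case instead flags values off the median.

ΔHO, the percent excess of the HO mean over the CD mean, is always computed
from unrounded means; rounding happens only at serialization. A
delta-method interval for ΔHO is provided (`delta_ho_ci()`).

### Conditional rates

A class rate is `count / (total line-generations × eligible nucleotides)`,
with pair-class targets counted as base pairs (an A·T pair counts once
regardless of strand). 95% confidence limits use the exact (Garwood)
Poisson interval on the count divided by the exposure; published MA
studies rarely state their interval method, and the exact interval is the
conservative default for pooled counts. The placement-asymmetry ratio
(LGST/LDST rate ratio) gets its interval from the conditional binomial
split of the two Poisson counts, which conditions away the common exposure.

## The synthetic generator

The generator's defaults describe the study conditions at desk scale:

| parameter | default | rationale |
|---|---|---|
| genome | 500 kb circular, 50% GC | desk-scale stand-in for a ~4.6 Mb chromosome |
| genes | 500, non-overlapping, CD fraction 0.55 | mirrors the roughly even CD/HO split of *E. coli* |
| CDS lengths | normal(900, 300) nt, min 120 | CDS lengths are approximately normal |
| MA design | 200 lines × 1,000 generations | 2 × 10^5 generations total |
| transitions | `mu_ts_AT` 1.2e-8, `mu_ts_GC` 6e-9 per bp per generation (LDST baseline) | scaled to genome-wide MMR^-^ BPS rates of order 2.5e-8 with transitions dominating ~3:1 AT:GC |
| placement bias | `strand_bias_rho` = 2 on the LGST | the ~2-fold replication-error asymmetry |
| transversions | 1e-9 | minor class |
| indels | per run of length l: `mu0 · b^(l−5)`, `mu0` 1e-9, `b` 10, saturating at l = 8; background 5e-11/nt | exponential run-length dependence of slippage |
| expression | log10(TPM) ~ N(1.3, 0.5) per phase + N(0, 0.3) gene effect | three correlated growth phases |

Counts are drawn Poisson per site class with exposure equal to summed line
generations — no within-line lineage structure and no selection, the
standard idealization of an MA design — and every event is assigned to a
line in proportion to its generations. Repeated hits at one site are
separate catalog rows, matching count-based tables. The saturation of the
run-indel exponent at length 8 is deliberate: without it a single long
natural run would dominate the whole catalog, which is neither realistic
nor useful for testing.

Scenarios: `null` sets the placement bias to 1 (CD and HO genes are then
exchangeable — the negative control); `strand_bias` keeps the defaults;
`expression_coupled` multiplies gene BPS rates by `exp(0.5·z)` of
standardized log10(TPM) to give the correlation machinery a known signal
(the default coupling is 0 because the real-data finding is *no*
correlation); `trna_artifact` plants four identical 120-nt "tRNA-like"
genes, each with one 8 bp and one 5 bp G·C run, three HO and one CD, well
inside a replichore, labels a cohort of 86 tRNA genes at a 52:34 CD:HO
split, forces the hotspot genes into the top expression stratum, and raises
the run-indel scale to `mu0` = 2e-7 so each hotspot accrues tens of indels
at the default exposure (at the global default the hotspot expectation
would be ~0.2 indels per gene and the decomposition would be vacuous). The
cohort is drawn from genes free of runs ≥ 7 nt, since most real tRNAs lack
long runs and a natural long run inside a cohort gene would be its own
hotspot.

This scenario reproduces the *target-placement artifact*: the four
homologues accumulate statistically homogeneous counts (chi-square), yet
the naive HO/CD tRNA comparison shows a several-fold HO excess purely
because three of the four copies sit head-on. Removing the declared
hotspots collapses the ratio.

What the generator does *not* emulate: sequencing error, calling bias,
local sequence-context effects beyond homopolymer length, the chromosomal
"wave" pattern of rates, selection, and IS/rearrangement events. Passing
tests on synthetic data therefore demonstrate correctness of the analysis
machinery under the stated model, not fidelity of any particular biological
estimate.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive externally (GFF3); interval logic uses
  IRanges internally; wrapped genes are split into two segments for
  overlap queries and get circular midpoints.
* Zero-variance samples and constant predictors are flagged `degenerate`
  rather than producing NaN p-values; empty orientation classes yield
  flagged rows (mirroring "NA — no mutations" table entries), never
  errors.
* The −10 element caller is an explicit scored rule (hexamer on the
  promoter sense strand, 3′ base the mutated T, 3′ end 5–9 nt upstream of
  the TSS, ≥ 4/6 matches to TATAAT): by-eye element identification is not
  reproducible in software, so the rule and its thresholds are arguments.
* Mutations inside both a promoter window and a CDS are counted in both
  feature classes, since the two analyses are reported as separate tables.
* The highly-expressed threshold (mean + 1 SD of log10 TPM per phase) is
  computed over genes with TPM > 0 by default; an `include_zero` mode with
  a half-minimum pseudocount is exposed because the original criterion is
  ambiguous on this point.
* Zero-count rate classes get a Garwood upper limit of
  `qchisq(0.975, 2)/2` ≈ 3.69 events over the exposure.

## Problem sizes

The test-suite simulations use genomes of 10–100 kb with reduced line
counts and elevated per-site rates chosen so that expected counts per class
match the full-scale run (hundreds to thousands of events); the three
acceptance-style scenario runs use the full default conditions above. These
sizes give every stochastic check an expected signal at least ~4 sampling
SDs from its decision boundary, except the scenario checks that are
themselves calibrated null hypothesis tests (a homogeneity p-value is
uniform under the null, so any fixed threshold fails at its nominal rate
under reseeding).

## Known limitations

* Orientation is purely geometric; there is no fork-kinetics, R-loop, or
  collision mechanism in either the classifier or the generator.
* The Mann-Whitney exact path is bounded by the enumeration budget;
  beyond it the tie-corrected normal approximation is used even for
  moderately small samples.
* Promoter analysis uses annotation-supplied TSSs only; no promoter
  prediction, and no −35 element analysis.
* Real-data magnitudes (e.g. genome-scale length correlations around 0.8,
  histogram fits with R² near 1) require the corresponding deposited
  catalogs; the package reproduces such quantities structurally on
  synthetic data only.
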