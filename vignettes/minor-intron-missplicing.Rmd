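---
title: "Quantifying minor-intron mis-splicing: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying minor-intron mis-splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misplice)
```

# Scope and model

misplice measures, per annotated intron, how often that intron fails to be
spliced (retention) or is spliced through an unannotated junction
(alternative splicing), and whether those rates differ between two
replicated conditions. It is aimed at the minor-spliceosome setting — a
small set of U12-type introns expected to respond selectively to a
perturbation, against a large background of U2-type introns — but every
stage is class-agnostic; the minor/major label is an annotation column.

The unit of analysis is the *collapsed intron*: introns with identical
(chromosome, start, end, strand) across transcripts are one record carrying
the union of transcript ids. This mirrors how minor-intron databases count
introns, and avoids double-counting statistics for transcript variants that
share a splice event. Per-transcript ordinals are retained separately (the
`tx_map` attribute) because flanking-intron analysis is a per-transcript
notion.

## Read evidence

For an intron $[s, e)$ and minimum overhang $m$ (default 6 nt, applied
identically to boundary and junction reads so the two read classes have the
same number of eligible start positions):

* a **boundary read** has one aligned block covering $[s-m, s+m)$ (5') or
  $[e-m, e+m)$ (3') — evidence that the intron was present in the molecule;
* a **canonical junction read** has a between-block gap exactly $(s, e)$
  with both anchors at least $m$ long;
* an **aberrant junction read** has a gap sharing exactly one endpoint with
  $(s, e)$ (cryptic donor or acceptor), or a gap containing the intron and
  reaching past the genomic extremes of the flanking exons (exon skipping),
  sharing neither endpoint.

Counting is strand-agnostic and order-independent; multi-mapped reads are
counted as aligned, once per position, with no NH-based down-weighting.

## Statistics

With $B = (n_5 + n_3)/2$, $C$ canonical and $A$ aberrant counts:

$$\mathrm{MSI}_{ret} = 100\,\frac{B}{B + C}, \qquad
  \mathrm{MSI}_{AS} = 100\,\frac{A}{A + C}, \qquad
  \mathrm{IRratio} = \frac{d_{trim}}{d_{trim} + C}$$

where $d_{trim}$ is the mean per-base intron depth after discarding the
highest and lowest 5% of positions (an intentional approximation of
IRFinder's exclusion of outlier features, not a reimplementation of it).

Two deliberate choices here:

* **Denominator.** The field also quotes the mis-splicing index as the
  unbounded ratio *to* canonical reads ($100\,B/C$). Both are implemented
  (`mode = "fraction"` / `"literal"`); the bounded fraction is the default
  because a $[0, 100]$ statistic is what downstream delta thresholds and
  volcano-style displays assume. Whether a given published analysis
  averaged or summed the two boundary counts is typically unstated; the
  mode used is logged.
* **Mean, not sum, of the two boundaries.** A retained molecule spans both
  boundaries, so $n_5$ and $n_3$ are two looks at the same event. Taking
  their mean makes $B$ count retained molecules, and makes
  $E[\mathrm{MSI}_{ret}] = 100\rho$ under the simulator's sampling model
  (see below). The sum would double retention evidence relative to the
  junction denominator.

Degenerate inputs: all statistics are 0 when there is no evidence at all;
$B > 0$ with $C = 0$ gives 100 (fraction) or `Inf` (literal).

## Differential calling

Two pipelines are exposed, because the field uses two:

* **MSI path** (per-event calls): Welch's unequal-variance t-test on
  replicate MSI values, two-tailed, with an intron called significant at
  raw $p \le \alpha$ (default 0.05) *and* treated-minus-control
  $\Delta\mathrm{MSI} \ge$ `min_delta` (default 5 points). Whether the
  original analyses added an FDR correction or a delta cutoff on this path
  is not stated in the sources this design follows; defaults use raw p with
  the 5-point delta chosen to parallel the IR-ratio rule, and both knobs
  are parameters.
* **IR-ratio path** (retention-only, FDR-filtered): the Audic–Claverie
  exact test on boundary counts pooled per condition (library size = pooled
  locus depth — AC is a two-library test, so replicates are pooled),
  BH-adjusted across introns, then the four-rule filter: FDR ≤ 0.05, 100%
  intron coverage in every sample of the called condition, IRratio ≥ 10%
  there, and ≥ 5 points above the other condition; mirrored for the
  opposite direction.

Welch degeneracies are resolved explicitly because replicate MSI vectors of
all zeros are routine: both variances zero with equal means gives $p = 1$;
with unequal means, a machine-minimum p sentinel (flagged by infinite $t$)
rather than NaN.

The Audic–Claverie two-sided p is $2\min(P(Y \le y \mid x),\,
P(X \le x \mid y))$ capped at 1, the second term being the lower tail of the
swapped orientation. By an exact identity this equals the upper tail
$P(Y > y \mid x)$, i.e. the conventional $2\min$ form with the observed
point assigned to one tail only — chosen because it makes the test
symmetric in the two libraries, which the naive form is not. The
conditional law is evaluated as a negative binomial
($\mathrm{NB}(x+1,\ N_1/(N_1+N_2))$) for numerical stability; tests verify
it against direct summation of the published formula.

BH adjustment is the step-up rule with ties broken by a stable sort on
(p, input index), so outputs are reproducible to the bit.

## Gene categories and flanking analysis

A detected gene is `IR`, `AS`, `IR_and_AS` or `unaffected` according to its
significant events (optionally restricted to minor introns, which is how a
minor-intron-gene summary should be computed); genes with no detected
intron are `not_detected` and excluded from the detected denominator.
Flanking analysis pairs each retained minor intron with the major introns
at ordinal ±1 within each transcript and reports what fraction of all
retained major introns are minor-flanking.

## Reporting arithmetic

Percentages are computed against the *detected* totals and rounded half
away from zero (R's banker's rounding would mis-print x.x5 cases).
Published summaries of this kind round inconsistently (whole percents for
some counts, one or two decimals for others), so precision is a
presentation parameter, not a constant. The enrichment ratio and the
down/up "fold propensity" are taken on the *rounded* percentages — that is
how such numbers are quoted from printed tables (24/5.5 ≈ 4.4; the
unrounded alternative 138/32 ≈ 4.3 is a count ratio, not a percentage
ratio, and is documented here rather than computed).

# The synthetic world

The generator states one world and the tests live in it:

* one chromosome, non-overlapping genes (one transcript each), alternating
  strands, exons 80–160 nt, introns 150–300 nt — small enough to run in
  seconds, large enough that overhang and window rules bind;
* a configured fraction of genes (default 0.5) carries exactly **one**
  minor intron among majors, matching the biology where minor introns
  almost never co-occur in tandem; planted minor introns receive the
  canonical U12 GT-AG elements (5'ss `GTATCCTT`, branch point `TTCCTTAAC`
  ending 16 nt upstream of the 3'ss), majors plain `GT..AG`. Major introns
  that would accidentally score as minor under the default PWMs are
  re-randomized, so planted truth and motif-recoverable truth coincide;
* two conditions × 4 replicates (the replication level of the experiment
  this design emulates); per intron and sample
  $D \sim \mathrm{Poisson}(\lambda)$ events, each retained with
  probability ρ, aberrant with α, canonical otherwise. Defaults state a
  knockdown-like world: minor introns ρ = 0.15 treated / 0.02 control,
  α = 0.03/0.01; major introns ρ = 0.01, α = 0.005 in both conditions;
  λ = 200. These are fixed a priori as realistic magnitudes for a strong
  knockdown and are not tuned against any test outcome.
* a retained event emits one boundary read at *each* boundary. With
  one-read-per-event emission at a random boundary, $E[B] = D\rho/2$ and
  the mean-based MSI would estimate $\rho/(2 - \rho)$, not ρ; paired
  emission is what makes the estimator unbiased
  ($E[\mathrm{MSI}_{ret}] = 100\rho$ exactly at α = 0, and
  $100\rho/(1-\alpha)$ otherwise — the Monte-Carlo tolerance of ±2 points
  absorbs the small α cross-term at the defaults). It also yields
  $n_5 \approx n_3$, which is what makes the mean-vs-sum mode difference
  predictable in tests;
* each aberrant event uses one fixed cryptic junction per intron (a 3'
  splice site 50 nt into the transcript-downstream exon, sharing the
  canonical donor), giving deterministic AS truth;
* each retained event additionally lays one deterministic tiling set over
  the intron body, so intron coverage is complete whenever retention
  occurred and trimmed per-base depth tracks the retained-event count
  (IRratio lands near ρ, mildly above it because tiling sets overlap at
  the 3' end). A switch disables tiling to exercise the coverage gate;
* read placements are uniform over positions that satisfy the overhang
  rule *and* stay clear of neighbouring splice-site windows — without the
  second constraint, deep-anchor reads of one intron would inflate the
  boundary counts of adjacent introns and the truth table would not verify;
* one RNG stream per sample keyed by (seed, sample index): byte-identical
  outputs per seed, independent replicates.

What the simulator does **not** model: sequencing error and quality,
fragment-length distributions, PCR duplicates, expression differences
between genes, multi-isoform genes, overlapping genes, mappability. A green
test therefore establishes the correctness of the counting/statistical
machinery under clean alignments — not robustness to alignment artefacts,
which real data supply in abundance.

# Numerical and policy choices

* Coordinates 0-based half-open internally; GTF (1-based inclusive)
  converted on read; BED written natively.
* PWM scores are log-odds in bits (base 2); columns built from a consensus
  with 0.91/0.03 majority/minority mass and a 0.001 probability floor; the
  branch-point motif is scored at its best placement in a window 40 to 5 nt
  upstream of the 3' splice site; default thresholds sit at 50% of each
  motif's maximal score. No published matrices exist for the database being
  approximated, so the motif route is a configurable approximation and the
  list-lookup route is the faithful path; `N` bases score 0; an intron
  whose sequence is unavailable is classified major, with a message.
* The coverage predicate is literal: every intronic base covered by ≥ 1
  read, integer positions, half-open.
* Condition roles (treated/control) always come from the design object,
  never from column order.
* Intron classification with both a list and a motif model: list entries
  are forced minor, the rest fall through to the motif.

# Known limitations

* The IR ratio's intronic abundance is a 5% trimmed mean of per-base depth;
  IRFinder's actual exclusion of known features (snoRNAs, low-mappability
  segments) needs external masks that are out of scope here.
* The Audic–Claverie path pools replicates and therefore ignores
  between-replicate dispersion; the Welch path is the guard against
  overdispersed replicates.
* Gene categories treat any significant aberrant junction as AS without
  distinguishing cryptic-site use from exon skipping.
* The CLI is a thin convenience wrapper; programmatic use is the primary
  interface.
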