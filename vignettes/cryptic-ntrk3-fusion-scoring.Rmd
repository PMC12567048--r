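---
title: "Cryptic NTRK3 fusion scoring and fusion-negative NTRK expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cryptic NTRK3 fusion scoring and fusion-negative NTRK expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

NTRK1, NTRK2 and NTRK3 encode the TrkA/B/C receptor kinases. In
colorectal cancer their best-known oncogenic mode is a 3' kinase fusion,
but structurally confirmed NTRK fusions occur in under 1% of cases. Two
observations motivate a second look: NTRK expression varies widely in
fusion-negative tumours, and a gene can participate in a fusion that
structural-variant calling misses. A fusion joining a 5' partner promoter
to the NTRK3 kinase domain leaves a genomic footprint — partial deletion
of the 5' portion of NTRK3, often with reciprocal loss in the partner —
and a transcriptional footprint, overexpression of the retained 3'
portion. `cryptkin` operationalises the co-occurrence of these footprints
as a per-sample score and embeds it in a full cohort analysis:
preprocessing, association testing, deregulation regression and gene-set
enrichment.

## The fusion scores

For each sample the package computes two additive indicator sums from
copy-number segments and dichotomized expression:

$$\mathrm{NFS1} = \mathbb{1}[\text{NTRK3 deleted}] +
\mathbb{1}[\text{any 5' partner deleted}] +
\mathbb{1}[\text{NTRK3 expression high}] \in \{0,\dots,3\}$$

$$\mathrm{NFS2} = \mathbb{1}[\text{NTRK3 deleted}] +
\mathbb{1}[\text{NTRK3 expression high}] \in \{0,\dots,2\}$$

A sample is called cryptic-fusion positive at the cut scores NFS1 = 3 and
NFS2 = 2; by construction NFS1-high implies NFS2-high, and the
intermediate scores remain reportable strata for association analyses.
The additive reading (rather than a single boolean) is a deliberate
design choice: it lets downstream tests use score strata, and the high
flags recover the boolean definition exactly.

**Deletion calling.** A gene is deleted when at least one segment
overlaps its locus — closed 1-based intervals, any partial overlap —
with log2 segment mean at or below −0.3, a threshold deliberately more
stringent than the common −0.2 shallow-loss convention. When several
qualifying segments overlap, the minimum mean is reported as support: a
presence call should rest on the strongest evidence. An optional
`mode = "five_prime"` restricts evidence to segments overlapping the
strand-aware 5' half of the gene, for users who want the overlap itself
to carry the fusion interpretation; the default is any overlap, because
the score's definition needs only gene deletion and the stricter mode
discards real calls when segment boundaries are coarse.

**The 5' partner registry** (ETV6/TEL, TPM3, TPR, SQSTM1, EML4, MYH9,
MYO5A) ships with approximate GRCh38 gene spans. The coordinates are
package data, not dogma: every function accepts a user-supplied locus
table, and the registry's role is interval overlap, where approximate
spans are adequate.

## Preprocessing

Expression for each NTRK gene is winsorized (total trimmed mass 0.15 for
NTRK1/NTRK3 and 0.30 for NTRK2, split symmetrically over the tails),
min-max normalized to [0, 1] within each cohort, and the cohorts pooled
with a retained cohort indicator. Two conventions deserve comment:

- *Winsorization mass.* A phrase like "trimmed mean 15%" is ambiguous
  between 15% total and 15% per tail. The package defaults to total mass
  split symmetrically (7.5% per tail) — the standard winsorization that
  matches the stated purpose of outlier mitigation — and exposes
  `per_tail = TRUE` for the other reading.
- *Dichotomization.* "High" expression is value strictly above the
  pooled per-gene median, with ties going low (deterministic and
  documented); a config switch pools the median across all three genes
  instead. The per-gene split is the default because gene-specific
  high/low subsets must be non-degenerate for per-gene association
  analyses.

Quantiles use linear (type-7) interpolation throughout, so external
oracles can match bit-for-bit. One consequence, verified in the test
suite: winsorize-then-normalize is only *near*-idempotent. The tail
quantile of already-clamped data sits a hair inside the clamp bound
(interpolation between the clamped mass and the first interior order
statistic), so a second pass moves clamped values by a small amount
bounded by the gap between tail order statistics. Interior values are
exact fixed points.

Cohort bias is assessed per variable (one-way ANOVA for continuous,
chi-square for categorical) and the cohort indicator is carried as a
covariate into every regression rather than "corrected" out of the data.

## Statistical battery

- Spearman correlation is the Pearson correlation of mid-ranks; p-values
  use the t approximation, switching to exact permutation enumeration for
  n < 10 without ties.
- Chi-square association is the uncorrected Pearson statistic; cells with
  expected counts below 5 are flagged. The K-sample median test is a
  chi-square on above/below-pooled-median counts. At moderate n the
  uncorrected median test runs slightly anti-conservative and the
  Yates-corrected variant over-corrects; the package keeps the classical
  uncorrected form, whose level is within the acceptable band at the
  cohort sizes (hundreds of samples) where the pipeline applies it. The
  calibration experiment in the test suite therefore simulates at n = 400
  per replicate.
- Benjamini–Hochberg adjustment is applied within each analysis block
  (all clinical variables for one marker), mirroring per-figure FDR
  reporting; missing values are handled pairwise-complete with per-test
  denominators reported.
- The deregulation model is ordinary least squares of normalized
  expression on methylation beta, copy-number category step, fusion score
  (NTRK3 only) and the cohort indicator, with collinear columns dropped
  and reported. Logistic regression (Wald tests, separation detection)
  adjusts binary associations for cohort. Survival uses Kaplan–Meier
  curves and the 1-df log-rank test; Cox modelling is intentionally out
  of scope, so stage-adjusted survival claims are approximated by
  logistic adjustment on the event indicator — a documented deviation,
  not an equivalence.

## Enrichment engine

The ranked list uses the signal-to-noise metric
$(\mu_A - \mu_B)/(s_A + s_B)$ with each class SD floored at
$\max(0.2\,|\mu|,\ 0.2)$ — the canonical floor that keeps near-constant
genes from dominating — with ties broken lexicographically by symbol so
results are bit-reproducible. The running sum adds
$|r_i|^p / \sum_{hits}|r_j|^p$ at hits and subtracts $1/(N - N_h)$ at
misses; the enrichment score is the signed maximum deviation (positive
preferred on exact magnitude ties), and at $p = 0$ the statistic reduces
to the classic KS deviation between hit and miss CDFs (checked
numerically in the tests).

The permutation null (default 1000 permutations) permutes phenotype
labels and recomputes the entire ranking per permutation — preserving
gene–gene correlation — implemented with matrix products of the
expression matrix against a permuted indicator matrix so that cohort
scale (hundreds of samples, 1000 permutations) stays in seconds.
Phenotype permutation requires at least 7 samples per class; below that
the engine switches to gene-label permutation with a message. Nominal p
is the same-sign tail fraction; NES divides ES by the mean same-sign
permuted magnitude; FDR is the canonical sign-pooled ratio of permuted to
observed NES tail masses, capped at 1 and made monotone non-increasing in
|NES| within each sign class by a running minimum from the least extreme
set upward. When no same-sign permutation exists, nominal p is reported
as $1/(n_{perm}+1)$, i.e. below $1/n_{perm}$.

Over-representation is the one-sided Fisher exact test per gene set
against a fixed universe, BH-adjusted across sets; the odds ratio is the
sample cross-product ratio with Haldane's +0.5 correction when any cell
is zero, so the volcano coordinates (log2 OR, −log10 adjusted p) are
always finite. The raw Fisher OR with BH-adjusted p is a deliberate
labelling decision where upstream web platforms leave the statistic
unspecified.

The cross-cohort protocol — compile the leading edge found in one cohort
into a derived gene set and re-test it on the second cohort — is
supported by passing any character vector as a gene set and is exercised
in the tests.

## The synthetic cohort generator

The generator exists so that every downstream stage has a ground truth.
Its defaults are the package's study conditions, fixed once:

| parameter | default | meaning |
|---|---|---|
| `fusion_fraction` | 0.085 | per-sample probability of a planted cryptic fusion, matching the observed NFS2-high scale (~8–9%) |
| planted deletion | mean ~ U(−1.2, −0.35) | one segment over the strand-aware 5' half of NTRK3, plus a whole-gene deletion of one random partner |
| expression shift | +3 × `noise_sd` | added to NTRK3 in planted samples; guarantees ≥95% land above the pooled median at default noise |
| `cna_dose_effect` | 1 | expression units per CNA category step, applied to NTRK2 |
| `methylation_slope` | −3 | expression units per unit beta; betas ~ Beta(2, 2) |
| `noise_sd` | 1 | residual SD of raw expression |
| `subtype_proportions` | 0.60/0.25/0.15 | CIN/MSI/GS mix driving MSI status, location, BRAF/TP53, FGA, TMB, stage and survival |
| background segments | mean ~ N(0, 0.1) | one per relevant chromosome per sample; spurious deletion calls at −0.3 are rare but possible |

Two cohorts are generated with different background panel sizes (defaults
190 and, conventionally, 110 extra genes) to exercise per-cohort
enrichment with unequal panels. Gene-level CNA categories are drawn as a
partially independent layer from the segment data (coherence is enforced
only for planted fusions): in real cohorts GISTIC-style loss calls are
far more frequent than deletions at the stringent −0.3 segment threshold,
and the generator reproduces that decoupling rather than a fictional
1:1 correspondence.

What the generator does *not* emulate: realistic whole-genome segment
landscapes, mutation signatures, read-level noise, expression
correlation structure between background genes, or informative censoring.
Passing tests therefore demonstrate that the pipeline recovers planted
structure under its own assumptions — parameter recovery, calibration and
oracle equivalence — not that real colorectal cohorts satisfy those
assumptions.

## Numerical choices and degenerate inputs

- Constant vectors: min-max normalization maps to 0.5 (midpoint carries
  no ordering information); Spearman rho is reported missing rather than
  fabricated; winsorization is a no-op.
- A sample with no segments is a no-call (deleted = FALSE, missing
  support), never an error.
- Enrichment of a set equal to the whole universe is an error (the miss
  decrement is undefined), as is an empty intersection.
- All-zero hit weights at p = 1 fall back to unweighted increments.
- Exact magnitude ties of the running-sum extrema resolve positive; the
  test oracles treat the sign as ambiguous within floating-point
  tolerance because extended-precision accumulation can flip near-ties.
- Seeds: every stochastic stage takes an explicit seed and the pipeline
  refuses to run enrichment without one.

## Problem sizes used in the tests

The suite runs the end-to-end recovery at 800 pooled samples (the scale
of the pooled study the analysis mirrors), the brute-force deletion
oracle at 1000 random configurations, the enrichment oracle exhaustively
for universes up to 12 genes and sets up to size 4, the planted-signal
enrichment at 800 samples × 500 genes × 1000 permutations, and the type-I
calibration at 2000 null replicates of n = 400. These sizes were chosen
to make Monte Carlo error small relative to the acceptance bands while
keeping the default test run fast.

## Known limitations

- The NFS denominators depend on the join between segment, expression
  and clinical layers; the pipeline logs per-stage row counts precisely
  because real exports disagree about sample sets.
- The deletion caller is presence/absence per gene; it does not attempt
  breakpoint reconstruction or RNA-level fusion detection.
- The logistic approximation to stage-adjusted survival is a
  substitution, not an equivalent model.
- Enrichment FDR follows the sign-pooled permutation convention; it is
  not a BH adjustment of the nominal p-values and the two can disagree,
  particularly for small set collections.
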