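---
title: "Methods: thermodynamic models, information footprints and site calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermodynamic models, information footprints and site calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regland)
```

## Overview

regland analyzes massively parallel reporter assay (MPRA) data for
bacterial promoters: libraries of randomly mutagenized promoter windows,
coupled to barcoded reporters, sequenced at the DNA level (variant
abundance) and the RNA level (variant expression) across growth
conditions. The pipeline goes from barcode counts to per-base
mutual-information footprints, expression-shift matrices, automated
footprint classification, HMM binding-site calls with activator/repressor
signs, emergent −10 transcription-start-site detection, and clustering of
conditions by regulatory response. A statistical-mechanics simulator
provides ground-truth datasets so that every stage is testable without
sequencing data.

## Library geometry

A promoter window spans 115 bp upstream to 45 bp downstream of the
transcription start site (TSS), 160 bp in total. The arithmetic is exact
only if the TSS base is counted inside the downstream 45, so array index
$i$ (0-based) carries label $i - 115$ and label 0 is the TSS base.
Figures in the field often use a −/+1 convention with no 0; the package
reports 0-based labels and offers `position_labels(w, "plus1")` for
display. On the minus strand the genomic segment is reverse-complemented
first, so "upstream" always means upstream in transcription orientation.

Mutagenesis substitutes each position independently with probability 0.1
(so a 160-bp variant carries 16 mutations on average), drawing the
replacement uniformly from the three alternative bases. The substitution
distribution is not constrained by the assay design; uniform is the
minimal assumption and is the generator's fixed choice. The ordered pool
per promoter is 1500 mutated sequences plus the wild type — at study
scale, 119 promoters × 1501 = 178,619 ordered variants.

## The thermodynamic generator

Expression is modeled as the equilibrium probability that RNA polymerase
(RNAP) occupies the promoter. Each site $s$ (RNAP, activator, repressor)
contributes a Boltzmann factor

$$ q_s(v, c) \;=\; w_s \, a_s(c) \, e^{-\beta E_s(v)}, $$

where $w_s$ is the dimensionless wild-type weight (copy number over
non-specific genomic sites times $e^{-\beta\Delta\varepsilon}$),
$a_s(c) \in [0,1]$ the condition-dependent active fraction of the
transcription factor (an input, not a mechanistic allostery model), and
$E_s(v)$ the additive energy-matrix score of the variant's site sequence
in $k_BT$ units, zero for the wild type by convention. The expression
rate of variant $v$ in condition $c$ is

$$ r(v, c) \;=\;
   \frac{\sum_{S \ni \mathrm{RNAP}} \prod_{s \in S} q_s \prod \omega}
        {\sum_{S} \prod_{s \in S} q_s \prod \omega}, $$

summing over admissible occupancy microstates $S$: repressors exclude
RNAP (occlusion), overlapping sites cannot co-bind, and each occupied
activator co-bound with RNAP multiplies the state weight by its
cooperativity $\omega$. Rates therefore live in $[0,1]$, increasing a
repressor's activity can only decrease them, and increasing an
activator's $\omega$ can only increase the wild-type rate — all of which
are property-tested against an independent exhaustive state-sum oracle.

Sequencing is simulated per replicate: variant abundances are log-normal
(dispersion 0.5 on the natural-log scale — real pools are uneven), DNA
counts are multinomial in abundance, RNA counts multinomial in
abundance × rate, at depth $10^6$ each by default. Counts can be split
across barcodes multinomially when barcode-level tables are needed.

### The canonical worlds

Three architectures back the recovery benchmarks:

* **`sim_repressor_promoter()`** (SITES class): a σ70 core in which only
  the −35 and −10 hexamers are sequence-sensitive (1.5 $k_BT$ per
  mutation; the 17-bp spacer is read by length, not sequence), RNAP
  weight 1, plus a 15-bp occlusion repressor at labels $[-75, -60)$ with
  weight 100 — roughly 100-fold repression, the classic strong-repressor
  regime. An earlier draft used a 37-bp uniformly sensitive RNAP block;
  it was rejected on realism grounds, and because so wide a sensitive
  region inflates the rate variance across the library and with it the
  finite-library noise floor of the footprint (see below).
* **`sim_spike_promoter()`** (SPIKE class): the wild type carries
  `TATAAA` — a −10 element failing only its last key position; the
  energy matrix rewards the completing A→T with −9 $k_BT$ over a basal
  weight of $10^{-3}$. Only the ≈3% of variants with exactly that
  substitution express, producing an isolated single-position MI spike:
  a transcription start site one mutation away from existence.
* **`sim_inactive_promoter()`** (INACTIVE class): a flat energy matrix.
  Note that a merely *weak* but sequence-sensitive core would still
  footprint, because per-sample sequencing depth normalizes away the
  absolute expression level; inactivity in a normalized assay must mean
  sequence-independence, not a small rate.

### What the generator does not emulate

PCR amplification bias, growth-fitness coupling between expression and
abundance, plasmid/genome copy-number effects, barcode sequencing errors,
and indel synthesis errors are all absent. A green recovery test
establishes that the estimators and the segmentation recover the stated
world at the stated depth — not that they are robust to every artifact of
real libraries.

## Information footprints

At each position the library splits into wild-type and mutated variants;
each sequencing read is a DNA or an RNA read. The footprint is the mutual
information (in bits) of that 2×2 joint distribution,

$$ I_i \;=\; \sum_{m \in \{wt, mut\}} \sum_{s \in \{DNA, RNA\}}
   p(m, s) \log_2 \frac{p(m, s)}{p(m)\,p(s)}, $$

with cell masses estimated from the summed variant counts plus a
pseudocount $\alpha = 1$ per cell. $I_i$ is bounded by 1 bit, symmetric
under swapping the DNA/RNA labels, and (at $\alpha = 0$) invariant to
scaling all counts. Positions the library never mutates have a degenerate
marginal and report 0 bits. An alternative binned-expression estimator is
out of scope; the 2×2 count-level estimator is fully determined by the
count table and matches the Sort-Seq lineage of the assay.

Two noise sources set the background: read sampling (order $1/N$ in total
reads, negligible at $10^6$) and the finite library — a random subset of
~150 variants has, by chance, a slightly different mean rate than its
complement, so the background floor scales with the rate variance across
the library. This second term dominates at default settings and is the
reason the activity floor below is calibrated by simulation rather than
derived from read counts.

## Expression-shift matrices

Per-variant normalized expression is
$e_v = \frac{(rna_v + \alpha)/(R + \alpha V)}{(dna_v + \alpha)/(D + \alpha V)}$.
The shift of base $b$ at position $i$ is the relative change of the mean
$e$ among variants carrying $b$ there versus the wild-type base carriers:
$(\langle e \rangle_b - \langle e \rangle_{wt}) / \langle e \rangle_{wt}$.
Wild-type entries are 0 by construction; unobserved base/position pairs
are NA, not 0. The normalization (relative to the wild-type-base mean) is
a package convention — the assay literature shows such matrices without
fixing the scale. Positive shifts mean a mutation increases expression
(loss of repression), negative shifts mean loss of activation or of the
core promoter itself.

## Footprint classification

Footprints fall into three classes: extended binding sites (SITES), an
isolated single informative position (SPIKE — the emergent-TSS
signature), and no signal (INACTIVE). The statistic is the coefficient of
variation (population convention, to avoid the $n$ vs $n-1$ ambiguity)
of the footprint before and after Gaussian smoothing (σ = 3 bp, kernel
truncated at 4σ, edge-renormalized). Smoothing collapses the variation
of an isolated spike far more than that of a 15-bp site, so the ratio
cv_smooth/cv_raw separates the two; the default cut is 0.55, roughly
midway between the impulse response of the σ = 3 kernel (ratio ≈ 0.35 on
a quiet baseline) and boxcar-like sites (ratio ≳ 0.8).

The activity floor `t_active` is scale-bearing (CVs are scale-free, mean
MI is not): the default, 7.97 × 10⁻⁷ bits, is five times the median
per-position MI of a no-signal simulation at the default depth and
library size, frozen from `calibrate_t_active(seed = 100)`. Footprints
computed at very different depths need their own calibration. The exact
numeric thresholds used in the original study are not public; both
thresholds are therefore mandatory, surfaced parameters.

## Binding-site segmentation

SITES-class footprints are segmented by a two-state hidden Markov model
(background vs site) with Gaussian emissions, fitted by Baum–Welch
(log-likelihood non-decreasing per iteration, states ordered by emission
mean, deterministic initialization at the 25%/90% quantiles). The default
pipeline (`call_binding_sites()`) fits on `log(mi_smoothed + 1e-6)` with
the two state variances tied. Both choices were forced by a concrete
failure mode: on the natural scale with free variances, a promoter
carrying one strong and one weaker site lets the background state inflate
its variance and absorb the weaker site (observed on the canonical
repressor world in most seeds). On the log scale site intensities are
commensurate, and the tied-variance (homoscedastic) model splits states
by mean alone, which is exactly what segmentation wants. Natural-scale
and free-variance fits remain available.

Decoding uses the forward–backward posterior rather than Viterbi so that
per-position confidence is visible: site intervals are maximal runs with
posterior > 0.5, runs separated by ≤ 1 background bp are merged, and
runs shorter than 4 bp are dropped. Viterbi decoding is provided and is
tested against exhaustive path enumeration. Calls are signed by the
aggregate expression shift over the interval — positive = repressor-like,
negative = activator-like — and flagged when they intersect the core
promoter region (labels $[-40, 0]$), where "activator-like" usually means
the σ element itself. Smoothing widens true 15-bp sites by a few bp on
each side; called boundaries are accurate to about ±3 bp at default
depth, and interval Jaccard against ground truth is ≈ 0.6–0.75.

## Emergent −10 elements

The σ70 −10 consensus is TATAAT, and its first two bases and last base
(hexamer positions 1, 2, 6) dominate recognition. `scan_emergent_tss()`
reports every (mutation, hexamer) pair where the wild-type hexamer fails
at least one key position and the single substitution leaves all three
matching. Only the key-position rule is implemented — −35 and spacer
scoring belong to external promoter-strength models and are deliberately
out of scope, and the rule does not constrain the three non-key
positions. The predicted TSS is placed 7 bp downstream of the hexamer's
last base, the canonical σ70 spacing; this offset is a convention, not a
measurement, and is configurable. Candidates can be corroborated against
an expression-shift matrix from a condition where the native promoter is
silent: a candidate is "supported" when its mutation's shift exceeds
5 × the median absolute shift of the matrix.

## Replicate QC and condition clustering

Replicate agreement is the Pearson correlation of raw MI tracks;
experiments whose mean correlation to all others falls below 0.2 are
flagged for exclusion (deliberately conservative, and mandatory at the
CLI, since the original criterion is not public). Conditions are
clustered on 1 − Pearson distance with average linkage; correlations use
pairwise-complete columns with a minimum overlap of 50 positions, rows
with zero variance or insufficient overlap are dropped with a warning,
and ties break deterministically by row order. Raw (unsmoothed,
unnormalized) MI is the default input; per-promoter clustering can be
restricted to experiments classified SITES. Dendrograms serialize to
Newick through `ape`, with each node at half its merge height
(ultrametric convention), and round-trip losslessly.

## Numerical choices

* Pseudocount α = 1 per joint MI cell; recorded in outputs.
* Log base 2 throughout (bits).
* Gaussian smoothing σ = 3 bp, truncation 4σ, edge renormalization.
* HMM emission density floored at 10⁻³⁰⁰, sd floored at 10⁻⁶; EM stops
  when the log-likelihood gain drops below 10⁻⁶ or at 200 iterations.
* MI of degenerate marginals is defined as 0; zero-count positions at
  α = 0 return 0 with a warning.
* Hamming-based variant assignment (default ≤ 4 mismatches) replaces full
  alignment: oligo variants are fixed-length substitutions by design, so
  indel alignment is unnecessary; ties are left unassigned and
  out-of-range reads become NEW (synthesis-error) variants.

## Known limitations

Energy-matrix inference per site, TF identity assignment, motif-database
comparison and quantitative promoter-strength prediction are out of
scope. The MI estimator applies no finite-sample bias correction beyond
the pseudocount. The HMM assumes exactly two intensity regimes; promoters
with several well-separated site strengths may need the pooled fit or a
per-promoter rerun after masking the strongest site.
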