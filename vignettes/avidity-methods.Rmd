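---
title: "Models and methods behind aviseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aviseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aviseq)
```

`aviseq` implements the computational layer of avidity (polony) sequencing:
a ground-truthed simulator of per-cycle four-channel polony intensities and
binding-kinetics traces, the primary-analysis base caller, empirical phred
quality-table training, kinetic parameter fitting, and alignment-based
error profiling around homopolymers and k-mer contexts. This vignette is
the package's account of the underlying models, the numerical choices, and
what the test suite does and does not demonstrate.

## The polony intensity forward model

Each polony is a clonal cluster of concatemeric template copies. At cycle
$t$ (0-based), the strands of a polony are distributed over template
positions according to a state distribution $P_{t\cdot}$ driven by two
run-level probabilities: *lag* $p_{\mathrm{lag}}$ (a strand fails to
advance in a cycle) and *lead* $p_{\mathrm{lead}}$ (it advances two
positions). We model stepping as an i.i.d. trinomial walk,

$$P_{t+1,j} = p_{\mathrm{lag}} P_{t,j} + (1 - p_{\mathrm{lag}} -
p_{\mathrm{lead}}) P_{t,j-1} + p_{\mathrm{lead}} P_{t,j-2},
\qquad P_{0,\cdot} = \delta_0 .$$

This is the minimal stepping model consistent with run-level lag/lead
estimates and standard stepwise-sequencing practice; its virtue is that it
is exactly invertible, which gives every downstream correction a testable
oracle. Whether real instruments show per-cycle variation in these
probabilities is an open question; we adopt run-level scalars.

The pure signal of channel $b$ at cycle $t$ is
$\beta \, d^{\,t} \sum_j P_{t,j}\,[\mathrm{tmpl}_j = b]$, with per-polony
brightness $\beta$ (log-normal with mean 1 and a configurable coefficient
of variation) and a per-cycle multiplicative decay $d \in (0,1]$ (a knob
for testing normalization robustness; instrument decay behavior is not
modeled mechanistically). The observed channel vector is $M x + \epsilon$
with a $4\times4$ spectral cross-talk matrix $M$ and additive Gaussian
noise, clipped at zero. Channels are fixed as A, C, G, T $\to$ 0–3.

Templates default to the read length. With that choice the
cycles-by-cycles truncation of $P$ captures the entire support of the
signal, and phasing deconvolution below is *exact*; with longer templates
the final $\approx 2\,p_{\mathrm{lead}} T$ cycles carry truncation error.

## Base calling

The pipeline mirrors the forward model in reverse, in fixed order:

1. **Cross-talk inversion** solves $Mx = y$ per polony and cycle. Negative
   components (noise-induced) are clamped to zero *after* the solve so the
   algebra stays exact; clamp counts are recorded. A condition number above
   `1e6` warns, above `1e12` errors.
2. **Phasing estimation** is a grid search (defaults: both axes 0–0.02 in
   steps of $5\times10^{-4}$) on a deterministic, evenly spaced subsample
   of polonies. Each candidate $(p_{\mathrm{lag}}, p_{\mathrm{lead}})$ is
   scored by mean clarity $(A+1)/(B+1)$ computed on the *absolute values*
   of the trial-corrected intensities. The absolute value matters: scored
   on clamped values, the objective monotonically rewards overcorrection,
   because the inverse solve amplifies the top channel while the clamp
   hides the negative mass pushed into the others. With $|x|$ the negative
   mass lands in $B$ and the objective peaks at the true parameters (we
   verified exact recovery of $(0.01, 0.002)$ on noiseless simulations
   where the clamped variant ran to the grid corner).
3. **Phasing deconvolution** builds the truncated state matrix and solves
   the per-polony, per-channel linear system over cycles. If the truncated
   system's condition number exceeds `1e10` a ridge-regularized solve
   ($\lambda = 10^{-8}$, logged) is used instead.
4. **Normalization** maps, per channel and cycle, the 5th percentile of
   all values to 0 and the 95th percentile of *on-state* values (those
   where the channel is the per-polony maximum) to 1. Keying the on-state
   to the per-polony maximum is robust to skewed base composition, at the
   price that invariance to rescaling one channel is only approximate (the
   argmax set can shift for borderline polonies; observed deviations are
   below $10^{-2}$ on noisy simulations, against $O(1)$ without percentile
   anchoring). Percentiles are configurable; channels with fewer than two
   distinct values in a cycle are an error, not a silent pass-through.
5. **Calling** takes the channel argmax; ties within $10^{-9}$ break
   toward the lowest channel index and set a tie flag.

On noiseless phased, cross-talked simulations this pipeline makes zero
miscalls (2,000 polonies over 150 cycles in the acceptance suite) — that
end-to-end oracle, not any single unit test, is the base caller's primary
correctness argument.

## Quality model

Four predictors are computed per call: (1) the maximum normalized channel
intensity; (2) clarity $(A+1)/(B+1)$, with $A, B$ the top two normalized
intensities; (3) the run-level sum of the phasing and prephasing
estimates; (4) cohort clarity, the per-cycle median clarity of the 10% of
polonies with the lowest maximum intensity. Predictor 1 uses normalized
(not raw) intensity, and predictor 4 is computed per cycle across polonies
— both points the source procedure leaves open.

Training discretizes predictor space into equal-frequency bins (defaults
$8 \times 12 \times 4 \times 4$; constant predictors collapse to a single
bin), tabulates empirical error rates against truth labels with
$(e+1)/(n+2)$ pseudocount smoothing, and converts to
$Q = \mathrm{round}(-10 \log_{10} p)$, clamped to $[2, 45]$. The cap of 45
accommodates the observed ceiling of Q44 on real instruments while keeping
a finite score for error-free bins. Bins under `min_bin_count` merge into
their nearest clarity neighbor within the same slice of the other three
predictors. Truth labels come from the simulator (or from alignment
mismatches when alignments are supplied); external recalibration tooling
is out of scope. Assignment clamps out-of-range predictors to edge bins
and falls back to the nearest populated clarity bin for tuples removed by
merging.

Calibration assessment groups calls by predicted Q and reports the
mismatch-derived observed Q per group; error-free groups report the
resolution bound $-10\log_{10}(1/(n+1))$. On self-consistent simulations
(errors drawn at each call's assigned error probability) predicted and
observed Q agree within one unit for groups of $10^5$ calls — this
validates the bookkeeping, not the realism of any particular predictor
distribution.

## Kinetics

Three models cover the binding and incorporation measurements:

* **Single exponential**, rise $y = b + a(1 - e^{-kt})$ or decay
  $y = b + a e^{-kt}$, direction auto-detected from the trend. Rates are
  initialized by log-linearizing the early trace, with five jittered
  multi-starts (tolerance $10^{-10}$), fit by Levenberg–Marquardt
  least squares. Uncertainty comes from seeded residual-resampling
  bootstrap (95% percentile interval); traces statistically
  indistinguishable from flat return rate 0 with CI $(0, \infty)$ rather
  than a spurious fit.
* **Hyperbolic concentration dependence**
  $k_{\mathrm{obs}} = k_{\mathrm{pol}} c / (K_{d,\mathrm{app}} + c)$, fit
  by weighted least squares (inverse-variance when rate uncertainties are
  supplied). When every concentration saturates the curve the two
  parameters are nearly collinear; the fit then warns that parameters are
  weakly identified and falls back to a direct log-parameter minimization.
  The specificity constant $k_{\mathrm{pol}}/K_{d,\mathrm{app}}$ carries a
  first-order (delta-method) standard error.
* **Association/dissociation**: per-concentration exponential rates
  regressed through the origin give $k_{\mathrm{on}}$; a decay whose rate
  CI includes zero reports the detection-limited bound
  $k_{\mathrm{off}} \le \ln(1/(1-f))/w$ over window $w$, with detectable
  fractional drop $f = 0.05$ by default — the persistent-signal regime of
  multivalent avidites, in contrast to the fast monovalent decay
  (a fourfold drop by the start of imaging).

The recovery experiments in the acceptance script use the published fit
values as ground truth: quench-flow series at 8 concentrations spanning
0.25–16 µM (straddling $K_{d,\mathrm{app}} = 1.6$ µM) with 5%
multiplicative noise, and association traces at 1, 7.5 and 10 nM with
additive noise at 5% of plateau, 100 replicates each. The 0.5 pM
association condition used on-instrument is omitted from the recovery
sweep: at that concentration the pseudo-first-order rise is far too slow
to saturate within a realistic acquisition window.

## Error profiling

Homopolymer analysis consumes a slop-padded BED (5 bases per side are
trimmed; trimmed intervals are verified single-base runs when a reference
is given, and runs shorter than 12 are dropped by default), alignments
filtered of secondary, supplementary, unmapped and MAPQ-0 records, and a
reference. Each read is oriented 5′→3′ and split by reference projection
into pre-run, overlapping, and post-run segments; substitutions are
counted excluding N calls, soft-clipped bases, inserted bases and deletion
columns (nothing contributes to any denominator from an indel), and masked
positions. Reads with fewer than 5 aligned bases in either flank, or lying
entirely inside the run, are discarded with a reason. The per-offset
matrix stacks reads by positional offset: offset 0 is the first aligned
base after the run's 3′ end in read orientation, negative offsets precede
the run. Reads overlapping two runs are counted once per run.

k-mer analysis counts, for every context of size $k \in \{1,2,3\}$, the
instances — $k$ consecutive reference positions fully covered by aligned,
non-clipped, non-indel, non-masked read bases — and the fraction with at
least one mismatch. Contexts are keyed in read (sequencing) orientation by
default (the reference context of a reverse-strand read is
reverse-complemented); reference orientation is available by flag, since
either convention is defensible. Masking excludes known variant positions
from every count so true polymorphisms are not scored as errors. Platform
comparison counts contexts where the first table is strictly lowest, with
ties reported separately. Full counting replaces any subsampling at desk
scale; a `--sample-fraction` flag reproduces seeded subsampling.

Counting correctness is established by equality with an independent naive
per-base walker on small mixed-CIGAR fixtures, by segment additivity, and
by invariance under reverse-complementing an entire fixture.

## The synthetic-data generator and what passing means

The profiling fixture plants homopolymer runs in a random reference,
tiles reads across them on both strands, and injects independent per-base
substitutions at one rate before the run and another after it (read
orientation), emulating the elevated post-homopolymer error regime of
short-read chemistries; equal rates emulate the stable avidity regime.
Fixture alignments are primary, mapped, MAPQ-60 records, plus deliberately
injected secondary/supplementary/unmapped/MAPQ-0 records to exercise
filters. What the generator does *not* emulate: indel errors around the
run (real post-homopolymer errors are partly indels), position- and
quality-dependent error profiles, coverage biases, or alignment artifacts
— so recovering injected rates demonstrates counting correctness, not
platform-level realism.

Problem sizes in the test and acceptance suites are chosen to make the
statistical assertions sharp at interactive runtimes: 2,000 polonies ×
150 cycles for the zero-error oracle, 50,000 60-bp reads for rate
recovery (flank rates then carry binomial standard errors near
$4\times10^{-5}$), 100 replicates for kinetic parameter recovery, and
$\ge 10^5$ calls per bin for calibration checks. Recovery assertions on
single seeded draws use 3σ binomial bands; the bootstrap coverage check
runs 50 replicates and guards against gross undercoverage of the nominal
95% interval.

## Known limitations

* Phasing probabilities are run-level scalars; per-cycle estimates are not
  supported.
* The estimator grid search is $O(|\mathrm{grid}|)$ linear solves; very
  fine grids on long reads are slow, and estimation accuracy is bounded by
  the grid step.
* The normalization's scale invariance is approximate (see above).
* Dissociation bounds depend on the assumed detectable signal drop; the
  default 5% is a convention, not a measurement.
* The k-mer counter requires windows contiguous in both read and
  reference; contexts spanning an indel are not counted under either
  orientation convention.
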