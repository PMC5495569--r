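---
title: "Methods: simulating and analysing multi-session fear-extinction experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing multi-session fear-extinction experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fearext)
```

## The analysis chain

Auditory fear conditioning pairs a tone (or pip-train) CS with a footshock
US; extinction training presents the CS alone until freezing subsides.
Studies of *multi-session* extinction track, across five behavioural
stages (habituation, conditioning, and up to three extinction sessions plus
a retention test), how conditioned freezing, CS-evoked single-unit activity
in infralimbic cortex (IL) and basal amygdala (Ba), and synaptic efficacy in
amygdala circuits evolve.  `fearext` re-implements that analysis chain as a
tested pipeline over *synthetic* cohorts with planted ground truth, so every
stage — freezing scoring, unit quality control, peri-event z-scoring, neuron
typing, slice metrics, and the nonparametric statistics battery — can be
validated by parameter recovery rather than by eye.

The recall logic is central: the leading `retention_window` (default 5) CSs
of each session are scored as the *retention test* of the previous session's
learning, giving the epochs Hab, post-Cond, post-Ext1, post-Ext2 and
post-Ext3 (`recall_epochs()`).

## The synthetic cohort generator

`make_session_plan()` carries three protocol presets (in vivo recording,
slice, lesion) differing in US parameters (0.5 mA/0.5 s x 5, 1 mA/1 s x 3,
0.4 mA/1 s x 4 pairings), CS counts and inter-trial intervals.  In pip mode
each 30-s CS is a train of 27 pips at 0.9 Hz, so five CSs contribute 135
alignable events.  Ext2/Ext3 CS counts in the recording preset default to
20 (only Ext1's count is fixed by the protocol; the value is configurable).

**Spike trains.** `simulate_unit()` draws an inhomogeneous Poisson process
by thinning a piecewise-constant rate: `baseline_rate_hz` (default 5 Hz,
typical for amygdala/mPFC principal cells) everywhere, elevated to the
session's evoked rate inside `[latency, latency + duration]` after each
aligned event.  Phenotypes map onto sessions so that the generator is the
exact mirror of the classifier: a *fear* neuron is elevated throughout Ext1
(whose leading CSs form the post-Cond recall epoch), an *extinction* neuron
throughout Ext2 (post-Ext1), a *session-selective* neuron in one chosen
session.  Default response onsets are the reported dialect means (43.33 ms
pip-aligned, 211.1 ms tone-aligned); default modulation is 10x.

**Freezing.** Human-scored freezing has no intrinsic sampling rate; traces
are laid on a 0.1-s grid, which makes the 2-s bout criterion exact.  Each
CS's scored target is a truncated-normal draw around a per-session linear
trajectory, realised as a single contiguous immobility bout placed uniformly
in the CS window.  A single bout (rather than fragmented bouts) keeps the
expected scored value equal to the target under the bout-length rule;
targets below the 2-s criterion score zero by construction.  Two trajectory
profiles (successful / poor recall) differ only after conditioning.

**Waveforms.** Snippets are a fixed biphasic template plus Gaussian noise;
between sessions the template drifts along a fixed unit-specific direction.
`drifted_templates()` constructs template sequences with an *exact* planted
consecutive-session correlation (`r * previous + sqrt(1-r^2) * orthogonal`
in standardised space), so the 0.97 stability gate can be exercised from
both sides.

**Patch-clamp sweeps.** `simulate_slice_data()` emits four families with
recoverable planted values: paired 50-ms-interval EPSCs (ratio `ppr`),
dual-holding-potential sweeps (AMPA peak at -70 mV; slow NMDA-like current
at +50 mV scaled so the sample 50 ms post-stimulus encodes `ampa_nmda`),
an intensity series with a planted linear input-output slope, and a
continuous trace with Poisson-timed inward miniature events.  Synaptic
kernels are bi-exponential (rise 1 ms, decay 8 ms; NMDA 3/80 ms),
re-normalised to their on-grid maximum, and each paired pulse's kernel is
truncated at the next stimulus — an idealisation that makes the noiseless
round trip exact (a free decay tail would bias the second peak by up to
~0.3%).

**Determinism.** One experiment seed fans out to per-rat/per-unit/per-stage
streams by string hashing (`substream_seed()`), so adding a unit never
perturbs another's data, and a fixed `(config, seed)` reproduces every
output byte for byte (the pipeline tests compare bundle checksums).

What the generator does *not* emulate: biophysical membrane dynamics, raw
extracellular voltage or LFPs, within-session response dynamics (a fear
neuron stays elevated for all of Ext1 rather than extinguishing within the
session), bursting/refractoriness, electrode drift other than template
translation, and correlated noise across units.  Passing recovery tests
therefore certify the *analysis* logic, not realism of amygdala dynamics.

## Behaviour

`score_freezing()` sums maximal immobility runs of at least `min_bout_s`
(default 2 s) inside the CS window and normalises to CS duration.
Extinction-recall groups are split at the *upper bound of the two-sided 99%
t-interval* of the across-rat mean of post-Ext1 freezing
(`mean + t_{0.995, n-1} * sd / sqrt(n)`); a rat is a successful recaller iff
its freezing lies strictly below the bound.  Two interpretive choices are
deliberate: the interval is taken across rats (not across CS trials), and
"lower than" is strict — with zero variance every rat sits at the bound and
is classed as a poor recaller.

## Unit quality control

Isolation is graded with the scatter-matrix ratio J3 and the Davies-Bouldin
index over snippets projected onto the top-2 principal components of the
pooled covariance:

$$J_1 = \sum_k \sum_{x \in k} \lVert x - m_k \rVert^2,\qquad
  J_2 = \sum_k n_k \lVert m_k - m \rVert^2,\qquad J_3 = J_2/J_1,$$

$$DB = \frac{1}{K}\sum_k \max_{j \neq k}
  \frac{s_k + s_j}{\lVert m_k - m_j \rVert},$$

with $s_k$ the mean within-cluster distance to the centroid.  High J3 / low
DB is a compact, well-separated unit.  Degenerate geometries are explicit:
zero within-scatter returns the `Inf` sentinel for J3; coincident centroids
flag DB as undefined rather than yielding a silent `NaN`.  No numeric J3/DB
acceptance cut is imposed by default (none is standard); the default gate is
cross-session stability — Pearson correlation of consecutive-session mean
templates, stable iff min r strictly exceeds 0.97.

## Peri-event z-scoring

Two dialects are implemented, average-then-z in both (the per-trial counts
are averaged first and the z-transform is applied to the trial-averaged
histogram; a pooled per-trial alternative can be built from the returned
baseline statistics):

* **tone dialect** — 100-ms bins; baseline mean and *sample* SD (n-1) from
  the 4 pre-tone bins; response statistic is the mean z over 0-400 ms.
* **pip dialect** — 20-ms bins aligned to every pip of the trial set (135
  pips for 5 CSs); baseline from the 25 bins covering the 500 ms preceding
  each tone onset; response statistic over 0-100 ms.

Bins are half-open `[left, right)`; the 0-ms edge belongs to the first
post-onset bin, and window statistics use only fully contained bins.  A zero
baseline SD sets a degeneracy flag and masks z as `NA` — never
epsilon-inflated, which would quietly manufacture responses in silent units.

A known limitation follows from the 4-bin baseline of the tone dialect: the
SD estimate has 3 degrees of freedom, and with small Poisson counts it is
occasionally far too small, inflating *every* bin of that cell's histogram.
This is a property of the dialect, not of the implementation; the latency
analysis below works on cell-averaged histograms for exactly this reason.

## Responsiveness, typing, latency

`cs_responsive_test()` is a two-sided unpaired Student t-test of per-event
spike counts in the response window against counts from an equal-duration
window immediately pre-onset (rate-matched baseline).  The response window
follows the dialect: 100 ms after each pip, 400 ms after tone onset (the
tone dialect judges CS responses over 0-400 ms).  Under null simulation the
test rejects at its nominal level (the suite checks 0.05 +/- 0.02 over
10,000 units).

Typing adds a *strength* criterion on top of significance: an epoch counts
for classification only when the t-test rejects **and** the mean windowed z
reaches `strength_z` (default 1.5) in magnitude.  The rationale is a
variance argument: the null mean-window z has SD near `1/sqrt(n_bins)`
(~0.45 in the pip dialect), so 1.5 is a >3-sigma gate that suppresses the
~5%-per-epoch false flags which would otherwise corrupt the multi-epoch
fear pattern (four required absences at 0.95 each cap fear recovery near
81%), while genuine 10x responses sit far above it (mean z ~ 3).  The
fear/extinction phenotypes are defined by *strong* excitatory responses:

* **fear** — strong excitatory at post-Cond, nothing strong in Hab or any
  post-extinction epoch;
* **extinction** — strong excitatory at post-Ext1, nothing strong in Hab or
  post-Cond;
* **session-selective** — strong in exactly one epoch, not matching the
  above;
* **non-responsive** otherwise.

Requiring absence in Hab is an interpretive choice (exemplar cells are
habituation-silent).  With the default generator the suite recovers planted
fear and extinction labels in over 90% of 200 seeds, and the per-test flag
retains its nominal null rate.

`response_latency()` reports the left edge of the first bin at or above
`criterion_z` (default 3) in the search window; `min_consecutive` optionally
requires a sustained run of bins, a standard hardening against single-bin
noise.  Latencies inherit bin granularity: an onset planted at 211.1 ms
reads as 200 ms in 100-ms bins, 43.33 ms as 40 ms in 20-ms bins.  Cohort
latency estimates are taken from the across-cell averaged z-histogram,
which suppresses the tone dialect's per-cell baseline-SD noise.

`cohort_summary()` reports counts and percentages (2 decimals) of each type
against two denominators: all recorded units and all CS-responsive units.

## Slice metrics

* `paired_pulse_ratio()` — sweeps averaged, pre-stimulus mean subtracted;
  ratio of absolute peaks, each searched from its stimulus to the next
  stimulus (or sweep end).  A first peak at or below the noise floor
  (default 5 pA) yields an undefined ratio with a reason code.
* `ampa_nmda_ratio()` — absolute peak of the averaged -70 mV trace over the
  averaged +50 mV current exactly 50 ms post-stimulus (nearest sample).
  A sub-noise-floor denominator is undefined-with-reason, never infinite.
* `detect_minis()` — median-baseline threshold crossings of the deflection
  (inward polarity by default) with a refractory `min_interval_ms` and
  hysteresis re-arming at half threshold (suppresses decay-tail
  retriggers); amplitudes are peak deflections; cumulative amplitude and
  inter-event-interval vectors are emitted for KS comparisons.  Frequency
  summaries are per-cell; interval distributions cover the per-interval
  reading of cumulative frequency plots.
* `io_slope()` — ordinary least squares of mean absolute EPSC amplitude on
  stimulus intensity, free intercept, slope in pA/uA.
* `sweep_qc()` — a cell is discarded iff series resistance changes by
  strictly more than 20% from its first reading at any point.

All ratios are invariant under uniform gain scaling; amplitudes are
reported as magnitudes with raw signs preserved in the sweeps.  The
paired-pulse interval defaults to 50 ms (a protocol constant of the
generator, configurable).

## The statistics battery

All tests are two-sided and return statistic, df, p and group sizes.

* **Mann-Whitney U** — midranks; reported `U = min(U_x, U_y)`.  Exact p
  (equivalent to enumerating all rank assignments, validated exhaustively
  for n1, n2 <= 8) when `max(n) <= 10` without ties, else a tie-corrected
  normal approximation with continuity correction.
* **Kruskal-Wallis H** — tie-corrected; chi-square reference with k-1 df.
* **Friedman** — within-block midranks,
  $\chi^2_F = \frac{12}{nk(k+1)}\sum_j R_j^2 - 3n(k+1)$, chi-square with
  k-1 df; blocks are cells (or rats), treatments are recall epochs.
* **Dunn post-hoc** — pairwise rank z-statistics with the design-matched
  variance (pooled-rank with tie correction for independent groups;
  `n k (k+1)/6` on Friedman rank sums for repeated measures), screened by
  the **two-stage Benjamini-Krieger-Yekutieli** step-up: BH at
  `q' = q/(1+q)`, re-estimate `m0 = m - r1`, then BH at `q' m / m0`
  (all-or-none short circuits at the boundary cases).
* **Repeated-measures one-way ANOVA** — subject effect removed by the SS
  decomposition; `F = MS_sessions/MS_error`, df `(k-1, (k-1)(n-1))`; zero
  error variance returns an explicit undefined-F contract.
* **Newman-Keuls** — step-down studentized-range procedure over ordered
  means with stretch-dependent critical values from `ptukey` (computed
  numerically, no embedded tables); pairs nested in a non-significant
  stretch inherit non-significance untested.
* **Kolmogorov-Smirnov** — EDF supremum over the pooled support; asymptotic
  Kolmogorov p with the small-sample-corrected effective size
  `(sqrt(ne) + 0.12 + 0.11/sqrt(ne)) D`.
* **Upper confidence bound** — `mean + t_{(1+level)/2, n-1} sd/sqrt(n)`,
  shared by the recall-group split.

Each test is cross-checked in the suite against an independent oracle
(enumeration, `wilcox.test`, `kruskal.test`, `friedman.test`,
`aov + Error()`, literal two-stage BH via `p.adjust`, `qtukey`, `ks.test`),
and the battery's empirical type-I error under null simulation is verified
to sit in [0.03, 0.07] at alpha = 0.05.

## Problem sizes and reproducibility

The test suite and the acceptance script size their simulations to be
informative yet quick: 10,000 null units for calibration, 200 seeds per
phenotype for recovery, the full 130-unit / 27-rat basal-amygdala cohort and
the 19-rat behavioural cohort once each, exhaustive Mann-Whitney enumeration
to n = 8, and 20-sweep / 120-s slice sets.  `scripts/acceptance.R --seed S
--out f.json` recomputes the headline quantities from scratch; every random
stream derives from the one `--seed`.

## Known limitations

Beyond the generator simplifications above: the classifier's strength gate
trades a small loss of sensitivity to weak (sub-1.5 z) responses for
multi-epoch specificity; exact Mann-Whitney p-values are unavailable under
ties (the tie-corrected approximation is used); the Friedman statistic uses
the plain midrank formula without a tie-correction factor; Newman-Keuls
controls error only per stretch (its usual caveat); and per-cell latency
estimates in the tone dialect remain noisy at low firing rates — use the
averaged-histogram latency for population statements.
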