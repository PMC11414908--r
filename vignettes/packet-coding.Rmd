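---
title: "Analyzing packet information encoding in EOD-aligned spike trains"
author: "packetcode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing packet information encoding in EOD-aligned spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(packetcode)
```

## The scientific problem

Pulse-type weakly electric fish sample their surroundings with discrete
electric organ discharges (EODs), emitted roughly every 44.5 ms.  Each EOD
generates an electrosensory image that neurons of the electrosensory lobe
(EL) re-encode within the following inter-EOD interval.  These
"phase-preferring" units fire sparsely — on the order of 0.35 spikes per
EOD — but at stereotyped latencies after the discharge, so a unit's response
to one EOD can be summarized by two variables: how many spikes it fires
(spike count) and when it fires them (the post-EOD spike-timing
distribution).  Together the two variables form a *packet* of information
per EOD.

`packetcode` implements the analysis chain for this kind of data:

1. **Event handling** (`readEvents`, `applyBlanking`,
   `minimumDataFilter`): timestamp series for EODs and sorted units, with
   the EOD artifact blanked in a closed [-2.5, +2.5] ms window around every
   discharge, and a minimum-data rule (at least 500 EODs and 100 spikes per
   unit).
2. **EOD-aligned histogramming** (`crosscorrHistogram`,
   `postEODHistogram`, `periEODProfile`): 1 ms bins centered on integer
   millisecond latencies; cross-correlograms over -200..+300 ms in percent
   per EOD; post-EOD histograms over 2.5–40 ms normalized to unit sum so
   they isolate the timing pattern.
3. **Unit-type classification** (`classifyUnits` and friends): Ward
   clustering of the Euclidean distances between unit-sum post-EOD
   histograms, a Davies-Bouldin curve over k = 2..12, cluster-count
   selection, percentile profiles per cluster, and pairwise two-sample
   Kolmogorov-Smirnov tests with Holm-Bonferroni correction.
4. **Step-response analysis** (`alignOrdinal`, `friedmanSteady`,
   `friedmanStep`, `triadDistributions`, `jsd`, `jsdBattery`,
   `jsdCountCorrelation`): ordinal-EOD alignment around stimulus steps
   (EOD\_-25..EOD\_+25), replicated Friedman tests on spike counts, and a
   Jensen-Shannon divergence battery on triad-pooled timing distributions
   with one-sided sign-rank inference.
5. **Receptive-field profiles** (`positionRateProfile`,
   `directionContrast`): spikes-per-EOD along a moving-object trajectory in
   1 mm bins and a direction-asymmetry index.
6. **A calibrated simulator** (`generateEODTrain`, `generateUnitSpikes`,
   `generatePopulation`, `generateStepExperiment`,
   `generateMovingObjectExperiment`): six firing-pattern archetypes with
   known ground truth, used throughout the test suite.

## The generative model

The simulator is phenomenological: it reproduces the statistical structure
of EOD-locked spike trains, not membrane biophysics.

**EOD train.**  Inter-EOD intervals are gamma-renewal with mean 44.5 ms
(22.5 EOD/s) and shape 50, giving the small interval jitter (cv about 0.14)
seen in resting discharge rasters.  Only the mean is an empirical constant;
the shape is exposed as a parameter.

**Within-interval spiking.**  For each inter-EOD interval the expected
spike count is the summed weight of the archetype's Gaussian latency modes
plus a uniform baseline mass, multiplied by the stimulus count gain.
Counts are Poisson, truncated at 4 spikes per interval; latencies are drawn
from the weighted mode mixture (plus the uniform baseline), thinned by
inhibition windows (each candidate spike inside a window is deleted with
probability `depth`), and clipped so that no spike falls within 2.5 ms of
either flanking EOD — the generator respects the same blanking convention
as the analyses, so generation and analysis windows agree.  Spike-count
dispersion is not reported for these neurons; Poisson is the maximum-
entropy choice and is flagged here as an assumption.

**Bursts.**  A surviving primary spike is expanded, with archetype-specific
probability, into a doublet or triplet with a 3.5–4 ms intra-burst
interval.  Bursting matters for the joint calibration (below).

**Stimulus steps.**  At a step the count gain jumps to `countGainUp` (or
`countGainDown`) and decays exponentially back to 1 with an e-fold constant
of 8 EODs — the phasic-then-adapting response profile; the time constant is
a modeling choice, as only the qualitative shape is constrained.  A
configurable `timingShift` moves the mode latencies while the stimulus sits
at its high level, providing a pure spike-timing channel for validation
studies.  The EOD rhythm itself stays stationary: the transient shortening
of inter-EOD intervals after a novel stimulus (the novelty response) is a
behavioral phenomenon outside this package's scope.

**Receptive fields.**  For moving objects the count gain follows a
Mexican-hat profile of object position (difference of two Gaussians, mm
units), clipped at zero; when the motion direction matches a configured
sign, positions the object has already passed are additionally suppressed —
a minimal model of the direction asymmetry seen in sweep experiments.

**The six archetypes.**  `defaultArchetypes()` encodes sharp monomodal
(silenced early, sharp 10–12 ms peak, bursts of 2–3 spikes), broad
monomodal (broad mode near 24 ms), bimodal (sharp ~10.5 ms plus broad
~17.5 ms), trimodal (additional sharp 5 ms spike), mildly inhibited
(firing immediately after the EOD and late in the interval, with dips near
5 and 10 ms) and deeply inhibited (deep suppression to ~22 ms with a slow
late recovery).  Center-on types (broad monomodal, bimodal, trimodal)
increase their counts at stimulus increases; center-off types (the other
three) decrease them.

## Calibration of the default population

Two empirical constants anchor the baseline statistics: a grand mean of
0.35 spikes/EOD and a grand mean inter-spike interval of 83.9 ms across
units.  These two are not jointly attainable under the plain per-unit mean
ISI: for a stationary unit the mean ISI is approximately the recording
span divided by the spike count, i.e. 44.5/rate ms, and averaging over
units can only push that above 44.5/0.35 ≈ 127 ms (Jensen's inequality).
The package therefore defines the ISI summary over intervals up to a
300 ms horizon — the same horizon as the cross-correlation analysis — so
that long silent stretches between response packets do not enter the
interval statistics.  Under this definition the short intra-burst
intervals of the doublet/triplet structure pull the windowed mean down,
and both constants are reproduced simultaneously: per-type weights were
solved iteratively so that every archetype fires ~0.35 spikes/EOD, and the
default burst probabilities place the windowed grand mean ISI at ~83.5 ms.
`baselineSummary()` reports both statistics.

Unit-to-unit variability is modeled by jittering each unit's mode
latencies (sd 0.2 ms) and log-scaling widths, weights and baseline (sd
0.07).  These values keep within-type histogram variability near the
multinomial sampling floor of a 500-EOD recording while units remain
distinguishable individuals; much larger jitter blurs the type boundaries
that the classification stage is designed to recover.

## Numerical and inferential choices

**Bin convention.**  Histogram bin k covers [k - 0.5, k + 0.5) ms — bin
zero is centered on the EOD — so the 2.5–40 ms post-EOD window comprises
the 38 bins centered on 3..40 ms, half-open at 40 ms.  Spikes contribute
to the windows of every EOD within the cross-correlation span (the sliding
construction); for ordinal and receptive-field analyses a spike belongs to
its preceding EOD.

**Blanking.**  The [-2.5, +2.5] ms window is treated as closed (endpoint
spikes removed); blanking is idempotent and never creates spikes, and the
brute-force pair-scan oracle in the test suite pins the fast
implementation down exactly.

**Cluster-count selection.**  The Davies-Bouldin curve is computed in the
textbook centroid form (per-cluster mean distance to centroid, centroid
separation) and, optionally, as the looser ratio of the minimal
inter-cluster to maximal intra-cluster distance (`variant = "extrema"`),
since published descriptions sometimes use the latter.  The two variants
have different shapes in k: the extrema ratio falls hyperbolically, and
for such monotone curves `selectKElbow()` applies the maximal-second-
difference elbow rule; the textbook index penalizes over-partitioning and
is V-shaped with an interior optimum, which `selectKElbow()` reads the
canonical way, at the curve minimum.  On simulated cohorts the raw second
difference of a V-shaped curve is dominated by sampling noise at large k,
which is why the regime split, rather than a single elbow rule, is the
default.  A manual k override is available throughout.

**Replicated Friedman test.**  Spike-count contrasts use blocks = units,
treatments = conditions, and replicated observations per cell (25 EODs for
the steady-state contrast, 3 ordinal means for the step contrast).  All
t·r observations of a block are ranked together (average ranks on ties)
and the treatment rank sums are tested with their exact within-block
permutation covariance, referred to chi-squared with t - 1 degrees of
freedom.  With one replicate and no ties this is exactly the classical
Friedman statistic.  A literal "aggregate, then re-rank 1..t per block"
reduction was rejected because at two treatments it collapses to a sign
test and mis-holds its level at small unit counts; the moment-based form
is calibrated to nominal type-I error under the stationary generator
(verified at 5000 replicates in the test suite).  A within-block
permutation p-value is available for small designs.

**Jensen-Shannon divergence.**  `jsd()` is the exact plug-in formula
H((p+q)/2) - (H(p)+H(q))/2 in bits (base-2, 0·log0 = 0, equal mixture
weights, no pseudocounts).  For *inference* the plug-in estimator's
upward small-sample bias matters: the long-control pool (22 ordinals) is
about seven times larger than a triad pool, and the count gain scales the
post-step pool, so plug-in divergences of differently-sized samples carry
different biases and the paired contrast JSD(pre, post) >
JSD(control, pre) would reject under a timing-invariant null.
`jsdBattery()` and `jsdCountCorrelation()` therefore equalize sample
sizes by rarefaction — within each step direction all triads of a unit are
subsampled to the smallest triad count, averaging over 20 draws — which
restores the nominal level of the sign-rank contrast while keeping power
near 1 for a 5 ms latency shift.  Equalization consumes the RNG; set a
seed for exact reproducibility, or pass `equalize = FALSE` for the raw
plug-in divergences.

**Sign-rank, rank-sum, Kruskal-Wallis, KS.**  Zero paired differences are
dropped before the sign-rank test; exact null distributions are used for
n ≤ 25 without ties, normal approximation with continuity correction
otherwise.  Ties in rank tests take average ranks.  Holm-Bonferroni is the
step-down procedure throughout, with decisions at strict inequality.

**Degenerate inputs.**  Units with no in-window spikes yield `NULL`
post-EOD histograms and are excluded upstream; empty triads exclude a unit
from the divergence battery (logged in the result); all-tied Friedman
tables and zero-variance correlations are flagged rather than silently
propagated.

## What the synthetic cohort does and does not show

The simulator reproduces: renewal EOD timing; sparse EOD-locked firing
with archetype-specific multimodal latency distributions; inhibition
windows; doublet/triplet bursts; phasic, adapting count responses to
three-fold stimulus steps in both directions; latency shifts under strong
stimuli; and Mexican-hat receptive-field modulation with direction
asymmetry.  Passing tests on this cohort demonstrate that the analysis
chain recovers known ground truth under realistic sample sizes (102 units,
500 EODs each, 16+ step trials).

It does not emulate: electrode drift or sorting errors; cross-unit
correlations within a fish; the EOD-rate novelty response; slow
nonstationarities (season, serotonergic state); or true receptive-field
geometry beyond a 1-D trajectory.  Agreement on synthetic data therefore
validates the *computations*, not the biological conclusions one might
draw from any particular recording.

## Problem sizes used in the validation suite

The test suite simulates cohorts of 102 units (17 per archetype, 500 EODs
each) for classification checks over 20 seeds; step experiments with 8
units x 16–48 trials per condition; and 5000-replicate null calibrations
for each statistical test, with the tolerances stated alongside each
check.  The full pipeline (`runPipeline`) on the default cohort completes
in well under ten minutes on one CPU.

## A worked mini-example

```{r example, eval = FALSE}
set.seed(1)
pop <- generatePopulation(nPerType = 17, nEods = 500, seed = 1)
for (id in names(pop$units))
  pop$units[[id]]$spikes <- applyBlanking(pop$units[[id]]$spikes,
                                          pop$units[[id]]$eods)
post <- Filter(Negate(is.null), lapply(pop$units, function(u)
  postEODHistogram(u$spikes, u$eods)))
cr <- classifyUnits(post)
chosenK(cr)                      # 6
baselineSummary(pop)$grand       # ~0.35 spikes/EOD, ~84 ms windowed ISI
```
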