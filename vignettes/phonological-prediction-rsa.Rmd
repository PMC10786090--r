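---
title: "Testing pre-stimulus phonological similarity coding with ERP RSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing pre-stimulus phonological similarity coding with ERP RSA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

When a reader processes a highly predictable phrase — the canonical case
being a four-character Chinese idiom whose final two characters are almost
fully determined by the first two — does the brain pre-activate the
*phonological form* of the upcoming material? Representational similarity
analysis (RSA) offers a direct test. Items are organized into sets that
share the syllable of the third character (the first character of the
idiom-final part): any two items of a set form a *within-pair* (shared
syllable, onset + rime + tone all identical), and items from different
sets form *between-pairs*. If phonology is pre-activated, the neural
activity patterns evoked by two within-pair items should already be more
similar to each other than between-pair patterns *before* the shared
syllable appears on screen.

`phonrsa` implements this analysis end to end for epoched, multichannel
EEG: stimulus handling and pair enumeration, baseline correction and
amplitude-based trial rejection, two complementary RSA flavours with
cluster-based permutation inference, a matched-subsample control, a
pair-level regression relating neural to stimulus similarity, and a
synthetic-EEG generator with known representational ground truth that
makes every stage testable without access to any recordings.

## Design and data model

The reference design has 100 items in 10 sets of 10. Each set contributes
`choose(10, 2) = 45` within-pairs (450 in total); the remaining
`choose(100, 2) - 450 = 4500` cross-set pairs are between-pairs. Epochs
span -1,400 to +600 ms around the onset of the idiom-final display at a
250 Hz sampling rate and 62 scalp channels: baseline -1,400..-1,100 ms,
idiom-initial display -1,100..-500 ms, inter-display interval -500..0 ms,
idiom-final 0..600 ms.

Epochs live in an `epoch_set`: a trials x channels x samples array
(microvolts) with a uniform millisecond time grid (0 = idiom-final onset),
channel labels with unit-sphere head coordinates, and a per-trial
participant/item table. On disk the container is a directory with a
little-endian float32 `data.bin` (trial-major, samples fastest) and a
`meta.json`.

### Stimulus similarity

The phonological similarity of two syllables is a weighted component
match,

$$ s(a,b) = w_i\,[a_\mathrm{ini} = b_\mathrm{ini}]
          + w_f\,[a_\mathrm{fin} = b_\mathrm{fin}]
          + w_t\,[a_\mathrm{tone} = b_\mathrm{tone}], $$

with nonnegative weights summing to one, default $(0.4, 0.4, 0.2)$. This
is a deliberately transparent quantification: published character
sound/shape coding schemes give graded values but their formulas are not
reproducible from the literature, and the analysis itself only needs the
property that within-pairs score maximally at the manipulated position
(they share the full syllable, so $s = 1$ regardless of the weights) while
all other positions are matched between conditions. The weights are
exposed so users can calibrate toward any published scale. Tone is an
equality predicate rather than a graded distance because the design treats
a shared syllable as shared tone-included. Orthographic and semantic
similarities are consumed as externally supplied matrices (TSV), never
computed: their published sources are look-up databases and proprietary
coding schemes, and recomputing them is out of scope.

## The synthetic-data generator

`generate_dataset()` simulates one trial per item per participant under

$$ x_{p,i,c,t} = A\, e(t)\, w_{s(i),c} + B\, e(t)\, v_{p,i,c}
              + \varepsilon_{p,i,c,t}, $$

- $w_s$: a unit-norm channel pattern per set, common to all participants —
  the representational content carried by the shared syllable;
- $v_{p,i}$: a unit-norm item pattern drawn *per participant*;
- $e(t)$: an envelope that is exactly 0 before `effect_onset` (default
  -200 ms) and ramps linearly to 1 over `effect_ramp` (default 100 ms);
- $\varepsilon$: channel-wise AR(1) noise (coefficient 0.5, innovation sd
  8 uV) plus white noise (sd 4 uV), about 10 uV of single-trial noise per
  channel.

Item patterns are participant-specific by design. If a single item pattern
were shared by all participants, the realized pattern geometry would give
*every* participant the same small stimulus-driven offset in the
within-minus-between difference — a "stimulus as fixed effect" component
that participant-level inference cannot absorb, and which would make even
a no-shared-pattern simulation reject above the nominal rate. With
idiosyncratic item patterns, participants are genuinely exchangeable under
the null ($A = 0$) and the tests calibrate; the set-shared pattern, the
effect of interest, remains common across participants. This is the one
place the generator's structure was chosen for statistical coherence
rather than physiological literalism, and it is the main caveat when
transferring calibration claims to real data, where item-level responses
do correlate across participants (real designs address this with item-side
controls such as the cloze and semantic matching of the reference design).

At a full-envelope sample the expected within-minus-between pattern
correlation is approximately $A^2 / (A^2 + B^2 + C\sigma^2)$ with $C$ the
channel count and $\sigma^2$ the per-channel noise variance (verified
against simulation in the test suite). The default amplitudes ($A = 45$,
$B = 15$; per-channel evoked signal $\approx A/\sqrt{C} \approx 6$ uV)
put that expectation near 0.5 and were chosen once, from this power
analysis, to give high (roughly 90%+) detection rates for the pre-onset
window at both the full design and the reduced validation dimensions.
They are free parameters of the generator, not estimates of any real
dataset, which does not publish effect sizes in correlation units.

Noise is AR(1) + white rather than full $1/f$: what matters for cluster
inference is temporal autocorrelation, which AR(1) supplies at minimal
cost; a spectral-exponent noise model is a natural config extension. The
envelope is a linear ramp because the time-course shape of a pre-activation
effect is not constrained by prior work; the ramp makes "onset" well
defined (first departure from zero). The generator does **not** emulate
ERP component morphology (N400 etc.), eye blinks or muscle artifacts,
volume-conduction channel correlation, or continuous recording — so
passing tests certify the statistical machinery under exchangeable,
Gaussian, spatially white noise, not robustness to every property of real
EEG.

`inject_artifacts()` plants single out-of-range samples in an exact
fraction of trials so that threshold rejection can be verified to remove
precisely the planted trials; a fraction of 0.029 reproduces the ~2.9%
rejection rate typical of the ±120 uV rule at this epoch length.

## Preprocessing

Baseline correction subtracts each trial x channel mean over
-1,400..-1,100 ms — the 300 ms fixation before idiom-initial onset — and
is idempotent. The same baseline serves the post-onset analyses; there is
no re-baselining at idiom-final onset, so pre- and post-onset similarity
are computed on the same scale. Amplitude rejection removes a trial when
any sample on any channel strictly exceeds the threshold (default 120 uV).
All windows and intervals are closed on both ends; at 250 Hz a half-open
convention would shift any result by at most one 4-ms sample. Upstream
steps on real data (re-referencing, filtering, downsampling, ICA) are out
of scope: the container is assumed to hold cleaned epochs, and the
generator produces data directly at the target rate and reference.

## Spatial RSA and time-cluster inference

At each timepoint, the channel-pattern (across-electrode) Pearson
correlation is computed for the two trials of every pair and averaged per
condition per participant; raw r values are averaged (a Fisher-z option
exists, off by default, and changes nothing qualitatively at these r
magnitudes). Pairs that lost a trial to rejection are dropped per
participant and counted; a condition mean uses the available pairs, which
affects its variance but not its expectation.

The predictive-window test averages each condition over -200..0 ms and
applies a paired two-sided t-test across participants. Paired is the only
design-consistent choice: both conditions are measured within every
participant. Two-sided is used throughout, claiming no directional prior.

The cluster permutation over time forms maximal runs of adjacent
timepoints whose paired t is suprathreshold (two-sided p < 0.05) *with a
consistent sign*, summarizes each run by its mass (summed t), and compares
observed masses against the permutation distribution of the maximal
absolute mass under random within/between label exchange per participant —
implemented as a sign flip of each participant's difference timecourse,
which is the exact group of label exchanges for a paired design
(pair-level reassignment would be wrong here: within- and between-pairs
are not exchangeable units, they have different set structure). Cluster
p-values count ties against significance. A run-length ("size") statistic
is available behind a flag; mass is the default for the time dimension.

The matched-subsample control re-runs the window test with between-pairs
subsampled without replacement to the within-pair count, one independent
draw per participant.

## Temporal RSA and electrode-cluster inference

Temporal RSA correlates whole time series (default -1,100..0 ms) between
the two trials of a pair at each electrode separately, yielding a
topography of condition means. Inference permutes condition labels per
participant to get a per-electrode p for the mean difference; significant
electrodes (p <= 0.05, two-sided) compose connected clusters on an
adjacency graph — composition is sign-agnostic, exactly as the procedure
is conventionally stated, unlike the sign-consistent runs of the time
dimension where runs of opposite-signed t cannot meaningfully concatenate
— and the cluster statistic is its **size** (electrode count); mass is
available behind a flag. The null distribution of the maximal cluster
size is built by thresholding every permutation's electrode statistics
against the same permutation distribution (rank-based), clustering each
permutation, and taking its largest cluster. The deliberate asymmetry —
mass over time, size over electrodes — mirrors how the two tests are
conventionally reported for this design.

Electrode adjacency is Euclidean distance at or below 1.3 x the median
nearest-neighbor distance of the montage, a threshold that gives the
packaged 62-channel extended 10-20 layout 2-6 neighbors per electrode and
a connected graph; a user-supplied adjacency matrix overrides it. For
reduced channel counts a contiguous sub-montage is grown outward from Cz,
keeping sub-layouts connected and geometrically realistic.

A caveat measured during validation: with few electrodes (16) the size
statistic is coarsely discrete — the null maximal size concentrates on
{1, 2, 3} — so the achievable familywise alpha sits below the nominal
0.05 and the test runs somewhat conservative (familywise rejection near
0.02 under the null at 16 channels). This is a property of size
statistics on small sparse graphs, not of the implementation; at 62
channels the distribution is finer.

## Pair-level regression

`build_pair_table()` extracts, per participant and pair, the mean
channel-pattern correlation over the predictive window alongside the
pair's phonological, semantic and orthographic similarities.
`two_stage_regression()` fits ordinary least squares per participant with
predictors standardized within participant, then tests each coefficient
across participants with a one-sample t. This is the classical
summary-statistics route to fixed-effect inference and stands in for a
random-intercept + random-slope mixed model: with one coefficient vector
per participant, the stage-2 t on a slope is the exact analogue of the
mixed model's fixed-effect test under participant exchangeability, without
a mixed-model dependency. The exported pair table is the full design
matrix, so the original formulation can be refit externally. The unit of
analysis is the (participant, pair): neural similarity is intrinsically
pairwise, so "trial-level" modelling of similarity necessarily means
pair-level rows. Standardizing within participant makes coefficients
comparable across participants and makes recovery targets scale-free;
predictors constant within a participant cannot be standardized and are
excluded for that participant rather than silently zeroed.

`simulate_pair_table()` generates pair tables directly from a linear model
with known coefficients on the standardized scale. Validating coefficient
recovery through this route is exact — the truth is defined in the same
units the estimator reports. A full EEG-route recovery (making the shared
amplitude depend on pair similarity) maps amplitudes through the nonlinear
amplitude-to-correlation curve, so its implied coefficient is not known in
closed form; the EEG route is therefore validated for direction and
significance, and the direct route for quantitative recovery.

## Orchestration and reproducibility

`run_pipeline()` ties the stages together from a YAML or list config.
Every stochastic stage consumes a sub-seed derived by hashing the master
seed with the stage name, so adding a stage never perturbs another stage's
stream, and identical config + seed reproduces every output file byte for
byte (the manifest records seeds, parameters, package version and input
digests, and deliberately no timestamps). A thin command-line wrapper
(`inst/cli/phonrsa.R`, verbs `simulate` and `run`) exposes the same entry
points to shell users; exit codes are 0 / 1 / 2 for success / input error
/ analysis error.

## Validation dimensions

The simulation-based checks in the test suite run at a reduced scale
chosen to keep the full suite fast while preserving the design's
structure: 12 participants, 4 sets x 4 items (24 within-, 96
between-pairs), a contiguous 16-channel sub-montage, 125 Hz, 500
permutations, with replicate counts of 50 (recovery rates), 100
(subsampling), and 200 (type-I calibration). The same dimensions are used
by `scripts/acceptance.R`, which re-derives the headline quantities from
scratch. Calibration bands in those checks are binomial 95%-style bands
around the nominal 0.05, i.e. [0.02, 0.08] at 200 replicates.

## Known limitations

- Calibration and recovery are demonstrated on the generator's synthetic
  conditions; real EEG adds shared item-level structure, non-Gaussian
  artifacts and spatial noise correlation that these tests do not probe.
- The electrode cluster-size test is conservative at small channel counts
  (see above).
- The regression stage is a fixed-effects summary-statistics procedure;
  it does not estimate variance components, and users wanting REML-based
  mixed-model output should refit the exported pair table.
- The phonological similarity measure is a component-match score, not a
  published graded phonetic distance; its absolute values are not
  comparable to published similarity tables, only its ordering structure.
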