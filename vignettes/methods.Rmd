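---
title: "Methods: sparse Gammatone scene coding, the slim CNN, and the audiometry simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse Gammatone scene coding, the slim CNN, and the audiometry simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models implemented in `hearscene`, the
assumptions behind them, the tunable parameters and their defaults, the
numerical choices that matter for reproducing results, and the limits of
what the synthetic-data experiments demonstrate.

## 1. The sparse Gammatone representation

### Model

An audio segment $x(t)$ is approximated as a $K$-term superposition of
dictionary atoms plus a residual,

$$x(t) = \sum_{k=1}^{K} a_k\,\gamma_{f_k,t_k}(t) + \varepsilon(t),$$

where $\gamma_{f,t}$ is the impulse response of a Gammatone filter with
centre frequency $f$, shifted to sample offset $t$. The Gammatone is the
standard model of basilar-membrane frequency analysis, which is the reason
it is used both as an auditory front end and as the sparse-coding
dictionary here: atoms are "what the cochlea would respond to", and a
list of (filter, time, amplitude) triples is a spike-like neural code of
the segment.

Matching pursuit builds the code greedily. At step $k$ the algorithm
selects

$$(f_k, t_k) = \arg\max_{f,t}\ \lvert\langle \varepsilon_k,\
\gamma_{f,t}\rangle\rvert,$$

with $\varepsilon_1 = x$, keeps the *signed* inner product as $a_k$, and
subtracts $a_k \gamma_{f_k,t_k}$ from the residual. Because every atom has
unit Euclidean norm, the inner product is the least-squares amplitude and
the step-wise energy identity

$$\lVert x \rVert^2 = \sum_k a_k^2 + \lVert\varepsilon\rVert^2$$

holds exactly in exact arithmetic; the tests assert it to $10^{-6}$
relative (observed error is at machine precision, but reconstruction uses
the stored amplitudes of non-orthogonal atoms, so the documented contract
leaves floating-point headroom).

### Dictionary construction

The filterbank (`build_filterbank()`) uses:

* **Order 4** Gammatone envelopes, $t^3 e^{-2\pi b t}\cos(2\pi f t)$ —
  the de-facto convention in auditory modelling.
* **Glasberg–Moore ERB bandwidths**, $\mathrm{ERB}(f) = 24.7\,(4.37
  f/1000 + 1)$ Hz, with the order-4 envelope parameter $b = 1.019\,
  \mathrm{ERB}(f)$. Bandwidth grows monotonically with $f$.
* **ERB-rate-uniform centre frequencies** between `fmin` and `fmax`,
  endpoints included. Defaults: $M = 64$ filters, 80 Hz to
  $0.45\,f_s$, $f_s = 16$ kHz. The working sample rate is a parameter;
  16 kHz covers the band that matters for everyday-scene discrimination
  at half the storage of 32 kHz.
* **Truncation at −60 dB of the envelope peak**, found by bisection on
  the log-envelope. This bounds atom length (46–1100 samples at the
  defaults) while discarding under $10^{-6}$ of atom energy, and is what
  makes the correlation search tractable.

### Placement rule and tie-breaks

Atoms are only placed where they lie **fully inside the signal**
(`0 <= t <= N - L`). An edge-truncated atom would no longer have unit
norm, so its inner product would not equal its least-squares amplitude
and the energy identity would fail; restricting the support keeps the
algebra exact. Filters longer than the signal are skipped; encoding fails
only if every filter is longer than the signal.

Ties in the argmax are broken toward the **lowest filter index, then the
smallest offset**. This makes runs bit-reproducible and lets the test
suite compare the encoder step by step against an exhaustive oracle.
Iteration stops early once the residual energy falls below $10^{-12}$
times the initial energy, so zero and near-zero signals produce codes
with fewer than $K$ atoms rather than numerically meaningless ones.

### Implementation of the correlation search

The encoder maintains the full correlation table
$C[t,m] = \langle \varepsilon_k, \gamma_{m,t}\rangle$. It is initialised
with direct inner products and then **updated incrementally**: subtracting
an atom changes correlations only at offsets overlapping it, by the
selected amplitude times the atom–atom cross-correlation. Those
cross-correlations (the shift-structured Gram of the dictionary) are
precomputed once per filterbank and cached, so one iteration costs
$O(M L_{\max})$ for the update plus argmax bookkeeping that tracks one
running maximum per filter. A frequency-domain initialisation would be
asymptotically equivalent; the direct time-domain form was chosen because
it matches the oracle's arithmetic bit-for-bit apart from summation
order, so acceleration provably does not change selections. A 10-s,
$K = 1024$ encode takes a few seconds on one CPU.

Binaural input is downmixed to the channel mean before encoding; the
representation itself is monaural.

### The privacy contract

A serialised code (`write_sparse_code()`) holds one CSV row per atom and
a JSON sidecar of scalars — there is no field that could carry
`signal_length` samples, which the tests assert. `reconstruct()` and
`privacy_report()` exist to *audit* rather than assume the privacy claim:
they materialise $\sum_k a_k\gamma_k$ and report the retained energy
fraction and the correlation of the reconstruction with the original. At
the canonical operating point (1024 atoms for 10 s, i.e. ~0.6% of the
sample count) roughly a quarter to a third of the energy is retained:
enough structure to classify the scene, far from a waveform copy.
Perceptual intelligibility of reconstructions is not scored; that is an
explicit non-goal.

## 2. Spikegram features

`rasterize()` converts a code into the classifier input: an
$M \times T$ grid in which cell $(m, \lfloor t/\mathrm{bin}\rfloor)$
accumulates transformed atom magnitudes. Defaults: **25-ms bins** (400
columns per 10 s, 80 per 2 s) and the **log1p transform**
$\log(1+|a_k|)$, a mild dynamic-range compression in the spirit of
log-spectral features. The grid is a deterministic, permutation-invariant
function of the atom multiset — selection order, which matching pursuit
imposes but the scene does not, is deliberately discarded. Signs are
discarded too; for a cosine-phase dictionary the sign of an amplitude
carries local phase, not scene identity.

## 3. The slim CNN and its training protocol

Architecture (`cnn_architecture()`, defaults):
four blocks of [3×3 convolution, same padding → spatial batch
normalisation → ReLU → 2×2 max pooling] with 32, 64, 128, 256 channels,
then flatten → 280-unit dense → ReLU → 50% dropout → 14-unit linear
output with softmax. For the 64×400 input of a full 10-s segment this is
7,561,014 trainable parameters (asserted against layer-by-layer
arithmetic in the tests). Same padding is used so four poolings divide
each dimension by exactly 16.

Training (`training_config()`, defaults): Adam at learning rate
$10^{-3}$ (the optimiser's conventional default), mini-batches of 24,
categorical cross-entropy, at most **250 epochs** with early stopping
after **10 epochs** without improvement of the monitored loss. The
protocol's "iterations" are read as *epochs*: 250 mini-batch steps would
be a fraction of one pass over a corpus of thousands of records and
could not interact meaningfully with a patience of 10. The monitored
quantity is the mean training loss per epoch — the protocol splits data
into train and test only, with no validation set — but
`train_classifier()` accepts an optional held-out monitor set.
Improvements smaller than `min_delta` ($10^{-8}$ by default) do not reset
the patience counter; without this, floating-point noise from batch
reordering (order of summation, at the $10^{-15}$ level) would count as
improvement and early stopping could never fire on a plateau.

Evaluation: `split_dataset()` makes a stratified split whose overall
training share is exactly `round(0.7 n)`; `repeated_experiment()` runs
the whole protocol (fresh split, fresh initialisation, training,
evaluation) $R$ times — 10 by default — and reports per-class accuracies,
the mean overall accuracy, and the elementwise mean and standard
deviation of the row-normalised confusion matrices.

Numerical details that affect reproduction: He-initialised weights;
batch normalisation with $\epsilon = 10^{-5}$, biased batch variance,
and running statistics updated with momentum 0.9 (used at inference);
inverted dropout; every stochastic element (initialisation, splits,
shuffling, dropout masks) drawn from R's RNG under explicit seeds, so
identical seeds give bit-identical loss histories. The forward/backward
engine is compiled (im2col + GEMM) and is verified against central finite
differences in the test suite; the conv biases have an exactly flat loss
direction (batch normalisation subtracts the channel mean), which the
gradient test treats as the expected zero rather than an error.

## 4. The synthetic scene corpus

`default_taxonomy()` defines 14 classes in the three-group structure of
hearing-aid scene corpora:

* **speech**: `cocktail_party` (six simultaneous speakers over a babble
  floor), `interfering_speakers` (three speakers in alternating turns);
* **background**: `traffic`, `in_vehicle`, `wind`, `rain`, `music`,
  `kitchen` — parameterised noises combining spectral tilt, engine-like
  harmonic hum, slow gust modulation, impulsive event trains and
  sustained chords;
* **speech_in_background**: one speech source added to a background at a
  spec-level SNR (0 dB default), including `speech_in_traffic` and
  `speech_in_vehicle`; `reverberant_environment` additionally convolves
  the speech with a synthetic exponentially decaying reverb tail.

Only the scene names the taxonomy fixes are meaningful; the remaining
labels are documented synthetic stand-ins, and nothing downstream depends
on specific names. Classes are balanced by default (imbalance is
available through per-class generation), and every record is
deterministic in `(spec, seed)` with per-record seeds derived from a
master seed.

Speech-like sources are harmonic complexes with a drifting fundamental,
fixed formant-shaped spectral emphasis and ~4 Hz syllabic amplitude
modulation. Mixing scales the two components so the realised
component-energy ratio equals the spec SNR *exactly* before the common
peak-normalisation gain. Stationary backgrounds pass through a soft
amplitude limiter (tanh at ≈2.2 σ), modelling sustained dense sources and
keeping their crest factor below 3; transient scenes add their event
bursts after limiting, so impulsiveness remains a class cue.

**What this does and does not show.** The generator gives the classifier
a learnable 14-class problem with realistic *feature types* (spectral
tilt, harmonicity, modulation, impulsiveness, reverberation) and controls
every nuisance variable. It does not contain real speech, real room
acoustics, recording-chain variation, or the class overlap of field
recordings. A high held-out accuracy here certifies that the
encode–rasterise–train–evaluate pipeline learns and generalises within
its design; it is *not* a claim about accuracy on real corpora, which is
why the published field-data accuracy is not a target of this package's
tests.

## 5. The audiometry simulator

`measure_audiogram()` runs a modified Hughson–Westlake staircase — the
clinical standard, which the remote app emulates — at each of the five
standard frequencies (500, 1000, 2000, 4000, 6000 Hz): start at 40 dB HL,
descend 10 dB after every response, ascend 5 dB after every miss, and
accept the first level that collects **two responses on ascending
presentations**; all levels lie on the 5-dB grid by construction. Bounds
are −10 and 110 dB HL; repeated ceiling misses flag the frequency
unmeasurable (`NA`) rather than fabricating a value.

Listeners (`sim_listener()`) respond by a Bernoulli draw with probability
$(1-\lambda)\,\Phi\!\big((L_\mathrm{eff}-\theta)/\sigma\big)$: true
threshold $\theta$ per frequency, probit slope $\sigma$ (3 dB default —
of the order of clinical test–retest spread; $\sigma = 0$ gives a
deterministic step listener, for which the staircase provably returns
$5\lceil\theta/5\rceil$), and lapse rate $\lambda$ (2% default). The
default cohort is normal-hearing: thresholds drawn from
$\mathcal{N}(5, 6^2)$ dB HL, clipped to [−10, 40].

**Latency-to-bias mechanism.** The clinical and remote paradigms differ
in response latency (button versus touchscreen). With presentation levels
effectively sweeping at rate $r$ (10 dB/s default), a latency $\tau$
shifts the effective level at the moment the response registers by
$\tau r$ dB downward, so the slower paradigm measures *higher*
thresholds. `compare_paradigms()` reports clinical − remote differences
per frequency (median, quartiles, extremes, 1.5-IQR outliers, box-plot
style). Under matched latencies the median difference is 0 at every
frequency; with the remote paradigm carrying an extra $\tau r = 5$ dB,
the median recovers −5 dB exactly. The sign convention deserves a note:
published descriptions of such comparisons are ambiguous about which
paradigm reads lower, and the direction depends only on which paradigm
carries the larger latency — the simulator's bias magnitude, one grid
step, is the robust quantity. The human-subject finding itself is a
property of people and hardware and is deliberately not a test target.

## 6. Problem sizes used by the tests and the acceptance script

The package's own evaluation runs at sizes chosen to exercise every
stage meaningfully on a single CPU:

* oracle comparison: 100 random instances, signal length ≤ 512, $M \le
  8$, 5 atoms each;
* one full-scale encode: 10 s, $M = 64$, $K = 1024$;
* classification: 14 × 40 records of **2 s** with the atom budget scaled
  proportionally ($K = 205 \approx 1024 \cdot 2/10$), giving 64×80
  features; one repetition, at most 30 epochs. Held-out accuracy on this
  problem is far above the 5× chance bar the tests require;
* audiometry: 200 listeners × 3 repetitions per paradigm.

## 7. Known limitations

* Plain matching pursuit with a fixed dictionary: no orthogonal
  re-projection and no dictionary learning, by design.
* The spikegram layout (bin width, log1p, unsigned magnitudes) is one
  reasonable bridge from sparse codes to a CNN; alternatives (finer bins,
  signed channels, per-band normalisation) are easy to add but
  deliberately not defaulted.
* The CNN engine is single-threaded compiled code adequate for the
  package's problem sizes, not a GPU framework; no quantisation or
  on-device deployment path is provided.
* The synthetic corpus and simulated listeners are stand-ins with
  documented scope (sections 4–5); conclusions about real recordings or
  real patients require real data.
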