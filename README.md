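# hearscene

Privacy-preserving sparse Gammatone coding, acoustic scene classification
and remote audiometry simulation for connected hearing devices.

Connected hearing devices can adapt their signal processing to the
listener's acoustic environment and can be fitted remotely, but both
services raise two computational problems that this package addresses
end to end:

1. **Scene classification without shipping audio.** Hearing-device users
   cannot be asked to upload raw recordings, so the device transmits a
   *sparse code* instead: the segment is decomposed over a dictionary of
   Gammatone atoms (the standard model of cochlear filtering) and only the
   list of selected atoms is kept. A slim convolutional network classifies
   the rasterised code into one of 14 everyday acoustic scenes.
2. **Remote pure-tone audiometry.** An app-based hearing test shares the
   5-dB staircase logic of the clinical procedure but differs in reaction
   latency, which biases measured thresholds. A simulator reproduces both
   paradigms on configurable virtual listeners and quantifies the
   per-frequency bias the way a clinical comparison study would.

## The model

A segment `x(t)` is approximated as a K-term superposition of Gammatone
atoms,

    x(t) = sum_{k=1}^{K} a_k * gamma_{f_k, t_k}(t) + eps(t),

where `gamma_{f,t}` is the unit-norm impulse response of the 4th-order
Gammatone filter with centre frequency `f` (ERB bandwidth, Glasberg-Moore),
shifted to offset `t`, and `eps` is the residual. Matching pursuit selects
atoms greedily: at step `k` the pair `(f_k, t_k)` maximises the absolute
inner product `<eps_k, gamma_{f,t}>` over all filters and offsets, and the
signed inner product becomes the amplitude `a_k`. The default dictionary
has M = 64 filters and the canonical budget is K = 1024 atoms per 10-s
segment. Because atoms have unit norm, the identity
`||x||^2 = sum a_k^2 + ||eps||^2` holds exactly and is asserted in the
tests.

The classifier is a four-block CNN (3x3 kernels, 32/64/128/256 channels,
each block conv -> batch norm -> ReLU -> 2x2 max pool) followed by a
280-unit dense layer, 50% dropout and a 14-way softmax, trained with Adam
on mini-batches of 24 for at most 250 epochs with patience-10 early
stopping, evaluated over repeated stratified 70/30 splits. The numerical
engine is compiled (RcppArmadillo); gradients are verified against finite
differences in the test suite.

Because the public corpus this pipeline targets cannot be bundled, the
package ships a deterministic synthetic corpus generator emulating its
structure: 14 scene classes in three groups (*speech*, *background*,
*speech in background*), 10-s segments, with mixed scenes created by
adding a speech-like harmonic source to a parameterised background at an
exact component-level SNR.

## Worked example

```r
library(hearscene)

bank <- build_filterbank()                     # M = 64, 80-7200 Hz, 16 kHz
spec <- default_taxonomy()[[9]]                # "speech_in_traffic"
rec  <- generate_scene(spec, seed = 7, duration = 2)
code <- matching_pursuit(rec$audio, bank, K = 205)
code
#> Sparse Gammatone code: 205 atoms over 32000 samples (2.00 s @ 16000 Hz)
#>   retained energy fraction: 0.3866
privacy_report(code, rec$audio, bank)$reconstruction_correlation
#> [1] 0.622
rasterize(code, bank)$grid |> dim()            # classifier input
#> [1] 64 80
```

The code captures the scene's character (enough energy structure for
classification) while the reconstruction correlates only weakly with the
waveform — the privacy/utility trade-off `privacy_report()` quantifies.

```r
cmp <- compare_paradigms(50, 3, latency_clinical = 0.2,
                         latency_remote = 0.7, seed = 1)
cmp$summary$median
#> [1] -5 -5 -5 -5 -5
```

With the remote paradigm carrying 0.5 s of extra response latency at a
10 dB/s level sweep rate, the median clinical-minus-remote difference is
-5 dB at all five audiometric frequencies — one grid step, the same order
as the bias reported in clinical comparisons of app-based audiometry.

A command-line wrapper is installed at `inst/cli/hearscene`
(subcommands `synth`, `encode`, `reconstruct`, `rasterize`, `experiment`,
`audiosim`).

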