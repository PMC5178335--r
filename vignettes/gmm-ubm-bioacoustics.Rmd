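---
title: "Classifying animal social calls with a GMM-UBM likelihood-ratio pipeline"
author: "batvoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying animal social calls with a GMM-UBM likelihood-ratio pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batvoc)
```

# The question and the method

Social mammals that live in dark roosts do most of their signalling by
voice, and the bulk of it consists of superficially similar aggressive
calls exchanged between two specific individuals. The question this
package operationalizes is: how much information do such everyday calls
carry about *who* is calling, *whom* they address, *what* the quarrel is
about, and *how* it will end? The answer is framed as a decoding
problem — if a statistical classifier can recover an attribute from the
acoustics alone, an eavesdropping conspecific could in principle do the
same.

The pipeline is the classical speaker-verification recipe transplanted
to bioacoustics:

1. **Segmentation.** Each annotated vocalization is a multisyllabic
   sequence; a short-time RMS energy detector partitions it into voiced
   syllables and silence.
2. **Features.** Each voiced segment is cut into 20 ms windows advancing
   1 ms (19 ms overlap), and each window becomes a vector of 64
   Mel-frequency cepstral coefficients (MFCCs). All frames of all
   segments of one vocalization are pooled into a single variable-size
   set of 64-dimensional vectors; per-channel coefficient means are
   subtracted to remove recording-channel coloration.
3. **Models.** A 16-component diagonal-covariance Gaussian mixture — the
   universal background model (UBM) — is fitted by EM to a pool of
   background syllables that never appears in training or testing. Each
   class model (an emitter, a context, …) is derived from the UBM by
   maximum-a-posteriori (MAP) adaptation of the component means toward
   the pooled frames of that class, with relevance factor $r$:
   $$\hat\mu_k = \frac{n_k \bar x_k + r\,\mu_k^{\mathrm{ubm}}}{n_k + r},$$
   where $n_k$ and $\bar x_k$ are soft counts and means of the class
   frames under the *fixed* UBM posteriors.
4. **Scoring.** A test vocalization's score for class $c$ is the
   per-frame mean log-likelihood under the class model minus that under
   the UBM (a log-likelihood ratio); the predicted class is the argmax.
5. **Evaluation.** Leave-one-out cross-validation, summarized by
   balanced accuracy (BA) — the mean of the row-normalized confusion
   matrix diagonal — and label-permutation tests (100 permutations),
   plus a control that repeats everything on the *unvoiced* spans.
6. **Visualization.** Each test vocalization's vector of class scores is
   projected to two dimensions by linear discriminant analysis; the
   projection plays no role in any accuracy number.

# Design choices and why

**Per-frame mean rather than summed likelihood.** Classes can differ
systematically in call duration; summing frame log-likelihoods would let
duration leak into a score meant to capture spectral content. The
per-frame mean is invariant to frame duplication, which the test suite
asserts.

**MAP adaptation: means only, relevance factor 16.** The canonical
speaker-verification configuration. Adapting only means keeps class
models anchored to the UBM's covariance structure, which is what makes
sufficient-statistic leave-one-out exact. Weights and variances
adaptation are implemented and config-exposed, but not default. Both
limits are contract-tested: $r \to \infty$ returns the UBM exactly, and
$r = 0$ gives per-component maximum-likelihood means wherever a
component saw data.

**Exact leave-one-out by statistic subtraction.** Because posteriors are
computed against the fixed UBM, the sufficient statistics of a class are
the sum of its members' statistics. Holding out a vocalization is a
subtraction, after which only its own class model needs re-adaptation.
This is algebraically identical to refitting the fold from scratch; the
suite verifies the equivalence on a 60-call corpus and the identity is
what makes 100-permutation tests affordable.

**UBM resolution versus class separation.** A property worth knowing
when designing simulations: with means-only adaptation the class signal
lives in *shared* components pulled in class-specific directions. If
classes are so well separated that the UBM dedicates components to each
class cluster, every class model reproduces the UBM in its own region
and all likelihood ratios collapse toward zero. Real call repertoires
overlap heavily, which is exactly the regime in which GMM-UBM works;
the synthetic feature-stream fixtures therefore either overlap classes
or use a deliberately broad (low-$K$) background model.

**p-values.** The add-one permutation estimator
$p = (1 + \#\{\mathrm{BA}_{\mathrm{null}} \ge \mathrm{BA}\}) / (1 + n_{\mathrm{perm}})$
is used, so $p$ is never zero and the smallest attainable value at 100
permutations is $1/101 \approx 0.0099$. The whole pipeline — class
accumulation, adaptation, leave-one-out, BA — is re-run for every
permutation.

**Chance levels.** A uniform random guesser's expected recall is $1/C$
for every class regardless of class sizes, so the expected BA is $1/C$:
14% for 7 classes, 25% for 4, 33% for 3, 50% for 2, 12.5% for 8. These
analytic values are what the acceptance suite checks, since balanced
accuracy was chosen precisely to pin chance at $1/C$ under imbalance.

# The synthetic generator

Field recordings of this kind are rarely deposited, so the package
carries a generator whose defaults emulate the recording conditions the
pipeline was designed for: 250 kHz PCM audio, multisyllabic calls of
1–20 broad-band multi-harmonic syllables separated by short silences,
two recording channels with fixed spectral coloration, and additive
white noise (default SNR 30 dB). Each syllable is a harmonic stack (at
least 8 harmonics, band-limited to 60 kHz or 0.45 × sample rate) shaped
by a formant-like Gaussian spectral envelope and faded in and out by
raised-cosine ramps.

The four annotation axes map to orthogonal, individually tunable
acoustic effects:

| axis | acoustic carrier | effect parameter (0 ⇒ null) |
|---|---|---|
| emitter | fundamental frequency (500–800 Hz) + envelope base centre | `f0Base`, fixed spread |
| context | formant-envelope centre shift | `formantShiftPerContext` (Hz, default 3000) |
| addressee | spectral tilt | `addresseeTilt` (dB/kHz, default 0.6) |
| outcome | amplitude gain and envelope bandwidth | `outcomeGain` (dB, default 4) |

Addressee sex is a deterministic attribute of the addressee identity, so
a sex-classification task is derivable from the labels. Syllable
durations (25–50 ms) and gaps (15–40 ms) are free parameters of the
simulation, not estimates of any real corpus — no duration statistics
were available to estimate them from, and the classifier deliberately
ignores temporal structure anyway.

What the generator does *not* emulate: echolocation clicks, overlapping
callers, non-stationary background noise, reverberation, or the
within-class acoustic diversity of real repertoires. Passing tests on
synthetic data therefore demonstrate the *pipeline's* correctness and
calibration, not the decodability of any real species' calls.

A second, audio-free mode (`generateFeatureStreams()`) draws feature
vectors directly from known per-class mixtures, so classifier behaviour
can be tested against generative truth with the DSP stages bypassed —
including exact nulls, where every class shares one mixture.

# Numerical choices

* **MFCC defaults:** 128 triangular mel filters spanning 100 Hz–60 kHz
  (the displayed energy band of this call type), FFT size = next power
  of two above the 20 ms window, Hann taper, orthonormal DCT-II, energy
  floor $10^{-10}$ before the log, $c_0$ retained (cepstral mean
  subtraction removes loudness/channel bias later). Pre-emphasis is off
  by default. Segments shorter than one 20 ms window are dropped, not
  padded — padding would fabricate spectra.
* **EM:** k-means-seeded, diagonal covariances floored at $10^{-3}$ of
  the global per-dimension variance, stopped on a log-likelihood gain
  below `tol` or at `maxIter`. Collapsed components are re-seeded from
  the worst-explained frame; the training log-likelihood trace is stored
  on the fitted object and asserted non-decreasing in the tests.
* **Segmentation:** short-time RMS (4 ms window, 1 ms hop) against a
  threshold 12 dB above the noise floor (20th percentile of windowed
  RMS), gaps under 8 ms bridged, runs under 10 ms discarded, and run
  boundaries refined to hop resolution. The noise-floor-relative mode
  makes boundaries invariant to amplitude scaling. Coordinates are
  1-based inclusive sample intervals (`IRanges`) throughout.
* **Ties:** exact score ties are broken by lexicographic class label, so
  degenerate inputs (e.g. two singleton classes) remain deterministic.
* **LDA:** within-class scatter is regularized by a ridge of $10^{-6}
  \times \mathrm{mean}(\mathrm{diag}(S_w))$; signs are fixed by making
  each discriminant's largest-magnitude loading positive.
* **Seeding:** one global seed fans out to per-stage and per-item seeds
  through a 32-bit avalanche hash. (Sequentially numbered seeds are not
  used directly: weak seed derivation can leave faint correlations or
  collisions between item streams, which a leave-one-out analysis is
  sensitive enough to expose.)

# Problem sizes used in the tests

The test suite exercises every stage at sizes chosen to keep a full run
comfortable on one CPU while retaining statistical resolution:

* waveform corpora of 2 emitters × 3–4 contexts × 4–10 calls per cell
  with 1–5 syllables per call (the generator's default of up to 20
  syllables is exercised, but not everywhere);
* the leave-one-out/refit equivalence on a 60-vocalization, 3-class
  corpus with a 16-component UBM;
* permutation-test calibration on 200 zero-effect feature-stream
  datasets (3 classes × 16 items × 18 frames, 100 permutations each),
  with the fraction of $p \le 0.05$ required to sit inside the binomial
  95% band around 0.05 — item counts were sized so the discreteness of
  BA (granularity 1/48) does not make the add-one estimator's tie
  handling dominate;
* detection power on 20 replicate corpora at the default planted
  context effect, requiring the minimal $p = 1/101$ in at least 19.

# Limitations

The package decodes *spectral* information only; temporal and prosodic
cues are intentionally out of scope. The segmentation is a simple
energy detector — adequate for clean synthetic audio and quiet
recordings, but it does not reject impulsive noises or separate
overlapping callers. The two-step composition (classify the emitter
first, then the attribute within that emitter) is expressed as a
`TaskSpec` with a population filter rather than a separate algorithm.
Balanced accuracy summarizes recall only; per-class confusion matrices
are always written alongside it.
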