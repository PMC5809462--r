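---
title: "Transdermal optical imaging of heart rate and HRV: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transdermal optical imaging of heart rate and HRV: models and methods}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(toiHRV)
```

## The measurement problem

Facial skin is translucent: light entering the epidermis is re-emitted
after scattering in deeper layers, and the dominant chromophores shaping
the re-emitted spectrum are hemoglobin and melanin. As the cardiac pulse
wave sweeps blood volume through the facial vasculature, the hemoglobin
contribution oscillates at the heart rate. A conventional RGB camera
therefore carries a faint cardiac signal, and the analysis problem is to
isolate it well enough to recover not just the mean heart rate but the
beat-to-beat R-R interval (RRI) series, from which heart-rate-variability
(HRV) indices are computed.

`toiHRV` implements this transdermal pipeline end to end, together with an
ECG reference branch and the agreement statistics used to compare the two,
and with synthetic generators so that every stage can be validated against
known ground truth without recorded data.

## Bitplane representation and signal composition

Each 8-bit RGB frame is viewed as 24 *bitplanes*: binary images formed by
one bit position of one channel across all pixels (`decomposeBitplanes`,
bit 0 least significant). The hemoglobin-concentration (HC) image is a
pixel-wise signed combination of bitplanes,

\[ \mathrm{HC}(x,y,t) \;=\; \sum_{c \,\in\, \{R,G,B\}} \sum_{b=0}^{7}
   w_{c,b}\, P_{c,b}(x,y,t), \qquad w_{c,b} \in \{-1, 0, +1\}, \]

with planes entering *unscaled* (no \(2^b\) positional weight): the
selector learns each plane's usefulness directly, and the only operations
applied are image addition and subtraction. Within each facial region of
interest (ROI) the HC image is averaged over pixels, which raises SNR by
roughly \(\sqrt{n_{\text{pixels}}}\) for uncorrelated noise. Because both
steps are linear, the package precomputes per-ROI mean time series of all
24 bitplanes (`bitplaneROIMeans`) and performs every subsequent
composition and selection step on those `T x 24` matrices.

Nine facial ROIs are used (forehead, between-eyes, nose bridge, nose tip,
both cheeks, both lips, chin). Masks are supplied by configuration file or
by the synthetic truth bundle; face detection and tracking are out of
scope, and masks are fixed over the recording (seated, still subjects).

## The selection objective and greedy search

The original selection step was trained against contact instruments
(laser Doppler flowmetry, continuous cuff blood pressure) that record the
facial pulse directly. Absent such ground truth, the package re-grounds
selection on a measurable objective: the **cardiac-band spectral SNR**

\[ \mathrm{SNR} \;=\; 10 \log_{10}
   \frac{P[f_{\mathrm{lo}}, f_{\mathrm{hi}}]}
        {P[0.05\,\mathrm{Hz}, f_{\mathrm{Nyq}}] - P[f_{\mathrm{lo}},
        f_{\mathrm{hi}}]} \]

with the cardiac band 0.7-4.0 Hz (42-240 beats/min) and power estimated by
a mean-removed, Hann-windowed, 8-segment, 50%-overlap averaged
periodogram (`welchPSD`). This is a stand-in, flagged as such: the
published method's "signal differentiation" is never defined
mathematically.

`selectBitplaneWeights` performs greedy coordinate ascent: starting from
all-zero weights it repeatedly applies the single `(channel, bit, sign)`
change that most increases the *mean* training-split SNR across ROIs,
stopping when the improvement falls below `snrTolerance` (0.5 dB) or
after `maxIterations` (24) accepted steps. Ties are broken by a fixed
enumeration order (R, G, B; bit 7 down to 0; +1 before -1), which makes
the search fully deterministic. The recording is split along the time
axis, by default 80% training / 20% validation; a cross-subject split is
not available to a single-recording tool. One global weight set is
produced and applied to every ROI.

Two reporting choices deserve note:

* The *objective* is the mean SNR over all nine ROIs, but the *reported*
  `snrTrain`/`snrValidation` are those of the best ROI under the final
  weights — the ROI the pulse stage consumes. The pulse does not reach
  every facial region with equal strength, so the across-ROI mean is a
  poor summary of whether a usable signal exists.
* `converged` is `TRUE` when at least one plane was selected *and* the
  best-ROI training SNR is positive (in-band power exceeds out-of-band
  power). On a noise-only recording no composition achieves that, so the
  selector reports failure and returns all-zero weights rather than a
  spurious combination.

A per-segment FFT cache makes each candidate evaluation an \(O(L)\)
complex update rather than a fresh FFT, so a full selection on a 120 s,
60 fps recording with nine ROIs takes well under a second.

## Pulse extraction: filtering and the Hilbert-Huang transform

The chosen ROI's composed signal is band-pass filtered with a 4th-order
Butterworth (0.7-4.0 Hz) applied forward-backward for zero phase; the
passband is maximally flat (gain error at 1.2 Hz about 0.2% after the
bidirectional pass) and DC is rejected entirely.

Empirical mode decomposition (`emd`) then splits the filtered signal into
intrinsic mode functions (IMFs) by standard sifting: cubic-spline
envelopes through the maxima and minima (with the two outermost extrema
mirrored past each end to tame boundary swings), subtraction of the
envelope mean, and the two-threshold stopping criterion of Rilling
(\(\sigma = |m|/a < 0.05\) on 95% of samples and \(< 0.5\) everywhere),
capped at 10 IMFs and 50 sifts per IMF. The decomposition is complete by
construction: IMFs plus residue sum back to the input to machine
precision.

The Hilbert stage (`principalFrequency`) computes each IMF's analytic
signal by the frequency-domain Hilbert transform, from it the
instantaneous frequency, and an amplitude-weighted mean frequency. The
**cardiac component** is the sum of all IMFs holding the majority of
their spectral power inside the cardiac band. Summing, rather than
picking the single strongest IMF, matters near the low band edge: sifting
can split one physiological oscillation across adjacent IMFs (mode
mixing), and a single-IMF rule then loses beats (deletions) or admits
noise modes (insertions) — at 48 beats/min the single-IMF rule produced
heart-rate errors of several BPM in development, while the summed
component recovers the grid 48-120 beats/min to well under 1 BPM. When no
IMF passes the majority rule the strongest in-band IMF is used; when no
IMF is in band at all the signal holds no cardiac component and an error
is raised.

Heartbeat peaks (`reconstructPeaks`) are the local maxima of the cardiac
component, refined by quadratic interpolation of the three samples around
each maximum (sub-frame timing at 60 fps). The first and last second are
excluded as filter/decomposition edge artifacts. The implied beat-to-beat
rate is confined using the synthesized frequency: peaks closer than
`mergeFraction` (0.55) principal periods are merged, keeping the larger
amplitude. A beat-to-beat shortening below roughly half the principal
period is not physiological, and without this guard in-band noise riding
the oscillation inserts spurious beats at low heart rates. Peak times are
amplitude-invariant: rescaling the signal by any positive constant leaves
them unchanged.

## ECG reference branch

`detectRPeaks` is an energy detector in the Pan-Tompkins tradition:
band-pass 5-35 Hz, squared derivative, 150 ms moving-window integration,
adaptive threshold, 250 ms refractory period, and refinement of each
detection to the band-passed signal's local maximum within ±50 ms. Two
engineering details: the record is mirror-padded by one second before
filtering so beats at the very edges of the recording survive the filter
and integration transients, and the threshold is placed a fixed fraction
(0.3) of the way from the noise floor (25th percentile of the integrated
energy) to the beat level (99.5th percentile). A location/scale
statistic such as median + 3 MAD fails at high heart rates, where the
integration window's duty cycle approaches one half and the median no
longer estimates the noise floor; the quantile-based threshold retains
scale invariance (arbitrary voltage units) across the whole 40-180
beats/min range. All constants are exposed as arguments. The ECG sampling
rate defaults to 1000 Hz and is read from the input sidecar when present.

## HRV: Poincaré SD1/SD2

The Poincaré plot scatters \(RR_n\) against \(RR_{n+1}\). The package
computes, with sample (n-1) standard deviations throughout,

\[ SD1 = \tfrac{\sqrt2}{2}\, SD(RR_n - RR_{n+1}), \qquad
   SD2 = \sqrt{\,2\, SD(RR_n)^2 - \tfrac12\, SD(RR_n - RR_{n+1})^2\,}. \]

SD1 measures dispersion perpendicular to the identity line (short-term,
respiration-driven variability), SD2 along it (long-term variability),
and SD1/SD2 is the stress index: lower ratios indicate higher basal
stress. Heart rate is `60000 / mean(rri)` — beats per elapsed time, not a
mean of per-beat rates.

Two numerical notes. First, for short anti-correlated series the SD2
radicand can round below zero; it is clamped to zero and flagged, and the
ratio is `NA` whenever SD2 is zero. Second, SD1 is *identical* to the
standard deviation of the point cloud projected perpendicular to the
identity line — the same expression — whereas the closed SD2 formula
(full-series SD, as in the HRV literature) differs from the projection SD
along the identity line by a finite-sample \(O(1/n)\) term: by the
parallelogram law the two agree exactly only if the \(2\,SD(RR_n)^2\)
term is replaced by the summed variances of the two lagged subseries.
The closed formulas are primary here; the projection view is used as a
cross-check for SD1 and as an approximate one for SD2.

Intervals outside 250-2500 ms are flagged as physiologically implausible
but never silently dropped.

## Agreement statistics

`blandAltman` reports the mean difference (bias) and 95% limits of
agreement (bias ± 1.96 sample SD of the differences; the 1.96 normal
multiplier is fixed, with no small-sample t correction), plus the Pearson
correlation of the paired values. Differences are TOI minus ECG, and the
convention is recorded in every serialized report.

## What the synthetic generators emulate — and what they do not

`genRRI` builds beat times iteratively: \(t_0 = 0\),
\(RRI_n = 60000/\mathrm{hr} + A\sin(2\pi f_r t_n) + \varepsilon_n\),
\(t_{n+1} = t_n + RRI_n/1000\). The sinusoid emulates respiratory sinus
arrhythmia (RSA) — heart rate rising on inhalation, falling on
exhalation — at the breathing frequency \(f_r\) (default 0.25 Hz);
\(\varepsilon_n\) is white jitter (default SD 10 ms). The RSA depth
default is 40 ms; recovery experiments use 60 ms.

`genECG` renders each beat as a unit Gaussian R wave (SD 10 ms) with
smaller P and T bumps (amplitudes 0.15 and 0.3 at -180 ms and +250 ms;
SDs 25 and 50 ms, chosen as round physiological widths), plus white noise
specified directly or via a target SNR in dB.

`genFaceVideo` repeats a static face-like base image and embeds the pulse
by *bit flipping*: inside the embedded ROIs (default: forehead and both
cheeks) each target bit of the target channel (default: green bits 5-7)
is set with probability \(p(t)\cdot a\), where \(p(t)\) is a raised
cosine peaking at each beat and \(a\) is the embedding amplitude (default
0.6). This places the cardiac signal genuinely in specific bitplanes of
specific regions — the premise the selection stage rests on — while the
Bernoulli sampling itself contributes realistic shot-like noise. White
sensor noise and a slow illumination drift (default: 2-unit sinusoid at
0.05 Hz) are added in intensity space before requantization to 8 bits.
The remaining six ROIs receive noise only, which is what exercises ROI
selection. `noiseSdForSNR` converts a target per-pixel cardiac SNR in dB
into a noise SD from the expected intensity modulation of the embedding;
the heart-rate recovery experiments use 10 dB.

Defaults chosen once as the study conditions: 120 s recordings at 60 fps;
48 x 48-pixel frames, which give the nine proportionally-placed ROIs
pixel counts in the tens-to-hundreds so that ROI averaging buys a
realistic SNR gain; and a base image combining a skin-toned shading
gradient with a deterministic quasi-periodic texture. The texture
matters: real skin imagery varies at the pixel scale, so every bitplane
holds a mixed population of set and unset bits, whereas a smooth gradient
saturates whole bitplanes at 0 or 1 and leaves the embedding nothing to
modulate.

What the generator does **not** emulate: head motion and the resulting
ROI misalignment, lighting changes correlated across the face, camera
compression artifacts (the package reads lossless frame archives
precisely because lossy codecs perturb the low-order bitplanes),
melanin/hemoglobin radiative transfer, and any physiological pulse-shape
detail beyond beat timing. Passing the recovery tests therefore
demonstrates that the analysis chain is correct and self-consistent under
the stated signal model — not that it would survive motion or compression
on real footage.

## Problem sizes and run times

The validation suite runs five 120 s heart-rate-grid recordings (48, 60,
72, 90, 120 beats/min at 10 dB pixel SNR), five RSA-modulated recordings
at 60 ms depth with matched ECGs, three selection recordings plus an
8 x 8-pixel, 30 s toy problem where greedy selection is compared against
exhaustive search over all \(3^6\) sign assignments of six designated
bitplanes, and an ECG detector sweep over 40-180 beats/min at 20 dB.
These sizes keep a full run in the minutes range on a single core while
leaving every recovery margin meaningful; `scripts/acceptance.R` re-runs
the same study conditions from scratch with a caller-chosen seed.

## Known limitations

* Fixed ROI masks; no face tracking or motion compensation.
* One global bitplane weight set for all ROIs (whether the published
  method selects per-ROI sets is unstated).
* The SNR objective is a declared stand-in for the published
  contact-instrument training signal.
* Ensemble EMD variants are not implemented; severe mode mixing beyond
  what the summed in-band component absorbs would require them.
* The ECG branch assumes a single lead with upright R waves, as the
  synthetic templates produce.
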