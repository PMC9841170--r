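---
title: "EEG markers of brain-state-dependent lymphatic drainage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG markers of brain-state-dependent lymphatic drainage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Activation of the brain's lymphatic drainage system is associated with two
states in rodents: natural sleep and a reversible, sound-induced opening of
the blood--brain barrier (OBBB). Neither state can be monitored directly in a
living animal at scale, so the question becomes: which features of the
two-lead cortical EEG (plus nuchal EMG) discriminate wakefulness, sleep and
OBBB? This package implements the complete analysis chain used to answer
that question --- linear spectral measures, a non-linear cross-recurrence
index, wavelet-based oscillatory-event statistics, and a neural-network
similarity score --- together with a synthetic cohort generator that plays
the role of the animals, so that every stage of the chain can be verified
against known ground truth.

# The measures

**Spectral power and coherence.** Power spectral densities are Welch
estimates: 100-s segments with 50-s overlap, per-segment mean removal (no
detrending --- a linear detrend would corrupt the 0.1-Hz band of interest),
a Bartlett (triangular) taper against leakage, one-sided normalisation so
the integrated density equals the signal variance, and Daniell (unweighted
moving-average) frequency smoothing over 0.03-Hz windows. Since the FFT
length equals the 100-s segment, the grid spacing is 0.01 Hz and the
0.03-Hz/0.13-Hz Daniell windows are exactly 3 and 13 bins. The magnitude
coherence is

$$C(f) = \frac{|G_{xy}(f)|}{\sqrt{G_{xx}(f)\,G_{yy}(f)}} \in [0, 1],$$

with the auto- and cross-spectra segment-averaged and Daniell-smoothed over
0.13-Hz windows *before* the ratio is formed; a single raw periodogram would
give $C \equiv 1$ identically, so the smoothing order is the only consistent
reading of the estimator. Band summaries are trapezoidal integrals (power)
or unweighted bin means (coherence). Two delta conventions coexist in this
literature --- a wide 0--4-Hz band and a "slow" 0.1--0.5-Hz band --- and both
are provided as named bands (`delta_wide`, `delta_slow`) rather than
guessing which one a given number refers to.

**Sleep staging.** The visual scoring criteria are implemented as a rule
cascade on 10-s epochs: high EMG with more than 10% of spectral power at
8--12 Hz scores WAKE; otherwise delta (0--4 Hz) above 30% with low EMG
scores NREM; otherwise theta (5--10 Hz) above 20% with low EMG scores REM;
anything else inherits the previous epoch's label (the first epoch defaults
to WAKE). "Percent of waveforms per epoch" has no computable definition, so
it is interpreted as the spectral power fraction of the epoch periodogram.
"High/low EMG" is an epoch RMS above/below a threshold; the default is the
per-recording median, but for cohorts of single-state recordings (where a
within-recording median is degenerate) the pipeline uses the cohort-wide
median. Note that OBBB epochs, which combine sleep-like synchronised EEG
with low muscle tone, are classified NREM by these EEG-only rules even
though the animals are behaviourally awake --- which is precisely the
phenomenon the study is about; staging accuracy is therefore assessed on
wake and sleep recordings.

**Cross-recurrence analysis (CRA).** Both channels are band-pass filtered
(zero-phase Butterworth), decimated (anti-aliased) to an analysis rate,
z-scored and delay-embedded with a common delay (first minimum of the
autocorrelation, falling back to the first zero crossing) and dimension
(Kennel false-nearest-neighbour criterion, 1% threshold, capped at 6). The
cross-recurrence matrix marks pairs of trajectory points within
$\varepsilon$, chosen by default to fix the recurrence rate at 10% (the
distance quantile); a fixed-$\varepsilon$ mode exists. From the diagonal
line-length histogram we report RR, DET, L, ENTR (the standard recurrence
quantification set, substituted for unavailable bespoke definitions and
labelled as such) and MDL, the maximal diagonal length --- the longest
stretch of jointly recurrent dynamics, in samples at the analysis rate.
Indices are computed per 100-s window and averaged per subject;
$l_{\min} = 2$ and no Theiler exclusion (cross recurrences between different
signals need none). The analysis rates default to 25 Hz for the theta band
and 10 Hz for delta, keeping 100-s windows tractable.

**Wavelet patterns.** The continuous Morlet transform
($\omega_0 = 6$, the field default for EEG rhythms) is computed by FFT with
an energy normalisation that makes the time-averaged power of white noise
flat in frequency; the cone of influence is annotated. The *skeleton* is
the set of ridges: per-column local maxima across frequency linked through
time when they stay within one frequency step. Oscillatory patterns in a
band are maximal ridge segments above a power floor; their durations $T$
are the headline statistic. The floor is $k$ times the per-voice median
power, bounded below by $k$ times the pooled in-band median --- the
per-voice form prevents leakage from strong neighbouring bands (delta into
the low theta voices) from masking theta events, and the pooled bound
prevents voices with little background from admitting arbitrarily weak
tails. The power surface is smoothed over 0.3 s in time, gaps shorter than
0.3 s are merged, and events shorter than two cycles of the band centre are
discarded. With $k = 2.5$ these choices were calibrated against generator
ground truth: the recovered mean duration matches the injected mean within
a few percent for both broadband and narrowband theta ($k = 2$ overshoots
by roughly 20%, $k = 3.5$ truncates short events).

**SNR features and the similarity network.** The feature series is the
windowed signal-to-noise ratio $\mathrm{SNR} = \bar X / s_X$ (sample mean
over sample standard deviation, $n-1$ denominator) over 60-s windows
advanced in 1-s steps --- 120,000 samples per window at the native 0.0005-s
step. Ninety consecutive SNR values (1.5 min) form one input fragment for a
multilayer perceptron with layers 90--500--50--500--50--1: sigmoid hidden
units, linear input and output, the output hard-clamped to $[0,1]$ at
inference. Training minimises binary cross-entropy through a sigmoid on the
output unit (the bounded-linear-output description is reconciled by
training through the sigmoid and clamping at inference), full-batch Adam,
at most 200 epochs with plateau early stopping; inputs are standardised
with training-set statistics stored in the model. Under the leave-one-subject
protocol a detector is trained per subject on that subject's OBBB (positive)
versus wake (negative) fragments and evaluated on all other subjects;
$C_s$ is the fraction of fragments scored above 0.5. Training fragments are
cut with a 15-value stride (a single 600-s record yields too few
non-overlapping fragments to train a 90-input network), while evaluation
fragments stay non-overlapping so the per-network $C_s$ values are
comparable; the summary reports mean $\pm$ SEM over the trained networks.
The printed definition of $C_s$ as a ratio of similar to dissimilar counts
cannot be a fraction of the data (it exceeds 1 whenever more than half the
fragments are similar); the prose meaning --- the *part* of fragments
recognised as similar --- is implemented as `compute_cs()`, and the literal
count ratio is exposed separately as `cs_count_ratio()`.

**Surrogate and group statistics.** Coupling measures are tested with
amplitude-adjusted Fourier transform (AAFT) surrogates: rank-remap to a
Gaussian, phase randomisation, rank-remap back --- the surrogate is a
permutation of the original samples (exact amplitude preservation) with an
approximately preserved periodogram. One AAFT iteration is used, as in the
original formulation; no iterative refinement. The one-sided p-value is
$(1 + \#\{\text{surrogate} \ge \text{observed}\})/(n_{\text{surr}} + 1)$,
which cannot be zero. Group contrasts use the two-sided
Mann--Whitney--Wilcoxon test (exact for groups of at most 8 without ties),
and summaries are mean $\pm$ SEM. No multiple-testing correction is applied,
matching the source analysis; this is a deliberate reporting convention,
not an oversight.

# The synthetic cohort generator

Because no recordings are deposited, the generator is a first-class module:
it emulates three-state rat EEG/EMG with *known* injected values for every
quantity the pipeline measures. Each state is a superposition of
band-limited Gaussian processes (spectral synthesis with exact unit-variance
normalisation) plus a $1/f$ background, at the native 2000-Hz rate by
default (configurable; the analyses in the test-suite run at 200--250 Hz,
since all EEG content lies below 12.5 Hz).

The published group means are the injected targets: theta-band coherence
0.68 (wake), 0.52 (sleep), 0.53 (OBBB); measured 0.1--0.5-Hz band power
4.91, 3.84, 11.85 units$^2$; mean theta-burst durations 1.47, 1.18, 1.16 s.
Structural choices that the publication does not (and cannot) pin down were
made once, on physiological grounds, and then frozen:

* **Synchrony.** Wakefulness is desynchronised: its delta components are
  mostly independent between the two leads (15% shared) and its residual
  0.08--0.12-Hz slow oscillation is lead-independent. Sleep and OBBB are
  synchronised (80% and 85% shared delta); OBBB additionally carries the
  strong *shared* 0.08--0.12-Hz oscillation (variance 16 units$^2$) that is
  its published hallmark. These choices are what make the delta-band MDL
  ordering (OBBB > sleep > wake) emerge mechanically: shared, regular slow
  components keep the two embedded trajectories evolving together.
* **Theta structure.** Theta occurs in bursts (shifted-exponential
  durations with a 0.4-s minimum --- an oscillatory event needs a couple of
  cycles to exist --- and a 2-s mean inter-burst gap in every state, so
  states with longer bursts do not also get longer quiet periods, which
  would leak into the recurrence statistics). Bursts are synchronous across
  leads and carry the inter-lead coherence; the inter-burst theta floor is
  lead-independent. Burst carriers are broadband 4--8 Hz in *every* state,
  so wavelet event detection behaves identically across states; the
  state-specific regularity lives in the quiet floor, which is 95%
  narrowband (5.85--6.15 Hz) for sleep/OBBB and fully broadband for wake.
  A narrow floor decorrelates slowly, so chance alignments of the two
  independent floors persist --- this is what produces the theta-band MDL
  ordering (sleep $\approx$ OBBB > wake) even though wakefulness has the
  *higher* linear coherence, reproducing the study's key dissociation
  between the linear and non-linear coupling measures.
* **Infra-slow activity.** A 0.005--0.03-Hz component with variance 0.08
  (wake), 2 (sleep) and 4 (OBBB) units$^2$ drives the SNR features: the
  60-s-window means fluctuate with the very-low-frequency power, so the
  SNR fragment distributions of sleep and OBBB resemble each other and
  differ from wake --- the structure the similarity network learns. The
  $1/f$ background is flattened below a 0.05-Hz knee so that this band
  belongs to the state-dependent component rather than to the common
  background.
* **Calibration constants.** The theta mixing coefficient is solved
  analytically from flat-spectrum band-average formulas and corrected by an
  empirically measured attenuation constant per profile (the burst envelope
  spectrally broadens the narrow components, which the flat-spectrum
  algebra cannot capture); the delta-slow component variance is solved so
  the *measured* Welch--Daniell band power hits the published value,
  accounting for the half-in-band slow oscillation and the background.
* **Between-subject variability.** Coherence and delta-slow power jitter
  use the published SEMs scaled to SDs ($\mathrm{SD} = \mathrm{SEM}\sqrt 7$).
  For burst durations that choice would make the wake--sleep contrast only
  marginally detectable at desk scale (the published SEM already contains
  the study's own estimation noise over far longer recordings), so burst
  means and EMG tone use a 5% coefficient of variation.
* **EMG.** White noise with RMS 3.0 (wake), 1.0 (sleep), 1.2 (OBBB);
  amplitudes are arbitrary units throughout, since no physical scale is
  published.

Ground truth (injected coherence, expected band power, the burst interval
table, per-epoch stage labels) is returned with every recording, and
per-subject seeds derive from the master seed by an explicit integer-mixing
scheme (`mix_seed()`), not the host language's hash.

# What the synthetic cohorts do and do not show

The generator produces Gaussian, piecewise-stationary signals with linear
cross-lead coupling and amplitude-modulated narrowband events. It does not
model genuine neuronal nonlinearity, cross-frequency coupling,
non-stationary state transitions within a recording, artefacts, volume
conduction, or tracer/permeability dynamics (explicit non-goals). Passing
the recovery tests therefore demonstrates that the *estimators* are
implemented correctly and that the advertised contrasts are detectable at
the published effect sizes and group size (n = 7) --- not that real rat EEG
has these properties.

# Numerical choices and degenerate inputs

Welch estimation refuses records shorter than one window; coherence refuses
the degenerate single-segment/no-smoothing case (which would force
$C \equiv 1$). Daniell bandwidths below the grid spacing are errors. The
recurrence-rate policy computes the distance quantile exactly up to $2^{21}$
pairs and by a deterministic stride sample (about $5\times10^5$ values,
quantile standard error below 0.05% RR) above; distances switch to single
precision there. All-zero recurrence matrices yield all-zero indices by
convention. Constant signals are rejected wherever a quantity is undefined
(autocorrelation delay, AAFT, SNR windows with zero variance). The EDF
writer auto-scales each channel's physical range, so round trips are exact
only to 16-bit quantisation; the CSV dialect is lossless. All simulations
in the test-suite use 600-s records, n = 7 per state and 20 replicate
cohorts for the contrast-recovery checks, with analysis rates of 25 Hz
(theta CRA), 10 Hz (delta CRA) and 25 Hz (wavelet patterns); these problem
sizes are stated here as the package's chosen verification scale.

# Known limitations

* The MDL magnitudes depend on the analysis rate and window length and are
  reported in samples at the analysis rate; published values without units
  cannot be compared numerically, only through their orderings.
* The rule-based scorer has no REM-rich default profile; REM rules are
  exercised by construction rather than by cohort-level recovery.
* The similarity network's absolute $C_s$ level depends on training-set
  size and the similarity threshold; orderings are robust, absolute levels
  are convention-dependent.
* The literal similar/dissimilar count ratio form of $C_s$ is exposed but
  not used in summaries, for the reason given above.
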