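# ldsbeeg

EEG markers of brain states linked to activation of the brain's lymphatic
drainage system. In rodents, two conditions activate this clearance route:
natural (NREM-dominated) sleep and a reversible, sound-induced opening of
the blood–brain barrier (OBBB). `ldsbeeg` implements the complete signal
analysis chain that discriminates wakefulness, sleep and OBBB from two-lead
cortical EEG plus nuchal EMG, and a seeded synthetic cohort generator with
recorded ground truth so every stage can be verified without animal data.

The package is aimed at researchers analysing rodent (or comparable)
polysomnographic recordings who need the full tool chain in one place:

* **Spectra and coherence** — Welch power spectral density (100-s segments,
  50-s overlap, Bartlett taper) with Daniell frequency smoothing, band
  power, and the magnitude coherence
  `C(f) = |Gxy(f)| / sqrt(Gxx(f) Gyy(f))` with the spectra smoothed before
  the ratio (`welch_psd()`, `daniell_smooth()`, `band_power()`,
  `coherence()`, `band_coherence()`).
* **Sleep staging** — a rule-based 10-s-epoch scorer implementing the
  visual criteria (WAKE: high EMG and >10% power at 8–12 Hz; NREM: delta
  0–4 Hz >30% with low EMG; REM: theta 5–10 Hz >20% with low EMG)
  (`score_recording()`).
* **Cross-recurrence analysis** — Takens delay embedding (autocorrelation
  delay, false-nearest-neighbour dimension), cross-recurrence matrices at a
  fixed 10% recurrence rate, and the diagonal-line indices RR, DET, L,
  ENTR and MDL — the maximal diagonal length, the headline non-linear
  coupling index (`cra_band_index()`, `cra_scan()`, `cra_indices()`).
* **Wavelet patterns** — Morlet continuous wavelet transform, skeleton
  (ridge) extraction, and oscillatory-event detection yielding per-band
  pattern durations T (`cwt()`, `skeleton()`, `detect_patterns()`,
  `band_patterns()`).
* **SNR features and a similarity network** — windowed signal-to-noise
  ratio (60-s windows, 1-s steps), 90-value fragments, a 90-500-50-500-50-1
  perceptron trained per subject (OBBB vs wake), and the Cs statistic: the
  fraction of fragments the network recognises as OBBB-like
  (`snr_series()`, `train_detector()`, `leave_one_subject_protocol()`).
* **Statistics** — AAFT surrogate significance testing for coupling
  measures, exact Mann–Whitney–Wilcoxon group contrasts, mean ± SEM
  summaries (`aaft_surrogate()`, `surrogate_test()`, `mww_test()`).
* **Synthetic cohorts** — three-state rat-like EEG/EMG with injected
  theta coherence, band powers, burst durations and stage labels
  (`default_profiles()`, `generate_recording()`, `generate_cohort()`), and
  an end-to-end pipeline (`run_pipeline()`). Recordings read/write as CSV
  or EDF (`read_recording()`, `write_recording()`).

## Worked example

Simulate one sleep-state recording and push it through the main measures:

```r
library(ldsbeeg)
profiles <- default_profiles(0.004)                  # 250-Hz demonstration rate
rec <- generate_recording(profiles$sleep, length_s = 600, seed = 42,
                          sampling_interval_s = 0.004)

x <- rec$recording$samples[, "EEG-L"]
y <- rec$recording$samples[, "EEG-R"]

band_coherence(coherence(x, y, 0.004), "theta")
#> theta coherence: 0.514 (injected: 0.52)

band_power(daniell_smooth(welch_psd(x, 0.004), 0.03), "delta_slow")
#> 0.1-0.5 Hz band power: 3.82

cra_band_index(x, y, 0.004, "theta")[, c("RR", "DET", "L", "MDL", "ENTR")]
#>       RR  DET   L  MDL ENTR
#> 1 0.0995 0.24 5.9 54.8 2.47

pats <- band_patterns(x, 0.004, "theta")
mean_duration(pats)
#> theta patterns: 161 events, mean T = 1.07 s (injected: 1.18 s)

table(score_recording(rec$recording, emg_threshold = 2)$label)
#> NREM
#>   60
```

The coherence lands on the injected 0.52 target, the 0.1–0.5 Hz band power
on the injected 3.84 units², the wavelet pattern durations near the
injected 1.18-s burst mean, and all sixty 10-s epochs score NREM — the
generated state. `run_pipeline()` does this for a whole cohort (by default
7 subjects in each of the three states), adds the leave-one-subject
network protocol, and writes per-subject metrics, group summaries and
Mann–Whitney contrasts as CSV tables with a checksummed manifest.

A thin command-line front end is included at `inst/cli/ldsb-eeg.R`
(`simulate`, `report` and `convert` subcommands over a YAML configuration).

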