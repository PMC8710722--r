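# flickerstates

EEG microstate and complexity analysis under rhythmic visual stimulation.

`flickerstates` is an R package for neurophysiologists analysing
multichannel scalp EEG recorded at rest and under visual flicker — in
particular 40 Hz ("low gamma") flicker, whose cortical entrainment is being
explored as a non-invasive intervention for brain disease. It implements
the full sensor-space pipeline:

* **Preprocessing** — common average reference
  (`V_i^CAR = V_i − (1/N)Σ_j V_j`), zero-phase Butterworth band-pass
  (0.1–100 Hz) and 50 Hz notch filtering, epoching, 1.5×IQR outlier
  screening.
* **Spectral power** — multitaper PSD (DPSS tapers), absolute band power
  `a_f = ∫ S(f) df`, relative (percent) power `r_f = a_f / T` with
  `T` the 0.1–100 Hz total, aggregated over the scalp regions
  F, FC, C, CP, P, PO, O (and mastoids M); decibels `L_dB = 10·log10 L`.
* **Microstates** — global field power
  `GFP(t) = sd_channels(x(t))` (population denominator), topographic maps
  at GFP peaks, polarity-invariant modified k-means (assignment by maximal
  squared spatial correlation, template update by dominant eigenvector),
  K = 4 classes, back-fitting by `argmax_k |corr(x_t, T_k)|`, reassignment
  of segments < 30 ms, and global explained variance
  `GEV = Σ_t (GFP_t·corr_t)² / Σ_t GFP_t²`.
* **Dynamics** — per-class coverage, mean duration, occurrence; Markov
  transition matrices with self-transitions (per sample; 2 ms resolution
  at 500 Hz) and without (per segment); Lempel–Ziv LZ76 complexity of the
  0–3 label sequence after epoch-length equalization.
* **Statistics** — Shapiro–Wilk / Kolmogorov–Smirnov normality screens,
  one-way ANOVA, two-stage Benjamini–Krieger–Yekutieli FDR per comparison
  family, Tukey HSD for transition probabilities.
* **Synthetic ground truth** — a generator that plants K template
  topographies switching as a semi-Markov process on an alpha-band
  carrier, an occipitally weighted 40 Hz SSVEP, and 1/f noise, so that
  every stage can be validated against a known answer.

## Worked example

Synthesize one minute of 64-channel EEG with four planted microstate
classes at SNR 5, then recover the microstate structure:

```r
library(flickerstates)

cfg <- synthetic_config(duration = 60, snr = 5, seed = 42)
sim <- synthesize_eeg(cfg)
rec <- common_average_reference(sim$recording)
rec
#> <eeg_recording> SYN / synthetic: 64 channels x 30000 samples @ 500 Hz (60.0 s)

g <- global_field_power(rec)
peaks <- find_gfp_peaks(g)
model <- relabel_states(
  modified_kmeans(t(rec$data[, peaks]), n_states = 4, seed = 1,
                  gfp = g[peaks]))
model
#> <microstate_model> K=4 over 64 channels, GEV=0.976

labels <- reject_short_segments(backfit(model, rec), min_duration = 30)
labels
#> <label_sequence> 30000 samples @ 500 Hz, K=4, 906 segments

compute_metrics(labels)
#>   class coverage mean_duration occurrence
#> 1     0    0.241          64.7       3.72
#> 2     1    0.243          66.8       3.63
#> 3     2    0.246          64.1       3.83
#> 4     3    0.271          69.1       3.92

lz76_complexity(labels)$lzc
#> [1] 482
```

The GEV of 0.976 says the four fitted templates explain nearly all
GFP-weighted topographic variance; coverages near 0.25 and durations near
the planted 60 ms mean show the planted dynamics are recovered (the
generator drew uniform transitions, so the segment-level transition matrix
is flat at ≈ 1/3 off the diagonal). Each recovered template matches a
distinct planted template with |spatial correlation| > 0.99.

The full experiment — simulate three conditions (rest, random flicker,
40 Hz flicker) for ten subjects, run spectral, microstate, dynamics and
statistics stages, and write all tables as CSV — is one call:

```r
report <- run_pipeline(default_run_config(seed = 1), output_dir = "out")
report
#> <run_report> 10 subjects x 3 conditions, K=4, GEV=0.864, 107.43s
```

`out/stats_results.csv` then contains, per family, the omnibus ANOVA and
the BKY-adjusted pairwise comparisons; with the default configuration the
39–41 Hz percent power in the O, PO and P regions is significantly higher
under 40 Hz flicker than at rest (adjusted P < 0.05), with a much weaker
anterior elevation — the same qualitative pattern reported for real
recordings.

A thin command-line front end with `simulate`, `preprocess`, `psd`,
`microstates`, `dynamics`, `stats`, `run-all` and `validate-config`
subcommands ships at `inst/scripts/flickerstates`.

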