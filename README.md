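# spikedec

Single-neuron decoding of tactile stimulation patterns from
trial-structured spike trains.

`spikedec` is for electrophysiologists who record single neurons while a
fixed set of spatiotemporal tactile (electrotactile) stimulation patterns
is delivered repeatedly, and who want to quantify how well each neuron's
spike responses identify which pattern was presented. The package
implements the complete analysis chain used in somatosensory decoding
studies — eight patterns over four skin-electrode channels, 100 trials per
pattern — together with the spike-shape, firing-regularity and
response-latency metrics that accompany it, and a synthetic spike-train
generator with known ground truth so every stage can be validated without
recorded data.

## The method

For one neuron with spike times grouped by (pattern, trial):

* **Decoding performance.** Each trial's spike train (1,000 ms window) is
  convolved with a causal exponential kernel
  *k(t) = τ⁻¹ e^(−t/τ)*, τ = 5 ms. Per iteration, responses are split
  half/half into training and test sets; each set is bootstrap-resampled
  per pattern (each bootstrapped response is the sum of *N* resampled
  responses, *N* = group size, 200 replicates per pattern); principal
  components explaining 95% of the training variance are extracted;
  responses are projected by least squares; and each test response is
  classified by relative majority among its *k* = 9 nearest training
  responses. Fifty iterations are averaged into a confusion matrix, scored
  by macro F1 (precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = their
  harmonic mean). Chance for eight patterns is 12.5%.
* **Shuffled-label null.** The identical pipeline re-run with pattern
  labels permuted gives each neuron's chance score; a population's
  mean + 2 SD of shuffled scores is the threshold above which a neuron
  counts as an above-chance decoder.
* **Response latency.** A PSTH (2 ms bins; 500 ms over all 800 pattern
  trials, or 300 ms over 400 single-pulse trials, normalised per trial) is
  compared against spontaneous activity: the latency is the first of two
  consecutive bins strictly exceeding the spontaneous mean + 2 SD.
  Latencies ≤ 10 ms are flagged as compatible with direct brainstem-relay
  input. Bin widths of 5 and 10 ms are supported for sensitivity analysis.
* **Spike metrics.** From waveforms: half-height amplitude and duration and
  10%-to-peak rise time on the filtered mean spike shape. From intervals:
  CV, mean CV2 and the firing regularity (log of the maximum-likelihood
  gamma shape), plus the mean firing frequency.

See the methods vignette (`vignettes/decoding-methods.Rmd`) for the model
the synthetic generator implements and every numerical choice.

## Worked example

```r
library(spikedec)

protocol <- stim_protocol(seed = 42)          # 8 surrogate patterns, 4 channels
neuron   <- neuron_model(baseline_rate_hz = 10, separability = 1.5,
                         response_latency_ms = 14)
ts  <- simulate_neuron(protocol, neuron, seed = 42, spontaneous_s = 60)
ts
#> <trial_set> neuron 'sim1': 8 patterns x 100 trials, 19188 spikes
#>   analysis window 1000 ms; 33 spontaneous segments (1800 ms each)

cfg <- decoding_config(n_bootstrap_per_pattern = 100, n_iterations = 10,
                       seed = 42)
decode_patterns(ts, cfg)
#> <decoding_result> macro F1 = 100.0% (8 patterns, 10 iterations)
#>   mean retained components: 19.3

shuffled_null(ts, cfg)
#> <decoding_result> [shuffled labels] macro F1 = 14.0% (8 patterns, 10 iterations)
#>   mean retained components: 117.2

estimate_latency(ts, "pattern")[, 1:5]
#> # A tibble: 1 × 5
#>   neuron_id stim_type latency_ms identified threshold
#>   <chr>     <chr>          <dbl> <lgl>          <dbl>
#> 1 sim1      pattern           24 TRUE          0.0477

regularity_metrics(ts)
#> # A tibble: 1 × 6
#>   neuron_id n_isis    cv cv2_mean firing_regularity firing_frequency_hz
#>   <chr>      <int> <dbl>    <dbl>             <dbl>               <dbl>
#> 1 sim1         560 0.897     1.02            0.0218                9.98
```

The simulated neuron responds to each pattern with pattern-specific
rate bumps (separability 1.5), so the decoder identifies every test
response correctly (F1 = 100%), while its shuffled null sits near the
12.5% chance level. Its spontaneous firing is Poisson-like (CV ≈ 1,
regularity ≈ 0) at ~10 Hz, and its PSTH first exceeds the spontaneous
mean + 2 SD criterion 24 ms after pattern onset (the first pulse of this
surrogate pattern set falls ~10 ms into the pattern, plus the neuron's
14 ms response latency). `tidy()`, `glance()` and `autoplot()` views are
available for every result object, and `run_pipeline()` chains
simulate → decode → latency → summarise for a whole cohort
(`inst/scripts/spikedec-cli.R` wraps it for the shell).

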