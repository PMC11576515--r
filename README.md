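# erpdeconv

Tools for separating overlapping stimulus-locked and response-locked
activity in event-related EEG — and for demonstrating how their overlap can
masquerade as something it is not.

## The problem

In decision tasks, EEG contains stimulus-locked transients (e.g. a parietal
positivity ~350 ms after the options appear, scaling with how positively
the choice set is appraised) and response-locked activity (scaling with
choice difficulty). The response trails the stimulus by a variable response
time (RT), so the two overlap by an RT-dependent amount. Averaging
response-locked epochs then smears the stimulus transient across the
pre-response window: for fast trials the result is a ramp rising to a peak
near the response, steeper when RTs are shorter, and with larger
pre-response amplitude on slow trials — precisely the classic signature of
an evidence-accumulation process, produced here without any accumulation
signal at all.

`erpdeconv` implements the full chain needed to produce, detect and remove
this artefact under known ground truth:

* **synthetic data** — per-trial behavioural measures from a two-construct
  latent model (appraisal, choice difficulty), continuous EEG assembled
  from placed component kernels with stored ground truth, and
  drift-diffusion accumulator traces with uniform stimulus/motor
  non-decision jitter;
* **construct scoring** — min–max normalization, permutation-tested PCA
  dimensionality (95th percentile of 1,000 column shuffles),
  Kaiser-normalized varimax rotation, trial-wise appraisal/choice scores;
* **regression ERPs** — mass-univariate OLS of single-trial voltages per
  channel × time point with missing-data masking, t-maps, predicted-ERP
  terciles, RT-sorted ERP images, median-split averages;
* **cluster statistics** — group-level spatiotemporal cluster-mass
  permutation tests (forming threshold p = 0.005, participant sign-flips,
  two-sided 2.5% max-mass tails);
* **deconvolution** — FIR/stick-basis time expansion of stimulus and
  response events into a sparse design, joint least-squares kernel
  estimation, ±250 µV artefact-interval exclusion, optional RT modulation
  of stimulus regressors, and overlap-corrected recordings.

The model at its core: with per-trial covariates x collected in a
time-expanded design matrix **X** (one column per event type × predictor ×
latency bin), the continuous recording **y** per channel is modelled as
**y** = **X**β + ε, so β unfolds into one FIR kernel per event type and
predictor. Because RT varies across trials, the stimulus and response
blocks of **X** are linearly independent and the overlapping kernels are
jointly identifiable — event-locked averaging is the special case of
isolated events.

## Worked example

Overlap-only data (stimulus transient only, no response component, no
ramp), fast-RT regime, analysed response-locked and then deconvolved:

```r
library(erpdeconv)
set.seed(2026)

beh <- simulate_trial_measures(behaviour_config(
  n_trials = 300, n_participants = 1,
  rt_shift = 0.25, rt_meanlog0 = -0.4, rt_sdlog = 0.45, rt_cap = 2))
cfg <- eeg_sim_config(srate = 100, appraisal_gain = 0,
                      resp_base = 0, choice_gain = 0, noise_sd = 2)
sim <- simulate_recording(beh$measures, beh$latents, cfg)

ep <- epoch_events(sim$recording, sim$events, "response", c(-1.5, 0.3))
ms <- median_split_average(ep, rt_max = 1.25)
pz <- match("Pz", ep$channel_labels)
cat(sprintf("fast trials (n=%d, mean RT %.2f s): peak at %+.2f s\n",
            ms$n_fast, mean(ms$rt_fast),
            erp_peak(ms$fast[pz, ], ep$times, c(-1.4, 0.2),
                     ms$coverage_fast[pz, ])))
cat(sprintf("slow trials (n=%d, mean RT %.2f s): peak at %+.2f s\n",
            ms$n_slow, mean(ms$rt_slow),
            erp_peak(ms$slow[pz, ], ep$times, c(-1.4, 0.2),
                     ms$coverage_slow[pz, ])))

spec <- event_design_spec(
  stimulus = list(window = c(-0.2, 0.8)),
  response = list(window = c(-1, 0.3)), srate = 100)
fit <- solve_deconv(time_expand(sim$events, spec,
                                ncol(sim$recording$data)),
                    sim$recording)
cat(sprintf("deconvolved response kernel max |amplitude| at Pz: %.2f uV\n",
            max(abs(fit$kernels$response[1, , pz]))))
cat(sprintf("deconvolved stimulus kernel peak at Pz: %.2f uV at %.2f s\n",
            max(fit$kernels$stimulus[1, , pz]),
            kernel_times(fit, "stimulus")[
              which.max(fit$kernels$stimulus[1, , pz])]))
```

Output:

```
fast trials (n=145, mean RT 0.58 s): peak at -0.27 s
slow trials (n=145, mean RT 0.90 s): peak at -0.47 s
deconvolved response kernel max |amplitude| at Pz: 0.31 uV
deconvolved stimulus kernel peak at Pz: 10.00 uV at 0.35 s
```

Read: in the naive response-locked averages both RT groups show a
pre-response peak, and it sits further from the response for slower trials
(−0.27 s vs −0.47 s — the smeared stimulus transient at ~0.35 s minus the
group's mean RT), mimicking accumulation. The joint deconvolution assigns
essentially everything to the stimulus kernel (10 µV, peaking at 0.35 s,
the generative truth) and leaves a response kernel at noise level
(0.31 µV).

Higher-level drivers reproduce the three packaged demonstrations with
provenance-logged reports:

```r
run_overlap_artefact(experiment_config("overlap_artefact", seed = 11))
run_deconv_rescue(experiment_config("deconv_rescue", seed = 1))
run_ddm_assignment(experiment_config("ddm_assignment", seed = 3))
```

A thin command-line front end over the same functions ships in
`inst/cli/erpdeconv` (subcommands `simulate`, `score-pca`, `rerp`,
`deconvolve`, `correct-overlap`, `cluster-test`, `experiment`).

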