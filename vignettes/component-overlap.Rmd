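---
title: "Component overlap, regression ERPs and deconvolution: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Component overlap, regression ERPs and deconvolution: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpdeconv)
```

# The problem

Event-related EEG during decision making contains at least two families of
activity: transients locked to stimulus onset (e.g. a parietal positivity
peaking roughly 350 ms after the options appear, modulated by how positively
the choice set is appraised) and activity locked to the response (modulated
by choice difficulty). Because the response follows the stimulus by a
variable response time (RT), the two families overlap, and the *amount* of
overlap covaries with RT. Averaging response-locked epochs therefore mixes a
stimulus transient into the pre-response window in an RT-dependent way: for
fast trials the smeared transient looks like a ramp rising to the response,
steeper when RTs are shorter — exactly the qualitative signature usually read
as neural evidence accumulation. `erpdeconv` provides (i) a synthetic-data
generator in which the true components are known, (ii) the standard analysis
chain (construct scoring, mass-univariate regression ERPs, cluster-mass
permutation inference), and (iii) an FIR deconvolution that models stimulus-
and response-locked kernels jointly, so the artefact can be produced,
detected and removed under controlled conditions.

# The synthetic generator

## Behaviour

Two standard-normal latent constructs drive all eight trial measures:
appraisal $a$ (how positively the set is evaluated) and difficulty $c$.
Their correlation defaults to 0, emulating task designs that decorrelate
overall value and value difference by construction. The value structure is

* overall value $OV = 5 + 1.5a + \varepsilon$ (0–10 rating units),
* value difference $VD = 2.5 - 0.8c + \varepsilon$, clipped at 0
  (clipping affects well under 1% of trials at the defaults),
* item values $OV \pm VD/2$; the better item is chosen with probability
  $\mathrm{logit}^{-1}(VD)$, so accuracy rises with value difference;
  chosen/unchosen value follow deterministically,
* set salience $= |OV - \overline{OV}|$.

The three subjective ratings (liking on $a$; confidence negatively and
anxiety positively on $c$; loadings 0.8, noise sd 0.4) are reported on the
task's discrete 1–5 key-press scale (rounded and clipped). This matters for
the permutation-PCA criterion: with artificial continuous Gaussian ratings,
min–max normalization leaves the ratings with unrealistically small
variances, the independent salience measure then carries the third-largest
eigenvalue on its own, and rank-matched parallel analysis — which compares
the observed $k$-th eigenvalue with the null distribution of $k$-th
eigenvalues — flags it as a spurious third component. The discrete scale that
participants actually use puts the rating variances (and hence the null
eigenvalue floor) where real data have them. A `rating_scale = "continuous"`
switch retains the linear generator for analytic oracles.

RTs are shifted lognormal, $rt = 0.3 + \exp(0.74 - 0.08\,VD - 0.04\,OV +
0.35 z)$, truncated at the 4 s deadline (truncated trials become
"no response"). These values give a median RT near 1.7 s, a few permille of
no-responses, and a usable fast subset below 1.25 s, matching an unspeeded
value-based choice task. The overlap demonstrations use a faster regime
(shift 0.25 s, location $\log 0.5$, sdlog 0.45, 2 s cap; mean RT ≈ 0.75 s)
emulating the speeded tasks in which ramp-like response-locked averages are
classically reported. The default trial count, 4,637, is the pooled trial
count of the emulated study.

## EEG

Trials are laid out sequentially (stimulus, response after `rt`, then a
1.5 s intertrial interval). Components are placed kernels:

* stimulus kernel: Gaussian-windowed half-sine positivity, peak 0.35 s,
  width 0.4 s, base amplitude 10 µV, per-trial amplitude
  `stim_base + appraisal_gain * a`, parietal topography;
* response kernel: biphasic (one windowed sine cycle, ±0.3 s), amplitude
  `resp_base + choice_gain * (-c)` so easier trials are larger,
  frontocentral topography;
* optional linear accumulation ramp from 0.2 s post-stimulus to a peak at
  the response (then a 0.1 s fall), for positive controls;
* white Gaussian noise (default 10 µV; optional $1/f^\alpha$ shaping).

Kernel shapes are pluggable; nothing downstream assumes them. The ground
truth stores every placement plus the noise realization, and
`reconstruct_ground_truth()` reproduces the recording exactly, which is the
basis of most oracle tests. Setting the response base, choice gain and ramp
to zero yields *overlap-only* data: any response-locked structure found
downstream is then attributable to stimulus overlap alone.

What the generator does **not** emulate: eye/muscle artefacts, volume
conduction from a head model, channel covariance of real noise, drifts, or
non-stationary RT dependence of component shape. Passing tests therefore
show that the analyses behave correctly under the stated generative model,
not that real data are this clean; the preprocessing the pipeline assumes
(referencing, 40 Hz low-pass, ocular correction) is an input contract.

## Accumulator traces

`simulate_ddm()` integrates a symmetric drift-diffusion model (bounds 0 and
$a$, start $a/2$) by Euler–Maruyama, with uniformly jittered non-decision
times on both ends: accumulation starts $t_s \sim U(0,\texttt{stim\_jitter})$
after the stimulus and the response follows absorption by
$t_m \sim U(0,\texttt{motor\_jitter})$. Drift/bound/noise defaults
(1.5 or 0.7, 1, 0.8) are package choices giving decision times of
0.3–0.4 s; they are exposed as configuration because the emulated
simulations do not publish theirs. Two numerical choices make the simulator
test-sharp: the bound-crossing time is linearly interpolated within the
crossing step (so the noise-free first-passage time $(a/2)/v$ is exact), and
the absorbing bounds are shrunk by the standard continuity correction
$0.5826\,s\sqrt{dt}$, which removes the $O(\sqrt{dt})$ discretization bias;
the simulated mean decision time then matches the closed form
$(a/2v)\tanh(av/2s^2)$ within Monte-Carlo error.

# Construct scoring

The eight measures are min–max normalized to $[0,1]$ (the bounds are stored
for provenance), PCA is computed on the covariance of the normalized data —
range normalization is itself the variance calibration, so covariance rather
than correlation is the default, with `use = "cor"` available — and the
number of components is chosen by permutation: each of 1,000 null datasets
shuffles every column independently, and component $k$ is retained iff its
observed eigenvalue exceeds the 95th percentile of the null $k$-th
eigenvalues. Retained loadings (eigenvectors scaled by component sd) are
rotated with Kaiser-normalized varimax, and trial scores are the centred
normalized data times the rotated loadings. Components are labelled by
convention: appraisal is the component loading most on liking (sign fixed
positive on liking), choice is the other (sign fixed so confidence loads
negatively, i.e. larger score = harder trial).

# Regression ERPs and displays

`fit_mass_univariate()` runs ordinary least squares independently at every
channel × time point, using only trials unmasked at that point (out-of-trial
samples — post-response in stimulus-locked epochs, pre-stimulus in
response-locked epochs — are set missing at epoching to prevent spill-over).
Coefficients are also reported as t-values ($\beta/SE$, df $= n - p$), the
form in which they enter group-level cluster tests, which shrinks unreliable
estimates toward zero. Display helpers implement the standard diagnostics:
predicted ERPs at within-tercile predictor means, RT-sorted single-trial
images with per-row event markers, and median-split averages with
stimulus-onset histograms. The artefact is visible in all three: single-trial
positivities track the stimulus diagonal; average peaks sit near
$0.35 - \overline{rt}$ before the response and march away from it as RT
grows.

# Cluster-mass permutation inference

Group inference is a one-sample t-test across participants at each point,
clustered at a two-tailed forming threshold of p = 0.005, with cluster mass
the sum of |t| over members connected through neighbouring channels at the
same sample or adjacent samples at the same channel (polarities never merge;
diagonal links are off by default). The null is built from 1,000 random
whole-participant sign flips, recording the maximum cluster mass per
polarity; an observed cluster is significant iff its mass exceeds the top
2.5% of its polarity's null (a two-sided 5% test), and its p-value is the
inverted percentile rank divided by 100 and doubled, floored at
$2/n_{perm}$. Two points were genuinely open and are package decisions:
the permutation scheme (participant sign-flipping, the standard one-sample
scheme) and the electrode neighbourhood, which no cluster method defines for
you — we use distance-threshold neighbours on template 10-20 unit-sphere
coordinates, threshold 0.7 (median 4 neighbours), both configurable.
Zero-variance points are excluded from cluster formation rather than set to
±∞.

# FIR deconvolution

`time_expand()` builds the stick-basis design: for each event (stimulus,
response) and each latency bin of its window (default ±2 s, one bin per
sample), the row at `event_sample + latency` carries the predictor value.
Estimating all kernels jointly by least squares separates overlapping
responses because RT variability makes the stimulus and response designs
linearly independent. Continuous covariates are mean-centred within event
type, so intercept kernels are average waveforms; trials without a response
contribute stimulus events only. Samples exceeding ±250 µV on any channel
are dropped from the fit (rows ignored, mask recorded).

The default solver forms the normal equations — sparse and band-limited for
stick designs — and factorises them with a sparse Cholesky decomposition,
which is exact, deterministic and fast at these problem sizes; an iterative
conjugate-gradient solver (`method = "cgls"`, tolerance 1e-10, iteration cap
10 × columns) is available and is the automatic fallback for singular
designs (e.g. constant RT, where stimulus and response regressors are
collinear), where its minimum-norm behaviour is the right convention. Ridge
regularization is available but off by default: the estimator is plain least
squares. `correct_overlap()` subtracts a fitted event type's reconstructed
contribution from the recording; subtracting the stimulus contribution
before response-locked averaging is the RT-agnostic overlap correction.
`add_rt_modulation()` mirrors the response-side RT regressor on the stimulus
side for the control analysis in which stimulus activity is allowed to vary
with RT.

# The three demonstrations

`run_overlap_artefact()` (240 trials, 100 Hz, 4 channels, 2 µV noise,
fast-RT regime): overlap-only data, epoched response-locked. Reported: peak
latency per RT quartile (expected to move monotonically away from the
response as bin RT grows) and a median split of the RT ≤ 1.25 s subset
(both group means < 0.9 s), with rise slopes measured over each curve's
0.3 s rising flank up to its peak — expected positive for both groups and
steeper for fast trials, peaks within 0.5 s of the response. With
`truth = "ramp"` the stimulus transient is replaced by a genuine
accumulation ramp and the same code expects response-aligned peaks and
larger pre-response amplitude on *slow* trials.

`run_deconv_rescue()` (12 participants × 120 trials): the same data analysed
naively (response-locked RT regression, group cluster test on first-level
t-maps — expected significant) and by joint deconvolution (response-side RT
kernels into the same cluster test — expected null), plus the normalized
RMSE of the recovered stimulus intercept kernel against the generative
kernel (expected < 0.05 at the default 2 µV noise) and the same contrast
after RT-agnostic overlap correction. The deconvolved branch is a calibrated
5% test, so across seeds it is occasionally significant by construction;
reports carry the seed.

`run_ddm_assignment()` (three jitter scenarios 2/1, 1/1, 1/2 =
stim/motor jitters 0.2/0.1, 0.2/0.2, 0.1/0.2 s; 300 trials each, dt 4 ms):
accumulator traces are laid out as a continuous series and deconvolved with
stimulus and response intercept kernels; the reported stimulus share of
reconstructed energy is expected to rise monotonically across the scenarios
as motor variability comes to dominate. For this analysis the traces end at
absorption (`motor_mode = "end"`): the alternative "hold" mode appends a
plateau at the bound during the motor time, which is response-locked by
construction — it models motor execution, not accumulation — and would
partially cancel the credit-assignment signature being measured.
`simulate_ddm()` itself defaults to "hold", which is the more natural trace
for visualisation.

# Numerical choices and problem sizes

* Time is sample-indexed; second↔sample conversions round to nearest;
  all windows are half-open `[start, end)`.
* Decimation uses an order-30 FIR low-pass normalized to exact unit DC gain
  (constants survive exactly), replicate-padded edges, integer factors only;
  epoch masks propagate conservatively (a decimated sample is missing if
  any source sample in its block was).
* The artefact gradient criterion is the maximum absolute
  successive-sample difference.
* Varimax uses Kaiser row-normalization with tolerance 1e-8.
* Statistics over masked windows use unmasked samples only and report the
  count used.
* Test and demonstration sizes (4–8 channels, 100 Hz, 80–240 trials,
  8–12 participants, 200–1,000 permutations; calibration: 200 null
  experiments of 20 participants on an 8 × 100 grid) were chosen so the
  full suite runs in a few minutes on one core while keeping every check
  comfortably powered; they are stated in the corresponding test files.

# Known limitations

* The generator's noise is spatially white; real EEG noise is correlated
  across channels, which mainly affects how far the cluster test's power
  generalises, not its error control (the permutation test is calibrated
  for any exchangeable noise).
* The deconvolution assumes linear superposition and time-invariant
  kernels within event type; genuinely time-compressed or RT-scaled
  components violate it and appear as residual structure.
* Per-participant construct scoring is out of scope: all trials enter one
  pooled PCA.
* The EDF writer covers the interchange subset used here (common sampling
  rate, µV units, 16-bit); it is not a general-purpose EDF+ implementation.
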