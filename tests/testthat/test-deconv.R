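test_that("a single intercept-only event gives an identity block that recovers the segment", {
  set.seed(60)
  rec <- kernel_recording(100L, sin(seq(0, pi, length.out = 40)),
                          srate = 100, n = 400, noise_sd = 0)
  ev <- simple_events(100L, srate = 100)
  spec <- event_design_spec(stimulus = list(window = c(0, 0.5)), srate = 100)
  td <- time_expand(ev, spec, 400)
  expect_equal(dim(td$X), c(400, 50))
  # identity block at rows 100..149
  expect_equal(as.matrix(td$X[100:149, ]), diag(50), ignore_attr = TRUE)
  fit <- solve_deconv(td, rec)
  expect_equal(as.vector(fit$kernels$stimulus[1, , 1]),
               rec$data[1, 100:149], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("column count and nonzero pattern match hand computation", {
  ev <- simple_events(c(100L, 300L), rt = c(0.5, 0.6), srate = 100,
                      extra = data.frame(z = c(1, -1)))
  spec <- event_design_spec(
    stimulus = list(window = c(-0.1, 0.3), predictors = "z"),
    response = list(window = c(-0.2, 0.2)), srate = 100, center = FALSE)
  td <- time_expand(ev, spec, 500)
  expect_equal(ncol(td$X), 2 * 40 + 1 * 40)  # 2 stim preds + 1 resp pred
  # brute-force stamping oracle
  M <- matrix(0, 500, 120)
  for (i in 1:2) {
    s <- ev$stimulus_sample[i]
    for (b in 0:39) {
      M[s - 10 + b, b + 1] <- 1
      M[s - 10 + b, 40 + b + 1] <- ev$z[i]
    }
    r <- ev$response_sample[i]
    for (b in 0:39) M[r - 20 + b, 80 + b + 1] <- 1
  }
  expect_equal(unname(as.matrix(td$X)), M)
})

test_that("events at the recording edge are clipped with a count", {
  ev <- simple_events(c(5L, 100L), srate = 100)
  spec <- event_design_spec(stimulus = list(window = c(-0.1, 0.1)),
                            srate = 100)
  td <- time_expand(ev, spec, 200)
  expect_equal(td$n_clipped, 6)  # rows -5..0 of the first event
})

test_that("artefact exclusion zeroes rows and makes the fit insensitive to them", {
  set.seed(61)
  kern <- sin(seq(0, pi, length.out = 30))
  events <- c(100L, 250L, 400L)
  rec <- kernel_recording(events, kern, srate = 100, n = 600, noise_sd = 0.1)
  ev <- simple_events(events, srate = 100)
  spec <- event_design_spec(stimulus = list(window = c(0, 0.3)), srate = 100)
  td <- time_expand(ev, spec, 600)
  # clean data: nothing excluded
  td0 <- exclude_artifact_intervals(rec, td, 250)
  expect_equal(sum(td0$excluded), 0)
  # inject a 300 uV spike: that sample's row is dropped
  rec2 <- rec; rec2$data[1, 500] <- 300
  td1 <- exclude_artifact_intervals(rec2, td, 250)
  expect_true(td1$excluded[500])
  expect_equal(sum(td1$excluded), 1)
  # the fit is invariant to arbitrary values at excluded samples
  fit1 <- solve_deconv(td1, rec2)
  rec3 <- rec2; rec3$data[1, 500] <- -9999
  fit2 <- solve_deconv(td1, rec3)
  expect_equal(fit1$coef, fit2$coef, tolerance = 1e-10)
  # guard margin expands the exclusion
  td2 <- exclude_artifact_intervals(rec2, td, 250, guard = 2)
  expect_equal(sum(td2$excluded), 5)
  expect_error(exclude_artifact_intervals(
    eeg_recording(matrix(1000, 1, 600), 100, "A"), td, 250), "90%")
})

test_that("zero data give zero kernels under both solvers", {
  rec <- eeg_recording(matrix(0, 1, 300), 100, "A")
  ev <- simple_events(c(50L, 150L), srate = 100)
  spec <- event_design_spec(stimulus = list(window = c(0, 0.4)), srate = 100)
  td <- time_expand(ev, spec, 300)
  expect_true(all(solve_deconv(td, rec, method = "normal")$coef == 0))
  expect_true(all(solve_deconv(td, rec, method = "cgls")$coef == 0))
})

test_that("solvers agree and are deterministic", {
  set.seed(62)
  kern <- stimulus_kernel(100)$values
  events <- as.integer(seq(100, 2000, by = 90))
  rec <- kernel_recording(events, kern, srate = 100, n = 2200,
                          noise_sd = 0.5)
  ev <- simple_events(events, srate = 100)
  spec <- event_design_spec(stimulus = list(window = c(-0.2, 0.8)),
                            srate = 100)
  td <- time_expand(ev, spec, 2200)
  f1 <- solve_deconv(td, rec, method = "normal")
  f2 <- solve_deconv(td, rec, method = "cgls")
  f3 <- solve_deconv(td, rec, method = "normal")
  expect_equal(f1$coef, f2$coef, tolerance = 1e-7)
  expect_identical(f1$coef, f3$coef)
})

test_that("without overlap, deconvolved kernels equal event-locked averages", {
  set.seed(63)
  kern <- stimulus_kernel(100)$values       # 0.7 s support
  events <- as.integer(seq(200, 6000, by = 250))  # 2.5 s apart: no overlap
  rec <- kernel_recording(events, kern, srate = 100, n = 6500, noise_sd = 0)
  ev <- simple_events(events, srate = 100)
  spec <- event_design_spec(stimulus = list(window = c(-0.5, 1)), srate = 100)
  td <- time_expand(ev, spec, 6500)
  fit <- solve_deconv(td, rec)
  ep <- epoch_events(rec, ev, "stimulus", c(-0.5, 1), verbose = FALSE)
  avg <- apply(ep$data, 3, mean)
  expect_lt(max(abs(as.vector(fit$kernels$stimulus[1, , 1]) - avg)), 1e-6)
})

test_that("overlapping stimulus activity is not credited to the response", {
  set.seed(64)
  # overlap-only data with lognormal RTs around 0.75 s
  beh <- simulate_trial_measures(behaviour_config(
    n_trials = 150, n_participants = 1, rt_shift = 0.25, rt_meanlog0 = -0.4,
    rt_sdlog = 0.45, rt_cap = 2))
  cfg <- eeg_sim_config(srate = 100, appraisal_gain = 0, resp_base = 0,
                        choice_gain = 0, noise_sd = 1)
  sim <- simulate_recording(beh$measures, beh$latents, cfg)
  spec <- event_design_spec(stimulus = list(window = c(-0.2, 0.8)),
                            response = list(window = c(-1, 0.3)),
                            srate = 100)
  td <- time_expand(sim$events, spec, ncol(sim$recording$data))
  fit <- solve_deconv(td, sim$recording)
  pz <- match("Pz", fit$channel_labels)
  stim_peak <- max(abs(fit$kernels$stimulus[1, , pz]))
  resp_peak <- max(abs(fit$kernels$response[1, , pz]))
  expect_lt(resp_peak, 0.1 * stim_peak)
  # whereas naive response-locked averaging shows a large spurious bump
  # (the RT spread smears the 10 uV transient to roughly 0.45 of its
  # height in the average - still far above the deconvolved kernel)
  ep <- epoch_events(sim$recording, sim$events, "response", c(-1, 0.3),
                     verbose = FALSE)
  naive <- apply(ep$data[, pz, ], 2, mean, na.rm = TRUE)
  expect_gt(max(abs(naive)), 0.3 * stim_peak)
  expect_gt(max(abs(naive)), 4 * resp_peak)
})

test_that("kernel recovery beats naive averaging under overlap at both SNRs", {
  set.seed(65)
  for (noise_sd in c(1, 4)) {        # high / medium SNR vs 10 uV kernels
    beh <- simulate_trial_measures(behaviour_config(
      n_trials = 150, n_participants = 1, rt_shift = 0.25,
      rt_meanlog0 = -0.4, rt_sdlog = 0.45, rt_cap = 2))
    cfg <- eeg_sim_config(srate = 100, appraisal_gain = 0, resp_base = 6,
                          choice_gain = 0, noise_sd = noise_sd)
    sim <- simulate_recording(beh$measures, beh$latents, cfg)
    spec <- event_design_spec(stimulus = list(window = c(-0.2, 0.8)),
                              response = list(window = c(-0.5, 0.5)),
                              srate = 100)
    td <- time_expand(sim$events, spec, ncol(sim$recording$data))
    fit <- solve_deconv(td, sim$recording)
    nrmse <- function(est, truth) sqrt(mean((est - truth)^2)) /
      max(abs(truth))
    kts <- kernel_times(fit, "stimulus")
    true_stim <- outer(cfg$stim_topo, cfg$stim_base * cfg$stim_kernel$values)
    est_stim <- t(fit$kernels$stimulus[1, kts >= 0 & kts <= 0.7, ])
    nk <- min(ncol(est_stim), ncol(true_stim))
    e_deconv <- nrmse(est_stim[, 1:nk], true_stim[, 1:nk])
    expect_lt(e_deconv, if (noise_sd == 1) 0.05 else 0.15)

    ktr <- kernel_times(fit, "response")
    true_resp <- outer(cfg$resp_topo, cfg$resp_base * cfg$resp_kernel$values)
    sel <- ktr >= cfg$resp_kernel$onset_s - 1e-9
    est_resp <- t(fit$kernels$response[1, sel, ])
    nr <- min(ncol(est_resp), ncol(true_resp))
    e_resp <- nrmse(est_resp[, 1:nr], true_resp[, 1:nr])
    # naive response-locked average as kernel estimate
    ep <- epoch_events(sim$recording, sim$events, "response",
                       c(cfg$resp_kernel$onset_s, 0.5), verbose = FALSE)
    naive <- apply(ep$data, c(2, 3), mean, na.rm = TRUE)
    e_naive <- nrmse(naive[, 1:nr], true_resp[, 1:nr])
    expect_lt(e_resp, e_naive)
  }
})

test_that("RT modulation kernels recover true slopes and stay at the noise floor otherwise", {
  set.seed(66)
  n <- 150
  rt <- exp(rnorm(n, -0.4, 0.4)) + 0.25
  stim <- as.integer(cumsum(c(300, (rt[-n] + 1.5) * 100)))
  ev <- simple_events(stim, rt = rt, srate = 100)
  kern <- stimulus_kernel(100)$values
  slope <- 4   # uV per second of RT
  ns <- max(stim) + 400
  x <- matrix(rnorm(ns, 0, 0.5), 1, ns)
  for (i in seq_len(n)) {
    idx <- stim[i] + seq_along(kern) - 1
    x[1, idx] <- x[1, idx] + (10 + slope * (rt[i] - mean(rt))) * kern
  }
  rec <- eeg_recording(x, 100, "A")
  spec0 <- event_design_spec(stimulus = list(window = c(-0.2, 0.8)),
                             response = list(window = c(-1, 0.3)),
                             srate = 100)
  spec1 <- add_rt_modulation(spec0)
  expect_identical(spec1$types$stimulus$predictors, "rt")
  td <- time_expand(ev, spec1, ns)
  fit <- solve_deconv(td, rec)
  kts <- kernel_times(fit, "stimulus")
  est_slope <- max(fit$kernels$stimulus["rt", , 1])
  expect_equal(est_slope, slope, tolerance = 0.1 * slope)

  # no true RT dependence: RT kernel below a permutation noise floor
  x0 <- matrix(rnorm(ns, 0, 0.5), 1, ns)
  for (i in seq_len(n)) {
    idx <- stim[i] + seq_along(kern) - 1
    x0[1, idx] <- x0[1, idx] + 10 * kern
  }
  rec0 <- eeg_recording(x0, 100, "A")
  fit0 <- solve_deconv(time_expand(ev, spec1, ns), rec0)
  obs <- max(abs(fit0$kernels$stimulus["rt", , 1]))
  floor_ <- replicate(20, {
    evp <- ev; evp$rt <- sample(evp$rt)
    fitp <- solve_deconv(time_expand(evp, spec1, ns), rec0)
    max(abs(fitp$kernels$stimulus["rt", , 1]))
  })
  expect_lt(obs, quantile(floor_, 0.95) * 1.5)
})

test_that("overlap correction subtracts exactly the modelled contribution", {
  set.seed(67)
  kern <- stimulus_kernel(100)$values
  events <- as.integer(seq(150, 2000, by = 120))
  rec <- kernel_recording(events, kern, srate = 100, n = 2300,
                          noise_sd = 0.3, nch = 2)
  rt <- round(runif(length(events), 0.4, 0.8), 2)
  ev <- simple_events(events, rt = rt, srate = 100)
  spec <- event_design_spec(stimulus = list(window = c(-0.2, 0.8)),
                            response = list(window = c(-0.6, 0.3)),
                            srate = 100)
  td <- time_expand(ev, spec, 2300)
  fit <- solve_deconv(td, rec)
  # algebraic identity: removing all types leaves data - X %*% coef
  corr_all <- correct_overlap(rec, fit, c("stimulus", "response"))
  oracle <- rec$data - t(as.matrix(td$X %*% fit$coef))
  expect_equal(unname(corr_all$data), unname(oracle), tolerance = 1e-10)
  expect_error(correct_overlap(rec, fit, "nope"), "unknown")
})

test_that("noiseless well-separated events are modelled to machine precision", {
  kern <- stimulus_kernel(100)$values
  events <- as.integer(seq(200, 3000, by = 300))
  rec <- kernel_recording(events, kern, srate = 100, n = 3400, noise_sd = 0)
  ev <- simple_events(events, srate = 100)
  spec <- event_design_spec(stimulus = list(window = c(-0.5, 1)),
                            srate = 100)
  td <- time_expand(ev, spec, 3400)
  fit <- solve_deconv(td, rec)
  corr <- correct_overlap(rec, fit, "stimulus")
  expect_lt(max(abs(corr$data)), 1e-6 * max(kern))
})

test_that("stimulus-contribution removal destroys the spurious ramp ordering", {
  set.seed(68)
  beh <- simulate_trial_measures(behaviour_config(
    n_trials = 150, n_participants = 1, rt_shift = 0.25, rt_meanlog0 = -0.4,
    rt_sdlog = 0.45, rt_cap = 2))
  cfg <- eeg_sim_config(srate = 100, appraisal_gain = 0, resp_base = 0,
                        choice_gain = 0, noise_sd = 1)
  sim <- simulate_recording(beh$measures, beh$latents, cfg)
  spec <- event_design_spec(stimulus = list(window = c(-0.2, 0.8)),
                            response = list(window = c(-1, 0.3)),
                            srate = 100)
  td <- time_expand(sim$events, spec, ncol(sim$recording$data))
  fit <- solve_deconv(td, sim$recording)
  pz <- 3
  contrast <- function(recording) {
    ep <- epoch_events(recording, sim$events, "response", c(-1, 0.1),
                       verbose = FALSE)
    ms <- median_split_average(ep)
    sel <- ep$times >= -0.3 & ep$times < 0
    mean(ms$fast[pz, sel], na.rm = TRUE) - mean(ms$slow[pz, sel], na.rm = TRUE)
  }
  before <- contrast(sim$recording)
  after <- contrast(correct_overlap(sim$recording, fit, "stimulus"))
  expect_gt(abs(before), 1)                  # clear artefactual ordering
  expect_lt(abs(after), 0.2 * abs(before))   # >80% of it removed
})
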