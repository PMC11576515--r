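# A small epoch fixture with optional masking, built directly.
make_epochs <- function(data, srate = 100, lock = "stimulus", rt = NULL,
                        times = NULL) {
  d <- dim(data)
  structure(list(
    data = data, mask = is.na(data),
    times = times %||% ((seq_len(d[3]) - 1) / srate),
    srate = srate, lock = lock, baseline_window = NULL,
    kept_trial_ids = seq_len(d[1]),
    channel_labels = paste0("ch", seq_len(d[2])),
    events = data.frame(rt = rt %||% rep(1, d[1]))),
    class = "eeg_epochs")
}

test_that("intercept-only regression returns the per-point trial mean", {
  set.seed(50)
  data <- array(rnorm(20 * 2 * 10), c(20, 2, 10))
  tm <- fit_mass_univariate(make_epochs(data), rerp_design(n_trials = 20))
  expect_equal(tm$beta[1, , ], apply(data, c(2, 3), mean), tolerance = 1e-12)
  expect_true(all(tm$df == 19))
})

test_that("betas and t-values match the normal-equations oracle", {
  set.seed(51)
  n <- 8
  data <- array(rnorm(n * 2 * 5), c(n, 2, 5))
  x1 <- rnorm(n); x2 <- rnorm(n)
  X <- cbind(1, x1, x2)
  tm <- fit_mass_univariate(make_epochs(data),
                            rerp_design(x1 = x1, x2 = x2))
  for (ch in 1:2) for (ti in 1:5) {
    y <- data[, ch, ti]
    b <- solve(t(X) %*% X) %*% t(X) %*% y
    res <- y - X %*% b
    s2 <- sum(res^2) / (n - 3)
    se <- sqrt(diag(s2 * solve(t(X) %*% X)))
    expect_equal(tm$beta[, ch, ti], as.vector(b), tolerance = 1e-10)
    expect_equal(tm$se[, ch, ti], unname(se), tolerance = 1e-10)
    expect_equal(tm$t[, ch, ti], unname(as.vector(b) / se), tolerance = 1e-10)
  }
})

test_that("masked points are dropped listwise per point", {
  set.seed(52)
  n <- 30
  data <- array(rnorm(n * 1 * 4), c(n, 1, 4))
  data[1:5, 1, 2] <- NA               # five trials masked at time 2 only
  x <- rnorm(n)
  tm <- fit_mass_univariate(make_epochs(data), rerp_design(x = x))
  expect_equal(tm$n_used[1, ], c(30, 25, 30, 30))
  y <- data[6:30, 1, 2]; X <- cbind(1, x[6:30])
  b <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(tm$beta[, 1, 2], as.vector(b), tolerance = 1e-10)
  expect_equal(tm$df[1, 2], 23)
})

test_that("appraisal effects localize to the stimulus kernel window", {
  set.seed(53)
  beh <- simulate_trial_measures(behaviour_config(n_trials = 120,
                                                  n_participants = 1))
  cfg <- eeg_sim_config(srate = 100, appraisal_gain = 3, resp_base = 0,
                        choice_gain = 0, noise_sd = 3)
  sim <- simulate_recording(beh$measures, beh$latents, cfg)
  ep <- epoch_events(sim$recording, sim$events, "stimulus", c(-0.2, 1),
                     verbose = FALSE)
  ep <- baseline_correct(ep, c(-0.2, 0))
  tm <- fit_mass_univariate(ep, rerp_design(appraisal = beh$latents[, 1],
                                            choice = beh$latents[, 2]))
  pz <- match("Pz", tm$channel_labels)
  peak_t <- tm$times[which.max(tm$t[2, pz, ])]
  expect_true(peak_t > 0 && peak_t < 0.7)        # inside kernel support
  # no choice effect at stimulus when the choice gain is 0
  expect_lt(max(abs(tm$t[3, pz, ]), na.rm = TRUE),
            max(tm$t[2, pz, ], na.rm = TRUE))
  expect_lt(max(abs(tm$t[3, pz, ]), na.rm = TRUE), 5)
})

test_that("OLS gain estimates are unbiased over replicates", {
  set.seed(54)
  gains <- replicate(60, {
    n <- 40
    a <- rnorm(n)
    data <- array(rnorm(n * 1 * 3, 0, 2), c(n, 1, 3))
    data[, 1, 2] <- data[, 1, 2] + 1.5 * a
    tm <- fit_mass_univariate(make_epochs(data), rerp_design(a = a))
    tm$beta[2, 1, 2]
  })
  expect_lt(abs(mean(gains) - 1.5), 3 * sd(gains) / sqrt(60))
})

test_that("predicted ERPs are linear in the tercile levels", {
  set.seed(55)
  data <- array(rnorm(30 * 2 * 6), c(30, 2, 6))
  x <- rnorm(30)
  tm <- fit_mass_univariate(make_epochs(data), rerp_design(x = x))
  pe <- predicted_erps(tm, "x", values = x)
  expect_equal(pe$levels, tercile_levels(x))
  # direct evaluation oracle
  for (k in 1:3)
    expect_equal(pe$curves[k, , ],
                 tm$beta[1, , ] + pe$levels[k] * tm$beta[2, , ])
  # spacing between curves proportional to level spacing
  d21 <- pe$curves[2, , ] - pe$curves[1, , ]
  d32 <- pe$curves[3, , ] - pe$curves[2, , ]
  ratio <- (pe$levels[2] - pe$levels[1]) / (pe$levels[3] - pe$levels[2])
  expect_equal(d21, d32 * ratio, tolerance = 1e-10)
  # zero slope collapses all curves onto the intercept
  tm0 <- tm; tm0$beta[2, , ] <- 0
  pe0 <- predicted_erps(tm0, "x", values = x)
  expect_equal(pe0$curves[1, , ], pe0$curves[3, , ])
})

test_that("ERP images sort, smooth and mark events correctly", {
  set.seed(56)
  n <- 12
  data <- array(rnorm(n * 1 * 8), c(n, 1, 8))
  rt <- seq(0.3, 1.4, length.out = n)
  ep <- make_epochs(data, lock = "response", rt = rt)
  img <- erp_image(ep, 1, sort_key = rt, smooth = 1)
  expect_equal(img$image, matrix(data[, 1, ], n, 8))  # already sorted
  expect_equal(img$markers, -rt)

  # moving-average oracle on shuffled keys
  key <- sample(n)
  img2 <- erp_image(ep, 1, sort_key = key, smooth = 3)
  ord <- order(key)
  raw <- matrix(data[ord, 1, ], n, 8)
  for (i in 1:n) {
    rows <- max(1, i - 1):min(n, i + 1)
    expect_equal(img2$image[i, ], colMeans(raw[rows, , drop = FALSE]))
  }
  expect_error(erp_image(ep, 1, rt, smooth = 99), "exceeds")
  expect_error(erp_image(ep, 1, c(rt[-1], NA)), "finite")
})

test_that("response-locked images of overlap-only data track the stimulus diagonal", {
  set.seed(57)
  beh <- simulate_trial_measures(behaviour_config(
    n_trials = 80, n_participants = 1, rt_shift = 0.25,
    rt_meanlog0 = -0.4, rt_sdlog = 0.45, rt_cap = 2))
  cfg <- eeg_sim_config(srate = 100, appraisal_gain = 0, resp_base = 0,
                        choice_gain = 0, noise_sd = 1)
  sim <- simulate_recording(beh$measures, beh$latents, cfg)
  ep <- epoch_events(sim$recording, sim$events, "response", c(-1.5, 0.3),
                     verbose = FALSE)
  img <- erp_image(ep, "Pz", sort_key = ep$events$rt, smooth = 1)
  # per-row stimulus markers sit at -rt; the single-trial positivity peaks
  # ~0.35 s after each marker
  expect_equal(img$markers, -sort(ep$events$rt))
  peaks <- vapply(seq_len(nrow(img$image)), function(i)
    img$times[which.max(img$image[i, ])], 0)
  expect_lt(median(abs(peaks - (img$markers + 0.35))), 0.1)
})

test_that("median splits and RT filters match group-by oracles", {
  set.seed(58)
  n <- 40
  data <- array(rnorm(n * 2 * 10), c(n, 2, 10))
  rt <- runif(n, 0.4, 2)
  ep <- make_epochs(data, lock = "response", rt = rt)
  ms <- median_split_average(ep, rt_max = 1.25)
  kept <- rt <= 1.25
  expect_equal(ms$n_filtered, sum(kept))          # brute-force filter count
  med <- median(rt[kept])
  fast <- kept & rt <= med
  expect_equal(ms$fast, apply(data[fast, , , drop = FALSE], c(2, 3), mean))
  expect_equal(ms$slow, apply(data[kept & rt > med, , , drop = FALSE],
                              c(2, 3), mean))
  expect_equal(sum(ms$hist_fast$counts), ms$n_fast)
  # identical trials give identical group means
  dd <- data; for (i in seq_len(n)) dd[i, , ] <- dd[1, , ]
  ms2 <- median_split_average(make_epochs(dd, lock = "response", rt = rt))
  expect_equal(ms2$fast, ms2$slow)
  expect_error(median_split_average(ep, rt_max = 0.1), "fewer than 2")
})
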