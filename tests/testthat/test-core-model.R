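test_that("epoching is a windowing identity and places the lock sample", {
  set.seed(1)
  rec <- eeg_recording(matrix(rnorm(2 * 3000), 2), 500, c("A", "B"))
  ev <- simple_events(stim = 1000L, srate = 500)
  ep <- epoch_events(rec, ev, "stimulus", c(0, 0.5), verbose = FALSE)
  expect_equal(dim(ep$data), c(1, 2, 250))
  expect_identical(ep$data[1, , ], unname(rec$data[, 1000:1249]))
  expect_equal(ep$times[1], 0)

  # the standard stimulus segmentation: 4.4 s window at 500 Hz
  rec2 <- eeg_recording(matrix(0, 1, 5000), 500, "A")
  ep2 <- epoch_events(rec2, simple_events(1500L, srate = 500), "stimulus",
                      c(-0.2, 4.2), verbose = FALSE)
  expect_equal(dim(ep2$data)[3], 2200)
  expect_equal(which(ep2$times == 0), 101)  # lock sample at index 100 (0-based)
})

test_that("out-of-trial samples are masked and the count matches a scan", {
  rec <- eeg_recording(matrix(1, 1, 4000), 500, "A")
  rt <- 0.8
  ev <- simple_events(stim = 1200L, rt = rt, srate = 500)
  ep <- epoch_events(rec, ev, "stimulus", c(0, 4.2), verbose = FALSE)
  # independent scan: samples strictly after the response are invalid
  expect_equal(sum(ep$mask[1, 1, ]), sum(ep$times > rt))
  expect_true(all(is.na(ep$data[1, 1, ep$times > rt])))
  # response-locked: samples before the stimulus are invalid
  epr <- epoch_events(rec, ev, "response", c(-2, 0.5), verbose = FALSE)
  expect_equal(sum(epr$mask[1, 1, ]), sum(epr$times < -rt))
  # response lock drops trials without a response
  ev2 <- simple_events(stim = c(1200L, 2500L), rt = c(0.8, NA), srate = 500)
  epr2 <- epoch_events(rec, ev2, "response", c(-1, 0.5), verbose = FALSE)
  expect_equal(dim(epr2$data)[1], 1)
})

test_that("window exclusion logs trials and empty epochs error", {
  rec <- eeg_recording(matrix(0, 1, 1000), 100, "A")
  ev <- simple_events(stim = c(10L, 500L, 995L), srate = 100)
  ep <- epoch_events(rec, ev, "stimulus", c(-0.2, 1), verbose = FALSE)
  expect_equal(dim(ep$data)[1], 1)
  expect_equal(ep$n_excluded, 2)
  expect_error(epoch_events(rec, simple_events(999L, srate = 100),
                            "stimulus", c(0, 1), verbose = FALSE),
               "no epochs")
})

test_that("mask monotonicity: larger windows never unmask a sample", {
  rec <- eeg_recording(matrix(0, 1, 4000), 100, "A")
  ev <- simple_events(stim = c(500L, 1500L), rt = c(0.5, 1.2), srate = 100)
  small <- epoch_events(rec, ev, "stimulus", c(0, 2), verbose = FALSE)
  large <- epoch_events(rec, ev, "stimulus", c(-0.5, 3), verbose = FALSE)
  common <- match(round(small$times, 10), round(large$times, 10))
  expect_true(all(large$mask[, , common][small$mask]))
})

test_that("baseline correction removes per-trial channel means", {
  # constant epochs go to zero
  rec <- eeg_recording(matrix(7, 2, 500), 100, c("A", "B"))
  ep <- epoch_events(rec, simple_events(100L, srate = 100), "stimulus",
                     c(-0.2, 1), verbose = FALSE)
  bc <- baseline_correct(ep, c(-0.2, 0))
  expect_true(all(abs(bc$data) < 1e-12))
  expect_equal(bc$baseline_window, c(-0.2, 0))

  # random epochs: mean over the baseline window is 0 afterwards, and the
  # result equals subtracting independently computed row means
  set.seed(2)
  rec2 <- eeg_recording(matrix(rnorm(3 * 2000), 3), 100, c("A", "B", "C"))
  ev <- simple_events(c(200L, 800L, 1500L), srate = 100)
  ep2 <- epoch_events(rec2, ev, "stimulus", c(-0.2, 1), verbose = FALSE)
  bc2 <- baseline_correct(ep2, c(-0.2, 0))
  sel <- ep2$times >= -0.2 & ep2$times < 0
  for (i in 1:3) for (ch in 1:3) {
    expect_lt(abs(mean(bc2$data[i, ch, sel])), 1e-10)
    expect_equal(bc2$data[i, ch, ],
                 ep2$data[i, ch, ] - mean(ep2$data[i, ch, sel]))
  }
})

test_that("a trial with no unmasked baseline samples is flagged", {
  rec <- eeg_recording(matrix(1, 1, 1000), 100, "A")
  ev <- simple_events(500L, rt = 0.5, srate = 100)
  ep <- epoch_events(rec, ev, "response", c(-1, 0.2), verbose = FALSE)
  # baseline window lies entirely before the stimulus: fully masked
  expect_warning(bc <- baseline_correct(ep, c(-1, -0.9)), "no unmasked")
  expect_equal(attr(bc, "flagged_trials"), 1L)
})

test_that("artefact rejection matches a brute-force scan", {
  set.seed(3)
  n <- 30
  data <- array(rnorm(n * 2 * 100, 0, 5), c(n, 2, 100))
  data[5, 1, 50] <- 151           # amplitude violation
  data[9, 2, 60:61] <- c(0, 60)   # gradient violation
  ep <- structure(list(data = data, mask = array(FALSE, dim(data)),
                       times = seq(0, 0.99, by = 0.01), srate = 100,
                       lock = "stimulus", baseline_window = NULL,
                       kept_trial_ids = seq_len(n),
                       channel_labels = c("A", "B"),
                       events = data.frame(rt = rep(1, n))),
                  class = "eeg_epochs")
  res <- reject_epochs(ep, 150, 50)
  # independent exhaustive scan
  oracle <- vapply(seq_len(n), function(i) {
    x <- data[i, , ]
    any(abs(x) > 150) || any(abs(t(diff(t(x)))) > 50)
  }, TRUE)
  expect_identical(res$rejected, oracle)
  expect_true(res$rejected[5] && res$rejected[9])
  expect_equal(dim(res$epochs$data)[1], n - sum(oracle))

  # all-zero epochs: none rejected
  ep0 <- ep; ep0$data[] <- 0
  expect_false(any(reject_epochs(ep0, 150, 50)$rejected))

  # permutation invariance over trial order
  perm <- sample(n)
  epp <- ep; epp$data <- ep$data[perm, , , drop = FALSE]
  epp$mask <- ep$mask[perm, , , drop = FALSE]
  epp$events <- ep$events[perm, , drop = FALSE]
  expect_identical(reject_epochs(epp, 150, 50)$rejected, oracle[perm])
})

test_that("adjacency equals thresholding of the distance matrix", {
  # single channel: empty neighbour set
  a1 <- build_adjacency(matrix(0, 1, 3), 1)
  expect_length(a1$neighbors[[1]], 0)

  # collinear chain at spacing d with threshold 1.5 d
  pos <- cbind(c(0, 1, 2), 0, 0)
  a2 <- build_adjacency(pos, 1.5)
  expect_identical(a2$neighbors, list(2L, c(1L, 3L), 2L))

  # random layout vs distance-matrix oracle; symmetric and irreflexive
  set.seed(4)
  pos3 <- matrix(rnorm(30), 10, 3)
  a3 <- build_adjacency(pos3, 0.9)
  d <- as.matrix(dist(pos3))
  oracle <- d < 0.9; diag(oracle) <- FALSE
  expect_identical(unname(a3$matrix), unname(oracle))
  expect_identical(a3$matrix, t(a3$matrix))
  expect_false(any(diag(a3$matrix)))
  expect_warning(build_adjacency(rbind(pos3, pos3[1, ]), 0.9), "duplicate")
})

test_that("decimation preserves constants and halves 500 Hz to 250 Hz", {
  rec <- eeg_recording(matrix(5, 2, 1000), 500, c("A", "B"))
  dec <- resample(rec, 250)
  expect_equal(dec$srate, 250)
  expect_equal(ncol(dec$data), 500)
  expect_equal(unname(dec$data), matrix(5, 2, 500))  # constants exact
  expect_error(resample(rec, 300), "evenly")
  # factor 1 is the identity
  expect_equal(resample(rec, 500)$data, rec$data)
})

test_that("epoch averaging of kernel-placed events reproduces the kernel", {
  kern <- sin(seq(0, pi, length.out = 50))
  events <- c(200L, 500L, 900L, 1400L)
  rec <- kernel_recording(events, kern, srate = 100, n = 2000)
  ep <- epoch_events(rec, simple_events(events, srate = 100), "stimulus",
                     c(0, 0.5), verbose = FALSE)
  avg <- apply(ep$data, c(2, 3), mean)
  expect_equal(as.vector(avg), kern, tolerance = 1e-12)
})

test_that("template montage returns plausible unit-sphere positions", {
  m <- template_montage()
  expect_true(all(abs(sqrt(m$x^2 + m$y^2 + m$z^2) - 1) < 1e-9))
  sub <- template_montage(c("Pz", "Cz"))
  expect_identical(sub$label, c("Pz", "Cz"))
  expect_error(template_montage("Nope"), "not in template")
  adj <- build_adjacency(template_montage())
  expect_true(median(lengths(adj$neighbors)) >= 4 &&
                median(lengths(adj$neighbors)) <= 8)
})
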