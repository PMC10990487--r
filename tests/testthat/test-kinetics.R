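test_that("the smoothed derivative is exact on ramps and constants", {
  fs <- 100
  tt <- seq(0, 10, by = 1 / fs)
  d <- trace_derivative(3.2 * tt, fs, 0.25)
  inner <- 30:(length(tt) - 30)
  expect_equal(d[inner], rep(3.2, length(inner)), tolerance = 1e-9)
  expect_equal(trace_derivative(rep(1.5, 500), fs, 0.25), rep(0, 500),
               tolerance = 1e-12)
  expect_error(trace_derivative(rnorm(10), fs, 1), "longer than trace")
  expect_error(trace_derivative(rnorm(100), fs, 0.01), "at least 3 samples")
})

test_that("derivative of the kernel converges to the analytic derivative", {
  taus <- c(0.6, 2.5)
  kprime <- function(t) {
    exp(-t / taus[2]) * (exp(-t / taus[1]) / taus[1] -
                           (1 - exp(-t / taus[1])) / taus[2])
  }
  err <- vapply(c(100, 1000), function(fs) {
    tt <- seq(0, 10, by = 1 / fs)
    d <- trace_derivative(transient_kernel(tt, taus[1], taus[2]), fs, 3.5 / fs)
    inner <- which(tt > 0.1 & tt < 9)
    max(abs(d[inner] - kprime(tt[inner])))
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 1e-3)
})

test_that("analytic zero crossings of a cosine derivative are recovered", {
  tt <- seq(0, 1, by = 1e-3)
  res <- find_zero_crossings(cos(2 * pi * tt), tt, 0)
  expect_equal(res$point_a_s, 0.25, tolerance = 1e-4)
  expect_equal(res$point_b_s, 0.75, tolerance = 1e-4)
})

test_that("monotone traces yield an absent point A rather than an error", {
  tt <- seq(0, 5, by = 0.01)
  d <- trace_derivative(tt^1.5, 100, 0.1)
  res <- find_zero_crossings(d, tt, 0)
  expect_true(is.na(res$point_a_s))
  expect_true(is.na(res$point_b_s))
})

test_that("noiseless kernel point A matches the analytic peak and a brute-force scan", {
  fs <- 1000
  for (region in c("NAc_dopamine", "LH_dopamine")) {
    kern <- region_kernel(region)
    tt <- seq(-1, 40, by = 1 / fs)
    x <- transient_kernel(tt, kern$tau_rise_s, kern$tau_decay_s)
    d <- trace_derivative(x, fs, 3 / fs)
    res <- find_zero_crossings(d, tt, 0)
    expect_equal(res$point_a_s,
                 kernel_peak_time(kern$tau_rise_s, kern$tau_decay_s),
                 tolerance = 1 / fs)
    # exhaustive oracle over all adjacent sample pairs
    brute <- which(d[-length(d)] > 0 & d[-1] < 0 & tt[-length(tt)] >= 0)[1]
    expect_lt(abs(res$point_a_s - tt[brute]), 2 / fs)
  }
})

test_that("interpolated crossings agree with a 10x-oversampled scan", {
  taus <- c(0.3, 1.2)
  fs <- 50
  tt <- seq(0, 8, by = 1 / fs)
  x <- transient_kernel(tt, taus[1], taus[2]) -
    0.6 * transient_kernel(tt - 2, taus[1], taus[2])
  d <- trace_derivative(x, fs, 3 / fs)
  res <- find_zero_crossings(d, tt, 0)

  tt_f <- seq(0, 8, by = 1 / (10 * fs))
  x_f <- transient_kernel(tt_f, taus[1], taus[2]) -
    0.6 * transient_kernel(tt_f - 2, taus[1], taus[2])
  d_f <- trace_derivative(x_f, 10 * fs, 3 / (10 * fs))
  a_f <- tt_f[which(d_f[-length(d_f)] > 0 & d_f[-1] < 0)[1]]
  b_cand <- which(d_f[-length(d_f)] < 0 & d_f[-1] > 0)
  b_f <- tt_f[b_cand[b_cand > which.max(x_f)][1]]

  expect_lt(abs(res$point_a_s - a_f), 1 / fs)
  expect_lt(abs(res$point_b_s - b_f), 1 / fs)
  expect_lt(res$point_a_s, res$point_b_s)
})

test_that("crossing points are equivariant under time shifts", {
  fs <- 100
  tt <- seq(0, 10, by = 1 / fs)
  x <- transient_kernel(tt - 1, 0.3, 1.2)
  d <- trace_derivative(x, fs, 0.1)
  base <- find_zero_crossings(d, tt, 1)
  shifted <- find_zero_crossings(d, tt + 2.5, 3.5)
  expect_equal(shifted$point_a_s, base$point_a_s, tolerance = 1e-9)
})

test_that("smoothing bias on noiseless kernels stays below half the window", {
  fs <- 200
  taus <- c(0.6, 2.5)
  tt <- seq(-1, 15, by = 1 / fs)
  x <- transient_kernel(tt, taus[1], taus[2])
  truth <- kernel_peak_time(taus[1], taus[2])
  bias <- vapply(c(0.2, 0.5, 1.0), function(w) {
    d <- trace_derivative(x, fs, w)
    abs(find_zero_crossings(d, tt, 0)$point_a_s - truth)
  }, numeric(1))
  expect_true(all(bias < c(0.2, 0.5, 1.0) / 2))
})

test_that("region comparison delegates to the unpaired t test", {
  zc <- function(a, b = NA) structure(list(point_a_s = a, point_b_s = b,
                                           reference_label = "laser_onset",
                                           smoothing_window_s = 0.5),
                                      class = "zero_crossing_result")
  ga <- lapply(c(1, 1.2, 0.9, 1.1), zc)
  gb <- lapply(c(1, 1.2, 0.9, 1.1), zc)
  same <- compare_regions(ga, gb)
  expect_equal(same$statistic, 0)
  expect_equal(same$df, 6)

  gc <- lapply(c(5.1, 5.3, 4.9, 5.2), zc)
  diff <- compare_regions(gc, ga, labels = c("NAc", "LH"))
  expect_lt(diff$p_value, 0.001)
  expect_gt(diff$statistic, 0)

  # absent crossings are excluded with a warning; emptied groups fail
  gd <- c(ga[1:2], list(zc(NA)))
  expect_warning(compare_regions(gd, gb), "absent point A")
  expect_error(
    suppressWarnings(compare_regions(list(zc(NA), zc(NA)), gb)),
    ">= 2 subjects")
})

test_that("fast and slow stimulation presets separate in small simulated cohorts", {
  stim_only <- task_config(iti_low_s = 8, iti_high_s = 12,
                           n_laser_trials = 4, n_nonlaser_trials = 0,
                           max_run_length = 4)
  point_a <- function(region, seed) {
    sch <- generate_schedule(stim_only, seed = seed, session_index = 11)
    sim <- simulate_traces(sch, region_kernel(region), ground_truth(),
                           fs = 25, seed = seed + 1, session_index = 11)
    dff <- compute_dff(sim$trace)
    tens <- align_trials(dff, sch, "laser_onset", window_s = c(-2, 12),
                         baseline_window_s = c(-2, 0))
    tensor_zero_crossings(tens, 0, 0.5)$point_a_s
  }
  for (seed in c(10, 20, 30)) {
    expect_lt(point_a("LH_dopamine", seed), point_a("NAc_dopamine", seed + 5))
  }
})
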