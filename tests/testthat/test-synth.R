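test_that("learning amplitude follows the saturating-exponential closed form", {
  gt <- ground_truth(a_max = 1, learning_rate_sessions = 3)
  expect_equal(learning_amplitude(1, "laser_paired", gt), 1 - exp(-1 / 3))
  # monotone, bounded by a_max, above the non-laser response
  a <- learning_amplitude(1:10, "laser_paired", ground_truth())
  expect_true(all(diff(a) > 0))
  expect_true(all(a <= ground_truth()$a_max))
  expect_true(all(a >= learning_amplitude(1:10, "non_laser", ground_truth())))
  # limits
  expect_equal(learning_amplitude(1:5, "laser_paired", ground_truth(a_max = 0)),
               rep(0, 5))
  expect_equal(learning_amplitude(1e6, "laser_paired", gt), 1, tolerance = 1e-12)
})

test_that("kernel peak time matches a brute-force argmax", {
  for (p in list(c(0.15, 0.5), c(0.6, 2.5), c(3.5, 12))) {
    tt <- seq(0, 20 * p[2], by = 1e-4)
    k <- transient_kernel(tt, p[1], p[2])
    expect_equal(kernel_peak_time(p[1], p[2]), tt[which.max(k)],
                 tolerance = 1e-3)
  }
  # closed-form window integral against numerical quadrature
  num <- stats::integrate(function(t) transient_kernel(t, 0.3, 1.2),
                          0.5, 2.5, rel.tol = 1e-10)$value
  expect_equal(kernel_window_integral(0.3, 1.2, 0.5, 2.5), num,
               tolerance = 1e-8)
  expect_error(kernel_params(0.5, 0.4), "exceed")
})

test_that("with zero amplitudes and no noise the channels are exactly proportional", {
  gt <- noiseless_truth(a_max = 0, nonlaser_amplitude = 0, stim_amplitude = 0,
                        dip_amplitude = 0, tonic = 0)
  sim <- simulate_traces(generate_schedule(quick_task(), seed = 1),
                         region_kernel("NAc_dopamine"), gt, fs = 25, seed = 1)
  ratio <- sim$trace$f_signal / sim$trace$f_control
  expect_equal(ratio, rep(ratio[1], length(ratio)), tolerance = 1e-12)
})

test_that("a single noiseless event peaks at the analytic kernel latency", {
  gt <- noiseless_truth(a_max = 0, nonlaser_amplitude = 0, tonic = 0.1)
  kern <- region_kernel("LH_dopamine")
  sch <- single_trial_schedule(cue_onset = 20)
  fs <- 100
  sim <- simulate_traces(sch, kern, gt, fs = fs, seed = 1)
  peak_t <- sim$trace$t[which.max(sim$trace$f_signal)]
  expect_equal(peak_t, 22 + kernel_peak_time(kern$tau_rise_s, kern$tau_decay_s),
               tolerance = 1 / fs)
})

test_that("traces are deterministic given the seed", {
  sch <- generate_schedule(quick_task(), seed = 5)
  kern <- region_kernel("NAc_dopamine")
  a <- simulate_traces(sch, kern, ground_truth(), fs = 25, seed = 9)
  b <- simulate_traces(sch, kern, ground_truth(), fs = 25, seed = 9)
  c <- simulate_traces(sch, kern, ground_truth(), fs = 25, seed = 10)
  expect_identical(a$trace$f_signal, b$trace$f_signal)
  expect_false(identical(a$trace$f_signal, c$trace$f_signal))
})

test_that("the noiseless signal is linear in event amplitudes", {
  sch <- generate_schedule(quick_task(omission = TRUE), seed = 2)
  kern <- region_kernel("LH_dopamine")
  base <- noiseless_truth(tonic = 0.5)
  dev <- function(truth) {
    sim <- simulate_traces(sch, kern, truth, fs = 25, seed = 1,
                           session_index = 11)
    sim$trace$f_signal / truth$gain_signal - 1 - truth$tonic
  }
  d1 <- dev(base)
  double <- noiseless_truth(tonic = 0.5, a_max = 2 * base$a_max,
                            nonlaser_amplitude = 2 * base$nonlaser_amplitude,
                            stim_amplitude = 2 * base$stim_amplitude,
                            dip_amplitude = 2 * base$dip_amplitude)
  expect_equal(dev(double), 2 * d1, tolerance = 1e-12)
})

test_that("condition scaling multiplies manifest amplitudes and the trace exactly", {
  sch <- generate_schedule(quick_task(omission = TRUE), seed = 3)
  kern <- region_kernel("LH_orexin")
  full <- noiseless_truth(tonic = 0.4)
  scaled <- noiseless_truth(tonic = 0.4, condition_scale = 0.35)
  s_full <- simulate_traces(sch, kern, full, fs = 25, seed = 4, session_index = 11)
  s_scal <- simulate_traces(sch, kern, scaled, fs = 25, seed = 4, session_index = 11)
  expect_equal(s_scal$manifest$events$amplitude,
               0.35 * s_full$manifest$events$amplitude)
  dev_full <- s_full$trace$f_signal / full$gain_signal - 1 - full$tonic
  dev_scal <- s_scal$trace$f_signal / full$gain_signal - 1 - full$tonic
  expect_equal(dev_scal, 0.35 * dev_full, tolerance = 1e-12)
})

test_that("a dip deeper than the tonic baseline is an explicit failure", {
  gt <- noiseless_truth(tonic = 0.05, dip_amplitude = -2.5)
  sch <- single_trial_schedule(cue_onset = 15, omission = TRUE)
  expect_error(simulate_traces(sch, region_kernel("NAc_dopamine"), gt,
                               fs = 25, seed = 1, session_index = 11),
               "non-positive")
})

test_that("trace CSV round trip preserves the recording", {
  sim <- simulate_traces(generate_schedule(quick_task(2, 2), seed = 1),
                         region_kernel("LH_dopamine"), ground_truth(),
                         fs = 25, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(sim$trace, path)
  back <- read_trace_csv(path)
  expect_equal(back$fs, sim$trace$fs)
  expect_equal(back$f_signal, sim$trace$f_signal, tolerance = 1e-12)
  expect_equal(back$f_control, sim$trace$f_control, tolerance = 1e-12)
})
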