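cf_true <- 9.36
tau_true <- 0.550e-6

test_that("the dead-time driver X_W is activity times the rate ratio", {
  expect_equal(x_w(100, 4000, 1000), 400)
  expect_equal(x_w(250, 1000, 1000), 250)   # ratio 1 leaves activity
  expect_error(x_w(100, 4000, 0), "undefined")
})

test_that("origin-forced OLS recovers an exact line and handles one point", {
  exact <- data.frame(activity_MBq = c(1, 2), r_po = c(9.4, 18.8))
  res <- fit_method_a_cf(exact)
  expect_equal(res$cf, 9.4)
  expect_equal(res$cf_se, 0)
  one <- fit_method_a_cf(data.frame(activity_MBq = 10, r_po = 94))
  expect_equal(one$cf, 9.4)
  expect_true(is.na(one$cf_se))
  expect_error(fit_method_a_cf(data.frame(activity_MBq = numeric(0),
                                          r_po = numeric(0))), "at least one")
})

test_that("dead-time-free selection applies the correction-factor rule", {
  # boundary: f(r) - 1 = 0.01 at r = log(1.01)/(1.01 * tau)
  r_bound <- log(1.01) / (1.01 * tau_true)
  s <- data.frame(acq = 1:4, activity_MBq = 1:4,
                  r_wo = c(0.5, 0.9, 1.1, 2) * r_bound)
  kept <- select_dt_free(s, tau_true, dt_threshold = 0.01)
  expect_equal(kept$acq, 1:2)
  # a sample at 2% dead time is excluded at the 1% threshold
  r_2pc <- log(1.02) / (1.02 * tau_true)
  expect_equal(select_dt_free(data.frame(acq = 1:2, activity_MBq = 1:2,
                                         r_wo = c(0.1, 1) * r_2pc),
                              tau_true)$acq, 1)
  expect_error(select_dt_free(data.frame(acq = 1, activity_MBq = 1,
                                         r_wo = 2 * r_bound), tau_true),
               "low-activity")
})

test_that("joint fit recovers truth exactly from noise-free on-model data", {
  s <- model_samples(exp(seq(log(20), log(12000), length.out = 12)))
  fit <- fit_method_b(s)
  expect_equal(fit$cf, cf_true, tolerance = 1e-8)
  expect_equal(fit$tau, tau_true, tolerance = 1e-8)
  # fixed-CF variant likewise
  res <- fit_method_a_tau(s, cf = cf_true)
  expect_equal(res$tau, tau_true, tolerance = 1e-8)
})

test_that("estimates are invariant to sample order and duration rescaling", {
  cam <- camera_truth()
  ph <- phantom_truth("Air-2D")
  rec <- generate_series(cam, ph, default_planar_plan(seed = 5,
                                                      noise = FALSE))
  f1 <- calibrate(rec, "B")
  shuffled <- rec[sample(nrow(rec)), ]
  f2 <- calibrate(shuffled, "B")
  expect_equal(f2$cf, f1$cf, tolerance = 1e-10)
  expect_equal(f2$tau, f1$tau, tolerance = 1e-10)
  # doubling durations and counts leaves every rate, hence the fit, unchanged
  rescaled <- rec
  cnt <- grep("^counts_", names(rec))
  rescaled$duration_s <- rec$duration_s * 2
  rescaled[cnt] <- rec[cnt] * 2
  f3 <- calibrate(rescaled, "B")
  expect_equal(f3$cf, f1$cf, tolerance = 1e-10)
  expect_equal(f3$tau, f1$tau, tolerance = 1e-10)
})

test_that("tau is flagged unidentifiable when samples span no curvature", {
  a <- seq(0.5, 5, length.out = 6)   # < 0.03% dead-time loss
  s <- model_samples(a)
  expect_warning(fit_method_a_tau(s, cf = cf_true), "poorly identified")
})

test_that("two-step and joint estimates agree within the dead-time-free bias bound", {
  cam <- camera_truth()
  ph <- phantom_truth("Air-2D")
  rec <- generate_series(cam, ph, default_planar_plan(seed = 2,
                                                      noise = FALSE))
  fb <- calibrate(rec, "B")
  fa <- calibrate(rec, "A", dt_threshold = 0.01)
  # Method A's CF carries a downward bias bounded by the tolerated loss
  expect_lt(abs(fa$cf - fb$cf) / fb$cf, 0.01)
  expect_lt(abs(fa$tau - fb$tau) / fb$tau, 0.05)
  # tightening the dead-time-free threshold tightens the agreement
  fa_tight <- calibrate(rec, "A", dt_threshold = 0.002)
  expect_lt(abs(fa_tight$cf - fb$cf), abs(fa$cf - fb$cf))
  expect_lt(abs(fa_tight$cf - fb$cf) / fb$cf, 0.005)
})

test_that("usable range is detected at the saturation boundary", {
  cam <- camera_truth()
  ph <- phantom_truth("Air-2D")
  rec <- generate_series(cam, ph, default_planar_plan(seed = 1,
                                                      noise = FALSE))
  fit <- calibrate(rec, "B")
  ur <- fit$usable_range
  expect_true(ur$reached)
  # boundary within one sample of the true saturation rate: the last
  # retained sample is below 350 kcps, the first excluded one above
  expect_lt(ur$max_wide_rate, cam$saturation_rate)
  s <- build_samples(rec)
  first_out <- min(s$x_w[!ur$in_range])
  expect_gt(cf_true * first_out * exp(-cf_true * first_out * tau_true),
            cam$saturation_rate)
  # on-model data with no distortion: no exclusions, limit not reached
  s_clean <- model_samples(exp(seq(log(20), log(8000), length.out = 10)))
  ur2 <- detect_usable_range(s_clean, list(cf = cf_true, tau = tau_true))
  expect_false(ur2$reached)
  expect_true(all(ur2$in_range))
  # single on-model sample: that sample is the (unreached) range
  ur3 <- detect_usable_range(s_clean[5, ], list(cf = cf_true, tau = tau_true))
  expect_false(ur3$reached)
  expect_equal(ur3$max_activity, s_clean$activity_MBq[5])
})

test_that("per-detector divergence beyond saturation marks samples out of range", {
  cam <- camera_truth()
  ph <- phantom_truth("Air-2D")
  rec <- generate_series(cam, ph, default_planar_plan(seed = 1,
                                                      noise = FALSE))
  s <- build_samples(rec)
  top <- which.max(s$x_w)
  expect_gt(abs(s$r_po_d1[top] - s$r_po_d2[top]) /
              ((s$r_po_d1[top] + s$r_po_d2[top]) / 2), 0.05)
  fit <- calibrate(rec, "B")
  expect_false(fit$usable_range$in_range[top])
})

test_that("sensitivity is flat after dead-time correction, declining before", {
  cam <- camera_truth()
  ph <- phantom_truth("Air-2D")
  rec <- generate_series(cam, ph, default_planar_plan(seed = 3,
                                                      noise = FALSE))
  fit <- calibrate(rec, "B")
  s <- build_samples(rec)[fit$usable_range$in_range, ]
  tab <- sensitivity_table(s, fit)
  expect_true(all(diff(tab$sensitivity[order(tab$activity_MBq)]) < 0))
  expect_equal(tab$corrected_sensitivity, rep(fit$cf, nrow(tab)),
               tolerance = 1e-6)
  expect_error(sensitivity_table(data.frame(acq = 1, activity_MBq = 0,
                                            r_po = 1, r_wo = 1)),
               "non-positive activity")
})

test_that("calibration results round-trip through JSON", {
  cam <- camera_truth()
  ph <- phantom_truth("Air-2D")
  rec <- generate_series(cam, ph, default_planar_plan(seed = 4,
                                                      noise = FALSE))
  fit <- calibrate(rec, "B")
  path <- tempfile(fileext = ".json")
  write_calibration(fit, path)
  back <- read_calibration(path)
  expect_equal(back$cf, fit$cf)
  expect_equal(back$tau, fit$tau, tolerance = 1e-12)
  expect_equal(back$method, "B")
  expect_equal(back$usable_range$max_wide_rate,
               fit$usable_range$max_wide_rate)
  unlink(path)
})
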