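test_that("window limits follow centre +/- half width, with display rounding", {
  expect_equal(window_limits(208, 0.20),
               c(lower = 187.2, upper = 228.8))
  expect_equal(window_limits(208, 0.20, report = TRUE),
               c(lower = 187, upper = 229))
  expect_equal(window_limits(111, 1.00),
               c(lower = 55.5, upper = 166.5))
  expect_error(window_limits(208, 0), "width_fraction")
  expect_error(window_limits(-5, 0.2), "centre")
  expect_error(window_limits(208, 1.5), "width_fraction")
})

test_that("bundled Lu-177 scheme stores the vendor-reported integer limits", {
  sch <- lu177_scheme()
  lims <- t(vapply(sch$windows, function(w) c(w$lower, w$upper), numeric(2)))
  expect_equal(lims[c("PP", "LS", "US", "G1", "G2", "G3"), ],
               matrix(c(187, 229, 166, 187, 229, 250, 250, 680, 55, 166,
                        18, 55),
                      ncol = 2, byrow = TRUE,
                      dimnames = list(c("PP", "LS", "US", "G1", "G2", "G3"),
                                      NULL)))
  expect_setequal(sch$combinations[["3W"]], c("PP", "LS", "G2"))
  expect_setequal(sch$combinations[["4W"]], c("PP", "LS", "US", "G2"))
  expect_setequal(sch$combinations[["6W"]],
                  c("PP", "LS", "US", "G1", "G2", "G3"))
  expect_setequal(sch$scatter_windows$TEW, c("LS", "US"))
  expect_identical(sch$scatter_windows$DEW, "LS")
})

test_that("scheme construction validates window and combination references", {
  w <- list(energy_window("PP", 208, 0.20), energy_window("LS", 176.5, 0.119))
  expect_error(window_scheme(w, list(bad = c("PP", "XX")),
                             list(TEW = "LS")),
               "unknown window")
  expect_error(window_scheme(w[2], list(a = "LS"), list(TEW = "LS")),
               "photopeak")
  expect_error(energy_window("PP", lower = 229, upper = 187), "lower < upper")
})

test_that("combined rate sums member windows over duration", {
  wc <- window_counts(c(PP = 100, LS = 20, US = 10, G1 = 0, G2 = 70, G3 = 0),
                      duration = 1)
  expect_equal(combined_rate(wc, "4W"), 200)
  expect_equal(combined_rate(wc, "photopeak"), 100)
  zero <- window_counts(c(PP = 0, LS = 0, US = 0, G1 = 0, G2 = 0, G3 = 0), 5)
  expect_equal(combined_rate(zero, "6W"), 0)
  expect_error(combined_rate(wc, "9W"), "unknown combination")
})

test_that("combined rate is permutation-invariant and additive over windows", {
  sch <- lu177_scheme()
  perm <- sch
  perm$combinations[["6W"]] <- rev(perm$combinations[["6W"]])
  set.seed(42)
  for (i in 1:10) {
    cnts <- stats::setNames(stats::rpois(6, 500),
                            c("PP", "LS", "US", "G1", "G2", "G3"))
    wc <- window_counts(cnts, duration = stats::runif(1, 1, 60))
    expect_equal(combined_rate(wc, "6W", sch), combined_rate(wc, "6W", perm))
    expect_equal(combined_rate(wc, "6W", sch),
                 combined_rate(wc, "4W", sch) +
                   cnts[["G1"]] / wc$duration + cnts[["G3"]] / wc$duration)
  }
})

test_that("TEW/DEW primary rate subtracts scatter windows", {
  wc <- window_counts(c(PP = 1000, LS = 60, US = 40), duration = 10)
  expect_equal(primary_rate(wc, "TEW"), 90)
  expect_equal(primary_rate(wc, "DEW"), 94)
  clean <- window_counts(c(PP = 1000, LS = 0, US = 0), 1)
  expect_equal(primary_rate(clean, "TEW"), 1000)
  expect_error(primary_rate(window_counts(c(PP = 10, LS = 1), 1), "TEW"),
               "missing")
})

test_that("negative scatter subtraction follows the clipping policy", {
  wc <- window_counts(c(PP = 50, LS = 60, US = 40), duration = 1)
  expect_warning(r <- primary_rate(wc, "TEW"), "clipped")
  expect_equal(r, 0)
  expect_equal(primary_rate(wc, "TEW", negative = "keep"), -50)
})

test_that("primary rate never exceeds the photopeak rate", {
  set.seed(7)
  for (i in 1:20) {
    cnts <- stats::setNames(stats::rpois(6, c(800, 50, 30, 20, 400, 60)),
                            c("PP", "LS", "US", "G1", "G2", "G3"))
    wc <- window_counts(cnts, duration = 3)
    expect_lte(suppressWarnings(primary_rate(wc, "TEW")),
               cnts[["PP"]] / wc$duration)
  }
  # equality iff scatter windows empty
  wc <- window_counts(c(PP = 500, LS = 0, US = 0), 2)
  expect_equal(primary_rate(wc, "TEW"), 250)
})

test_that("width-weighted TEW reduces to plain subtraction for half-width scatter windows", {
  wc <- window_counts(c(PP = 1000, LS = 60, US = 40), duration = 10)
  expect_equal(primary_rate(wc, "TEW", width_weighted = TRUE),
               primary_rate(wc, "TEW"))
})

test_that("window schemes round-trip through JSON and YAML", {
  sch <- lu177_scheme()
  for (ext in c("json", "yaml")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_window_scheme(sch, path)
    back <- read_window_scheme(path)
    expect_equal(back$combinations, sch$combinations)
    expect_equal(back$scatter_windows, sch$scatter_windows)
    expect_equal(vapply(back$windows, function(w) w$lower, numeric(1)),
                 vapply(sch$windows, function(w) w$lower, numeric(1)))
    unlink(path)
  }
})
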