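#' Read / write acquisition records
#'
#' Acquisition records hold one row per acquisition and detector with the raw
#' per-window counts.  Required columns: `acq` (acquisition id, shared by the
#' two detector rows of one acquisition), `phantom`, `mode`
#' (`"planar"`/`"tomo"`), `detector` (1 or 2), `duration_s` (frame duration,
#' or time per projection for tomographic data), `n_projections` (1 for
#' planar), `activity_MBq` (known activity at scan time) and `counts_<W>`
#' for every window `<W>` of the scheme (e.g. `counts_PP` .. `counts_G3`).
#'
#' @param path CSV file path.
#' @return A data frame of acquisition records.
#' @export
read_acquisitions <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_records(rec)
  rec
}

#' @param records Acquisition-record data frame.
#' @rdname read_acquisitions
#' @export
write_acquisitions <- function(records, path) {
  validate_records(records)
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

validate_records <- function(records, scheme = NULL) {
  need <- c("acq", "phantom", "mode", "detector", "duration_s",
            "n_projections", "activity_MBq")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("acquisition records lack column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!any(grepl("^counts_", names(records))))
    stop("acquisition records lack counts_* columns", call. = FALSE)
  if (!is.null(scheme)) {
    missing <- setdiff(paste0("counts_", names(scheme$windows)),
                       names(records))
    if (length(missing))
      stop("acquisition records lack column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(records$activity_MBq <= 0))
    stop("activities must be > 0", call. = FALSE)
  if (any(records$duration_s <= 0) || any(records$n_projections <= 0))
    stop("durations and projection counts must be > 0", call. = FALSE)
  invisible(records)
}

#' Dead-time driver term X_W
#'
#' `X_W = A * R_Wo / R_Po`: the known activity scaled by the ratio of the
#' observed wide-spectrum rate to the observed primary rate.  Plotting `R_Wo`
#' against `X_W` linearizes the calibration problem into the paralysable form
#' `R_Wo = CF * X_W * exp(-CF * X_W * tau)`.
#'
#' @param activity Known activity in MBq.
#' @param r_wo Observed wide-spectrum count rate in cps.
#' @param r_po Observed primary count rate in cps (> 0).
#' @return `X_W` in MBq (activity scaled by a dimensionless rate ratio).
#' @export
x_w <- function(activity, r_wo, r_po) {
  if (any(r_po <= 0))
    stop("X_W undefined where the observed primary rate is 0", call. = FALSE)
  activity * r_wo / r_po
}

#' Build calibration samples from acquisition records
#'
#' Converts raw per-window counts into one calibration observation per
#' acquisition: the scatter-corrected primary rate `r_po`, the wide-spectrum
#' rate `r_wo` for the chosen window combination, the photopeak-window rate
#' `r_pp`, and the driver `x_w`.  With `detector = "avg"` the per-window
#' counts of the two detectors are averaged before any rate is computed, and
#' the per-detector primary rates are kept alongside for divergence
#' diagnostics.
#'
#' @inheritParams read_acquisitions
#' @param combination Window combination driving the dead-time model:
#'   `"photopeak"`, `"3W"`, `"4W"` or `"6W"` for the bundled scheme.
#' @param scatter Scatter-correction mode, `"TEW"` or `"DEW"`.
#' @param detector `"avg"`, `1` or `2`.
#' @param scheme A [window_scheme()].
#' @param negative Negative scatter-subtraction policy, see [primary_rate()].
#' @return A data frame of class `acq_samples` with one row per acquisition.
#' @export
build_samples <- function(records, combination = "6W",
                          scatter = c("TEW", "DEW"), detector = "avg",
                          scheme = lu177_scheme(),
                          negative = c("clip", "keep")) {
  scatter <- match.arg(scatter)
  negative <- match.arg(negative)
  validate_records(records, scheme)
  cnt_cols <- paste0("counts_", names(scheme$windows))

  per_detector_rpo <- function(rec_rows, det) {
    rows <- rec_rows[rec_rows$detector == det, , drop = FALSE]
    if (nrow(rows) != 1) return(NA_real_)
    wc <- row_window_counts(rows, scheme)
    suppressWarnings(primary_rate(wc, scatter, scheme, negative))
  }

  out <- lapply(split(records, records$acq), function(rr) {
    first <- rr[1, , drop = FALSE]
    if (identical(detector, "avg")) {
      cnts <- colMeans(rr[, cnt_cols, drop = FALSE])
      use <- first
      use[, cnt_cols] <- as.list(cnts)
      det_label <- "avg"
      rpo_d1 <- per_detector_rpo(rr, 1)
      rpo_d2 <- per_detector_rpo(rr, 2)
    } else {
      use <- rr[rr$detector == as.integer(detector), , drop = FALSE]
      if (nrow(use) != 1)
        stop("acquisition ", first$acq, ": expected one row for detector ",
             detector, call. = FALSE)
      det_label <- as.character(detector)
      rpo_d1 <- rpo_d2 <- NA_real_
    }
    wc <- row_window_counts(use, scheme)
    r_po <- primary_rate(wc, scatter, scheme, negative)
    r_wo <- combined_rate(wc, combination, scheme)
    r_pp <- wc$counts[[scheme$photopeak]] / wc$duration
    data.frame(
      acq = first$acq, phantom = first$phantom, mode = first$mode,
      detector = det_label, activity_MBq = first$activity_MBq,
      duration_s = first$duration_s, n_projections = first$n_projections,
      r_pp = r_pp, r_po = r_po, r_wo = r_wo,
      x_w = if (r_po > 0) x_w(first$activity_MBq, r_wo, r_po) else NA_real_,
      r_po_d1 = rpo_d1, r_po_d2 = rpo_d2,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$acq), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "combination") <- combination
  attr(out, "scatter") <- scatter
  class(out) <- c("acq_samples", "data.frame")
  out
}

row_window_counts <- function(row, scheme) {
  cnts <- unlist(row[paste0("counts_", names(scheme$windows))])
  names(cnts) <- names(scheme$windows)
  window_counts(cnts, row$duration_s * row$n_projections)
}

#' Method A, step 1: calibration factor from dead-time-free samples
#'
#' Ordinary least squares of the observed primary rate on known activity,
#' forced through the origin: `CF = sum(A * R_Po) / sum(A^2)`.  Meant to be
#' applied to a low-rate subset where dead-time losses are negligible (see
#' [select_dt_free()]).
#'
#' @param samples Data frame with columns `activity_MBq` and `r_po`.
#' @return List with `cf` (cps/MBq) and `cf_se` (its standard error from the
#'   residual variance; `NA` for a single sample).
#' @export
fit_method_a_cf <- function(samples) {
  a <- samples$activity_MBq
  r <- samples$r_po
  if (length(a) < 1) stop("need at least one sample", call. = FALSE)
  if (any(a <= 0)) stop("activities must be > 0", call. = FALSE)
  cf <- sum(a * r) / sum(a^2)
  n <- length(a)
  se <- if (n > 1) sqrt(sum((r - cf * a)^2) / (n - 1) / sum(a^2))
        else NA_real_
  list(cf = cf, cf_se = se, n = n)
}

#' Select dead-time-free samples
#'
#' Keeps samples whose dead-time correction factor, computed from the
#' wide-spectrum observed rate under a provisional dead-time constant, is
#' below `1 + dt_threshold` (default: less than 1% dead time).
#'
#' @param samples An `acq_samples` data frame (needs `r_wo`).
#' @param tau_provisional Provisional dead-time constant in seconds.
#' @param dt_threshold Maximum tolerated fractional dead-time loss.
#' @return The retained subset of `samples`.
#' @export
select_dt_free <- function(samples, tau_provisional, dt_threshold = 0.01) {
  check_tau(tau_provisional)
  f <- correction_factor(samples$r_wo, tau_provisional)
  keep <- (f - 1) < dt_threshold
  if (!any(keep))
    stop("no sample below ", 100 * dt_threshold,
         "% dead time: series lacks low-activity data", call. = FALSE)
  samples[keep, , drop = FALSE]
}

# core nonlinear fit of R_Wo = cf * x * exp(-cf * x * tau); tau is
# parameterized as log(tau) for positivity and conditioning.  Data heavily
# contaminated by post-saturation samples can drive the Levenberg-Marquardt
# fit into a singular corner, so a derivative-free restart supplies better
# starting values before giving up.
fit_paralysable_nls <- function(x, r_wo, cf_start, tau_start = 0.5e-6,
                                fix_cf = NULL, weights = c("none", "poisson")) {
  weights <- match.arg(weights)
  df <- data.frame(x = x, rwo = r_wo)
  w <- if (weights == "poisson") 1 / pmax(df$rwo, 1) else rep(1, nrow(df))
  run_nls <- function(cf0, tau0) {
    if (is.null(fix_cf)) {
      minpack.lm::nlsLM(
        rwo ~ cf * x * exp(-cf * x * exp(ltau)), data = df,
        start = list(cf = cf0, ltau = log(tau0)), weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14))
    } else {
      cf <- fix_cf
      minpack.lm::nlsLM(
        rwo ~ cf * x * exp(-cf * x * exp(ltau)), data = df,
        start = list(ltau = log(tau0)), weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14))
    }
  }
  fit <- try(run_nls(cf_start, tau_start), silent = TRUE)
  if (inherits(fit, "try-error")) {
    ssr <- function(p) {
      cf <- if (is.null(fix_cf)) exp(p[1]) else fix_cf
      tau <- exp(p[length(p)])
      sum(w * (df$rwo - cf * df$x * exp(-cf * df$x * tau))^2)
    }
    p0 <- if (is.null(fix_cf)) c(log(cf_start), log(tau_start))
          else log(tau_start)
    opt <- stats::optim(p0, ssr, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    fit <- try(run_nls(if (is.null(fix_cf)) exp(opt$par[1]) else cf_start,
                       exp(opt$par[length(opt$par)])), silent = TRUE)
    if (inherits(fit, "try-error"))
      stop("paralysable-model fit failed to converge; data may not span ",
           "enough dead-time curvature or may be dominated by ",
           "post-saturation samples", call. = FALSE)
  }
  est <- summary(fit)$coefficients
  tau <- exp(est["ltau", "Estimate"])
  tau_se <- tau * est["ltau", "Std. Error"]   # delta method on log scale
  list(
    cf = if (is.null(fix_cf)) est["cf", "Estimate"] else fix_cf,
    cf_se = if (is.null(fix_cf)) est["cf", "Std. Error"] else NA_real_,
    tau = tau, tau_se = tau_se, fit = fit)
}

warn_tau_identifiability <- function(cf, tau, tau_se, x) {
  loss_span <- cf * max(x) * tau
  if (!is.finite(tau_se) || (is.finite(loss_span) && loss_span < 0.01) ||
      (is.finite(tau_se) && tau_se > tau))
    warning("dead-time constant poorly identified: samples span ",
            sprintf("%.3g", 100 * loss_span),
            "% maximum dead-time loss; its SE is unreliable", call. = FALSE)
  invisible(NULL)
}

#' Method A, step 2: dead-time constant with the calibration factor fixed
#'
#' Unweighted nonlinear least squares of
#' `R_Wo = CF * X_W * exp(-CF * X_W * tau)` over `tau` alone, with `CF` held
#' at the value determined from the dead-time-free subset.
#'
#' @param samples Data frame with columns `x_w` and `r_wo` (full usable
#'   activity range).
#' @param cf Fixed calibration factor in cps/MBq.
#' @param weights `"none"` (default) or `"poisson"` (inverse-rate weights).
#' @return List with `tau` (s), `tau_se` (s) and the underlying `nls` fit.
#' @export
fit_method_a_tau <- function(samples, cf, weights = c("none", "poisson")) {
  if (nrow(samples) < 2)
    stop("need at least two samples to fit tau", call. = FALSE)
  if (cf <= 0) stop("cf must be > 0", call. = FALSE)
  res <- fit_paralysable_nls(samples$x_w, samples$r_wo, cf_start = cf,
                             fix_cf = cf, weights = match.arg(weights))
  warn_tau_identifiability(cf, res$tau, res$tau_se, samples$x_w)
  res[c("tau", "tau_se", "fit")]
}

#' Method B: joint fit of calibration factor and dead-time constant
#'
#' Single nonlinear least-squares fit of
#' `R_Wo = CF * X_W * exp(-CF * X_W * tau)` over the full usable activity
#' range, determining `CF` and `tau` simultaneously.  The functional form
#' forces the curve through the origin; no dead-time-free subset needs to be
#' designated in advance.  Starting values: `CF` from a through-origin slope
#' of the lowest-decile `X_W` points, `tau = 0.5` microseconds.
#'
#' @inheritParams fit_method_a_tau
#' @param combination Window-combination label stored in the result.
#' @return An object of class `calibration_fit`.
#' @export
fit_method_b <- function(samples, weights = c("none", "poisson"),
                         combination = attr(samples, "combination")) {
  if (nrow(samples) < 3)
    stop("need at least three samples spanning low and high rates",
         call. = FALSE)
  ord <- order(samples$x_w)
  low <- samples[ord[seq_len(max(2, ceiling(nrow(samples) / 10)))], ]
  cf0 <- sum(low$x_w * low$r_wo) / sum(low$x_w^2)
  res <- fit_paralysable_nls(samples$x_w, samples$r_wo, cf_start = cf0,
                             weights = match.arg(weights))
  warn_tau_identifiability(res$cf, res$tau, res$tau_se, samples$x_w)
  new_calibration_fit(
    cf = res$cf, cf_se = res$cf_se, tau = res$tau, tau_se = res$tau_se,
    method = "B", combination = combination, n_used = nrow(samples),
    fit = res$fit)
}

new_calibration_fit <- function(cf, cf_se, tau, tau_se, method, combination,
                                n_used, scatter = NULL, detector = NULL,
                                usable_range = NULL, excluded = NULL,
                                fit = NULL) {
  if (cf <= 0 || tau <= 0)
    stop("calibration fit produced non-positive parameters (cf = ",
         signif(cf, 4), ", tau = ", signif(tau, 4), ")", call. = FALSE)
  structure(
    list(cf = cf, cf_se = cf_se, tau = tau, tau_se = tau_se,
         method = method,
         combination = if (is.null(combination)) NA_character_ else combination,
         scatter = scatter, detector = detector, n_used = n_used,
         usable_range = usable_range, excluded = excluded, fit = fit),
    class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit>  Method ", x$method,
      if (!is.na(x$combination)) paste0(", driver ", x$combination), "\n",
      sep = "")
  cat(sprintf("  CF  = %.4g +/- %.2g cps/MBq\n", x$cf, x$cf_se))
  cat(sprintf("  tau = %.4g +/- %.2g us\n", x$tau * 1e6, x$tau_se * 1e6))
  cat("  samples used:", x$n_used,
      if (!is.null(x$excluded) && nrow(x$excluded))
        paste0("(", nrow(x$excluded), " excluded)"), "\n")
  if (!is.null(x$usable_range)) print(x$usable_range)
  invisible(x)
}

#' Detect the usable operating range of the system
#'
#' Walks the samples in order of increasing `X_W` and flags the onset of
#' detector misbehaviour: the first sample whose observed wide-spectrum rate
#' falls more than `drop_tolerance` below the fitted paralysable prediction
#' (sensitivity drop), or whose per-detector primary rates differ by more
#' than `drop_tolerance` of their mean (divergent detectors).  All samples
#' from that point on are out of range.
#'
#' @param samples An `acq_samples` data frame.
#' @param fit A [fit_method_b()]-style `calibration_fit` (or any list with
#'   `cf` and `tau`).
#' @param drop_tolerance Fractional deviation triggering exclusion
#'   (default 0.05).
#' @return An object of class `usable_range`: `max_activity` (MBq),
#'   `max_photopeak_rate` and `max_wide_rate` (cps) of the last in-range
#'   sample, `reached` (`FALSE` when no drop was found), and `in_range`, a
#'   logical vector over the rows of `samples`.
#' @export
detect_usable_range <- function(samples, fit, drop_tolerance = 0.05) {
  ord <- order(samples$x_w)
  pred <- fit$cf * samples$x_w * exp(-fit$cf * samples$x_w * fit$tau)
  drop <- samples$r_wo < (1 - drop_tolerance) * pred
  diverge <- rep(FALSE, nrow(samples))
  if (all(c("r_po_d1", "r_po_d2") %in% names(samples))) {
    d1 <- samples$r_po_d1
    d2 <- samples$r_po_d2
    ok <- is.finite(d1) & is.finite(d2) & (d1 + d2) > 0
    diverge[ok] <- abs(d1[ok] - d2[ok]) / ((d1[ok] + d2[ok]) / 2) >
      drop_tolerance
  }
  violation <- drop | diverge
  viol_sorted <- violation[ord]
  in_range <- rep(TRUE, nrow(samples))
  reached <- any(viol_sorted)
  if (reached) {
    first <- which(viol_sorted)[1]
    in_range[ord[first:length(ord)]] <- FALSE
  }
  if (any(in_range)) {
    last <- samples[in_range, , drop = FALSE]
    last <- last[which.max(last$x_w), ]
    maxes <- list(last$activity_MBq, last$r_pp, last$r_wo)
  } else {
    maxes <- list(NA_real_, NA_real_, NA_real_)
  }
  structure(
    list(max_activity = maxes[[1]], max_photopeak_rate = maxes[[2]],
         max_wide_rate = maxes[[3]], reached = reached, in_range = in_range,
         violation = violation),
    class = "usable_range")
}

#' @export
print.usable_range <- function(x, ...) {
  cat(sprintf(
    "  usable range%s: A <= %.4g MBq, photopeak <= %.4g kcps, wide <= %.4g kcps\n",
    if (!x$reached) " (limit not reached)" else "",
    x$max_activity, x$max_photopeak_rate / 1000, x$max_wide_rate / 1000))
  invisible(x)
}

#' Calibrate a camera from serial acquisitions
#'
#' End-to-end calibration: builds samples from raw acquisition records,
#' iteratively fits the paralysable model (Method B) and excludes samples
#' beyond the detected usable range until the selection is stable, then
#' reports either the joint Method B estimates or the two-step Method A
#' estimates (dead-time-free subset for `CF`, fixed-`CF` fit for `tau`).
#' Method A's dead-time-free subset is chosen with the provisional Method B
#' `tau` unless a fixed low-activity cutoff is supplied.
#'
#' @param records Acquisition records (see [read_acquisitions()]), or an
#'   `acq_samples` data frame from [build_samples()].
#' @param method `"B"` (joint fit, default) or `"A"` (two-step).
#' @inheritParams build_samples
#' @inheritParams fit_method_a_tau
#' @inheritParams detect_usable_range
#' @param dt_threshold Method A dead-time-free threshold (fractional loss).
#' @param low_activity_max Optional fixed activity cutoff (MBq) overriding
#'   the dead-time-based selection of Method A's `CF` subset.
#' @param max_iter Maximum fit/exclude iterations.
#' @return A `calibration_fit` with the detected [detect_usable_range()]
#'   and an `excluded` data frame of out-of-range acquisitions.
#' @export
calibrate <- function(records, method = c("B", "A"), combination = "6W",
                      scatter = c("TEW", "DEW"), detector = "avg",
                      scheme = lu177_scheme(), weights = c("none", "poisson"),
                      dt_threshold = 0.01, drop_tolerance = 0.05,
                      low_activity_max = NULL, max_iter = 5,
                      negative = c("clip", "keep")) {
  method <- match.arg(method)
  scatter <- match.arg(scatter)
  weights <- match.arg(weights)
  samples <- if (inherits(records, "acq_samples")) records
             else build_samples(records, combination, scatter, detector,
                                scheme, match.arg(negative))

  # iterative trimming: a fit contaminated by post-saturation samples can
  # make the whole low-rate series look deviant, so violating samples are
  # removed from the top of the X_W range one step per iteration and the
  # model refitted until the retained samples are all consistent with it
  include <- rep(TRUE, nrow(samples))
  fit_b <- NULL
  ur <- NULL
  for (i in seq_len(max_iter)) {
    fit_b <- fit_method_b(samples[include, , drop = FALSE],
                          weights = weights, combination = combination)
    ur <- detect_usable_range(samples, fit_b, drop_tolerance)
    viol_in <- ur$violation & include
    if (!any(viol_in)) break
    include <- include & samples$x_w < max(samples$x_w[viol_in])
    if (sum(include) < 3)
      stop("usable-range trimming left fewer than 3 samples; ",
           "data inconsistent with the paralysable model at drop_tolerance = ",
           drop_tolerance, call. = FALSE)
  }
  include <- ur$in_range
  used <- samples[include, , drop = FALSE]
  excluded <- data.frame(
    acq = samples$acq[!include],
    activity_MBq = samples$activity_MBq[!include],
    reason = rep("beyond usable range", sum(!include)))

  if (method == "B") {
    out <- new_calibration_fit(
      cf = fit_b$cf, cf_se = fit_b$cf_se, tau = fit_b$tau,
      tau_se = fit_b$tau_se, method = "B", combination = combination,
      scatter = scatter, detector = as.character(detector),
      n_used = nrow(used), usable_range = ur, excluded = excluded,
      fit = fit_b$fit)
    return(out)
  }

  low <- if (!is.null(low_activity_max)) {
    sub <- used[used$activity_MBq <= low_activity_max, , drop = FALSE]
    if (!nrow(sub))
      stop("no sample at or below low_activity_max = ", low_activity_max,
           " MBq", call. = FALSE)
    sub
  } else {
    select_dt_free(used, tau_provisional = fit_b$tau,
                   dt_threshold = dt_threshold)
  }
  cf_a <- fit_method_a_cf(low)
  tau_a <- fit_method_a_tau(used, cf = cf_a$cf, weights = weights)
  new_calibration_fit(
    cf = cf_a$cf, cf_se = cf_a$cf_se, tau = tau_a$tau, tau_se = tau_a$tau_se,
    method = "A", combination = combination, scatter = scatter,
    detector = as.character(detector), n_used = nrow(used),
    usable_range = ur, excluded = excluded, fit = tau_a$fit)
}

#' Camera sensitivity table
#'
#' Sensitivity is the observed primary rate per unit known activity; it
#' equals the calibration factor only after dead-time correction.  Given a
#' calibration fit, the dead-time-corrected sensitivity
#' `f(R_Wo, tau) * R_Po / A` is added; corrected values should scatter
#' flatly around `CF` within the usable range.
#'
#' @param samples An `acq_samples` data frame (activities must be > 0).
#' @param fit Optional `calibration_fit` supplying `tau`.
#' @return Data frame with `activity_MBq`, `r_po`, `r_wo`, `sensitivity`
#'   and (if `fit` given) `f` and `corrected_sensitivity`.
#' @export
sensitivity_table <- function(samples, fit = NULL) {
  if (any(samples$activity_MBq <= 0))
    stop("sensitivity undefined for non-positive activity", call. = FALSE)
  out <- data.frame(
    acq = samples$acq, activity_MBq = samples$activity_MBq,
    r_po = samples$r_po, r_wo = samples$r_wo,
    sensitivity = samples$r_po / samples$activity_MBq)
  if (!is.null(fit)) {
    out$f <- correction_factor(samples$r_wo, fit$tau)
    out$corrected_sensitivity <- out$f * out$sensitivity
  }
  out
}

#' Read / write a calibration result
#'
#' Calibration results are serialized as JSON with the dead-time constant in
#' microseconds (`tau_us`), the calibration factor in cps/MBq, the usable
#' range, and the excluded acquisitions.
#'
#' @param fit A `calibration_fit`.
#' @param path JSON file path.
#' @return `read_calibration()` returns a `calibration_fit` (without the
#'   underlying `nls` object); `write_calibration()` returns `path`
#'   invisibly.
#' @export
write_calibration <- function(fit, path) {
  ur <- fit$usable_range
  out <- list(
    cf_cps_per_MBq = fit$cf, cf_se = fit$cf_se,
    tau_us = fit$tau * 1e6, tau_se_us = fit$tau_se * 1e6,
    method = fit$method, combination = fit$combination,
    scatter = fit$scatter, detector = fit$detector, n_used = fit$n_used,
    usable_range = if (!is.null(ur)) list(
      max_activity_MBq = ur$max_activity,
      max_photopeak_rate_cps = ur$max_photopeak_rate,
      max_wide_rate_cps = ur$max_wide_rate, reached = ur$reached),
    excluded = if (!is.null(fit$excluded) && nrow(fit$excluded))
      fit$excluded)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ur <- NULL
  if (!is.null(x$usable_range))
    ur <- structure(
      list(max_activity = x$usable_range$max_activity_MBq,
           max_photopeak_rate = x$usable_range$max_photopeak_rate_cps,
           max_wide_rate = x$usable_range$max_wide_rate_cps,
           reached = x$usable_range$reached, in_range = NULL),
      class = "usable_range")
  new_calibration_fit(
    cf = x$cf_cps_per_MBq, cf_se = null2na(x$cf_se),
    tau = x$tau_us * 1e-6, tau_se = null2na(x$tau_se_us) * 1e-6,
    method = x$method, combination = x$combination, scatter = x$scatter,
    detector = x$detector, n_used = x$n_used, usable_range = ur,
    excluded = x$excluded)
}

null2na <- function(x) if (is.null(x)) NA_real_ else x
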