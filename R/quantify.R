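#' Recover activity from observed rates
#'
#' Dead-time-corrects the observed primary rate using the wide-spectrum
#' driver and converts it to activity with the calibration factor:
#' `A_rec = R_Po * f(R_Wo, tau) / CF`.  When the known activity is supplied,
#' the accuracy (percent deviation of recovered from known) is scored, and
#' when the calibration carries a usable range, samples beyond it are
#' flagged out of range.
#'
#' @param r_po Observed primary count rate(s) in cps.
#' @param r_wo Observed wide-spectrum count rate(s) in cps (dead-time
#'   driver); must be below saturation for the fit's `tau`.
#' @param fit A `calibration_fit` (or any list with `cf`, `tau` and
#'   optionally `usable_range`, `combination`).
#' @param known_activity Optional known activities in MBq.
#' @param apply_dt_correction Set `FALSE` to skip the dead-time correction
#'   (`f` forced to 1), e.g. to study the uncorrected underestimation.
#' @param range_tolerance Fractional shortfall of the observed wide rate
#'   below the fitted paralysable prediction (at the sample's own driver
#'   `X_W`, computable when the known activity is given) beyond which a
#'   sample is flagged out of range.
#' @return A data frame of class `quant_result` with columns
#'   `recovered_activity_MBq`, `correction_factor`, `known_activity_MBq`,
#'   `accuracy_percent`, `in_range` and `combination`.
#' @export
recover_activity <- function(r_po, r_wo, fit, known_activity = NULL,
                             apply_dt_correction = TRUE,
                             range_tolerance = 0.05) {
  f <- if (apply_dt_correction) correction_factor(r_wo, fit$tau)
       else rep(1, length(r_wo))
  rec <- r_po * f / fit$cf
  n <- length(rec)
  known <- if (is.null(known_activity)) rep(NA_real_, n) else known_activity
  acc <- ifelse(is.finite(known) & known > 0,
                (rec - known) / known * 100, NA_real_)
  in_range <- rep(TRUE, n)
  ur <- fit$usable_range
  if (!is.null(ur) && isTRUE(ur$reached))
    in_range <- r_wo <= ur$max_wide_rate
  # beyond saturation the observed wide rate folds back below the usable
  # maximum, so the rate ceiling alone cannot flag a distorted sample.  With
  # a known activity the driver X_W is computable and the geometry-free
  # check is a shortfall of R_Wo against the fitted paralysable prediction.
  chk <- is.finite(known) & known > 0 & r_po > 0
  if (any(chk)) {
    x <- known[chk] * r_wo[chk] / r_po[chk]
    pred <- fit$cf * x * exp(-fit$cf * x * fit$tau)
    in_range[chk] <- in_range[chk] &
      r_wo[chk] >= (1 - range_tolerance) * pred
  }
  out <- data.frame(
    recovered_activity_MBq = rec, correction_factor = f,
    known_activity_MBq = known, accuracy_percent = acc, in_range = in_range,
    combination = if (!is.null(fit$combination)) fit$combination
                  else NA_character_,
    stringsAsFactors = FALSE)
  class(out) <- c("quant_result", "data.frame")
  out
}

#' Summarize quantification accuracy
#'
#' Arithmetic mean and sample standard deviation of the percent accuracies.
#' Out-of-range results are excluded from the summary by default and
#' reported separately (set `include_out_of_range = TRUE` to pool them).
#'
#' @param results A `quant_result` data frame from [recover_activity()].
#' @param include_out_of_range Pool out-of-range samples into the summary.
#' @return List with `mean`, `sd` (NA for a single value), `n` and
#'   `n_out_of_range`.
#' @export
accuracy_summary <- function(results, include_out_of_range = FALSE) {
  acc <- results$accuracy_percent
  keep <- !is.na(acc)
  if (!include_out_of_range && "in_range" %in% names(results))
    keep <- keep & results$in_range
  if (!any(keep))
    stop("no in-range accuracy values to summarize", call. = FALSE)
  x <- acc[keep]
  list(mean = mean(x),
       sd = if (length(x) > 1) stats::sd(x) else NA_real_,
       n = length(x),
       n_out_of_range = sum(!is.na(acc)) - length(x))
}

#' Rescale slope mapping voxel counts to activity concentration
#'
#' The multiplicative factor that converts reconstructed voxel counts into
#' Bq/mL, integrating acquisition time, voxel volume, the calibration factor
#' and the dead-time correction factor:
#' `slope = f / (CF * acq_time * voxel_volume) * 1e6`.
#' Multiplying voxel counts by the slope yields activity concentration
#' (useful e.g. for exporting quantitative volumes in PET-like units).
#'
#' @param fit A `calibration_fit`, or a numeric calibration factor in
#'   cps/MBq.
#' @param f Dead-time correction factor for the acquisition (>= 1).
#' @param voxel_volume_ml Voxel volume in mL (> 0).
#' @param acq_time_s Total acquisition counting time in seconds (> 0); for
#'   tomographic data, projections times time per projection.
#' @return Slope in Bq/mL per voxel count.
#' @export
rescale_slope <- function(fit, f, voxel_volume_ml, acq_time_s) {
  cf <- if (inherits(fit, "calibration_fit")) fit$cf else fit
  if (any(c(cf, f, voxel_volume_ml, acq_time_s) <= 0))
    stop("cf, f, voxel_volume_ml and acq_time_s must all be > 0",
         call. = FALSE)
  f / (cf * acq_time_s * voxel_volume_ml) * 1e6
}

#' Quantify a series of calibration samples
#'
#' Convenience wrapper applying [recover_activity()] to every row of an
#' `acq_samples` data frame against its known activities.
#'
#' @param samples An `acq_samples` data frame (see [build_samples()]).
#' @inheritParams recover_activity
#' @return A `quant_result` data frame, one row per sample.
#' @export
quantify_samples <- function(samples, fit, apply_dt_correction = TRUE) {
  recover_activity(samples$r_po, samples$r_wo, fit,
                   known_activity = samples$activity_MBq,
                   apply_dt_correction = apply_dt_correction)
}
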