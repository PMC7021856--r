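#' Ground-truth camera description for the simulator
#'
#' Describes the synthetic dual-head camera: a per-detector calibration
#' factor, a single paralysable dead-time constant driven by the total
#' (wide-spectrum) event rate, the observed wide-spectrum rate beyond which
#' the detectors leave their usable range, per-detector post-saturation
#' sensitivity-decay coefficients (detector 2 degrades faster, emulating a
#' system that prioritizes detector 1 at high rate), and an optional pile-up
#' time constant displacing surviving primary events out of the photopeak.
#'
#' Defaults are a realistic Lu-177 system: `cf = 9.36` cps/MBq,
#' `tau = 0.550` microseconds, saturation at an observed wide-spectrum rate
#' of 350 kcps.
#'
#' @param cf Calibration factor(s) in cps/MBq; length 1 (both detectors) or 2.
#' @param tau Dead-time constant in seconds.
#' @param saturation_rate Observed wide-spectrum rate (cps) beyond which
#'   detector behaviour degrades; must not exceed the paralysable maximum
#'   `1/(e*tau)`.
#' @param divergence Length-2 per-detector decay coefficients applied beyond
#'   saturation (sensitivity multiplied by
#'   `exp(-divergence * excess / saturation_rate)`).
#' @param pileup_tau Pile-up time constant in seconds; 0 disables pile-up.
#' @return An object of class `camera_truth`.
#' @export
camera_truth <- function(cf = 9.36, tau = 0.550e-6, saturation_rate = 350e3,
                         divergence = c(3, 6), pileup_tau = 0) {
  check_tau(tau)
  if (any(cf <= 0)) stop("cf must be > 0", call. = FALSE)
  if (length(cf) == 1) cf <- rep(cf, 2)
  if (saturation_rate <= 0 || saturation_rate > max_observed_rate(tau))
    stop("saturation_rate must lie in (0, 1/(e*tau)]", call. = FALSE)
  if (length(divergence) != 2 || any(divergence < 0))
    stop("divergence must be two non-negative coefficients", call. = FALSE)
  if (pileup_tau < 0) stop("pileup_tau must be >= 0", call. = FALSE)
  structure(list(cf = cf, tau = tau, saturation_rate = saturation_rate,
                 divergence = divergence, pileup_tau = pileup_tau),
            class = "camera_truth")
}

# fractions of the total (6W) spectrum falling in each window, per phantom.
# The primary fraction is f_PP - f_LS - f_US (TEW-subtracted), so the
# wide-spectrum/primary ratio k grows with the volume of scattering medium,
# bracketing the count-rate ratios seen on a real system (air ~3.9 up to
# large water-equivalent cylinders ~7.8).
.phantom_presets <- list(
  "Air-2D" = list(
    fractions = c(PP = 0.270, LS = 0.008, US = 0.004,
                  G1 = 0.060, G2 = 0.550, G3 = 0.108),
    background_level = 0,
    geometry = NULL),
  "Air-3D" = list(
    fractions = c(PP = 0.265, LS = 0.012, US = 0.006,
                  G1 = 0.060, G2 = 0.550, G3 = 0.107),
    background_level = 0.01,
    geometry = list(medium_radius_mm = 160, source = "capillary")),
  "CTDI-10" = list(
    fractions = c(PP = 0.210, LS = 0.025, US = 0.015,
                  G1 = 0.050, G2 = 0.560, G3 = 0.140),
    background_level = 0.02,
    geometry = list(medium_radius_mm = 50, source = "capillary")),
  "CTDI-16" = list(
    fractions = c(PP = 0.200, LS = 0.030, US = 0.018,
                  G1 = 0.050, G2 = 0.550, G3 = 0.152),
    background_level = 0.03,
    geometry = list(medium_radius_mm = 80, source = "capillary")),
  "CTDI-32" = list(
    fractions = c(PP = 0.185, LS = 0.035, US = 0.021,
                  G1 = 0.045, G2 = 0.560, G3 = 0.154),
    background_level = 0.05,
    geometry = list(medium_radius_mm = 160, source = "capillary")),
  "Jaszczak" = list(
    fractions = c(PP = 0.220, LS = 0.040, US = 0.037,
                  G1 = 0.050, G2 = 0.520, G3 = 0.133),
    background_level = 0.02,
    geometry = list(medium_radius_mm = 105, source = "cylinder",
                    sphere = list(diameter_mm = 40, ratio = 6)))
)

#' Ground-truth phantom description for the simulator
#'
#' A phantom is characterized by how it spreads the recorded spectrum over
#' the six energy windows (`window_fractions`, summing to 1), a spurious
#' reconstructed-background level emulating residual scatter in dense
#' non-radioactive medium, and a simple source/medium geometry for volume
#' synthesis.  Named presets (`"Air-2D"`, `"Air-3D"`, `"CTDI-10"`,
#' `"CTDI-16"`, `"CTDI-32"`, `"Jaszczak"`) supply all fields; explicit
#' arguments override preset values.
#'
#' @param name Phantom label (a preset name, or any label if all fields are
#'   given explicitly).
#' @param window_fractions Named numeric vector over the scheme's windows,
#'   summing to 1; the photopeak fraction must exceed the two adjacent
#'   scatter fractions combined (positive primary spectrum).
#' @param background_level Spurious background counts as a fraction of
#'   primary counts at low rate (>= 0).
#' @param geometry List describing the volume layout (see presets), or
#'   `NULL` for planar-only phantoms.
#' @return An object of class `phantom_truth`.
#' @export
phantom_truth <- function(name, window_fractions = NULL,
                          background_level = NULL, geometry = NULL) {
  preset <- .phantom_presets[[name]]
  if (is.null(window_fractions)) {
    if (is.null(preset)) stop("unknown phantom preset '", name,
                              "' and no window_fractions given", call. = FALSE)
    window_fractions <- preset$fractions
  }
  if (is.null(background_level))
    background_level <- if (!is.null(preset)) preset$background_level else 0
  if (is.null(geometry) && !is.null(preset)) geometry <- preset$geometry
  if (abs(sum(window_fractions) - 1) > 1e-8)
    stop("window_fractions must sum to 1", call. = FALSE)
  if (any(window_fractions < 0)) stop("window_fractions must be >= 0",
                                      call. = FALSE)
  prim <- window_fractions[["PP"]] - window_fractions[["LS"]] -
    window_fractions[["US"]]
  if (prim <= 0)
    stop("photopeak fraction must exceed the adjacent scatter fractions",
         call. = FALSE)
  if (background_level < 0) stop("background_level must be >= 0",
                                 call. = FALSE)
  structure(list(name = name, window_fractions = window_fractions,
                 background_level = background_level, geometry = geometry),
            class = "phantom_truth")
}

#' Spectral ratio of a phantom for a window combination
#'
#' The ratio `k = R_W / R_P` between the rate recorded in a window
#' combination and the primary (TEW-corrected photopeak) rate, as implied by
#' the phantom's window fractions.  Under the simulator's baseline model all
#' windows lose the same paralysable fraction, so `k` holds for true and
#' observed rates alike and `X_W = k * A`.
#'
#' @param phantom A [phantom_truth()].
#' @param combination Combination name.
#' @param scheme A [window_scheme()].
#' @return Dimensionless ratio `>= 1` for combinations containing the
#'   photopeak.
#' @export
spectral_ratio <- function(phantom, combination, scheme = lu177_scheme()) {
  fr <- phantom$window_fractions
  members <- scheme$combinations[[combination]]
  if (is.null(members)) stop("unknown combination '", combination, "'",
                             call. = FALSE)
  sum(fr[members]) / (fr[["PP"]] - fr[["LS"]] - fr[["US"]])
}

#' Acquisition plan for the simulator
#'
#' @param activities Known activities in MBq at the reference time, one per
#'   acquisition.
#' @param frame_duration Frame duration (planar) or time per projection
#'   (tomo), in seconds; length 1 or one per acquisition.
#' @param mode `"planar"` or `"tomo"`.
#' @param n_projections Projections per acquisition (tomo; forced to 1 for
#'   planar).
#' @param seed Integer seed making generated counts reproducible.
#' @param decay_days Elapsed days from the reference time to each scan; the
#'   known activity is decayed accordingly.
#' @param noise Draw Poisson counts (`TRUE`) or emit exact expected counts.
#' @return An object of class `acquisition_plan`.
#' @export
acquisition_plan <- function(activities, frame_duration = 60,
                             mode = c("planar", "tomo"),
                             n_projections = NULL, seed = 1,
                             decay_days = 0, noise = TRUE) {
  mode <- match.arg(mode)
  if (any(activities <= 0)) stop("activities must be > 0", call. = FALSE)
  if (any(frame_duration <= 0)) stop("durations must be > 0", call. = FALSE)
  if (any(decay_days < 0)) stop("decay_days must be >= 0", call. = FALSE)
  n <- length(activities)
  if (is.null(n_projections)) n_projections <- if (mode == "planar") 1 else 96
  structure(
    list(activities = activities,
         frame_duration = rep_len(frame_duration, n), mode = mode,
         n_projections = if (mode == "planar") 1 else n_projections,
         seed = as.integer(seed), decay_days = rep_len(decay_days, n),
         noise = isTRUE(noise)),
    class = "acquisition_plan")
}

#' Default planar calibration plan
#'
#' Seventeen activities spaced geometrically from 19 MBq to 15.1 GBq,
#' acquired as 60-s planar frames: a serial source-addition experiment
#' spanning negligible dead time up to beyond the saturation of the system.
#'
#' @inheritParams acquisition_plan
#' @return An [acquisition_plan()].
#' @export
default_planar_plan <- function(seed = 1, noise = TRUE,
                                frame_duration = 60) {
  acquisition_plan(
    activities = exp(seq(log(19), log(15123), length.out = 17)),
    frame_duration = frame_duration, mode = "planar", seed = seed,
    noise = noise)
}

#' Radioactive decay of Lu-177 activity
#'
#' @param a0 Activity in MBq at the reference time (> 0).
#' @param t_days Elapsed time in days (>= 0).
#' @param half_life_days Half-life in days (default 6.6443 d for Lu-177).
#' @return Decayed activity in MBq.
#' @export
decay_activity <- function(a0, t_days, half_life_days = 6.6443) {
  if (any(a0 <= 0)) stop("a0 must be > 0", call. = FALSE)
  if (any(t_days < 0)) stop("t_days must be >= 0", call. = FALSE)
  a0 * 2^(-t_days / half_life_days)
}

# expected observed per-window rates for one detector at activity A (MBq).
# Baseline: true wide rate k6*cf*A drives a single paralysable loss shared by
# all windows, so TEW recovers the observed primary rate exactly.  Pile-up
# then displaces a fraction of surviving primaries from PP into US/G1
# (conserving the 6W total); saturation applies a multiplicative sensitivity
# decay beyond the usable range.
expected_window_rates <- function(activity, camera, phantom, detector) {
  fr <- phantom$window_fractions
  k6 <- 1 / (fr[["PP"]] - fr[["LS"]] - fr[["US"]])
  cf <- camera$cf[detector]
  r_pt <- cf * activity
  r_wt <- k6 * r_pt
  loss <- exp(-r_wt * camera$tau)
  rates <- fr * k6 * r_pt * loss
  r_po <- r_pt * loss
  if (camera$pileup_tau > 0) {
    p <- 1 - exp(-r_wt * camera$pileup_tau)
    displaced <- p * r_po
    rates[["PP"]] <- rates[["PP"]] - displaced
    rates[["US"]] <- rates[["US"]] + displaced / 2
    rates[["G1"]] <- rates[["G1"]] + displaced / 2
  }
  r_wo6 <- sum(rates)
  if (r_wo6 > camera$saturation_rate) {
    excess <- (r_wo6 - camera$saturation_rate) / camera$saturation_rate
    rates <- rates * exp(-camera$divergence[detector] * excess)
  }
  list(rates = rates, r_pt = r_pt, r_po_expected = r_po, k6 = k6)
}

#' Generate a serial calibration series
#'
#' Produces acquisition records (one row per acquisition and detector, raw
#' counts per energy window) from a ground-truth camera and phantom under an
#' acquisition plan.  The baseline generative model satisfies the
#' paralysable wide-spectrum-driven loss model exactly with a constant
#' spectral ratio per phantom, so joint calibration recovers the true
#' parameters to machine precision on noise-free output; Poisson counting
#' noise, Lu-177 decay of the known activities, pile-up displacement and
#' post-saturation detector divergence are layered on top.
#'
#' @param camera A [camera_truth()].
#' @param phantom A [phantom_truth()].
#' @param plan An [acquisition_plan()].
#' @param scheme A [window_scheme()].
#' @return Acquisition records as accepted by [build_samples()], with a
#'   `truth` attribute (camera, phantom, plan and a per-acquisition table of
#'   true rates).
#' @export
generate_series <- function(camera, phantom, plan,
                            scheme = lu177_scheme()) {
  stopifnot(inherits(camera, "camera_truth"),
            inherits(phantom, "phantom_truth"),
            inherits(plan, "acquisition_plan"))
  wnames <- names(scheme$windows)
  if (!setequal(names(phantom$window_fractions), wnames))
    stop("phantom window fractions do not match the scheme windows",
         call. = FALSE)
  if (plan$noise) set.seed(plan$seed)
  rows <- list()
  truth_rows <- list()
  for (i in seq_along(plan$activities)) {
    a <- decay_activity(plan$activities[i], plan$decay_days[i])
    t_total <- plan$frame_duration[i] * plan$n_projections
    for (det in 1:2) {
      ex <- expected_window_rates(a, camera, phantom, det)
      expected_counts <- ex$rates[wnames] * t_total
      counts <- if (plan$noise) stats::rpois(length(expected_counts),
                                             expected_counts)
                else unname(expected_counts)
      row <- data.frame(
        acq = i, phantom = phantom$name, mode = plan$mode, detector = det,
        duration_s = plan$frame_duration[i],
        n_projections = plan$n_projections, activity_MBq = a,
        stringsAsFactors = FALSE)
      row[paste0("counts_", wnames)] <- as.list(counts)
      rows[[length(rows) + 1]] <- row
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        acq = i, detector = det, activity_MBq = a, r_pt = ex$r_pt,
        r_po_expected = ex$r_po_expected, r_wo6_expected = sum(ex$rates))
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  attr(records, "truth") <- list(
    camera = camera, phantom = phantom, plan = plan,
    k6 = 1 / (phantom$window_fractions[["PP"]] -
                phantom$window_fractions[["LS"]] -
                phantom$window_fractions[["US"]]),
    table = do.call(rbind, truth_rows))
  records
}

#' Generate a reconstructed count volume
#'
#' Synthesizes a scatter-corrected reconstructed SPECT count volume for one
#' acquisition: primary counts (consistent with [generate_series()] totals
#' for the same activity, averaged over both detectors) are deposited in the
#' source voxels of the phantom geometry, and spurious diffuse background
#' counts — emulating residual scatter in dense non-radioactive medium,
#' relatively stronger at low count rate — are spread over the cold medium
#' (or, for a fully active cylinder, its wall shell).  Reconstructed counts
#' carry the projection-number scaling, so [volume_primary_rate()] recovers
#' the observed primary rate.
#'
#' @inheritParams generate_series
#' @param activity Known activity in MBq at scan time.
#' @param grid Volume dimensions in voxels (length 3).
#' @param voxel_mm Isotropic voxel size in mm.
#' @param bg_reference_rate Wide-spectrum rate (cps) below which the
#'   background artefact reaches its full `background_level`; above it the
#'   artefact shrinks inversely with rate.
#' @return A [count_volume()] with attributes `injected_primary` (ground
#'   truth primary counts deposited), `r_po` (observed primary rate),
#'   `r_wo6` (observed wide-spectrum rate) and `background_counts`.
#' @export
generate_volume <- function(phantom, activity, camera, plan,
                            grid = c(48, 48, 32), voxel_mm = 4.8,
                            bg_reference_rate = 20e3,
                            scheme = lu177_scheme()) {
  geom <- phantom$geometry
  if (is.null(geom))
    stop("phantom '", phantom$name, "' has no volume geometry", call. = FALSE)
  if (plan$noise) set.seed(plan$seed)
  ex1 <- expected_window_rates(activity, camera, phantom, 1)
  ex2 <- expected_window_rates(activity, camera, phantom, 2)
  fr <- phantom$window_fractions
  prim_frac <- fr[["PP"]] - fr[["LS"]] - fr[["US"]]
  r_po <- (sum(ex1$rates[c("PP", "LS", "US")] * c(1, -1, -1)) +
             sum(ex2$rates[c("PP", "LS", "US")] * c(1, -1, -1))) / 2
  r_wo6 <- (sum(ex1$rates) + sum(ex2$rates)) / 2
  t_total <- plan$frame_duration[1] * plan$n_projections
  total_primary <- r_po * t_total

  # concentration map: 1 inside active regions, sphere ratio where present
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  centre <- (grid[1:2] / 2) * voxel_mm
  xc <- (seq_len(nx) - 0.5) * voxel_mm
  yc <- (seq_len(ny) - 0.5) * voxel_mm
  r2 <- outer((xc - centre[1])^2, (yc - centre[2])^2, `+`)
  medium2d <- r2 <= geom$medium_radius_mm^2
  conc <- array(0, dim = grid)
  zmid <- seq.int(max(1L, floor(nz / 4)), ceiling(3 * nz / 4))
  if (geom$source == "capillary") {
    src2d <- r2 <= (1.5 * voxel_mm)^2
    conc[, , zmid][rep(src2d, length(zmid))] <- 1
  } else {
    conc[, , zmid][rep(medium2d, length(zmid))] <- 1
    if (!is.null(geom$sphere)) {
      sr <- geom$sphere$diameter_mm / 2
      scx <- centre[1] + geom$medium_radius_mm / 2
      zc <- (seq_len(nz) - 0.5) * voxel_mm
      szc <- zc[zmid[ceiling(length(zmid) / 2)]]
      d2 <- outer(outer((xc - scx)^2, (yc - centre[2])^2, `+`),
                  (zc - szc)^2, `+`)
      conc[d2 <= sr^2] <- geom$sphere$ratio
    }
  }
  lam <- conc / sum(conc) * total_primary
  voxels <- if (plan$noise) array(stats::rpois(length(lam), lam), dim = grid)
            else lam
  injected <- sum(voxels)

  # spurious background in dense but cold voxels (or the wall shell of a
  # fully active cylinder), stronger at low count rate
  bg_total <- 0
  if (phantom$background_level > 0) {
    bg2d <- medium2d & !(r2 <= (1.5 * voxel_mm)^2)
    bg_mask <- array(FALSE, dim = grid)
    bg_mask[, , zmid][rep(bg2d, length(zmid))] <- TRUE
    bg_mask[conc > 0] <- FALSE
    if (!any(bg_mask)) {
      shell2d <- r2 > geom$medium_radius_mm^2 &
        r2 <= (geom$medium_radius_mm + 2 * voxel_mm)^2
      bg_mask[, , zmid][rep(shell2d, length(zmid))] <- TRUE
    }
    if (any(bg_mask)) {
      bg_total <- phantom$background_level * total_primary *
        min(1, bg_reference_rate / r_wo6)
      lam_bg <- bg_total / sum(bg_mask)
      add <- if (plan$noise) stats::rpois(sum(bg_mask), lam_bg)
             else rep(lam_bg, sum(bg_mask))
      voxels[bg_mask] <- voxels[bg_mask] + add
      bg_total <- sum(add)
    }
  }
  v <- count_volume(voxels, voxel_size = rep(voxel_mm, 3),
                    n_projections = plan$n_projections,
                    t_projection = plan$frame_duration[1])
  attr(v, "injected_primary") <- injected
  attr(v, "r_po") <- r_po
  attr(v, "r_wo6") <- r_wo6
  attr(v, "background_counts") <- bg_total
  v
}
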