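#' Paralysable dead-time model: forward losses
#'
#' Observed count rate of a paralysable detector,
#' `R_o = R_t * exp(-R_t * tau)`.  The observed rate is unimodal in the true
#' rate, peaking at `1/(e*tau)` when `R_t = 1/tau`.
#'
#' @param r_true True (input) count rate in cps (>= 0).  Vectorized.
#' @param tau Dead-time constant in seconds (> 0).
#' @return Observed count rate in cps.
#' @examples
#' observed_rate(100, 0.550e-6)
#' @export
observed_rate <- function(r_true, tau) {
  check_tau(tau)
  if (any(r_true < 0)) stop("r_true must be >= 0", call. = FALSE)
  r_true * exp(-r_true * tau)
}

#' Maximum observable paralysable rate
#'
#' The apex of the paralysable response, `1/(e*tau)`: no observed rate above
#' this value is possible whatever the input rate.
#'
#' @inheritParams observed_rate
#' @return Rate in cps.
#' @examples
#' max_observed_rate(0.550e-6) / 1000   # ~669 kcps
#' @export
max_observed_rate <- function(tau) {
  check_tau(tau)
  1 / (exp(1) * tau)
}

check_tau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau <= 0)
    stop("tau must be a single positive number (seconds)", call. = FALSE)
  invisible(tau)
}

# margin below the apex at which inversion is refused: the two solution
# branches meet at the apex and the inverse is ill-conditioned there
.saturation_margin <- 1e-9

#' Invert the paralysable model
#'
#' Recovers the true rate from an observed rate on the physical
#' (below-saturation) branch, i.e. the smaller root of
#' `r_obs = x * exp(-x * tau)` (the one with `x * tau < 1`).  Uses the
#' principal branch of the Lambert W function, `x = -W0(-r_obs*tau)/tau`
#' (iteration-capped Halley steps), falling back to bisection on
#' `[r_obs, 1/tau]` for any element that fails to converge.
#'
#' @param r_obs Observed count rate in cps, in `[0, 1/(e*tau))`.  Vectorized.
#' @inheritParams observed_rate
#' @return True count rate in cps.
#' @examples
#' invert_paralysable(300000, 0.550e-6)
#' @export
invert_paralysable <- function(r_obs, tau) {
  check_tau(tau)
  if (any(r_obs < 0)) stop("r_obs must be >= 0", call. = FALSE)
  rmax <- max_observed_rate(tau)
  if (any(r_obs >= (1 - .saturation_margin) * rmax))
    stop("observed rate at or beyond the paralysable maximum 1/(e*tau) = ",
         signif(rmax, 6), " cps: beyond usable range, cannot invert",
         call. = FALSE)
  x <- -lambert_w0(-r_obs * tau) / tau
  # residual check guards against non-converged Halley elements
  bad <- !is.finite(x) | x < 0 |
    abs(x * exp(-x * tau) - r_obs) > 1e-9 * pmax(r_obs, 1)
  if (any(bad))
    x[bad] <- vapply(r_obs[bad], invert_bisect, numeric(1), tau = tau)
  x[r_obs == 0] <- 0
  x
}

# principal-branch Lambert W on [-1/e, 0], vectorized Halley iteration with a
# hard iteration cap; non-converged elements come back NaN for the caller's
# bisection fallback
lambert_w0 <- function(a) {
  w <- ifelse(a < -0.25, -1 + sqrt(2 * (1 + exp(1) * a)), a * exp(-a))
  ok <- rep(FALSE, length(a))
  for (i in 1:100) {
    ew <- exp(w)
    f <- w * ew - a
    ok <- abs(f) <= 1e-16 + 1e-15 * abs(a)
    if (all(ok)) break
    den <- ew * (w + 1) - (w + 2) * f / (2 * w + 2)
    step <- ifelse(ok | den == 0, 0, f / den)
    w <- w - step
  }
  w[!ok & abs(w * exp(w) - a) > 1e-12 * pmax(abs(a), 1e-300)] <- NaN
  w
}

# bisection fallback/oracle on the increasing branch [r_obs, 1/tau];
# absolute tolerance 1e-12 on x*tau
invert_bisect <- function(r_obs, tau) {
  if (r_obs == 0) return(0)
  lo <- r_obs
  hi <- 1 / tau
  while ((hi - lo) * tau > 1e-12) {
    mid <- (lo + hi) / 2
    if (mid * exp(-mid * tau) > r_obs) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Dead-time correction factor driven by the wide-spectrum rate
#'
#' The factor `f = R_Pt / R_Po` by which observed primary counts must be
#' multiplied to recover true primary counts, as a function of the observed
#' wide-spectrum acquisition rate `R_Wo`.  It solves
#' `1 = f * exp(-f * r_wo * tau)`, i.e.
#' `f = invert_paralysable(r_wo, tau) / r_wo`, with `f = 1` at zero rate.
#' `f` increases with both `r_wo` and `tau` and reaches `e` at the
#' paralysable maximum.
#'
#' @param r_wo Observed wide-spectrum count rate in cps.  Vectorized.
#' @inheritParams observed_rate
#' @return Dimensionless correction factor `>= 1`.
#' @examples
#' correction_factor(2e5, 0.550e-6)
#' @export
correction_factor <- function(r_wo, tau) {
  f <- rep(1, length(r_wo))
  pos <- r_wo > 0
  f[pos] <- invert_paralysable(r_wo[pos], tau) / r_wo[pos]
  f
}

#' Dead-time-correct an observed primary rate
#'
#' Applies the correction factor derived from the wide-spectrum observed rate
#' to an observed primary rate: `R_Pt = f(R_Wo, tau) * R_Po`.  The driver of
#' the correction is always the wide-spectrum rate, never the primary rate
#' itself.
#'
#' @param r_po Observed primary count rate in cps.
#' @param r_wo Observed wide-spectrum count rate in cps (the dead-time
#'   driver).
#' @inheritParams observed_rate
#' @return An object of class `correction_result`: a list with `f`, `r_po`,
#'   `r_pt` and `r_wo`.
#' @export
correct_primary <- function(r_po, r_wo, tau) {
  if (any(r_po < 0)) stop("r_po must be >= 0", call. = FALSE)
  f <- correction_factor(r_wo, tau)
  structure(list(f = f, r_po = r_po, r_pt = f * r_po, r_wo = r_wo),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat("<correction_result>\n")
  print(data.frame(r_po = x$r_po, r_wo = x$r_wo, f = x$f, r_pt = x$r_pt))
  invisible(x)
}
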