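#' Energy-window limits from centre and fractional width
#'
#' Computes the lower and upper limit of a symmetric energy window defined by
#' its centre and a width expressed as a fraction of the centre (a "20%"
#' window at 208 keV spans 208 +/- 10% of 208).
#'
#' Limits are kept as exact reals; use `report = TRUE` for the conventional
#' integer-keV display (half-up rounding).
#'
#' @param centre Window centre in keV (> 0).
#' @param width_fraction Window width as a fraction of the centre, in (0, 1].
#' @param report If `TRUE`, round limits half-up to integer keV for display.
#' @return Named numeric vector `c(lower = , upper = )` in keV.
#' @examples
#' window_limits(208, 0.20)            # 187.2, 228.8
#' window_limits(208, 0.20, report = TRUE)  # 187, 229
#' @export
window_limits <- function(centre, width_fraction, report = FALSE) {
  if (!is.numeric(centre) || any(centre <= 0))
    stop("`centre` must be positive", call. = FALSE)
  if (!is.numeric(width_fraction) || any(width_fraction <= 0) ||
      any(width_fraction > 1))
    stop("`width_fraction` must be in (0, 1]", call. = FALSE)
  lower <- centre * (1 - width_fraction / 2)
  upper <- centre * (1 + width_fraction / 2)
  if (report) {
    lower <- round_half_up(lower)
    upper <- round_half_up(upper)
  }
  c(lower = lower, upper = upper)
}

# round-half-up (base round() is half-to-even)
round_half_up <- function(x) floor(x + 0.5)

#' Construct an energy window
#'
#' Either `centre` + `width_fraction` (limits derived) or explicit
#' `lower`/`upper` limits must be given.  Explicit limits take precedence,
#' allowing vendor-reported integer limits to be stored verbatim.
#'
#' @param name Short window label (e.g. `"PP"`, `"LS"`).
#' @param centre Centre in keV, or `NULL`.
#' @param width_fraction Width as a fraction of centre, or `NULL`.
#' @param lower,upper Explicit limits in keV, or `NULL` to derive them.
#' @return An object of class `energy_window`.
#' @export
energy_window <- function(name, centre = NULL, width_fraction = NULL,
                          lower = NULL, upper = NULL) {
  if (is.null(lower) || is.null(upper)) {
    if (is.null(centre) || is.null(width_fraction))
      stop("give either explicit limits or centre + width_fraction",
           call. = FALSE)
    lim <- window_limits(centre, width_fraction)
    lower <- lim[["lower"]]
    upper <- lim[["upper"]]
  }
  if (lower >= upper) stop("window must satisfy lower < upper", call. = FALSE)
  structure(
    list(name = as.character(name), centre = centre,
         width_fraction = width_fraction, lower = lower, upper = upper),
    class = "energy_window"
  )
}

#' Construct an energy-window scheme
#'
#' A scheme bundles a set of energy windows, named wide-spectrum combinations
#' (lists of window names whose counts are summed into an observed acquisition
#' rate), and the scatter-window sets used by TEW/DEW scatter correction.
#'
#' @param windows List of [energy_window()] objects.
#' @param combinations Named list of character vectors of window names.
#' @param scatter_windows Named list with elements `TEW` and `DEW`, each a
#'   character vector of scatter window names subtracted from the photopeak.
#' @param photopeak Name of the photopeak window (default `"PP"`).
#' @param name Optional scheme label.
#' @return An object of class `window_scheme`.
#' @export
window_scheme <- function(windows, combinations, scatter_windows,
                          photopeak = "PP", name = "custom") {
  wnames <- vapply(windows, function(w) w$name, character(1))
  if (anyDuplicated(wnames)) stop("duplicate window names", call. = FALSE)
  if (!photopeak %in% wnames)
    stop("photopeak window '", photopeak, "' not present in scheme",
         call. = FALSE)
  for (cn in names(combinations)) {
    bad <- setdiff(combinations[[cn]], wnames)
    if (length(bad))
      stop("combination '", cn, "' references unknown window(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  for (sn in names(scatter_windows)) {
    bad <- setdiff(scatter_windows[[sn]], wnames)
    if (length(bad))
      stop("scatter mode '", sn, "' references unknown window(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  names(windows) <- wnames
  structure(
    list(name = name, windows = windows, combinations = combinations,
         scatter_windows = scatter_windows, photopeak = photopeak),
    class = "window_scheme"
  )
}

#' @export
print.window_scheme <- function(x, ...) {
  cat("<window_scheme> ", x$name, "\n", sep = "")
  for (w in x$windows)
    cat(sprintf("  %-3s [%g-%g] keV\n", w$name, w$lower, w$upper))
  cat("  combinations:",
      paste(sprintf("%s(%s)", names(x$combinations),
                    vapply(x$combinations, paste, "", collapse = "+")),
            collapse = ", "), "\n")
  cat("  scatter:",
      paste(sprintf("%s(%s)", names(x$scatter_windows),
                    vapply(x$scatter_windows, paste, "", collapse = "+")),
            collapse = ", "), "\n")
  invisible(x)
}

#' Default Lu-177 six-window scheme
#'
#' The bundled acquisition scheme for Lu-177: a 20% photopeak window at
#' 208 keV, two adjacent 10%-width scatter windows, and three general-scatter
#' windows covering 18-680 keV, with the `photopeak`/`3W`/`4W`/`6W`
#' combinations and TEW/DEW scatter-window sets.  Window limits are the
#' vendor-reported integer keV values.
#'
#' @return A [window_scheme()].
#' @export
lu177_scheme <- function() {
  path <- system.file("extdata", "lu177_windows.json", package = "luqspect",
                      mustWork = TRUE)
  read_window_scheme(path)
}

#' Read / write a window scheme
#'
#' Schemes are serialized as JSON or YAML (chosen by file extension): a list
#' of `{name, centre_keV, width_percent, lower_keV, upper_keV}` records plus
#' the combination and scatter-window maps.
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_window_scheme()` returns a [window_scheme()];
#'   `write_window_scheme()` returns `path` invisibly.
#' @export
read_window_scheme <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported scheme format: .", ext, call. = FALSE))
  windows <- lapply(raw$windows, function(w) {
    energy_window(
      name = w$name,
      centre = if (!is.null(w$centre_keV)) w$centre_keV,
      width_fraction = if (!is.null(w$width_percent)) w$width_percent / 100,
      lower = w$lower_keV, upper = w$upper_keV)
  })
  window_scheme(
    windows, lapply(raw$combinations, unlist),
    lapply(raw$scatter_windows, unlist),
    name = if (!is.null(raw$name)) raw$name else "unnamed")
}

#' @param scheme A [window_scheme()].
#' @rdname read_window_scheme
#' @export
write_window_scheme <- function(scheme, path) {
  out <- list(
    name = scheme$name,
    windows = lapply(unname(scheme$windows), function(w) list(
      name = w$name,
      centre_keV = w$centre,
      width_percent = if (!is.null(w$width_fraction)) 100 * w$width_fraction,
      lower_keV = w$lower, upper_keV = w$upper)),
    combinations = lapply(scheme$combinations, as.list),
    scatter_windows = lapply(scheme$scatter_windows, as.list))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                                null = "null", digits = NA),
    yaml = ,
    yml  = yaml::write_yaml(out, path),
    stop("unsupported scheme format: .", ext, call. = FALSE))
  invisible(path)
}

#' Per-acquisition window counts
#'
#' @param counts Named numeric vector of non-negative counts per window.
#' @param duration Counting time in seconds (> 0).  For tomographic data this
#'   is the total counting time, i.e. number of projections times time per
#'   projection.
#' @return An object of class `window_counts`.
#' @export
window_counts <- function(counts, duration) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be > 0", call. = FALSE)
  structure(list(counts = counts, duration = duration),
            class = "window_counts")
}

#' Combined wide-spectrum count rate
#'
#' Sums the counts of all windows in a named combination and divides by the
#' counting duration.
#'
#' @param wc A [window_counts()] object.
#' @param combination Combination name defined in `scheme`.
#' @param scheme A [window_scheme()] (default [lu177_scheme()]).
#' @return Count rate in cps.
#' @export
combined_rate <- function(wc, combination, scheme = lu177_scheme()) {
  if (!combination %in% names(scheme$combinations))
    stop("unknown combination '", combination, "'", call. = FALSE)
  members <- scheme$combinations[[combination]]
  missing <- setdiff(members, names(wc$counts))
  if (length(missing))
    stop("counts missing for window(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  sum(wc$counts[members]) / wc$duration
}

#' Scatter-corrected primary count rate
#'
#' Subtracts the counts of the scatter window(s) from the photopeak counts
#' and divides by the counting duration, yielding the observed primary-photon
#' rate R_Po.  TEW subtracts the lower and upper scatter windows; DEW only
#' the lower one.  Because the two scatter windows are each half the
#' photopeak width, the trapezoidal scatter estimate reduces to this plain
#' subtraction; `width_weighted = TRUE` applies the explicit
#' width-ratio weighting instead (identical for the bundled scheme).
#'
#' @param wc A [window_counts()] object.
#' @param scatter `"TEW"` or `"DEW"`.
#' @param scheme A [window_scheme()].
#' @param negative Policy when the subtraction goes negative on noisy
#'   low-count frames: `"clip"` (to zero, with a warning) or `"keep"`.
#' @param width_weighted Use the width-ratio-weighted scatter estimate.
#' @return Primary count rate in cps.
#' @export
primary_rate <- function(wc, scatter = c("TEW", "DEW"),
                         scheme = lu177_scheme(),
                         negative = c("clip", "keep"),
                         width_weighted = FALSE) {
  scatter <- match.arg(scatter)
  negative <- match.arg(negative)
  sw <- scheme$scatter_windows[[scatter]]
  if (is.null(sw)) stop("scheme defines no '", scatter, "' scatter windows",
                        call. = FALSE)
  pp <- scheme$photopeak
  needed <- c(pp, sw)
  missing <- setdiff(needed, names(wc$counts))
  if (length(missing))
    stop("counts missing for window(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (width_weighted) {
    wpp <- scheme$windows[[pp]]
    w_pp <- wpp$upper - wpp$lower
    scat <- mean(vapply(sw, function(nm) {
      w <- scheme$windows[[nm]]
      wc$counts[[nm]] / (w$upper - w$lower)
    }, numeric(1))) * w_pp
    # trapezoid: average scatter density under the photopeak times its width;
    # a single (DEW) window degenerates to a rectangle estimate
    net <- wc$counts[[pp]] - scat
  } else {
    net <- wc$counts[[pp]] - sum(wc$counts[sw])
  }
  if (net < 0 && negative == "clip") {
    warning("scatter subtraction negative (", signif(net, 4),
            " counts); clipped to 0", call. = FALSE)
    net <- 0
  }
  net / wc$duration
}
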