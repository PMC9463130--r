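#' Spherical-cap geometry of the distended membrane
#'
#' The silicone membrane clamped under the 7-mm support ring is modelled as a
#' spherical cap over the ring aperture: for aperture radius `a` and apex
#' height `h` the cap lies on a sphere of radius `R = (a^2 + h^2) / (2 h)`
#' with half-angle `theta = asin(a / R)`. `h = 0` is the flat limit
#' (`R = Inf`, `theta = 0`); `h = a` is a hemisphere.
#'
#' @param a Ring aperture radius in mm (default 3.5, the 7-mm support ring).
#' @param h Apex height of the distended membrane in mm, `0 <= h <= a`.
#' @return An object of class `ctcm_cap` with fields `a`, `h`, `R` (sphere
#'   radius, mm) and `theta` (half-angle, radians).
#' @examples
#' cap_from_height(3.5, 2.221)  # the 80 mmHg operating point
#' @export
cap_from_height <- function(a = 3.5, h) {
  if (!is.finite(a) || a <= 0) stop("`a` must be positive", call. = FALSE)
  if (!is.finite(h) || h < 0) stop("`h` must be non-negative", call. = FALSE)
  if (h > a)
    stop("`h` must not exceed `a` (hemisphere is the maximal cap)",
         call. = FALSE)
  if (h == 0) {
    geom <- list(a = a, h = 0, R = Inf, theta = 0)
  } else {
    R <- (a^2 + h^2) / (2 * h)
    geom <- list(a = a, h = h, R = R, theta = asin(min(1, a / R)))
  }
  structure(geom, class = "ctcm_cap")
}

#' @export
print.ctcm_cap <- function(x, ...) {
  cat(sprintf("Spherical cap: a = %g mm, h = %g mm, R = %g mm, theta = %g rad\n",
              x$a, x$h, x$R, x$theta))
  invisible(x)
}

# Vectorised percent stretch over apex heights (internal workhorse).
stretch_from_height <- function(a, h) {
  out <- numeric(length(h))
  pos <- h > 0
  hh <- h[pos]
  R <- (a^2 + hh^2) / (2 * hh)
  theta <- asin(pmin(1, a / R))
  out[pos] <- 100 * (theta / sin(theta) - 1)
  out
}

#' Percent stretch of the membrane cap
#'
#' The tissue stretch imposed by membrane distension, defined as the
#' arc-over-chord elongation of the deflected profile: a diametral transect
#' of the cap has arc length `2 R theta` over a rest chord `2 a`, so
#' `stretch = 100 (theta / sin(theta) - 1)` percent. Zero for a flat
#' membrane and strictly increasing in apex height. The device's calibrated
#' operating points give 25% at 80 mmHg and 32% at 140 mmHg.
#'
#' @param cap A [cap_from_height()] geometry.
#' @return Percent stretch (scalar).
#' @examples
#' percent_stretch(cap_from_height(3.5, 2.221))  # ~25
#' percent_stretch(cap_from_height(3.5, 2.537))  # ~32
#' @export
percent_stretch <- function(cap) {
  stopifnot(inherits(cap, "ctcm_cap"))
  stretch_from_height(cap$a, cap$h)
}

#' Apex height producing a target percent stretch
#'
#' Inverts [percent_stretch()] by bracketed bisection on `h` in `[0, a]`.
#' Used for device calibration and synthetic ground truth.
#'
#' @param target_percent Target stretch in percent, `0 <= target <` the
#'   hemisphere stretch (`100 (pi/2 - 1)`, about 57.1%).
#' @param a Ring aperture radius in mm.
#' @return Apex height in mm such that the cap's stretch equals
#'   `target_percent` to better than 1e-6 relative.
#' @examples
#' height_for_stretch(25, 3.5)  # ~2.2215 mm
#' @export
height_for_stretch <- function(target_percent, a = 3.5) {
  max_stretch <- 100 * (pi / 2 - 1)
  if (!is.finite(target_percent) || target_percent < 0 ||
      target_percent >= max_stretch)
    stop(sprintf("`target_percent` must lie in [0, %.3f)", max_stretch),
         call. = FALSE)
  if (target_percent == 0) return(0)
  stats::uniroot(function(h) stretch_from_height(a, h) - target_percent,
                 lower = 1e-12 * a, upper = a, tol = 1e-12 * a)$root
}

#' Pressure-to-apex-height calibration map
#'
#' The device translates air-chamber pressure into membrane deflection; the
#' package represents that translation as a monotone map through measured
#' (pressure, apex height) anchor pairs. [default_calibration()] anchors the
#' map at the device's two calibrated operating points — 25% stretch at
#' 80 mmHg and 32% at 140 mmHg — plus the resting point (0 mmHg, 0 mm).
#'
#' @param pressures_mmHg Strictly increasing anchor pressures; the first
#'   anchor is the resting point and must map to height 0.
#' @param heights_mm Strictly increasing anchor apex heights.
#' @return An object of class `ctcm_calibration`.
#' @examples
#' cal <- default_calibration()
#' pressure_to_height(80, cal)  # ~2.2215 mm
#' @export
calibration_map <- function(pressures_mmHg, heights_mm) {
  if (length(pressures_mmHg) != length(heights_mm) ||
      length(pressures_mmHg) < 2)
    stop("need at least two (pressure, height) anchor pairs", call. = FALSE)
  if (any(diff(pressures_mmHg) <= 0) || any(diff(heights_mm) <= 0))
    stop("calibration anchors must be strictly increasing in both coordinates",
         call. = FALSE)
  if (heights_mm[1] != 0)
    stop("the first (resting) anchor must have height 0", call. = FALSE)
  structure(list(pressures_mmHg = pressures_mmHg, heights_mm = heights_mm),
            class = "ctcm_calibration")
}

#' @rdname calibration_map
#' @param a Ring aperture radius in mm used to derive the anchor heights.
#' @export
default_calibration <- function(a = 3.5) {
  calibration_map(c(0, 80, 140),
                  c(0, height_for_stretch(25, a), height_for_stretch(32, a)))
}

#' Map pressure to membrane apex height
#'
#' Monotone piecewise-cubic (Hyman-filtered) interpolation through the
#' calibration anchors; exact at the anchors. Pressures outside the anchor
#' range are refused rather than extrapolated.
#'
#' @param p_mmHg Pressure(s) in mmHg, within the anchor range.
#' @param cal A [calibration_map()].
#' @return Apex height(s) in mm.
#' @export
pressure_to_height <- function(p_mmHg, cal) {
  stopifnot(inherits(cal, "ctcm_calibration"))
  rng <- range(cal$pressures_mmHg)
  if (any(p_mmHg < rng[1] - 1e-9) || any(p_mmHg > rng[2] + 1e-9))
    stop(sprintf("pressure outside calibration range [%g, %g] mmHg",
                 rng[1], rng[2]), call. = FALSE)
  if (length(cal$pressures_mmHg) == 2) {
    # two anchors: linear
    slope <- diff(cal$heights_mm) / diff(cal$pressures_mmHg)
    return(cal$heights_mm[1] + slope * (p_mmHg - cal$pressures_mmHg[1]))
  }
  f <- stats::splinefun(cal$pressures_mmHg, cal$heights_mm, method = "hyman")
  f(pmin(pmax(p_mmHg, rng[1]), rng[2]))
}

#' Cut diameter for area-oversized tissue slices
#'
#' Slices are cut larger than the support ring so diastolic distension does
#' not overstretch the tissue: oversizing the *area* by a fraction `f`
#' scales the diameter by `sqrt(1 + f)`. The device protocol oversizes by
#' 25% of the ring area, giving a 7.826-mm cut for the 7-mm ring.
#'
#' @param ring_diameter_mm Support ring diameter in mm.
#' @param area_fraction Fractional area oversize (0.25 for the protocol).
#' @return Cut diameter in mm.
#' @examples
#' oversize_cut_diameter(7, 0.25)  # 7.826
#' @export
oversize_cut_diameter <- function(ring_diameter_mm, area_fraction = 0.25) {
  if (!is.finite(ring_diameter_mm) || ring_diameter_mm <= 0)
    stop("`ring_diameter_mm` must be positive", call. = FALSE)
  if (!is.finite(area_fraction) || area_fraction < 0)
    stop("`area_fraction` must be non-negative", call. = FALSE)
  ring_diameter_mm * sqrt(1 + area_fraction)
}
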