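## Beam/eye geometry of the three-beam sample arm: three parallel beams
## arranged on the corners of an equilateral triangle at the pupil plane,
## focused onto a mutual retinal spot by the eye's optics.

#' Three-beam pupil-plane geometry
#'
#' Describes the equilateral-triangle arrangement of the three sample
#' beams at the pupil plane together with the eye parameters needed for
#' angular and aperture calculations.
#'
#' @param center_wavelength_nm Source centre wavelength (nm).
#' @param bandwidth_fwhm_nm Source FWHM bandwidth (nm).
#' @param beam_diameter_mm 1/e^2 beam diameter at the pupil (mm).
#' @param triangle_side_mm Pupil-plane separation between adjacent beams (mm).
#' @param channel_azimuths_deg Azimuths of the three pupil entry positions
#'   (degrees); must be pairwise distinct modulo 360.
#' @param eye_axial_length_mm Axial eye length (mm).
#' @param vitreous_index Refractive index of the vitreous.
#' @return An object of class `beam_geometry`.
#' @examples
#' g <- beam_geometry()
#' min_pupil_aperture(g)
#' chief_ray_inclination(g)
#' @export
beam_geometry <- function(center_wavelength_nm = 840,
                          bandwidth_fwhm_nm = 50,
                          beam_diameter_mm = 0.8,
                          triangle_side_mm = 2.5,
                          channel_azimuths_deg = c(90, 210, 330),
                          eye_axial_length_mm = 24,
                          vitreous_index = 1.336) {
  if (triangle_side_mm <= 0) stop("invalid geometry: triangle_side_mm must be > 0")
  if (beam_diameter_mm <= 0) stop("invalid geometry: beam_diameter_mm must be > 0")
  if (eye_axial_length_mm <= 0) stop("invalid geometry: eye_axial_length_mm must be > 0")
  if (length(channel_azimuths_deg) != 3)
    stop("invalid geometry: exactly three channel azimuths required")
  az <- wrap360(channel_azimuths_deg)
  if (anyDuplicated(round(az, 9)))
    stop("invalid geometry: channel azimuths must be pairwise distinct modulo 360")
  structure(list(center_wavelength_nm = center_wavelength_nm,
                 bandwidth_fwhm_nm = bandwidth_fwhm_nm,
                 beam_diameter_mm = beam_diameter_mm,
                 triangle_side_mm = triangle_side_mm,
                 channel_azimuths_deg = az,
                 eye_axial_length_mm = eye_axial_length_mm,
                 vitreous_index = vitreous_index),
            class = "beam_geometry")
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat("Three-beam pupil geometry\n",
      sprintf("  lambda0 %g nm, FWHM %g nm\n", x$center_wavelength_nm, x$bandwidth_fwhm_nm),
      sprintf("  triangle side %g mm, beam diameter %g mm\n",
              x$triangle_side_mm, x$beam_diameter_mm),
      sprintf("  channel azimuths %s deg\n",
              paste(x$channel_azimuths_deg, collapse = ", ")),
      sprintf("  eye length %g mm (n = %g)\n", x$eye_axial_length_mm, x$vitreous_index),
      sep = "")
  invisible(x)
}

#' Minimal pupil aperture for unvignetted three-beam entry
#'
#' Diameter of the smallest circle, centred on the beam triangle's
#' centroid, that contains all three beam footprints:
#' `2 * (side / sqrt(3)) + beam_diameter` (twice the circumradius of the
#' triangle plus one beam diameter). Pupils smaller than this vignette at
#' least one beam, so intensity variation along a B-scan may then reflect
#' vignetting rather than tissue directionality.
#'
#' @param geometry A [beam_geometry()].
#' @return Aperture diameter in mm.
#' @export
min_pupil_aperture <- function(geometry) {
  stopifnot(inherits(geometry, "beam_geometry"))
  2 * geometry$triangle_side_mm / sqrt(3) + geometry$beam_diameter_mm
}

#' Chief-ray inclination at the retina
#'
#' Angle between each beam's chief ray and the central optical axis after
#' the eye focuses the three parallel beams onto a mutual retinal spot:
#' `atan(circumradius / eye_axial_length)` with circumradius
#' `side / sqrt(3)`. For the default geometry (side 2.5 mm, 24 mm eye)
#' this is about 3.4 degrees. The pairwise angle between two beams is a
#' factor ~sqrt(3) larger (the chords subtend the triangle side rather
#' than the circumradius); [pairwise_beam_angle()] reports it.
#'
#' @param geometry A [beam_geometry()].
#' @return Inclination in degrees.
#' @export
chief_ray_inclination <- function(geometry) {
  stopifnot(inherits(geometry, "beam_geometry"))
  r <- geometry$triangle_side_mm / sqrt(3)
  atan(r / geometry$eye_axial_length_mm) * 180 / pi
}

#' Pairwise angle between two sampling beams at the retina
#'
#' Angle subtended at the retinal focus by two adjacent pupil entry
#' positions (separated by one triangle side).
#'
#' @param geometry A [beam_geometry()].
#' @return Angle in degrees.
#' @export
pairwise_beam_angle <- function(geometry) {
  stopifnot(inherits(geometry, "beam_geometry"))
  ## chord of length `side` seen from distance L
  2 * atan(geometry$triangle_side_mm / 2 / geometry$eye_axial_length_mm) * 180 / pi
}

#' Scan pattern description
#'
#' @param kind One of `"circumpapillary"`, `"linear"`, `"raster"`.
#' @param ascans_per_bscan A-scans per B-scan. Defaults follow the
#'   acquisition protocols: 6144 (circumpapillary), 8192 (linear),
#'   2048 (raster).
#' @param bscans Number of B-scans (250 default for raster, else 1).
#' @param fov_degrees Field of view; for circumpapillary scans the circle
#'   diameter in degrees (default 10).
#' @return An object of class `scan_pattern`.
#' @export
scan_pattern <- function(kind = c("circumpapillary", "linear", "raster"),
                         ascans_per_bscan = NULL, bscans = NULL,
                         fov_degrees = 10) {
  kind <- match.arg(kind)
  if (is.null(ascans_per_bscan))
    ascans_per_bscan <- switch(kind, circumpapillary = 6144L,
                               linear = 8192L, raster = 2048L)
  if (is.null(bscans)) bscans <- if (kind == "raster") 250L else 1L
  ascans_per_bscan <- as.integer(ascans_per_bscan)
  bscans <- as.integer(bscans)
  if (ascans_per_bscan < 2L) stop("ascans_per_bscan must be >= 2")
  if (bscans < 1L) stop("bscans must be >= 1")
  structure(list(kind = kind, ascans_per_bscan = ascans_per_bscan,
                 bscans = bscans, fov_degrees = fov_degrees),
            class = "scan_pattern")
}

#' A-scan azimuths of a circumpapillary pattern
#'
#' Azimuth of A-scan `i` (1-based) is `(i - 1) / N * 360` degrees:
#' strictly increasing on the half-open interval `[0, 360)`.
#'
#' @param pattern A [scan_pattern()]; for non-circular patterns the
#'   normalized lateral position is mapped onto `[0, 360)` as well so the
#'   directional models remain usable for linear scans.
#' @return Numeric vector of azimuths in degrees.
#' @export
scan_azimuths <- function(pattern) {
  stopifnot(inherits(pattern, "scan_pattern"))
  n <- pattern$ascans_per_bscan
  (seq_len(n) - 1) / n * 360
}
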