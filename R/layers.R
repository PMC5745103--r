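## Phenomenological directional reflectance models for retinal layers.
##
## The three functional forms encode the angular behaviours seen in
## multi-directional imaging: a single von Mises-type lobe per revolution
## for the photoreceptor IS/OS and COST bands (optical Stiles-Crawford
## type apodization about the pointing axis), a 180-degree-periodic
## cos^2 two-lobe model for the cylindrically scattering RNFL, and a
## clipped-cosine one-sided model for Henle's fiber layer, which is only
## visible when illuminated from the side its oblique fibers face.

#' Layer reflectance model
#'
#' @param name Layer label (free-form; e.g. "RNFL", "ISOS", "RPE").
#' @param base_reflectivity Mean linear reflectance at the directional
#'   peak (>= 0).
#' @param directional_kind One of `"isotropic"`,
#'   `"photoreceptor_vonmises"`, `"rnfl_bilobed"`, `"hfl_onesided"`.
#' @param concentration Von Mises kappa (photoreceptor model) or clip
#'   exponent p (HFL model); >= 0.
#' @param modulation_depth Modulation fraction m in `[0, 1]` for the
#'   bilobed RNFL model.
#' @return An object of class `layer_model`.
#' @export
layer_model <- function(name, base_reflectivity,
                        directional_kind = c("isotropic",
                                             "photoreceptor_vonmises",
                                             "rnfl_bilobed",
                                             "hfl_onesided"),
                        concentration = 0, modulation_depth = 0) {
  directional_kind <- match.arg(directional_kind)
  if (base_reflectivity < 0) stop("base_reflectivity must be >= 0")
  if (concentration < 0) stop("parameter error: concentration (kappa/p) must be >= 0")
  if (modulation_depth < 0 || modulation_depth > 1)
    stop("parameter error: modulation_depth must be in [0, 1]")
  structure(list(name = name, base_reflectivity = base_reflectivity,
                 directional_kind = directional_kind,
                 concentration = concentration,
                 modulation_depth = modulation_depth),
            class = "layer_model")
}

#' Directional gain of a layer
#'
#' Dimensionless angular gain factor (>= 0) applied to a layer's base
#' reflectivity for a beam entering at channel azimuth `channel_azimuth`
#' while the scan samples azimuth `scan_azimuth`. With
#' `phi = scan_azimuth - channel_azimuth`:
#' \describe{
#'   \item{isotropic}{1 everywhere.}
#'   \item{photoreceptor_vonmises}{`exp(kappa * cos(phi)) / exp(kappa)` —
#'     a single lobe per revolution, peak 1 at `phi = 0`.}
#'   \item{rnfl_bilobed}{`(1 - m) + m * cos(phi)^2` — peaks at `phi = 0`
#'     and `phi = 180`.}
#'   \item{hfl_onesided}{`max(0, cos(phi))^p` — nonzero only on the
#'     beam-facing side.}
#' }
#'
#' @param layer A [layer_model()].
#' @param scan_azimuth Scan azimuth(s), degrees.
#' @param channel_azimuth Channel (pupil entry) azimuth, degrees.
#' @return Gain value(s), same length as `scan_azimuth`.
#' @export
directional_gain <- function(layer, scan_azimuth, channel_azimuth) {
  stopifnot(inherits(layer, "layer_model"))
  phi <- (scan_azimuth - channel_azimuth) * pi / 180
  switch(layer$directional_kind,
    isotropic = rep(1, length(phi)),
    photoreceptor_vonmises = exp(layer$concentration * (cos(phi) - 1)),
    rnfl_bilobed = (1 - layer$modulation_depth) +
      layer$modulation_depth * cos(phi)^2,
    hfl_onesided = pmax(0, cos(phi))^layer$concentration)
}

#' Default retinal layer stack
#'
#' Twelve-layer phenomenological retina used by the phantom: a thin
#' specular ILM band, a thick directional RNFL (bilobed), an inner
#' retina lump (GCL..OPL), a one-sided HFL, the dim ONL, the ELM, the
#' strongly directional IS/OS and COST photoreceptor bands separated and
#' followed by low-reflectivity gap zones, the bright isotropic RPE
#' (the normalization reference) and choroid.
#'
#' @param photoreceptor_kappa Von Mises concentration of IS/OS and COST.
#' @param rnfl_modulation Modulation depth m of the RNFL bilobed model.
#' @param hfl_power Clip exponent of the HFL one-sided model.
#' @return Named list of [layer_model()] objects, in anterior-to-posterior
#'   order matching [default_interfaces()].
#' @export
default_retina_layers <- function(photoreceptor_kappa = 1.5,
                                  rnfl_modulation = 0.6,
                                  hfl_power = 2) {
  list(
    ILM     = layer_model("ILM",     0.9,  "isotropic"),
    RNFL    = layer_model("RNFL",    1.2,  "rnfl_bilobed",
                          modulation_depth = rnfl_modulation),
    GCL_OPL = layer_model("GCL_OPL", 0.45, "isotropic"),
    HFL     = layer_model("HFL",     0.6,  "hfl_onesided",
                          concentration = hfl_power),
    ONL     = layer_model("ONL",     0.12, "isotropic"),
    ELM     = layer_model("ELM",     0.5,  "isotropic"),
    ISOS    = layer_model("ISOS",    1.5,  "photoreceptor_vonmises",
                          concentration = photoreceptor_kappa),
    OS      = layer_model("OS",      0.15, "isotropic"),
    COST    = layer_model("COST",    1.1,  "photoreceptor_vonmises",
                          concentration = photoreceptor_kappa),
    OPR     = layer_model("OPR",     0.15, "isotropic"),
    RPE     = layer_model("RPE",     2.2,  "isotropic"),
    choroid = layer_model("choroid", 0.3,  "isotropic"))
}

#' Default layer interface rows
#'
#' Anterior interface row (1-based depth index) of each default layer at
#' a 3.5 um axial pixel pitch and 280-pixel imaging depth. Each layer
#' occupies rows `start .. next_start - 1`; the choroid extends to the
#' bottom of the frame. Rows above the ILM are vitreous (noise only).
#'
#' @return Named integer vector of interface rows.
#' @export
default_interfaces <- function() {
  c(ILM = 60L, RNFL = 62L, GCL_OPL = 120L, HFL = 160L, ONL = 170L,
    ELM = 196L, ISOS = 199L, OS = 205L, COST = 208L, OPR = 214L,
    RPE = 224L, choroid = 230L)
}
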