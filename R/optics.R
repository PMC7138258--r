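#' Hemoglobin extinction table
#'
#' Molar extinction coefficients of oxy- and deoxyhemoglobin over
#' 750--850 nm, from the standard near-infrared tabulation shipped with the
#' package. Values between tabulated wavelengths are linearly interpolated.
#'
#' @return data.frame with columns `wavelength`, `eps_hbo2`, `eps_hb`
#' @export
hb_extinction <- function() {
  path <- system.file("extdata", "hb_extinction.tsv", package = "cepaq")
  tab <- utils::read.delim(path, comment.char = "#", header = FALSE,
                           col.names = c("wavelength", "eps_hbo2", "eps_hb"))
  stopifnot(all(tab$eps_hbo2 > 0), all(tab$eps_hb > 0))
  tab
}

#' Blood optics model
#'
#' Bundles the parameters that turn wavelength and oxygenation into an
#' absorption coefficient: total hemoglobin concentration (150 g/L, typical
#' whole blood), the extinction table, and the blood volume fractions used by
#' the phantoms (100% inside vessels, 0.5% in background tissue).
#'
#' @param c_hb hemoglobin concentration in g/L
#' @param extinction extinction table as returned by [hb_extinction()]
#' @param bvf_background,bvf_vessel blood volume fractions
#' @export
blood_optics <- function(c_hb = 150, extinction = hb_extinction(),
                         bvf_background = 0.005, bvf_vessel = 1.0) {
  structure(list(c_hb = c_hb, extinction = extinction,
                 bvf_background = bvf_background, bvf_vessel = bvf_vessel,
                 m_hb = 64500), class = "cepaq_blood_optics")
}

#' Absorption coefficient of (partially) oxygenated blood
#'
#' \eqn{\mu_a = bvf \cdot \ln(10) \cdot (c_{Hb}/M_{Hb}) \cdot
#' [sO_2\,\epsilon_{HbO2}(\lambda) + (1 - sO_2)\,\epsilon_{Hb}(\lambda)]}
#' in cm\eqn{^{-1}}, with \eqn{M_{Hb} = 64{,}500} g/mol. Affine in `so2` at
#' fixed wavelength and proportional to both `c_hb` and `bvf`.
#'
#' @param wavelength wavelength in nm (must lie within the shipped table)
#' @param so2 oxygen saturation in `[0, 1]` (vectorised)
#' @param bvf blood volume fraction
#' @param model a [blood_optics()] model
#' @return absorption coefficient(s) in cm^-1
#' @export
blood_mu_a <- function(wavelength, so2, bvf = 1, model = blood_optics()) {
  tab <- model$extinction
  if (any(wavelength < min(tab$wavelength)) || any(wavelength > max(tab$wavelength)))
    stop("wavelength outside extinction table range [",
         min(tab$wavelength), ", ", max(tab$wavelength), "] nm")
  stopifnot(all(so2 >= 0 & so2 <= 1))
  e_o <- approx(tab$wavelength, tab$eps_hbo2, wavelength)$y
  e_d <- approx(tab$wavelength, tab$eps_hb, wavelength)$y
  conc <- model$c_hb / model$m_hb          # mol/L
  bvf * log(10) * conc * (so2 * e_o + (1 - so2) * e_d)
}

#' Background absorption for the multispectral oxygenation phantom
#'
#' Background tissue carries a 0.5% blood volume fraction at the local
#' oxygenation plus a constant non-hemoglobin baseline. The baseline is
#' calibrated once so that the background absorption is 0.1 cm^-1 at 800 nm
#' (reference oxygenation 70%), matching the monospectral phantoms.
#'
#' @param wavelength nm
#' @param so2 background oxygen saturation
#' @param model a [blood_optics()] model
#' @return absorption coefficient in cm^-1
#' @export
background_mu_a_oxy <- function(wavelength, so2, model = blood_optics()) {
  baseline <- 0.1 - blood_mu_a(800, 0.7, model$bvf_background, model)
  blood_mu_a(wavelength, so2, model$bvf_background, model) + baseline
}

#' Reference spectra matrix for spectral unmixing
#'
#' Rows are wavelengths, columns the chromophores (HbO2, Hb), on the molar
#' absorption scale of the forward model. Built from the same extinction
#' table as the phantom generator so that forward simulation and unmixing
#' share one spectral model.
#'
#' @param wavelengths nm vector (default the 750/800/850 nm comb)
#' @param model a [blood_optics()] model
#' @export
reference_spectra <- function(wavelengths = c(750, 800, 850),
                              model = blood_optics()) {
  A <- cbind(hbo2 = blood_mu_a(wavelengths, 1, 1, model),
             hb = blood_mu_a(wavelengths, 0, 1, model))
  rownames(A) <- as.character(wavelengths)
  A
}
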