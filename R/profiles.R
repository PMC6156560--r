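#' Nominal component band tables
#'
#' The simulator mixes three component spectra resembling the infrared
#' signatures of proteins, lipids and nucleic acids, each built from the
#' same 16 bands (cm^-1): 1030, 1080, 1172, 1242, 1280, 1342, 1400, 1462,
#' 1550, 1650, 1754, 2352, 2850, 2920, 2962 and 3300.  Band heights and
#' widths per component are package defaults chosen to resemble tissue
#' spectra (protein dominated by amide I/II at 1650/1550 and the 3300
#' stretch; lipid by the C-H stretches 2920/2850 and the 1754 carbonyl;
#' nucleic acid by the phosphate bands 1080/1242/1030); they are fully
#' overridable.
#'
#' @return `default_profiles()` returns a data.frame with columns `center`,
#'   `fwhm` (cm^-1) and one height column per component
#'   (`protein`, `lipid`, `nucleic`).
#' @export
default_profiles <- function() {
  data.frame(
    center = c(1030, 1080, 1172, 1242, 1280, 1342, 1400, 1462,
               1550, 1650, 1754, 2352, 2850, 2920, 2962, 3300),
    fwhm   = c(  24,   28,   22,   30,   26,   22,   26,   24,
                 36,   40,   26,   30,   28,   34,   26,  160),
    protein = c(0.08, 0.12, 0.15, 0.25, 0.20, 0.15, 0.30, 0.20,
                0.70, 1.00, 0.05, 0.04, 0.15, 0.30, 0.15, 0.60),
    lipid   = c(0.05, 0.10, 0.12, 0.08, 0.06, 0.05, 0.15, 0.45,
                0.05, 0.20, 0.60, 0.04, 0.70, 1.00, 0.50, 0.15),
    nucleic = c(0.70, 1.00, 0.30, 0.80, 0.25, 0.20, 0.25, 0.15,
                0.20, 0.30, 0.08, 0.04, 0.10, 0.15, 0.10, 0.25))
}

# the 16 canonical band centers; profile tables are validated against them
BAND_CENTERS <- c(1030, 1080, 1172, 1242, 1280, 1342, 1400, 1462,
                  1550, 1650, 1754, 2352, 2850, 2920, 2962, 3300)

#' @rdname default_profiles
#' @param name component name, one of `"protein"`, `"lipid"`, `"nucleic"`.
#' @param profiles band table in the format of [default_profiles()].
#' @return `component_profile()` returns a data.frame with columns `center`,
#'   `height`, `fwhm` (16 rows, one per band).
#' @export
component_profile <- function(name = c("protein", "lipid", "nucleic"),
                              profiles = default_profiles()) {
  name <- match.arg(name)
  validate_profiles(profiles)
  data.frame(center = profiles$center, height = profiles[[name]],
             fwhm = profiles$fwhm)
}

validate_profiles <- function(profiles) {
  need <- c("center", "fwhm", "protein", "lipid", "nucleic")
  if (!all(need %in% names(profiles)))
    stop("profile table must have columns ", paste(need, collapse = ", "))
  if (!setequal(profiles$center, BAND_CENTERS) ||
      nrow(profiles) != length(BAND_CENTERS))
    stop("profile table must contain exactly the 16 canonical band centers")
  if (any(profiles$fwhm <= 0)) stop("band FWHM must be positive")
  if (any(profiles[c("protein", "lipid", "nucleic")] < 0))
    stop("band heights must be nonnegative")
  invisible(profiles)
}

#' Mixed Gaussian-Lorentzian band shape
#'
#' Evaluates a single absorption band as a 50:50 mixture of a Gaussian and a
#' Lorentzian of equal height `h`, center `center` and full width at half
#' maximum `fwhm`:
#' `h * (0.5 * exp(-4 ln 2 (v - c)^2 / w^2) + 0.5 / (1 + 4 ((v - c)/w)^2))`.
#' Both shapes peak at `h` and equal `h/2` at `c +- w/2`, so the mixture
#' preserves the nominal height and FWHM.
#'
#' @param wavenumbers axis values (cm^-1).
#' @param center band center (cm^-1).
#' @param height peak absorbance.
#' @param fwhm full width at half maximum (cm^-1), > 0.
#' @return numeric vector of the band's contribution on the axis.
#' @export
mixed_band <- function(wavenumbers, center, height, fwhm) {
  if (any(fwhm <= 0)) stop("`fwhm` must be positive")
  u <- (wavenumbers - center) / fwhm
  height * (0.5 * exp(-4 * log(2) * u^2) + 0.5 / (1 + 4 * u^2))
}
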