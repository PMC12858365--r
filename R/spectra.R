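#' Chromophore absorption spectra
#'
#' Loads the packaged table of specific absorption values for the five
#' chromophores relevant to near-infrared breast imaging: oxyhemoglobin
#' (HbO2), deoxyhemoglobin (Hb), water, fat (lipid) and melanin, at the
#' three excitation wavelengths 757, 800 and 850 nm. Hemoglobin values are
#' in mm^-1 per mM of heme; water/fat/melanin are mm^-1 per unit volume
#' fraction, so that the voxel absorption coefficient is a plain weighted
#' sum of concentrations/volume fractions times these values.
#'
#' Users may substitute their own table (same columns) to audit or change
#' the provenance of the constants.
#'
#' @param path optional path to an alternative CSV
#'   (columns \code{name,wavelength_nm,epsilon,units}).
#' @return data.frame of class \code{chromophore_spectra}. The condition
#'   number of the 3x2 hemoglobin extinction matrix is attached as
#'   attribute \code{hb_condition} (it must be finite for unmixing to be
#'   well posed).
#' @export
chromophore_spectra <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "chromophores.csv", package = "qpactsim")
  sp <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("name", "wavelength_nm", "epsilon") %in% names(sp)))
  if (any(sp$epsilon < 0)) stopf("negative epsilon in spectra table")
  class(sp) <- c("chromophore_spectra", "data.frame")
  wl <- c(757, 800, 850)
  if (all(c("HbO2", "Hb") %in% sp$name)) {
    E <- extinction_matrix(sp, intersect(wl, sp$wavelength_nm))
    attr(sp, "hb_condition") <- kappa(E, exact = TRUE)
  }
  sp
}

#' Extinction matrix for hemoglobin unmixing
#'
#' @param spectra a \code{chromophore_spectra} table.
#' @param wavelengths wavelengths (nm) to use as rows.
#' @param chromophores column chromophores; default HbO2 and Hb.
#' @return matrix (length(wavelengths) x length(chromophores)).
#' @export
extinction_matrix <- function(spectra, wavelengths,
                              chromophores = c("HbO2", "Hb")) {
  E <- sapply(chromophores, function(ch)
    get_epsilon(spectra, ch, wavelengths))
  E <- matrix(E, nrow = length(wavelengths),
              dimnames = list(wavelengths, chromophores))
  if (qr(E)$rank < ncol(E))
    stopf("extinction matrix is singular over wavelengths %s",
          paste(wavelengths, collapse = ", "))
  E
}

# epsilon values for one chromophore at given wavelengths; errors name the
# offending chromophore and wavelength.
get_epsilon <- function(spectra, name, wavelengths) {
  sub <- spectra[spectra$name == name, ]
  if (nrow(sub) == 0) stopf("no spectrum for chromophore '%s'", name)
  idx <- match(wavelengths, sub$wavelength_nm)
  if (anyNA(idx))
    stopf("chromophore '%s' has no value at wavelength %s nm",
          name, paste(wavelengths[is.na(idx)], collapse = ", "))
  sub$epsilon[idx]
}

# Packaged per-tissue optical/acoustic baseline table.
tissue_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "tissue_properties.csv", package = "qpactsim")
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Packaged functional ranges and skin-tone melanosome ranges.
functional_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "functional_ranges.csv", package = "qpactsim")
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

skin_tone_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "skin_tones.csv", package = "qpactsim")
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
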