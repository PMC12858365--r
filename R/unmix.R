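#' Linear spectral unmixing of hemoglobin
#'
#' Baseline sO2 estimator assuming wavelength-invariant optical fluence:
#' per masked voxel the multiwavelength signal is fit by least squares to
#' \code{p(lambda) ~ c_hbo2 * eps_HbO2(lambda) + c_hb * eps_Hb(lambda)}
#' jointly over all wavelengths (the unknown common scale cancels in the
#' saturation ratio). Negative concentration solutions are clipped at zero
#' before forming the ratio; voxels whose total concentration falls below
#' a floor (relative to the volume maximum) are marked invalid rather than
#' given a saturation value.
#'
#' @param p_volumes named per-wavelength list of volumes (>= 2 wavelengths).
#' @param spectra a [chromophore_spectra()] table containing HbO2 and Hb.
#' @param mask logical volume of voxels to unmix (default all).
#' @param floor_frac invalidity floor as a fraction of the maximum total
#'   concentration.
#' @return list of class \code{unmix_result}: \code{c_hbo2}, \code{c_hb},
#'   \code{so2} (in [0,1], NA outside \code{valid_mask}), \code{valid_mask}.
#' @export
linear_unmix <- function(p_volumes, spectra = chromophore_spectra(),
                         mask = NULL, floor_frac = 1e-12) {
  stopifnot(is.list(p_volumes), length(p_volumes) >= 2)
  wl <- as.numeric(names(p_volumes))
  if (anyNA(wl)) stopf("p_volumes must be named by wavelength")
  E <- extinction_matrix(spectra, wl)  # rejects singular systems
  sh <- dim(p_volumes[[1]])
  if (is.null(mask)) mask <- array(TRUE, sh)
  idx <- which(mask)
  P <- vapply(p_volumes, function(v) as.numeric(v)[idx], numeric(length(idx)))
  if (length(idx) == 1) P <- matrix(P, nrow = 1)
  # normal-equations solve for the two concentrations, all voxels at once
  pinv <- solve(crossprod(E), t(E))  # 2 x n_wl
  C <- P %*% t(pinv)
  C[C < 0] <- 0
  tot <- C[, 1] + C[, 2]
  floor_val <- floor_frac * max(tot, 0)
  valid <- tot > max(floor_val, 0) & tot > 0
  so2v <- rep(NA_real_, length(idx))
  so2v[valid] <- pmin(pmax(C[valid, 1] / tot[valid], 0), 1)
  mk <- function(vals) { a <- array(NA_real_, sh); a[idx] <- vals; a }
  vm <- array(FALSE, sh); vm[idx] <- valid
  structure(list(c_hbo2 = mk(C[, 1]), c_hb = mk(C[, 2]), so2 = mk(so2v),
                 valid_mask = vm),
            class = "unmix_result")
}

#' Fluence-compensated linear spectral unmixing
#'
#' Rescales the per-wavelength pressure estimates by estimated fluence maps
#' (voxelwise division) before linear unmixing, partially undoing spectral
#' coloring. The fluence estimates must be strictly positive on the mask
#' (a floor is applied upstream by [homogeneous_fluence()]).
#'
#' @param p_volumes named per-wavelength list of volumes.
#' @param phi_est matching named list of fluence volumes or
#'   \code{fluence_volume} objects.
#' @param spectra,mask,floor_frac as in [linear_unmix()].
#' @return an \code{unmix_result}.
#' @export
fluence_compensated_unmix <- function(p_volumes, phi_est,
                                      spectra = chromophore_spectra(),
                                      mask = NULL, floor_frac = 1e-12) {
  stopifnot(is.list(phi_est), length(phi_est) == length(p_volumes))
  phi <- lapply(phi_est, function(f)
    if (inherits(f, "fluence_volume")) f$phi else f)
  if (is.null(mask)) mask <- array(TRUE, dim(p_volumes[[1]]))
  for (w in seq_along(phi))
    if (any(phi[[w]][mask] <= 0))
      stopf("non-positive fluence inside mask at wavelength %s",
            names(p_volumes)[w])
  rescaled <- mapply(function(p, f) p / f, p_volumes, phi, SIMPLIFY = FALSE)
  names(rescaled) <- names(p_volumes)
  linear_unmix(rescaled, spectra = spectra, mask = mask,
               floor_frac = floor_frac)
}
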