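#' Illumination source model
#'
#' Arc-shaped illuminators on a hemispherical shell around the z axis.
#' The default geometry mirrors the emulated imager: 20 arcs, each spanning
#' 80 degrees in polar angle with 5 linear fiber segments, giving 100 line
#' beams with conical emission of 12.5 degree half-angle on a 145 mm-radius
#' shell. For desk-scale grids the shell radius can be reduced; beams are
#' always aimed at the hemisphere center.
#'
#' @param n_arcs number of arcs (azimuthal positions).
#' @param segments_per_arc fiber segments per arc.
#' @param arc_span_deg polar span of each arc.
#' @param cone_half_angle_deg emission cone half-angle.
#' @param shell_radius_mm radius of the source shell.
#' @param polar_start_deg polar angle of the first segment (from +z).
#' @return object of class \code{source_model}.
#' @export
source_model <- function(n_arcs = 20, segments_per_arc = 5,
                         arc_span_deg = 80, cone_half_angle_deg = 12.5,
                         shell_radius_mm = 145, polar_start_deg = 5) {
  structure(list(n_arcs = n_arcs, segments_per_arc = segments_per_arc,
                 arc_span_deg = arc_span_deg,
                 cone_half_angle_deg = cone_half_angle_deg,
                 shell_radius_mm = shell_radius_mm,
                 polar_start_deg = polar_start_deg),
            class = "source_model")
}

#' Beam table for a source model aimed at a grid
#'
#' @param source a [source_model()] or a numeric beam matrix with columns
#'   (x, y, z, dx, dy, dz, half_angle_rad, weight), passed through as-is.
#' @param grid a [grid_spec()]; beams aim at the hemisphere center on the
#'   chest-wall face unless \code{center} is given.
#' @param center optional aim point (mm).
#' @return beam matrix; all direction rows are unit-norm.
#' @export
source_beams <- function(source, grid, center = NULL) {
  if (is.matrix(source)) return(source)
  stopifnot(inherits(source, "source_model"))
  ext <- grid_extent(grid)
  if (is.null(center)) center <- c(ext[1] / 2, ext[2] / 2, 0)
  phis <- seq(0, 2 * pi, length.out = source$n_arcs + 1)[seq_len(source$n_arcs)]
  thetas <- source$polar_start_deg +
    seq(0, source$arc_span_deg, length.out = source$segments_per_arc)
  thetas <- thetas * pi / 180
  rows <- list()
  for (phi in phis) for (th in thetas) {
    pos <- center + source$shell_radius_mm *
      c(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))
    dir <- center - pos
    dir <- dir / sqrt(sum(dir^2))
    rows[[length(rows) + 1L]] <-
      c(pos, dir, source$cone_half_angle_deg * pi / 180, 1)
  }
  do.call(rbind, rows)
}

#' Pencil and isotropic point sources (mainly for physics tests)
#' @param pos position (mm); @param dir unit direction.
#' @return single-row beam matrix.
#' @rdname point_sources
#' @export
pencil_beam <- function(pos, dir) {
  dir <- dir / sqrt(sum(dir^2))
  matrix(c(pos, dir, 0, 1), nrow = 1)
}

#' @rdname point_sources
#' @export
isotropic_source <- function(pos)
  matrix(c(pos, 0, 0, 1, pi, 1), nrow = 1)

#' Monte Carlo optical fluence
#'
#' Voxelized Monte Carlo photon transport: step lengths sampled from the
#' local attenuation coefficient, continuous absorption weighting (the
#' photon deposits the absorbed fraction of its weight at each collision),
#' Henyey-Greenstein scattering with the local anisotropy, Russian roulette
#' below a weight threshold, and a track-length fluence estimator (weight
#' times path length per voxel, divided by voxel volume). Refractive-index
#' boundaries are matched (no Fresnel reflection); the n map is carried but
#' unused. Fluence is per unit delivered energy (mm^-2). Deterministic
#' given \code{seed}.
#'
#' @param optical optical maps as from [assign_optical_properties()].
#' @param grid a [grid_spec()].
#' @param source a [source_model()] or beam matrix (see [source_beams()]).
#' @param wavelength one wavelength present in \code{optical}.
#' @param n_photons number of photon packets (>= 1).
#' @param seed RNG seed for the photon stream.
#' @param roulette_wmin,roulette_m Russian roulette threshold and survival
#'   factor.
#' @return object of class \code{fluence_volume}: list with \code{phi}
#'   (3D volume), \code{n_photons}, \code{seed}, \code{wavelength} and the
#'   \code{energy} ledger (launched, absorbed, escaped, killed, boost and
#'   the relative conservation residual).
#' @export
mc_fluence <- function(optical, grid, source, wavelength, n_photons,
                       seed = 1L, roulette_wmin = 1e-4, roulette_m = 10) {
  if (n_photons < 1) stopf("n_photons must be >= 1")
  wl <- as.character(wavelength)
  if (!wl %in% names(optical$mua))
    stopf("wavelength %s not present in optical maps", wl)
  mua <- optical$mua[[wl]]; mus <- optical$mus[[wl]]; g <- optical$g
  beams <- source_beams(source, grid)
  res <- mc_run_cpp(as.numeric(mua), as.numeric(mus), as.numeric(g),
                    grid$shape, grid$voxel_size, beams,
                    n_photons, roulette_wmin, roulette_m,
                    as.double(seed))
  resid <- abs(res$launched -
                 (res$absorbed + res$escaped + res$killed - res$boost)) /
    res$launched
  structure(list(phi = array(res$phi, dim = grid$shape),
                 n_photons = n_photons, seed = seed, wavelength = wavelength,
                 energy = list(launched = res$launched,
                               absorbed = res$absorbed,
                               escaped = res$escaped, killed = res$killed,
                               boost = res$boost, residual = resid)),
            class = "fluence_volume")
}

#' Ensemble-average homogeneous optical properties of a cohort
#'
#' Voxel-weighted per-wavelength means of mua, mus, g and n over all breast
#' (non-water) voxels pooled across the cohort, as used by the
#' fluence-compensated baseline.
#'
#' @param cohort list of \code{qpact_phantom}.
#' @param wavelengths wavelengths (nm).
#' @return named list per wavelength with scalars mua, mus, g, n.
#' @export
ensemble_average_props <- function(cohort, wavelengths = c(757, 800, 850)) {
  if (length(cohort) == 0) stopf("empty cohort")
  out <- setNames(vector("list", length(wavelengths)),
                  as.character(wavelengths))
  for (wl in as.character(wavelengths)) {
    num <- c(mua = 0, mus = 0, g = 0, n = 0); den <- 0
    for (ph in cohort) {
      m <- breast_mask(ph)
      nv <- sum(m)
      num["mua"] <- num["mua"] + sum(ph$optical$mua[[wl]][m])
      num["mus"] <- num["mus"] + sum(ph$optical$mus[[wl]][m])
      num["g"] <- num["g"] + sum(ph$optical$g[m])
      num["n"] <- num["n"] + sum(ph$optical$n[m])
      den <- den + nv
    }
    out[[wl]] <- as.list(num / den)
  }
  out
}

#' Homogeneous-property fluence for the compensated baseline
#'
#' Computes Monte Carlo fluence on a two-compartment medium: uniform
#' ensemble-average properties inside the breast mask and water properties
#' outside, then clamps the result below by a configured floor so the
#' downstream division is safe.
#'
#' @param breast_mask logical volume of breast voxels (nonempty).
#' @param avg_props per-wavelength homogeneous values, as from
#'   [ensemble_average_props()].
#' @param source,wavelength,n_photons,seed as in [mc_fluence()].
#' @param grid a [grid_spec()].
#' @param floor_frac fluence floor as a fraction of the volume maximum.
#' @return a \code{fluence_volume} with \code{phi >= floor}.
#' @export
homogeneous_fluence <- function(breast_mask, avg_props, source, wavelength,
                                n_photons, seed = 1L, grid,
                                floor_frac = 1e-6) {
  if (!any(breast_mask)) stopf("empty breast mask")
  wl <- as.character(wavelength)
  sp <- chromophore_spectra()
  tt <- tissue_table()
  wrow <- tt[tt$label == "water", ]
  mua_w <- get_epsilon(sp, "water", as.numeric(wavelength))
  mus_w <- wrow$musp800 * (as.numeric(wavelength) / 800)^(-wrow$bmie) /
    (1 - wrow$g)
  sh <- dim(breast_mask)
  mua <- array(mua_w, sh); mus <- array(mus_w, sh); g <- array(wrow$g, sh)
  ap <- avg_props[[wl]]
  mua[breast_mask] <- ap$mua; mus[breast_mask] <- ap$mus
  g[breast_mask] <- ap$g
  opt <- list(mua = setNames(list(mua), wl), mus = setNames(list(mus), wl),
              g = g, n = array(1.33, sh))
  fv <- mc_fluence(opt, grid, source, wavelength, n_photons, seed)
  fv$floor <- floor_frac * max(fv$phi)
  fv$phi <- pmax(fv$phi, fv$floor)
  fv
}
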