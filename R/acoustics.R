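#' Induced initial pressure
#'
#' The photoacoustic initial pressure is the Grueneisen-scaled absorbed
#' energy density, \code{p0 = gamma * mua * phi}, evaluated voxelwise.
#' The Grueneisen parameter defaults to 1.
#'
#' @param mua absorption volume (mm^-1) or per-wavelength list of volumes.
#' @param phi fluence volume, [mc_fluence()] result, or per-wavelength list
#'   matching \code{mua}.
#' @param gamma scalar Grueneisen parameter.
#' @return volume (or list of volumes) of initial pressure.
#' @export
induced_pressure <- function(mua, phi, gamma = 1) {
  if (inherits(phi, "fluence_volume")) phi <- phi$phi
  if (is.list(mua)) {
    stopifnot(is.list(phi), length(mua) == length(phi))
    return(mapply(induced_pressure, mua, phi,
                  MoreArgs = list(gamma = gamma), SIMPLIFY = FALSE))
  }
  if (inherits(phi, "fluence_volume")) phi <- phi$phi
  if (!identical(dim(mua), dim(phi)))
    stopf("mua and phi shapes differ")
  gamma * mua * phi
}

#' Transducer array geometry
#'
#' Rotating arc of point-like elements (3D) or a full ring (2D). The
#' default 3D geometry mirrors the emulated imager: 108 elements on an
#' 85 mm-radius, 80-degree arc rotated through 480 evenly distributed
#' views about z, each element recording 3720 samples at 20 MHz. Element
#' positions are later snapped to the nearest voxel centers of the
#' simulation grid.
#'
#' @param geometry "arc3d" or "ring2d".
#' @param n_elements elements per view (per ring for 2D).
#' @param radius_mm arc/ring radius.
#' @param span_deg arc polar span (3D only).
#' @param n_views tomographic views (3D only).
#' @param sampling_rate Hz; \code{n_samples} temporal samples.
#' @param center rotation center (mm); defaults to the hemisphere center
#'   when positions are generated for a grid.
#' @return object of class \code{transducer_array}.
#' @export
transducer_array <- function(geometry = c("arc3d", "ring2d"),
                             n_elements = 108, radius_mm = 85,
                             span_deg = 80, n_views = 480,
                             sampling_rate = 20e6, n_samples = 3720,
                             center = NULL) {
  geometry <- match.arg(geometry)
  structure(list(geometry = geometry, n_elements = n_elements,
                 radius_mm = radius_mm, span_deg = span_deg,
                 n_views = n_views, sampling_rate = sampling_rate,
                 n_samples = n_samples, center = center),
            class = "transducer_array")
}

#' Physical element positions of a transducer array
#'
#' @param array a [transducer_array()].
#' @param grid a [grid_spec()] (supplies the default center).
#' @return matrix of positions (mm) with columns x,y[,z] and attributes
#'   \code{view}, \code{element}.
#' @export
array_positions <- function(array, grid) {
  ext <- grid_extent(grid)
  d <- length(grid$shape)
  center <- array$center %||%
    (if (d == 2) c(ext[1] / 2, ext[2] / 2) else c(ext[1] / 2, ext[2] / 2, 0))
  if (array$geometry == "ring2d" || d == 2) {
    th <- seq(0, 2 * pi, length.out = array$n_elements + 1)[
      seq_len(array$n_elements)]
    pos <- cbind(center[1] + array$radius_mm * cos(th),
                 center[2] + array$radius_mm * sin(th))
    attr(pos, "view") <- rep(1L, nrow(pos))
    attr(pos, "element") <- seq_len(nrow(pos))
    return(pos)
  }
  phis <- seq(0, 2 * pi, length.out = array$n_views + 1)[
    seq_len(array$n_views)]
  # elements spread over the polar span, kept above the chest-wall plane
  thetas <- seq(8, 8 + array$span_deg, length.out = array$n_elements)
  thetas <- pmin(thetas, 89.5) * pi / 180
  pos <- matrix(0, array$n_views * array$n_elements, 3)
  vid <- integer(nrow(pos)); eid <- integer(nrow(pos))
  k <- 0L
  for (v in seq_along(phis)) for (e in seq_along(thetas)) {
    k <- k + 1L
    pos[k, ] <- center + array$radius_mm *
      c(sin(thetas[e]) * cos(phis[v]), sin(thetas[e]) * sin(phis[v]),
        cos(thetas[e]))
    vid[k] <- v; eid[k] <- e
  }
  attr(pos, "view") <- vid
  attr(pos, "element") <- eid
  pos
}

# Snap physical positions to nearest voxel centers; returns 1-based index
# matrix plus linear indices. Positions outside the grid are clamped.
snap_positions <- function(pos, grid) {
  h <- grid$voxel_size
  sh <- grid$shape
  idx <- sweep(pos, 2, rep(h, ncol(pos)), "/") + 0.5
  idx <- round(idx)
  for (j in seq_len(ncol(idx)))
    idx[, j] <- pmin(pmax(idx[, j], 1), sh[j])
  lin <- idx[, 1]
  mult <- 1
  for (j in 2:ncol(idx)) {
    mult <- mult * sh[j - 1]
    lin <- lin + (idx[, j] - 1) * mult
  }
  list(idx = idx, lin = as.integer(lin))
}

# ---- k-space pseudospectral solver ------------------------------------------

kvec_axis <- function(n, h) {
  f <- 0:(n - 1)
  f[f > n / 2] <- f[f > n / 2] - n
  2 * pi * f / (n * h)
}

# broadcast a 1D vector along one axis of an nD shape
axis_array <- function(v, axis, sh) {
  d <- length(sh)
  if (axis == 1) return(array(rep(v, times = prod(sh[-1])), dim = sh))
  inner <- prod(sh[seq_len(axis - 1)])
  outer_n <- prod(sh[seq_len(d)][-seq_len(axis)])
  array(rep(rep(v, each = inner), times = max(outer_n, 1)), dim = sh)
}

# First-order coupled k-space pseudospectral solver with split-field PML.
# Spatially staggered spectral derivatives (exp(+-ik h/2) shifts) and a
# k-space correction sinc(c_ref k dt / 2). Supports 2D and 3D fields.
# source_traces: matrix (n_sensor x n_steps) injected as Dirichlet pressure
# at sensor voxels (used for time reversal). Returns sensor records and the
# final pressure field.
kspace_sim <- function(p0, c_map, rho_map, h, dt, n_steps, sensor_lin,
                       pml_width = 10, pml_alpha = 2,
                       source_traces = NULL, record = TRUE,
                       record_energy = FALSE) {
  sh <- dim(p0)
  d <- length(sh)
  h <- h * 1e-3  # grid spacing in meters (c is in m/s)
  if (length(c_map) == 1) c_map <- array(c_map, sh)
  if (length(rho_map) == 1) rho_map <- array(rho_map, sh)
  csq <- c_map^2
  cref <- max(c_map)
  ks <- lapply(seq_len(d), function(a) kvec_axis(sh[a], h))
  kmag2 <- Reduce(`+`, lapply(seq_len(d), function(a)
    axis_array(ks[[a]]^2, a, sh)))
  kmag <- sqrt(kmag2)
  arg <- cref * kmag * dt / 2
  kappa <- ifelse(arg == 0, 1, sin(arg) / pmax(arg, .Machine$double.xmin))
  Kp <- Km <- vector("list", d)
  for (a in seq_len(d)) {
    ka <- axis_array(ks[[a]], a, sh)
    Kp[[a]] <- 1i * ka * kappa * exp(1i * ka * h / 2)
    Km[[a]] <- 1i * ka * kappa * exp(-1i * ka * h / 2)
  }
  # PML damping per axis
  pa <- vector("list", d)
  for (a in seq_len(d)) {
    n <- sh[a]
    prof <- numeric(n)
    w <- min(pml_width, floor(n / 2) - 1)
    if (w > 0) {
      ramp <- ((w:1) / w)^4
      prof[1:w] <- ramp
      prof[(n - w + 1):n] <- rev(ramp)
    }
    sig <- pml_alpha * (cref / h) * prof
    pa[[a]] <- axis_array(exp(-sig * dt / 2), a, sh)
  }

  nvox <- prod(sh)
  u <- lapply(seq_len(d), function(a) array(0, sh))
  rhos <- lapply(seq_len(d), function(a) p0 / (d * csq))
  p <- p0
  rec <- if (record && length(sensor_lin))
    matrix(0, length(sensor_lin), n_steps) else NULL
  energy <- if (record_energy) numeric(n_steps) else NULL

  for (t in seq_len(n_steps)) {
    Pf <- fft(p)
    for (a in seq_len(d)) {
      dp <- Re(fft(Kp[[a]] * Pf, inverse = TRUE)) / nvox
      u[[a]] <- pa[[a]] * (pa[[a]] * u[[a]] - (dt / rho_map) * dp)
    }
    for (a in seq_len(d)) {
      du <- Re(fft(Km[[a]] * fft(u[[a]]), inverse = TRUE)) / nvox
      rhos[[a]] <- pa[[a]] * (pa[[a]] * rhos[[a]] - dt * rho_map * du)
    }
    p <- csq * Reduce(`+`, rhos)
    if (!is.null(source_traces)) {
      s <- source_traces[, t]
      for (a in seq_len(d)) rhos[[a]][sensor_lin] <- s / (d * csq[sensor_lin])
      p[sensor_lin] <- s
    }
    if (!is.null(rec)) rec[, t] <- p[sensor_lin]
    if (record_energy)
      energy[t] <- sum(p^2 / (2 * rho_map * csq)) +
        sum(rho_map * Reduce(`+`, lapply(u, function(x) x^2)) / 2)
  }
  list(records = rec, p_final = p, energy = energy)
}

#' Simulate acoustic sensor data from an initial pressure distribution
#'
#' Propagates \code{p0} through the heterogeneous medium with a first-order
#' k-space pseudospectral solver (heterogeneous sound speed and density,
#' k-space-corrected staggered spectral derivatives, split-field absorbing
#' boundary layer) and records the pressure at transducer positions snapped
#' to the nearest voxel centers. Power-law acoustic attenuation is applied
#' as a per-trace frequency-domain filter parameterized by the
#' medium-averaged attenuation coefficient and exponent and the
#' source-centroid-to-sensor path length (a surrogate for the full
#' fractional-Laplacian absorption operator).
#'
#' @param p0 initial pressure volume (2D or 3D array).
#' @param acoustic list with \code{c}, \code{rho}, \code{alpha0}, \code{y}
#'   maps (scalars allowed).
#' @param array a [transducer_array()].
#' @param grid matching [grid_spec()].
#' @param cfl_max maximum allowed CFL number \code{c_max dt / h}; a
#'   configuration violating it is rejected before stepping.
#' @param pml_width absorbing layer width in voxels.
#' @param attenuation apply the power-law attenuation surrogate.
#' @return object of class \code{sensor_data}: \code{records}
#'   (n_positions x n_samples), \code{dt}, \code{positions},
#'   \code{positions_snapped}, \code{array}, \code{noise_sigma} (NULL until
#'   noise is added).
#' @export
simulate_acoustics <- function(p0, acoustic, array, grid, cfl_max = 0.3,
                               pml_width = 10, attenuation = TRUE) {
  if (!identical(dim(p0), as.integer(grid$shape)) &&
      !identical(dim(p0), grid$shape))
    stopf("p0 does not match grid shape")
  dt <- 1 / array$sampling_rate
  cmax <- max(acoustic$c)
  cfl <- cmax * dt / (grid$voxel_size * 1e-3)
  if (cfl > cfl_max)
    stopf("unstable configuration: CFL %.3f exceeds bound %.3f", cfl, cfl_max)
  pos <- array_positions(array, grid)
  sn <- snap_positions(pos, grid)
  sim <- kspace_sim(p0, acoustic$c, acoustic$rho, grid$voxel_size, dt,
                    array$n_samples, sn$lin, pml_width = pml_width)
  rec <- sim$records
  if (attenuation && !is.null(acoustic$alpha0) && any(acoustic$alpha0 > 0) &&
      any(rec != 0)) {
    a0 <- mean(acoustic$alpha0)  # dB MHz^-y cm^-1, path-averaged surrogate
    yb <- mean(acoustic$y)
    tot <- sum(p0)
    cen <- if (tot > 0) {
      idx <- which(p0 > 0, arr.ind = TRUE)
      colSums(idx * p0[p0 > 0]) / tot * grid$voxel_size
    } else grid_extent(grid) / 2
    nf <- ncol(rec)
    fr <- abs(kvec_axis(nf, 1)) / (2 * pi) / dt / 1e6  # MHz
    for (i in seq_len(nrow(rec))) {
      dist_cm <- sqrt(sum((pos[i, ] - cen)^2)) / 10
      H <- exp(-(a0 / 8.686) * (fr^yb) * dist_cm)
      rec[i, ] <- Re(fft(fft(rec[i, ]) * H, inverse = TRUE)) / nf
    }
  }
  structure(list(records = rec, dt = dt, positions = pos,
                 positions_snapped = sn$idx, array = array,
                 grid = grid, noise_sigma = NULL),
            class = "sensor_data")
}

#' Add measurement noise using the 1 percent-of-ensemble-max rule
#'
#' The noise standard deviation is \code{fraction} times the ensemble mean
#' of the per-record maximum absolute signal, pooled across all wavelengths
#' of each record set; iid zero-mean Gaussian noise of that standard
#' deviation is added to every sample.
#'
#' @param sensor_multiwavelength a list of per-wavelength
#'   \code{sensor_data} objects for one phantom, or a list of such lists
#'   for an ensemble (the sigma is then shared across the ensemble).
#' @param fraction noise fraction (default 0.01).
#' @param seed RNG seed.
#' @return same structure with noisy \code{records} and \code{noise_sigma}
#'   recorded on each \code{sensor_data}.
#' @export
add_sensor_noise <- function(sensor_multiwavelength, fraction = 0.01,
                             seed = 1L) {
  if (fraction < 0) stopf("fraction must be >= 0")
  x <- sensor_multiwavelength
  ensemble <- !inherits(x, "sensor_data") && !inherits(x[[1]], "sensor_data")
  sets <- if (ensemble) x else list(x)
  if (inherits(sets[[1]], "sensor_data")) sets <- lapply(sets, list)
  maxes <- vapply(sets, function(s)
    max(vapply(s, function(sd1) max(abs(sd1$records)), 0)), 0)
  sigma <- fraction * mean(maxes)
  if (fraction == 0) sigma <- 0
  out <- with_seed(seed, lapply(sets, function(s) lapply(s, function(sd1) {
    if (sigma > 0)
      sd1$records <- sd1$records +
        array(rnorm(length(sd1$records), 0, sigma), dim = dim(sd1$records))
    sd1$noise_sigma <- sigma
    sd1
  })))
  if (!ensemble) {
    res <- out[[1]]
    if (inherits(sensor_multiwavelength, "sensor_data")) return(res[[1]])
    return(res)
  }
  out
}

#' Time-reversal image reconstruction
#'
#' Re-emits the recorded traces backward in time as Dirichlet pressure
#' sources at the sensor voxels of a homogeneous model medium (assumed
#' constant sound speed and density, no attenuation) and returns the
#' final-time field. Transducer positions are snapped to the nearest voxels
#' of the reconstruction grid, which may be coarser than the forward grid;
#' duplicate snapped positions are collapsed to a single one (the count is
#' reported).
#'
#' @param sensor a \code{sensor_data} (records + physical positions).
#' @param array the [transducer_array()] (geometry bookkeeping).
#' @param c_assumed scalar assumed sound speed (m/s).
#' @param rho_assumed scalar assumed density (kg/m^3).
#' @param recon_grid reconstruction [grid_spec()].
#' @param pml_width absorbing layer width.
#' @return list of class \code{recon_volume}: \code{p0} (reconstructed
#'   volume), \code{grid}, \code{n_sensors}, \code{n_collapsed}.
#' @export
time_reversal <- function(sensor, array = sensor$array, c_assumed = 1480,
                          rho_assumed = 1000, recon_grid = sensor$grid,
                          pml_width = 10) {
  rec <- sensor$records
  if (is.null(rec) || nrow(rec) == 0) stopf("empty sensor set")
  sn <- snap_positions(sensor$positions, recon_grid)
  keep <- !duplicated(sn$lin)
  n_collapsed <- sum(!keep)
  lin <- sn$lin[keep]
  traces <- rec[keep, , drop = FALSE]
  traces <- traces[, rev(seq_len(ncol(traces))), drop = FALSE]
  p0 <- array(0, recon_grid$shape)
  sim <- kspace_sim(p0, c_assumed, rho_assumed, recon_grid$voxel_size,
                    sensor$dt, ncol(traces), lin, pml_width = pml_width,
                    source_traces = traces, record = FALSE)
  structure(list(p0 = sim$p_final, grid = recon_grid,
                 n_sensors = length(lin), n_collapsed = n_collapsed),
            class = "recon_volume")
}

#' Image-domain colored noise by time reversal of iid sensor noise
#'
#' Applies [time_reversal()] to pure iid zero-mean Gaussian sensor noise of
#' standard deviation \code{sigma}; the result is spatially correlated
#' (colored) noise, linear in \code{sigma}.
#'
#' @param array a [transducer_array()].
#' @param recon_grid reconstruction [grid_spec()].
#' @param sigma sensor-noise standard deviation (>= 0).
#' @param c_assumed assumed sound speed.
#' @param seed RNG seed.
#' @param n_samples optional override of the trace length.
#' @return noise volume on \code{recon_grid}.
#' @export
colored_noise_image <- function(array, recon_grid, sigma, c_assumed = 1480,
                                seed = 1L, n_samples = array$n_samples) {
  if (sigma < 0) stopf("sigma must be >= 0")
  if (sigma == 0) return(array(0, recon_grid$shape))
  pos <- array_positions(array, recon_grid)
  traces <- with_seed(seed,
    matrix(rnorm(nrow(pos) * n_samples, 0, sigma), nrow(pos), n_samples))
  sensor <- structure(list(records = traces, dt = 1 / array$sampling_rate,
                           positions = pos, array = array,
                           grid = recon_grid, noise_sigma = sigma),
                      class = "sensor_data")
  tr <- time_reversal(sensor, array, c_assumed, 1000, recon_grid)
  tr$p0
}

#' Study-1 network input: ground-truth pressure plus colored noise
#'
#' @param p0_multiwavelength named list of per-wavelength p0 volumes.
#' @param noise_volumes matching list of colored-noise volumes.
#' @return list of per-wavelength input volumes (elementwise sums).
#' @export
study1_input <- function(p0_multiwavelength, noise_volumes) {
  stopifnot(is.list(p0_multiwavelength), is.list(noise_volumes),
            length(p0_multiwavelength) == length(noise_volumes))
  mapply(function(p, n) {
    if (!identical(dim(p), dim(n))) stopf("p0/noise shape mismatch")
    p + n
  }, p0_multiwavelength, noise_volumes, SIMPLIFY = FALSE)
}
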