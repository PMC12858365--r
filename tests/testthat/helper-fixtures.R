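# Shared fixtures: all test data are generated in code at run time.

# small phantom configuration used across tests (fast to generate)
tiny_config <- function(...) {
  phantom_config(grid = grid_spec(c(32, 32, 32), 0.7),
                 breast_radius_mm = 9,
                 tumor_viable_volume_mm3 = 18, ...)
}

# desk-scale study phantom (vessels span several voxels)
desk_config <- function(...) {
  phantom_config(grid = grid_spec(c(48, 48, 48), 0.5),
                 breast_radius_mm = 10,
                 tumor_viable_volume_mm3 = 27, ...)
}

# homogeneous optical maps for Monte Carlo physics tests
uniform_optics <- function(sh, mua, mus, g = 0, wl = "800") {
  list(mua = setNames(list(array(mua, sh)), wl),
       mus = setNames(list(array(mus, sh)), wl),
       g = array(g, sh), n = array(1.4, sh))
}

# synthetic multiwavelength pressure volumes from concentrations under a
# flat unit fluence (exact single-voxel forward model)
flat_fluence_pressure <- function(so2, thb, spectra = chromophore_spectra(),
                                  wavelengths = c(757, 800, 850)) {
  E <- extinction_matrix(spectra, wavelengths)
  n <- length(so2)
  side <- ceiling(n^(1 / 3))
  sh <- c(side, side, side)
  pad <- prod(sh) - n
  P <- cbind(thb * so2, thb * (1 - so2)) %*% t(E)
  vols <- lapply(seq_along(wavelengths), function(j)
    array(c(P[, j], rep(0, pad)), sh))
  names(vols) <- wavelengths
  list(vols = vols, sh = sh, n = n,
       mask = array(c(rep(TRUE, n), rep(FALSE, pad)), sh))
}

# 2D disc initial pressure + matching ring array for acoustic tests
disc_setup <- function(n = 128, h = 0.5, radius = 8, n_elements = 128) {
  g <- grid_spec(c(n, n), h)
  ax <- (seq_len(n) - 0.5) * h
  c0 <- n * h / 2
  p0 <- (outer((ax - c0)^2, (ax - c0)^2, "+") <= radius^2) * 1.0
  arr <- transducer_array("ring2d", n_elements = n_elements,
                          radius_mm = n * h * 0.39,
                          sampling_rate = 1 / (0.285 * h * 1e-3 / 1480),
                          n_samples = 320)
  list(grid = g, p0 = p0, arr = arr, ax = ax, center = c0)
}
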