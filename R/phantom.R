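#' Tissue label codes
#'
#' Integer codes used in phantom label volumes. Water (the acoustic
#' coupling bath) is the complement of the breast + skin region; arteries,
#' veins and viable tumor together form the ground-truth target mask.
#'
#' @return named integer vector.
#' @export
label_codes <- function() {
  c(water = 0L, epidermis = 1L, dermis = 2L, fat = 3L, fibroglandular = 4L,
    artery = 5L, vein = 6L, tumor_viable = 7L, tumor_necrotic = 8L,
    tumor_angiogenesis = 9L)
}

#' Phantom generator configuration
#'
#' Desk-scale defaults: a 64^3 grid of 0.5 mm voxels holding a 13 mm-radius
#' hemispherical breast in a water bath. The chest-wall plane is the z = 0
#' face; the hemisphere apex points into +z. Epidermis pigmentation follows
#' the Fitzpatrick 1-6 melanosome ranges in the packaged constants table.
#' When the configured epidermis is thinner than one voxel it is rasterized
#' as a single voxel shell and the melanosome volume fraction is scaled by
#' epidermis_mm / voxel_size so the areal melanin content is preserved.
#'
#' @param grid a [grid_spec()].
#' @param breast_radius_mm outer hemisphere radius (skin included), mm.
#' @param epidermis_mm,dermis_mm skin layer thicknesses, mm.
#' @param density_type BI-RADS density "A".."D" (fibroglandular fraction
#'   0.07/0.25/0.50/0.75).
#' @param skin_tone Fitzpatrick tone 1..6.
#' @param tumor_location "none", "middle" or "posterior".
#' @param tumor_viable_volume_mm3 target viable-region volume; the default
#'   59.5 mm^3 equals 3808 voxels at 0.25 mm resolution.
#' @param tumor_necrotic_frac necrotic core radius relative to the viable
#'   radius; \code{tumor_angio_mm} angiogenesis shell thickness (mm);
#'   \code{tumor_spiculation} relative amplitude of the procedural
#'   spiculation noise.
#' @param posterior_depth_mm tumor-center height above the chest wall for
#'   "posterior" placement.
#' @param vessels list of stochastic branching parameters (roots per tree,
#'   root/minimum radii in mm, step length, branching probability, child
#'   radius ratio, direction jitter, segment budget).
#' @param fibro_corr_mm correlation length of the fibroglandular texture.
#' @param blood_thb_mM whole-blood total heme concentration (mM); voxel
#'   thb = blood_vf * blood_thb_mM.
#' @param wavelengths excitation wavelengths (nm).
#' @return list of class \code{phantom_config}.
#' @export
phantom_config <- function(grid = grid_spec(c(64, 64, 64), 0.5),
                           breast_radius_mm = 13,
                           epidermis_mm = 0.15, dermis_mm = 1.35,
                           density_type = "B", skin_tone = 1,
                           tumor_location = "none",
                           tumor_viable_volume_mm3 = 59.5,
                           tumor_necrotic_frac = 0.45,
                           tumor_angio_mm = 1.0,
                           tumor_spiculation = 0.10,
                           posterior_depth_mm = 4,
                           vessels = list(),
                           fibro_corr_mm = 5,
                           blood_thb_mM = 2.33,
                           wavelengths = c(757, 800, 850)) {
  vdef <- list(n_roots = 2L, root_radius_mm = 1.2, min_radius_mm = 0.6,
               step_mm = NULL, branch_prob = 0.5, radius_ratio = 0.79,
               jitter_sd = 0.35, max_segments = NULL)
  vdef[names(vessels)] <- vessels
  # step length and tree budget scale with the breast so vascular density
  # stays roughly size-invariant (a few percent volume fraction)
  if (is.null(vdef$step_mm)) vdef$step_mm <- 0.25 * breast_radius_mm
  if (is.null(vdef$max_segments))
    vdef$max_segments <- max(8L, round(15 * (breast_radius_mm / 10)^3))
  stopifnot(inherits(grid, "grid_spec"))
  if (!density_type %in% c("A", "B", "C", "D"))
    stopf("density_type must be one of A-D")
  if (!skin_tone %in% 1:6) stopf("skin_tone must be 1..6")
  if (!tumor_location %in% c("none", "middle", "posterior"))
    stopf("tumor_location must be none/middle/posterior")
  structure(list(grid = grid, breast_radius_mm = breast_radius_mm,
                 epidermis_mm = epidermis_mm, dermis_mm = dermis_mm,
                 density_type = density_type, skin_tone = skin_tone,
                 tumor_location = tumor_location,
                 tumor_viable_volume_mm3 = tumor_viable_volume_mm3,
                 tumor_necrotic_frac = tumor_necrotic_frac,
                 tumor_angio_mm = tumor_angio_mm,
                 tumor_spiculation = tumor_spiculation,
                 posterior_depth_mm = posterior_depth_mm,
                 vessels = vdef, fibro_corr_mm = fibro_corr_mm,
                 blood_thb_mM = blood_thb_mM, wavelengths = wavelengths),
            class = "phantom_config")
}

fibro_fraction <- function(density_type)
  c(A = 0.07, B = 0.25, C = 0.50, D = 0.75)[[density_type]]

# Smooth zero-mean unit-variance noise field on the grid shape.
smooth_noise_field <- function(shape, sigma_vox) {
  x <- array(rnorm(prod(shape)), dim = shape)
  x <- array(gauss_blur3_cpp(as.numeric(x), as.integer(shape), sigma_vox),
             dim = shape)
  (x - mean(x)) / max(sd(x), 1e-12)
}

# ---- stochastic vessel trees -------------------------------------------------

grow_vessel_tree <- function(root_pos, root_dir, vcfg, center, interior_radius) {
  segs <- list()
  queue <- list(list(p = root_pos, d = root_dir / sqrt(sum(root_dir^2)),
                     r = vcfg$root_radius_mm))
  while (length(queue) > 0 && length(segs) < vcfg$max_segments) {
    nd <- queue[[1]]; queue <- queue[-1]
    len <- runif(1, 0.6, 1.0) * vcfg$step_mm
    d <- nd$d + rnorm(3, 0, vcfg$jitter_sd)
    d <- d / sqrt(sum(d^2))
    end <- nd$p + d * len
    # steer back toward the interior when the tip would leave the breast
    rel <- end - center
    rr <- sqrt(sum(rel^2))
    if (rr > interior_radius - nd$r || end[3] < nd$r) {
      d <- d - 1.6 * rel / max(rr, 1e-9)
      d[3] <- abs(d[3]) * 0.5 + d[3] * 0.5
      d <- d / sqrt(sum(d^2))
      end <- nd$p + d * len
      rel <- end - center; rr <- sqrt(sum(rel^2))
      if (rr > interior_radius - nd$r || end[3] < 0) next
    }
    segs[[length(segs) + 1L]] <- list(a = nd$p, b = end, r = nd$r)
    rc <- nd$r * vcfg$radius_ratio
    if (rc >= vcfg$min_radius_mm && runif(1) < vcfg$branch_prob) {
      for (k in 1:2) {
        dd <- d + rnorm(3, 0, 2.2 * vcfg$jitter_sd)
        queue[[length(queue) + 1L]] <- list(p = end, d = dd / sqrt(sum(dd^2)),
                                            r = rc)
      }
    } else {
      rs <- nd$r * 0.97
      if (rs >= vcfg$min_radius_mm)
        queue[[length(queue) + 1L]] <- list(p = end, d = d, r = rs)
    }
  }
  segs
}

# Mark a logical volume with capsules (tubes) for a list of segments.
rasterize_tubes <- function(mask, segs, grid) {
  h <- grid$voxel_size; sh <- grid$shape
  ax <- voxel_centers(grid)
  for (s in segs) {
    L <- sqrt(sum((s$b - s$a)^2))
    npt <- max(2L, ceiling(L / (h / 2)))
    ts <- seq(0, 1, length.out = npt)
    rv <- s$r
    for (k in seq_len(npt)) {
      p <- s$a + ts[k] * (s$b - s$a)
      i0 <- pmax(1L, floor((p - rv) / h - 0.5) + 1L)
      i1 <- pmin(sh, ceiling((p + rv) / h + 0.5))
      if (any(i0 > i1)) next
      dx2 <- (ax[[1]][i0[1]:i1[1]] - p[1])^2
      dy2 <- (ax[[2]][i0[2]:i1[2]] - p[2])^2
      dz2 <- (ax[[3]][i0[3]:i1[3]] - p[3])^2
      ball <- outer(outer(dx2, dy2, "+"), dz2, "+") <= rv^2
      cur <- mask[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3], drop = FALSE]
      mask[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- cur | ball
    }
  }
  mask
}

# ---- phantom assembly --------------------------------------------------------

#' Generate a stochastic numerical breast phantom
#'
#' Builds a hemispherical breast in a water bath with an epidermis/dermis
#' shell, fibroglandular/fat interior texture matched to the BI-RADS
#' density type, independently grown stochastic artery and vein trees
#' (arteries assigned high sO2, veins lower), an optional tumor (viable rim
#' with procedural spiculation, necrotic core, angiogenesis shell), and
#' voxelwise functional, optical and acoustic property maps.
#'
#' Identical (config, seed) pairs give bit-identical phantoms.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed controlling all randomness.
#' @return object of class \code{qpact_phantom}: list with \code{grid},
#'   \code{labels} (integer volume, see [label_codes()]), \code{functional}
#'   (so2, blood_vf, water_vf, fat_vf, melanosome_vf, thb volumes),
#'   \code{optical} (per-wavelength mua/mus lists, g, n), \code{acoustic}
#'   (c, rho, alpha0, y) and \code{metadata}.
#' @export
make_breast_phantom <- function(config = phantom_config(), seed = 1L) {
  grid <- config$grid
  h <- grid$voxel_size
  ext <- grid_extent(grid)
  Rb <- config$breast_radius_mm
  center <- c(ext[1] / 2, ext[2] / 2, 0)
  margin <- 2 * h
  if (Rb + margin > min(ext[1] / 2, ext[2] / 2) || Rb + margin > ext[3])
    stopf(paste("grid too small: breast radius %.3g mm + %.3g mm margin does",
                "not fit the %s mm domain"), Rb, margin,
          paste(format(ext), collapse = " x "))

  with_seed(seed, {
    sh <- grid$shape
    ax <- voxel_centers(grid)
    rx2 <- (ax[[1]] - center[1])^2
    ry2 <- (ax[[2]] - center[2])^2
    rz2 <- (ax[[3]] - center[3])^2
    r <- sqrt(outer(outer(rx2, ry2, "+"), rz2, "+"))

    lc <- label_codes()
    labels <- array(lc[["water"]], dim = sh)
    t_epi <- max(config$epidermis_mm, h)
    t_derm <- config$dermis_mm
    breast <- r <= Rb
    labels[breast] <- lc[["fat"]]
    labels[breast & r > Rb - t_epi] <- lc[["epidermis"]]
    labels[breast & r <= Rb - t_epi & r > Rb - t_epi - t_derm] <- lc[["dermis"]]
    interior <- breast & r <= Rb - t_epi - t_derm

    # fibroglandular texture: smooth field with a central bias, thresholded
    # at the quantile that realizes the density-type fraction
    field <- smooth_noise_field(sh, config$fibro_corr_mm / h)
    rho_lat <- sqrt(outer(outer(rx2, ry2, "+"), rz2 * 0, "+")) / Rb
    field <- field + 0.8 * (1 - 2 * rho_lat)
    ffrac <- fibro_fraction(config$density_type)
    thr <- quantile(field[interior], 1 - ffrac, names = FALSE)
    labels[interior & field > thr] <- lc[["fibroglandular"]]

    # vessel trees: arteries and veins as independent stochastic trees
    vcfg <- config$vessels
    interior_radius <- Rb - t_epi - t_derm - 0.5
    amask <- array(FALSE, sh); vmask <- array(FALSE, sh)
    for (tree in seq_len(vcfg$n_roots)) {
      th <- runif(1, 0, 2 * pi); rr0 <- runif(1, 0.15, 0.45) * Rb
      root <- center + c(rr0 * cos(th), rr0 * sin(th), 1)
      segs <- grow_vessel_tree(root, c(0.2 * rnorm(2), 1), vcfg, center,
                               interior_radius)
      amask <- rasterize_tubes(amask, segs, grid)
    }
    for (tree in seq_len(vcfg$n_roots)) {
      th <- runif(1, 0, 2 * pi); rr0 <- runif(1, 0.15, 0.45) * Rb
      root <- center + c(rr0 * cos(th), rr0 * sin(th), 1)
      segs <- grow_vessel_tree(root, c(0.2 * rnorm(2), 1), vcfg, center,
                               interior_radius)
      vmask <- rasterize_tubes(vmask, segs, grid)
    }
    amask <- amask & interior
    vmask <- vmask & interior & !amask
    labels[amask] <- lc[["artery"]]
    labels[vmask] <- lc[["vein"]]

    ph <- structure(list(grid = grid, labels = labels,
                         functional = NULL, optical = NULL, acoustic = NULL,
                         metadata = list(density_type = config$density_type,
                                         skin_tone = config$skin_tone,
                                         tumor_location = "none",
                                         seed = seed),
                         config = config),
                    class = "qpact_phantom")
    ph <- assign_functional_maps(ph, derive_seed(seed, 1L, salt = 11L))
    if (config$tumor_location != "none")
      ph <- insert_tumor(ph, config$tumor_location,
                         derive_seed(seed, 2L, salt = 13L))
    ph <- finalize_property_maps(ph)
    ph
  })
}

# Draw per-structure functional values and fill the functional volumes.
assign_functional_maps <- function(ph, seed) {
  with_seed(seed, {
    lc <- label_codes()
    ftab <- functional_table()
    sh <- dim(ph$labels)
    maps <- list(so2 = array(0, sh), blood_vf = array(0, sh),
                 water_vf = array(0, sh), fat_vf = array(0, sh),
                 melanosome_vf = array(0, sh))
    for (i in seq_len(nrow(ftab))) {
      lab <- ftab$label[i]
      sel <- ph$labels == lc[[lab]]
      if (!any(sel)) next
      so2 <- if (ftab$so2_hi[i] > ftab$so2_lo[i])
        runif(1, ftab$so2_lo[i], ftab$so2_hi[i]) else ftab$so2_lo[i]
      maps$so2[sel] <- so2
      maps$blood_vf[sel] <- ftab$blood_vf[i]
      maps$water_vf[sel] <- ftab$water_vf[i]
      maps$fat_vf[sel] <- ftab$fat_vf[i]
    }
    # epidermal pigmentation by Fitzpatrick tone; melanosome volume fraction
    # rescaled when the rasterized epidermis is thicker than configured
    tt <- skin_tone_table()
    row <- tt[tt$tone == ph$metadata$skin_tone, ]
    mel <- runif(1, row$mel_lo, row$mel_hi)
    t_epi_cfg <- ph$config$epidermis_mm
    t_epi_eff <- max(t_epi_cfg, ph$grid$voxel_size)
    epi <- ph$labels == lc[["epidermis"]]
    maps$melanosome_vf[epi] <- mel * t_epi_cfg / t_epi_eff
    maps$thb <- maps$blood_vf * ph$config$blood_thb_mM
    ph$functional <- maps
    ph
  })
}

# Recompute optical and acoustic maps from labels + functional maps.
finalize_property_maps <- function(ph) {
  sp <- chromophore_spectra()
  ph$optical <- assign_optical_properties(ph$labels, ph$functional, sp,
                                          ph$config$wavelengths)
  ph$acoustic <- assign_acoustic_properties(ph$labels)
  ph
}

#' Voxelwise optical property maps from chromophore composition
#'
#' The absorption coefficient is the chromophore sum
#' \code{mua = thb*so2*eps_HbO2 + thb*(1-so2)*eps_Hb + water_vf*eps_water +
#' fat_vf*eps_fat + melanosome_vf*eps_melanin}, evaluated per voxel and
#' wavelength. Scattering, anisotropy and refractive index are assigned per
#' tissue label from the packaged literature-informed table.
#'
#' @param labels integer label volume ([label_codes()]).
#' @param functional list of functional volumes (so2, water_vf, fat_vf,
#'   melanosome_vf, thb).
#' @param spectra a [chromophore_spectra()] table.
#' @param wavelengths wavelengths (nm); each chromophore spectrum must
#'   cover all of them.
#' @param tissue per-label property table (default packaged).
#' @return list with per-wavelength \code{mua} and \code{mus} volumes
#'   (mm^-1, named by wavelength) and label-based \code{g}, \code{n}
#'   volumes.
#' @export
assign_optical_properties <- function(labels, functional, spectra,
                                      wavelengths = c(757, 800, 850),
                                      tissue = tissue_table()) {
  lc <- label_codes()
  eps <- lapply(c("HbO2", "Hb", "water", "fat", "melanin"), function(ch)
    get_epsilon(spectra, ch, wavelengths))
  names(eps) <- c("HbO2", "Hb", "water", "fat", "melanin")
  f <- functional
  sh <- dim(labels)
  mua <- mus <- setNames(vector("list", length(wavelengths)),
                         as.character(wavelengths))
  g <- array(0.9, sh); n <- array(1.33, sh)
  lab_of <- match(labels, lc[tissue$label])  # row index per voxel
  if (anyNA(lab_of)) stopf("label volume contains codes absent from tissue table")
  g[] <- tissue$g[lab_of]
  n[] <- tissue$n[lab_of]
  for (j in seq_along(wavelengths)) {
    wl <- wavelengths[j]
    mua[[j]] <- f$thb * f$so2 * eps$HbO2[j] +
      f$thb * (1 - f$so2) * eps$Hb[j] +
      f$water_vf * eps$water[j] +
      f$fat_vf * eps$fat[j] +
      f$melanosome_vf * eps$melanin[j]
    musp <- tissue$musp800[lab_of] * (wl / 800)^(-tissue$bmie[lab_of])
    mus[[j]] <- array(musp / (1 - tissue$g[lab_of]), sh)
  }
  list(mua = mua, mus = mus, g = g, n = n)
}

# Per-label acoustic maps (sound speed m/s, density kg/m^3, attenuation
# dB MHz^-y cm^-1, power-law exponent).
assign_acoustic_properties <- function(labels, tissue = tissue_table()) {
  lc <- label_codes()
  sh <- dim(labels)
  lab_of <- match(labels, lc[tissue$label])
  list(c = array(tissue$c[lab_of], sh),
       rho = array(tissue$rho[lab_of], sh),
       alpha0 = array(tissue$alpha0[lab_of], sh),
       y = array(tissue$ypow[lab_of], sh))
}

# ---- tumors ------------------------------------------------------------------

insert_tumor <- function(ph, location, seed) {
  with_seed(seed, {
    cfg <- ph$config
    grid <- ph$grid; h <- grid$voxel_size
    ext <- grid_extent(grid)
    Rb <- cfg$breast_radius_mm
    center <- c(ext[1] / 2, ext[2] / 2, 0)
    r0 <- (3 * cfg$tumor_viable_volume_mm3 / (4 * pi))^(1 / 3)
    # fit check uses the spiculated viable bound; the angiogenesis shell is
    # restricted to soft tissue and may be clipped at region boundaries
    outer_r <- r0 * (1 + 2 * cfg$tumor_spiculation)
    skin <- max(cfg$epidermis_mm, h) + cfg$dermis_mm
    zc <- if (location == "middle") 0.4 * Rb else cfg$posterior_depth_mm
    lc0 <- label_codes()
    vessel_vol <- ph$labels == lc0[["artery"]] | ph$labels == lc0[["vein"]]
    ax0 <- voxel_centers(grid)
    # lateral placement keeping the whole tumor inside the breast interior,
    # preferring sites with minimal overlap with existing vessels
    best <- NULL; best_frac <- Inf
    for (try in 1:50) {
      th <- runif(1, 0, 2 * pi)
      rad <- runif(1, 0, 0.3 * Rb)
      tc <- center + c(rad * cos(th), rad * sin(th), zc)
      if (sqrt(sum((tc - center)^2)) + outer_r > Rb - skin - h ||
          tc[3] - outer_r * 0.4 < 0) next
      rchk <- outer_r + 2 * h  # spiculated bound plus two-voxel clearance
      j0 <- pmax(1L, floor((tc - rchk) / h))
      j1 <- pmin(grid$shape, ceiling((tc + rchk) / h))
      rr <- sqrt(outer(outer((ax0[[1]][j0[1]:j1[1]] - tc[1])^2,
                             (ax0[[2]][j0[2]:j1[2]] - tc[2])^2, "+"),
                       (ax0[[3]][j0[3]:j1[3]] - tc[3])^2)) <= rchk
      vfrac <- sum(vessel_vol[j0[1]:j1[1], j0[2]:j1[2], j0[3]:j1[3]][rr]) /
        max(sum(rr), 1)
      if (vfrac < best_frac) { best <- tc; best_frac <- vfrac }
      if (vfrac == 0) break
    }
    if (is.null(best))
      stopf("tumor at location '%s' does not fit inside the breast", location)
    tc <- best

    lc <- label_codes()
    sh <- grid$shape
    ax <- voxel_centers(grid)
    half <- outer_r + cfg$tumor_angio_mm + 2 * h
    i0 <- pmax(1L, floor((tc - half) / h))
    i1 <- pmin(sh, ceiling((tc + half) / h))
    xs <- ax[[1]][i0[1]:i1[1]]; ys <- ax[[2]][i0[2]:i1[2]]
    zs <- ax[[3]][i0[3]:i1[3]]
    bsh <- c(length(xs), length(ys), length(zs))
    rho <- sqrt(outer(outer((xs - tc[1])^2, (ys - tc[2])^2, "+"),
                      (zs - tc[3])^2, "+")) / r0
    xi <- smooth_noise_field(bsh, 1 / h)
    xi <- pmax(pmin(xi, 2), -2)
    rim <- 1 + cfg$tumor_spiculation * xi
    sub <- ph$labels[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3], drop = FALSE]
    # the growing mass displaces vasculature in its clearance zone: vessel
    # voxels within the spiculated bound plus a two-voxel margin revert to
    # fat before tumor tissue is written
    clear <- rho * r0 <= outer_r + 2 * h
    displaced <- clear & array(sub %in% c(lc[["artery"]], lc[["vein"]]), bsh)
    sub[displaced] <- lc[["fat"]]
    if (any(displaced)) {
      idx_disp <- which(displaced)
      fat_sel <- ph$labels == lc[["fat"]]
      for (nm in c("so2", "blood_vf", "water_vf", "fat_vf")) {
        fat_val <- if (any(fat_sel)) ph$functional[[nm]][fat_sel][1] else 0
        blk <- ph$functional[[nm]][i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]]
        blk[idx_disp] <- fat_val
        ph$functional[[nm]][i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- blk
      }
    }
    soft <- sub %in% c(lc[["fat"]], lc[["fibroglandular"]])
    soft <- array(soft, bsh)
    viable <- rho <= rim & soft
    necro <- rho <= cfg$tumor_necrotic_frac & soft
    angio <- rho > rim & rho <= rim + cfg$tumor_angio_mm / r0 & soft
    sub[viable] <- lc[["tumor_viable"]]
    sub[necro] <- lc[["tumor_necrotic"]]
    sub[angio] <- lc[["tumor_angiogenesis"]]
    ph$labels[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- sub

    # functional values for the new tissue (elevated blood volume in the
    # viable rim and angiogenesis shell)
    ftab <- functional_table()
    for (lab in c("tumor_viable", "tumor_necrotic", "tumor_angiogenesis")) {
      row <- ftab[ftab$label == lab, ]
      sel <- ph$labels == lc[[lab]]
      so2 <- runif(1, row$so2_lo, row$so2_hi)
      ph$functional$so2[sel] <- so2
      ph$functional$blood_vf[sel] <- row$blood_vf
      ph$functional$water_vf[sel] <- row$water_vf
      ph$functional$fat_vf[sel] <- row$fat_vf
      ph$functional$melanosome_vf[sel] <- 0
    }
    ph$functional$thb <- ph$functional$blood_vf * cfg$blood_thb_mM
    ph$metadata$tumor_location <- location
    ph$metadata$tumor_vessel_overlap <- best_frac
    ph$metadata$tumor_center_mm <- tc
    ph$metadata$tumor_viable_radius_mm <- r0
    ph
  })
}

#' Insert a tumor into a tumor-free phantom
#'
#' Returns a phantom identical to \code{base} outside the inserted tumor
#' region: the pair shares breast anatomy and differs only in tumor
#' presence. The tumor has a spiculated viable rim, a necrotic core
#' strictly inside it, and an angiogenesis shell; blood volume fraction is
#' elevated in the viable and angiogenesis subregions.
#'
#' @param base a \code{qpact_phantom} with \code{tumor_location == "none"}.
#' @param tumor_location "middle" or "posterior".
#' @param seed optional; defaults to a seed derived from the base phantom's.
#' @return a new \code{qpact_phantom}.
#' @export
paired_phantom <- function(base, tumor_location, seed = NULL) {
  stopifnot(inherits(base, "qpact_phantom"))
  if (base$metadata$tumor_location != "none")
    stopf("base phantom already contains a tumor")
  if (!tumor_location %in% c("middle", "posterior"))
    stopf("tumor_location must be middle or posterior")
  seed <- seed %||% derive_seed(base$metadata$seed, 2L, salt = 13L)
  ph <- insert_tumor(base, tumor_location, seed)
  finalize_property_maps(ph)
}

#' Sample a phantom cohort with a BI-RADS density distribution
#'
#' Density types are allocated to match the requested proportions as
#' closely as integer counts allow (largest-remainder rounding); per-
#' phantom seeds are derived deterministically from the master seed.
#'
#' @param n number of phantoms (> 0).
#' @param density_distribution proportions for types A, B, C, D (sum 1).
#' @param seed master seed.
#' @param config base [phantom_config()]; the density type is overridden
#'   per phantom.
#' @return list of \code{qpact_phantom}.
#' @export
sample_cohort <- function(n, density_distribution = c(0.1, 0.4, 0.4, 0.1),
                          seed = 1L, config = phantom_config()) {
  if (n <= 0) stopf("n must be positive")
  p <- density_distribution
  if (abs(sum(p) - 1) > 1e-8) stopf("density proportions must sum to 1")
  counts <- cohort_counts(n, p)
  types <- rep(c("A", "B", "C", "D"), counts)
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$density_type <- types[i]
    make_breast_phantom(cfg, seed = derive_seed(seed, i))
  })
}

# Largest-remainder allocation of n items to proportions p.
cohort_counts <- function(n, p) {
  raw <- n * p
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

#' @export
print.qpact_phantom <- function(x, ...) {
  lc <- label_codes()
  tab <- table(factor(x$labels, levels = lc, labels = names(lc)))
  cat(sprintf("qpact_phantom: %s voxels @ %.3g mm, density %s, tone %d, tumor %s, seed %s\n",
              paste(x$grid$shape, collapse = "x"), x$grid$voxel_size,
              x$metadata$density_type, x$metadata$skin_tone,
              x$metadata$tumor_location, x$metadata$seed))
  print(tab[tab > 0])
  invisible(x)
}

# Ground-truth target mask: arteries, veins and viable tumor.
target_mask <- function(ph) {
  lc <- label_codes()
  ph$labels == lc[["artery"]] | ph$labels == lc[["vein"]] |
    ph$labels == lc[["tumor_viable"]]
}

breast_mask <- function(ph) ph$labels != label_codes()[["water"]]
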