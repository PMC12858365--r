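# Phantom generator: type invariants, determinism, pairing, optical
# property assignment against a brute-force oracle.

ph_cache <- new.env()
get_phantom <- function() {
  if (is.null(ph_cache$ph))
    ph_cache$ph <- make_breast_phantom(tiny_config(tumor_location = "middle"),
                                       seed = 7)
  ph_cache$ph
}

test_that("generated phantom satisfies the type invariants", {
  ph <- get_phantom()
  lc <- label_codes()
  # all tumor subregions and both vessel types are populated
  for (lab in c("artery", "vein", "tumor_viable", "tumor_necrotic",
                "tumor_angiogenesis"))
    expect_gt(sum(ph$labels == lc[[lab]]), 0)
  f <- ph$functional
  expect_true(all(f$so2 >= 0 & f$so2 <= 1))
  expect_true(all(f$blood_vf + f$water_vf + f$fat_vf + f$melanosome_vf <= 1 + 1e-12))
  expect_true(all(f$thb >= 0))
  # arteries strictly more oxygenated than veins
  expect_gt(min(f$so2[ph$labels == lc[["artery"]]]),
            max(f$so2[ph$labels == lc[["vein"]]]))
  # melanin confined to the epidermis
  expect_true(all(f$melanosome_vf[ph$labels != lc[["epidermis"]]] == 0))
  expect_gt(max(f$melanosome_vf[ph$labels == lc[["epidermis"]]]), 0)
  # water complement and acoustic water values
  w <- ph$labels == lc[["water"]]
  expect_true(all(ph$acoustic$c[w] == 1480))
  expect_true(all(ph$acoustic$rho[w] == 1000))
  expect_true(all(ph$optical$mua[["800"]] >= 0))
  expect_true(all(ph$optical$mus[["757"]] >= 0))
  expect_true(all(ph$optical$g > -1 & ph$optical$g < 1))
  expect_true(all(ph$optical$n >= 1))
})

test_that("identical (config, seed) pairs give identical phantoms", {
  cfg <- tiny_config(tumor_location = "middle")
  a <- make_breast_phantom(cfg, seed = 7)
  b <- make_breast_phantom(cfg, seed = 7)
  expect_identical(a$labels, b$labels)
  expect_identical(a$functional, b$functional)
  expect_identical(a$optical, b$optical)
  c1 <- make_breast_phantom(cfg, seed = 8)
  expect_false(identical(a$labels, c1$labels))
})

test_that("tumor_location none yields no tumor voxels; grid too small rejected", {
  ph <- make_breast_phantom(tiny_config(), seed = 3)
  lc <- label_codes()
  expect_equal(sum(ph$labels %in% lc[c("tumor_viable", "tumor_necrotic",
                                       "tumor_angiogenesis")]), 0)
  expect_error(make_breast_phantom(
    phantom_config(grid = grid_spec(c(16, 16, 16), 0.5),
                   breast_radius_mm = 9), seed = 1),
    "too small")
})

test_that("paired phantom differs only in the tumor neighborhood", {
  base <- make_breast_phantom(desk_config(), seed = 21)
  tum <- paired_phantom(base, "middle")
  lc <- label_codes()
  diff <- base$labels != tum$labels
  expect_gt(sum(diff), 0)
  # changed voxels lie within the insertion neighborhood of the center
  tc <- tum$metadata$tumor_center_mm
  h <- tum$grid$voxel_size
  ax <- lapply(tum$grid$shape, function(n) (seq_len(n) - 0.5) * h)
  r <- sqrt(outer(outer((ax[[1]] - tc[1])^2, (ax[[2]] - tc[2])^2, "+"),
                  (ax[[3]] - tc[3])^2, "+"))
  rmax <- max(r[diff])
  r0 <- tum$metadata$tumor_viable_radius_mm
  expect_lt(rmax, r0 * 1.4 + tum$config$tumor_angio_mm + 3 * h)
  # all maps equal outside the changed region
  expect_equal(base$functional$so2[!diff], tum$functional$so2[!diff])
  expect_equal(base$optical$mua[["850"]][!diff], tum$optical$mua[["850"]][!diff])
  expect_equal(base$acoustic$c[!diff], tum$acoustic$c[!diff])
  # necrotic core strictly inside the viable region (morphology)
  necro <- tum$labels == lc[["tumor_necrotic"]]
  grown <- necro
  for (k in 1:2) grown <- qpactsim:::dilate_ball1(grown)
  expect_true(all(tum$labels[grown & !necro] %in%
                    lc[c("tumor_viable", "artery", "vein")]))
  # elevated blood volume in viable rim relative to surrounding fat
  expect_gt(mean(tum$functional$blood_vf[tum$labels == lc[["tumor_viable"]]]),
            mean(tum$functional$blood_vf[tum$labels == lc[["fat"]]]))
  expect_error(paired_phantom(tum, "middle"), "already contains")
})

test_that("optical assignment reproduces the chromophore sum exactly", {
  sp <- chromophore_spectra()
  set.seed(42)
  n <- 1000
  sh <- c(10, 10, 10)
  f <- list(so2 = array(runif(n), sh), blood_vf = array(runif(n, 0, 0.5), sh),
            water_vf = array(runif(n, 0, 0.4), sh),
            fat_vf = array(runif(n, 0, 0.1), sh),
            melanosome_vf = array(0, sh))
  f$thb <- f$blood_vf * 2.33
  labels <- array(label_codes()[["fat"]], sh)
  opt <- assign_optical_properties(labels, f, sp)
  # brute-force per-voxel scalar oracle
  for (wl in c(757, 800, 850)) {
    idx <- sample(n, 50)
    expected <- vapply(idx, function(i) {
      f$thb[i] * f$so2[i] * get_epsilon(sp, "HbO2", wl) +
        f$thb[i] * (1 - f$so2[i]) * get_epsilon(sp, "Hb", wl) +
        f$water_vf[i] * get_epsilon(sp, "water", wl) +
        f$fat_vf[i] * get_epsilon(sp, "fat", wl) +
        f$melanosome_vf[i] * get_epsilon(sp, "melanin", wl)
    }, 0)
    expect_equal(opt$mua[[as.character(wl)]][idx], expected, tolerance = 1e-12)
  }
  # single-chromophore limits
  f0 <- lapply(f, function(x) x * 0)
  f0$water_vf <- array(1, sh)
  opt0 <- assign_optical_properties(labels, f0, sp)
  expect_equal(opt0$mua[["800"]][1], get_epsilon(sp, "water", 800))
  # missing wavelength errors name chromophore and wavelength
  expect_error(assign_optical_properties(labels, f, sp, wavelengths = 900),
               "900")
})

test_that("cohort sampling matches density proportions and is reproducible", {
  expect_equal(qpactsim:::cohort_counts(10, c(0.1, 0.4, 0.4, 0.1)),
               c(1L, 4L, 4L, 1L))
  expect_equal(qpactsim:::cohort_counts(4, rep(0.25, 4)), rep(1L, 4))
  expect_equal(qpactsim:::cohort_counts(64, rep(0.25, 4)), rep(16L, 4))
  expect_error(sample_cohort(0), "positive")
  expect_error(sample_cohort(4, c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
  co <- sample_cohort(4, rep(0.25, 4), seed = 2, config = tiny_config())
  expect_equal(vapply(co, function(p) p$metadata$density_type, ""),
               c("A", "B", "C", "D"))
  co2 <- sample_cohort(4, rep(0.25, 4), seed = 2, config = tiny_config())
  expect_identical(lapply(co, `[[`, "labels"), lapply(co2, `[[`, "labels"))
})

test_that("phantom volumes satisfy invariants across random seeds", {
  lc <- label_codes()
  for (seed in c(101, 202, 303, 404, 505)) {
    ph <- make_breast_phantom(tiny_config(), seed = seed)
    f <- ph$functional
    expect_true(all(f$so2 >= 0 & f$so2 <= 1))
    expect_true(all(f$blood_vf + f$water_vf + f$fat_vf + f$melanosome_vf <= 1 + 1e-12))
    expect_gt(sum(ph$labels == lc[["artery"]]), 0)
    expect_gt(sum(ph$labels == lc[["vein"]]), 0)
    expect_gt(min(f$so2[ph$labels == lc[["artery"]]]),
              max(f$so2[ph$labels == lc[["vein"]]]))
    # epidermis forms a closed shell on the curved surface: breast-boundary
    # voxels adjacent to water are epidermis (chest-wall face excluded --
    # the hemisphere is open there by construction)
    bm <- ph$labels != lc[["water"]]
    boundary <- bm & !qpactsim:::erode_ball1(bm)
    boundary[, , 1] <- FALSE
    expect_true(mean(ph$labels[boundary] == lc[["epidermis"]]) > 0.95)
  }
})
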