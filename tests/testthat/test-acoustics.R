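# Acoustic forward model, noise rule, time reversal and colored noise.
# Heavier quantitative benchmarks (travel time, disc reconstruction,
# matched-vs-mismatched) run in the acceptance suite.

test_that("induced pressure is the Grueneisen-scaled product", {
  set.seed(1)
  mua <- array(runif(4^3), c(4, 4, 4))
  phi <- array(runif(4^3), c(4, 4, 4))
  expect_equal(induced_pressure(mua, phi), mua * phi)
  expect_equal(induced_pressure(mua * 0, phi), mua * 0)
  expect_equal(induced_pressure(mua, phi, gamma = 2),
               2 * induced_pressure(mua, phi, gamma = 1))
  # brute-force elementwise oracle
  p <- induced_pressure(mua, phi, gamma = 1.3)
  for (i in sample(64, 10)) expect_equal(p[i], 1.3 * mua[i] * phi[i])
  expect_error(induced_pressure(mua, array(1, c(3, 3, 3))), "differ")
  # multiwavelength list form
  pl <- induced_pressure(list(a = mua, b = mua), list(a = phi, b = phi))
  expect_equal(pl$b, mua * phi)
})

test_that("transducer geometry: positions on the arc, views rotate about z", {
  g <- grid_spec(c(48, 48, 48), 0.5)
  arr <- transducer_array("arc3d", n_elements = 8, radius_mm = 10,
                          n_views = 6)
  pos <- array_positions(arr, g)
  expect_equal(nrow(pos), 48)
  center <- c(12, 12, 0)
  expect_equal(sqrt(rowSums(sweep(pos, 2, center)^2)), rep(10, 48),
               tolerance = 1e-9)
  expect_equal(length(unique(attr(pos, "view"))), 6)
  # 2D ring
  arr2 <- transducer_array("ring2d", n_elements = 16, radius_mm = 10)
  g2 <- grid_spec(c(64, 64), 0.5)
  pos2 <- array_positions(arr2, g2)
  expect_equal(sqrt(rowSums(sweep(pos2, 2, c(16, 16))^2)), rep(10, 16),
               tolerance = 1e-9)
})

test_that("zero initial pressure gives identically zero sensor records", {
  d <- disc_setup(n = 64, n_elements = 16)
  sd0 <- simulate_acoustics(d$p0 * 0, list(c = 1480, rho = 1000,
                                           alpha0 = 0, y = 1),
                            d$arr, d$grid)
  expect_true(all(sd0$records == 0))
})

test_that("CFL violations are rejected before stepping", {
  d <- disc_setup(n = 64, n_elements = 8)
  arr_bad <- d$arr
  arr_bad$sampling_rate <- arr_bad$sampling_rate / 3  # dt tripled
  expect_error(simulate_acoustics(d$p0, list(c = 1480, rho = 1000,
                                             alpha0 = 0, y = 1),
                                  arr_bad, d$grid), "CFL")
})

test_that("forward simulation is linear in the initial pressure", {
  d <- disc_setup(n = 64, n_elements = 8)
  ac <- list(c = 1480, rho = 1000, alpha0 = 0, y = 1)
  set.seed(2)
  a <- d$p0
  b <- array(0, dim(a)); b[20:26, 30:38] <- runif(63)
  ra <- simulate_acoustics(a, ac, d$arr, d$grid)$records
  rb <- simulate_acoustics(b, ac, d$arr, d$grid)$records
  rab <- simulate_acoustics(2 * a + 3 * b, ac, d$arr, d$grid)$records
  expect_equal(rab, 2 * ra + 3 * rb, tolerance = 1e-8)
})

test_that("sensor noise follows the 1% ensemble-max rule exactly", {
  mk <- function(peak) structure(list(records = matrix(c(peak, -1, 0.5, 0), 2),
                                      dt = 1e-7), class = "sensor_data")
  # two phantoms; per-phantom max over wavelengths: 10 and 6 -> mean 8
  ens <- list(list("757" = mk(10), "850" = mk(4)),
              list("757" = mk(6), "850" = mk(2)))
  out <- add_sensor_noise(ens, fraction = 0.01, seed = 1)
  expect_equal(out[[1]][[1]]$noise_sigma, 0.01 * 8)
  # fraction 0 leaves records untouched
  out0 <- add_sensor_noise(ens, fraction = 0, seed = 1)
  expect_identical(out0[[1]][["757"]]$records, ens[[1]][["757"]]$records)
  expect_error(add_sensor_noise(ens, fraction = -0.1), ">= 0")
  # empirical std within 3 standard errors over many samples
  big <- list(list("800" = structure(list(records = matrix(100, 1, 1),
                                          dt = 1e-7), class = "sensor_data"),
              "850" = structure(list(records = matrix(0, 250, 400),
                                     dt = 1e-7), class = "sensor_data")))
  outb <- add_sensor_noise(big, fraction = 0.01, seed = 9)
  sig <- outb[[1]][["850"]]$noise_sigma
  expect_equal(sig, 1)
  n <- length(outb[[1]][["850"]]$records)
  expect_lt(abs(sd(outb[[1]][["850"]]$records) - sig), 3 * sig / sqrt(2 * n))
})

test_that("time reversal: empty sensors rejected, zero traces give zero image", {
  d <- disc_setup(n = 64, n_elements = 16)
  ac <- list(c = 1480, rho = 1000, alpha0 = 0, y = 1)
  sd1 <- simulate_acoustics(d$p0, ac, d$arr, d$grid)
  sd1$records[] <- 0
  tr <- time_reversal(sd1, d$arr, 1480, 1000, d$grid)
  expect_true(all(tr$p0 == 0))
  sd1$records <- sd1$records[0, , drop = FALSE]
  expect_error(time_reversal(sd1, d$arr, 1480, 1000, d$grid), "empty")
})

test_that("grid mismatch collapses duplicate snapped transducers and logs it", {
  # fine-grid positions snapped onto a coarser grid must collapse
  g_fine <- grid_spec(c(64, 64), 0.25)
  g_coarse <- grid_spec(c(26, 26), 0.25 * 64 / 26)
  arr <- transducer_array("ring2d", n_elements = 96, radius_mm = 7,
                          sampling_rate = 1 / (0.285 * 0.25e-3 / 1480),
                          n_samples = 40)
  pos <- array_positions(arr, g_fine)
  sensor <- structure(list(records = matrix(0, 96, 40),
                           dt = 1 / arr$sampling_rate, positions = pos,
                           array = arr, grid = g_fine),
                      class = "sensor_data")
  tr <- time_reversal(sensor, arr, 1480, 1000, g_coarse)
  expect_gt(tr$n_collapsed, 0)
  expect_equal(tr$n_sensors + tr$n_collapsed, 96)
})

test_that("study1 inputs are elementwise sums with matching arity", {
  p0 <- list("757" = array(1, c(4, 4, 4)), "800" = array(2, c(4, 4, 4)),
             "850" = array(3, c(4, 4, 4)))
  nz <- lapply(p0, function(p) array(rnorm(64), dim(p)))
  inp <- study1_input(p0, nz)
  expect_equal(length(inp), 3)
  expect_equal(inp[["850"]], p0[["850"]] + nz[["850"]])
  # additivity: subtracting p0 recovers the noise exactly
  expect_equal(inp[["757"]] - p0[["757"]], nz[["757"]])
  # zero noise is the identity
  expect_equal(study1_input(p0, lapply(nz, function(x) x * 0)), p0)
  bad <- nz; bad[[1]] <- array(0, c(3, 3, 3))
  expect_error(study1_input(p0, bad), "mismatch")
})

test_that("colored noise is zero for sigma 0 and exactly linear in sigma", {
  g <- grid_spec(c(24, 24, 24), 0.7)
  arr <- qpactsim:::desk_array(g, 7, 12, 6)
  expect_true(all(colored_noise_image(arr, g, 0) == 0))
  n1 <- colored_noise_image(arr, g, 1, seed = 3, n_samples = 60)
  n2 <- colored_noise_image(arr, g, 2.5, seed = 3, n_samples = 60)
  expect_equal(n2, 2.5 * n1, tolerance = 1e-12)
  expect_error(colored_noise_image(arr, g, -1), ">= 0")
})
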