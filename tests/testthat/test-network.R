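# Dual-task network: architecture contracts, backprop correctness against
# finite differences, loss oracle, augmentation geometry, shell mask.

test_that("forward pass emits two (0,1)-valued volumes of the input shape", {
  sh <- c(8, 8, 8)
  net <- build_network(network_config(levels = 2, base_channels = 3), seed = 5)
  X <- matrix(rnorm(prod(sh) * 3), prod(sh), 3)
  fw <- qpactsim:::net_forward(net, X, sh)
  expect_length(fw$so2, prod(sh))
  expect_length(fw$seg_prob, prod(sh))
  expect_true(all(fw$so2 > 0 & fw$so2 < 1))
  expect_true(all(fw$seg_prob > 0 & fw$seg_prob < 1))
  # indivisible input dims rejected with a padding message
  expect_error(qpactsim:::net_forward(net, matrix(0, 9 * 9 * 9, 3), c(9, 9, 9)),
               "divisible")
})

test_that("builds are seeded and attention ablation changes the output", {
  cfg <- network_config(levels = 2, base_channels = 4)
  a <- build_network(cfg, seed = 3)
  b <- build_network(cfg, seed = 3)
  expect_identical(a$params, b$params)
  expect_equal(n_parameters(a), n_parameters(b))
  sh <- c(8, 8, 8)
  X <- matrix(rnorm(prod(sh) * 3), prod(sh), 3)
  with_att <- qpactsim:::net_forward(a, X, sh)
  noatt <- build_network(network_config(levels = 2, base_channels = 4,
                                        attention = FALSE), seed = 3)
  without <- qpactsim:::net_forward(noatt, X, sh)
  expect_false(isTRUE(all.equal(with_att$so2, without$so2)))
})

test_that("backpropagation matches finite differences", {
  set.seed(3)
  sh <- c(8, 8, 8)
  net <- build_network(network_config(levels = 2, base_channels = 3), seed = 5)
  X <- matrix(rnorm(prod(sh) * 3), prod(sh), 3)
  truth <- list(so2 = runif(prod(sh)), seg = rbinom(prod(sh), 1, 0.3))
  lcfg <- loss_config(eta = 0.7)
  loss_of <- function(n) {
    f <- qpactsim:::net_forward(n, X, sh)
    composite_loss(list(so2 = f$so2, seg_prob = f$seg_prob), truth, lcfg)$total
  }
  fw <- qpactsim:::net_forward(net, X, sh)
  gr <- qpactsim:::composite_loss_grad(
    list(so2 = fw$so2, seg_prob = fw$seg_prob), truth, lcfg)
  G <- qpactsim:::net_backward(net, fw, gr$dso2, gr$dseg, sh)
  eps <- 1e-5
  for (nm in sample(names(net$params), 10)) {
    i <- sample(length(net$params[[nm]]), 1)
    up <- net; up$params[[nm]][i] <- up$params[[nm]][i] + eps
    dn <- net; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
    num <- (loss_of(up) - loss_of(dn)) / (2 * eps)
    expect_equal(G[[nm]][i], num, tolerance = 1e-4,
                 label = sprintf("analytic grad of %s", nm))
  }
})

test_that("composite loss matches an elementwise oracle and its limits", {
  set.seed(9)
  n <- 500
  pred <- list(so2 = runif(n, 0.01, 0.99), seg_prob = runif(n, 0.01, 0.99))
  truth <- list(so2 = runif(n), seg = rbinom(n, 1, 0.4))
  lcfg <- loss_config(eta = 0.8, w_target = 10, dice_smooth = 1)
  lo <- composite_loss(pred, truth, lcfg)
  # independently coded elementwise oracle
  w <- ifelse(truth$seg == 1, 10, 1)
  reg_o <- sum(w * (pred$so2 - truth$so2)^2) / sum(w)
  bce_o <- -sum(w * (truth$seg * log(pred$seg_prob) +
                       (1 - truth$seg) * log(1 - pred$seg_prob))) / sum(w)
  dice_o <- 1 - (2 * sum(pred$seg_prob * truth$seg) + 1) /
    (sum(pred$seg_prob) + sum(truth$seg) + 1)
  expect_equal(lo$reg, reg_o, tolerance = 1e-6)
  expect_equal(lo$seg, bce_o + dice_o, tolerance = 1e-6)
  expect_equal(lo$total, reg_o + 0.8 * (bce_o + dice_o), tolerance = 1e-6)
  # eta = 0 reduces the total to the regression term
  expect_equal(composite_loss(pred, truth, lcfg, eta = 0)$total, lo$reg)
  # monotone non-decreasing in eta when the segmentation term is positive
  expect_gt(composite_loss(pred, truth, lcfg, eta = 1.5)$total, lo$total)
  # perfect predictions reach the analytic floors
  perfect <- list(so2 = truth$so2,
                  seg_prob = pmin(pmax(truth$seg, 1e-7), 1 - 1e-7))
  lp <- composite_loss(perfect, truth, lcfg)
  expect_equal(lp$reg, 0)
  expect_lt(lp$bce, 1e-5)
  expect_lt(lp$dice, 1 / (sum(truth$seg)))  # smoothing-governed bound
  expect_true(all(c(lo$reg, lo$bce, lo$dice) >= 0))
  expect_error(composite_loss(pred, list(so2 = truth$so2,
                                         seg = truth$seg + 0.5), lcfg),
               "binary")
})

test_that("curriculum ramps eta and a constant schedule is the identity", {
  lcfg <- loss_config(eta = 2, curriculum = "ramp", ramp_frac = 0.2)
  etas <- sapply(1:10, function(e) qpactsim:::curriculum_eta(lcfg, e, 10))
  expect_equal(etas[1], 1)      # ramp reaches eta/ramp_epochs at epoch 1
  expect_equal(etas[2], 2)
  expect_true(all(diff(etas) >= 0))
  expect_equal(etas[10], 2)
  const <- loss_config(eta = 2, curriculum = "constant")
  expect_equal(sapply(1:10, function(e)
    qpactsim:::curriculum_eta(const, e, 10)), rep(2, 10))
})

test_that("z-rotation augmentation: identities and approximate inversion", {
  set.seed(11)
  sh <- c(24, 24, 8)
  vol <- array(0, sh)
  vol[8:12, 14:18, ] <- 1
  smooth <- array(gauss_blur3_cpp(as.numeric(vol), as.integer(sh), 2), sh)
  s <- list(inputs = list(a = smooth), so2 = smooth, seg = vol)
  expect_identical(augment_rotation(s, k = 0)$so2, s$so2)
  expect_identical(augment_rotation(s, k = 20)$so2, s$so2)
  k <- 7
  r1 <- augment_rotation(s, k = k)
  r2 <- augment_rotation(r1, k = 20 - k)
  inner <- array(FALSE, sh); inner[6:19, 6:19, ] <- TRUE
  expect_lt(max(abs(r2$so2[inner] - s$so2[inner])), 0.12)
  expect_true(all(r2$seg %in% c(0, 1)))
  expect_gt(dice(r2$seg, s$seg), 0.8)
  # seeded draw of k is deterministic and in range
  a1 <- augment_rotation(s, seed = 4)
  a2 <- augment_rotation(s, seed = 4)
  expect_equal(a1$k, a2$k)
  expect_true(a1$k %in% 0:19)
})

test_that("shell mask and depth map match a brute-force distance oracle", {
  sh <- c(20, 20, 20)
  h <- 0.8
  ax <- (seq_len(20) - 0.5) * h
  bm <- sqrt(outer(outer((ax - 8)^2, (ax - 8)^2, "+"), ax^2, "+")) <= 6
  d <- depth_map(bm, h)
  # brute force: distance to nearest water voxel center
  water_idx <- which(!bm, arr.ind = TRUE)
  tis_idx <- which(bm, arr.ind = TRUE)
  pick <- tis_idx[sample(nrow(tis_idx), 25), , drop = FALSE]
  for (r in seq_len(nrow(pick))) {
    dd <- sqrt(colSums((t(water_idx) - pick[r, ])^2)) * h
    expect_equal(d[pick[r, , drop = FALSE]], min(dd), tolerance = 1e-9)
  }
  shl <- shell_mask(bm, depth_mm = 3, voxel_mm = h)
  expect_true(all(d[shl] <= 3))
  expect_true(all(!shl[bm & d > 3]))
  # surface voxels included, deep voxels excluded at the default depth
  surf <- bm & !qpactsim:::erode_ball1(bm)
  expect_true(all(shell_mask(bm, depth_mm = 15, voxel_mm = h)[surf]))
  expect_error(shell_mask(bm & FALSE, depth_mm = 3, voxel_mm = h), "empty")
})

test_that("prediction thresholds strictly above 0.5 and respects the shell", {
  sh <- c(8, 8, 8)
  net <- build_network(network_config(levels = 2, base_channels = 3), seed = 1)
  vols <- list("757" = array(0.5, sh), "800" = array(0.2, sh),
               "850" = array(0.1, sh))
  shell <- array(FALSE, sh); shell[1:4, , ] <- TRUE
  est <- predict_qpact(net, vols, shell)
  expect_s3_class(est, "qpact_estimate")
  expect_true(all(!est$seg_mask[!shell]))
  expect_true(all(est$seg_mask == (est$seg_prob > 0.5 & shell)))
  # explicit boundary check on the thresholding rule used
  expect_identical((c(0.5, 0.5 + 1e-9) > 0.5), c(FALSE, TRUE))
})

test_that("training is seeded, resumable in form, and rejects empty data", {
  sh <- c(8, 8, 8)
  mk <- function() array(runif(prod(sh)), sh)
  seg <- array(0, sh); seg[3:6, 3:6, 3:6] <- 1
  s <- list(inputs = list("757" = mk(), "800" = mk(), "850" = mk()),
            so2 = array(0.5, sh), seg = seg)
  net <- build_network(network_config(levels = 2, base_channels = 3), seed = 2)
  t1 <- train_qpact(net, list(s), training_config(epochs = 3, lr = 1e-3,
                                                  seed = 5), loss_config())
  t2 <- train_qpact(net, list(s), training_config(epochs = 3, lr = 1e-3,
                                                  seed = 5), loss_config())
  expect_equal(t1$history, t2$history)
  expect_equal(nrow(t1$history), 3)
  # resuming from a trained model continues the optimizer state
  t3 <- train_qpact(t1$model, list(s), training_config(epochs = 1, lr = 1e-3,
                                                       seed = 6), loss_config())
  expect_equal(t3$model$opt$t, t1$model$opt$t + 1)
  expect_error(train_qpact(net, list(), training_config()), "empty")
})
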