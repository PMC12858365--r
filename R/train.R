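#' Loss configuration for the composite objective
#'
#' The total loss is \code{L_total = L_reg + eta * L_seg}: a voxel-weighted
#' mean squared error on the sO2 map plus a segmentation term combining
#' voxel-weighted binary cross-entropy and a smoothed Dice loss. Voxel
#' weights emphasize the target structures: weight \code{w_target} on
#' artery/vein/viable-tumor voxels and 1 elsewhere, for both the
#' regression and cross-entropy terms. The curriculum ramps \code{eta}
#' linearly from 0 to its final value over the first \code{ramp_frac} of
#' the epochs ("constant" disables the ramp).
#'
#' @param eta segmentation weight (>= 0).
#' @param w_target voxel weight on target-structure voxels.
#' @param dice_smooth Dice smoothing constant (> 0).
#' @param curriculum "ramp" or "constant".
#' @param ramp_frac fraction of epochs over which eta ramps.
#' @return list of class \code{loss_config}.
#' @export
loss_config <- function(eta = 1, w_target = 10, dice_smooth = 1,
                        curriculum = c("ramp", "constant"),
                        ramp_frac = 0.2) {
  if (eta < 0) stopf("eta must be >= 0")
  if (dice_smooth <= 0) stopf("dice_smooth must be > 0")
  structure(list(eta = eta, w_target = w_target, dice_smooth = dice_smooth,
                 curriculum = match.arg(curriculum), ramp_frac = ramp_frac),
            class = "loss_config")
}

curriculum_eta <- function(lcfg, epoch, n_epochs) {
  if (lcfg$curriculum == "constant") return(lcfg$eta)
  ramp_epochs <- max(1, ceiling(lcfg$ramp_frac * n_epochs))
  lcfg$eta * min(1, epoch / ramp_epochs)
}

#' Composite loss: weighted MSE + eta * (weighted BCE + smoothed Dice loss)
#'
#' @param pred list with \code{so2} and \code{seg_prob} (volumes or
#'   vectors, values in (0,1)).
#' @param truth list with \code{so2} and binary \code{seg}.
#' @param lcfg a [loss_config()]; \code{eta} may be overridden via
#'   \code{eta}.
#' @param eta optional eta override (used by the curriculum).
#' @return list with \code{total}, \code{reg}, \code{seg}, \code{bce},
#'   \code{dice} components.
#' @export
composite_loss <- function(pred, truth, lcfg = loss_config(), eta = NULL) {
  eta <- eta %||% lcfg$eta
  p_so2 <- as.numeric(pred$so2)
  p_seg <- as.numeric(pred$seg_prob)
  t_so2 <- as.numeric(truth$so2)
  t_seg <- as.numeric(truth$seg)
  if (!all(t_seg %in% c(0, 1))) stopf("truth segmentation must be binary")
  w <- 1 + (lcfg$w_target - 1) * t_seg
  reg <- sum(w * (p_so2 - t_so2)^2) / sum(w)
  eps <- 1e-7
  pc <- pmin(pmax(p_seg, eps), 1 - eps)
  bce <- sum(w * -(t_seg * log(pc) + (1 - t_seg) * log(1 - pc))) / sum(w)
  s <- lcfg$dice_smooth
  dice_loss <- 1 - (2 * sum(p_seg * t_seg) + s) / (sum(p_seg) + sum(t_seg) + s)
  seg <- bce + dice_loss
  list(total = reg + eta * seg, reg = reg, seg = seg, bce = bce,
       dice = dice_loss)
}

# Gradients of the composite loss w.r.t. the post-sigmoid outputs.
composite_loss_grad <- function(pred, truth, lcfg, eta = NULL) {
  eta <- eta %||% lcfg$eta
  p_so2 <- as.numeric(pred$so2)
  p_seg <- as.numeric(pred$seg_prob)
  t_so2 <- as.numeric(truth$so2)
  t_seg <- as.numeric(truth$seg)
  w <- 1 + (lcfg$w_target - 1) * t_seg
  dreg <- 2 * w * (p_so2 - t_so2) / sum(w)
  eps <- 1e-7
  pc <- pmin(pmax(p_seg, eps), 1 - eps)
  dbce <- w * (-t_seg / pc + (1 - t_seg) / (1 - pc)) / sum(w)
  s <- lcfg$dice_smooth
  num <- 2 * sum(p_seg * t_seg) + s
  den <- sum(p_seg) + sum(t_seg) + s
  ddice <- -(2 * t_seg * den - num) / den^2
  list(dso2 = dreg, dseg = eta * (dbce + ddice))
}

#' Rotation augmentation about the illumination symmetry axis
#'
#' Rotates a training sample about the z axis by an integer multiple of
#' 18 degrees (the angular spacing of the 20-arc illumination geometry).
#' Continuous maps use bilinear interpolation in-plane; binary masks use
#' nearest-neighbor and stay binary. k = 0 and k = 20 are the identity.
#'
#' @param sample list with \code{inputs} (list of volumes), \code{so2},
#'   \code{seg}.
#' @param k integer rotation count (0..19); drawn uniformly when NULL.
#' @param seed seed for drawing k.
#' @return the rotated sample (element \code{k} records the draw).
#' @export
augment_rotation <- function(sample, k = NULL, seed = NULL) {
  if (is.null(k)) k <- with_seed(seed, sample.int(20, 1) - 1L)
  k <- as.integer(k) %% 20L
  if (k == 0L) { sample$k <- 0L; return(sample) }
  ang <- k * 18 * pi / 180
  sample$inputs <- lapply(sample$inputs, rotate_volume_z, ang, "linear")
  sample$so2 <- rotate_volume_z(sample$so2, ang, "linear")
  sample$seg <- rotate_volume_z(sample$seg, ang, "nearest")
  sample$k <- k
  sample
}

# Rotate every z-slice of a volume by `ang` about the volume center.
rotate_volume_z <- function(vol, ang, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  sh <- dim(vol)
  n1 <- sh[1]; n2 <- sh[2]
  cx <- (n1 + 1) / 2; cy <- (n2 + 1) / 2
  xg <- rep(seq_len(n1), times = n2) - cx
  yg <- rep(seq_len(n2), each = n1) - cy
  # inverse rotation of target coordinates
  xs <- cos(ang) * xg + sin(ang) * yg + cx
  ys <- -sin(ang) * xg + cos(ang) * yg + cy
  vm <- matrix(vol, n1 * n2, if (length(sh) == 3) sh[3] else 1)
  gather <- function(ix, iy) {
    ok <- ix >= 1 & ix <= n1 & iy >= 1 & iy <= n2
    lin <- pmin(pmax(ix, 1), n1) + (pmin(pmax(iy, 1), n2) - 1) * n1
    out <- vm[lin, , drop = FALSE]
    out[!ok, ] <- 0
    out
  }
  if (interp == "nearest") {
    out <- gather(round(xs), round(ys))
  } else {
    x0 <- floor(xs); y0 <- floor(ys)
    fx <- xs - x0; fy <- ys - y0
    out <- gather(x0, y0) * ((1 - fx) * (1 - fy)) +
      gather(x0 + 1, y0) * (fx * (1 - fy)) +
      gather(x0, y0 + 1) * ((1 - fx) * fy) +
      gather(x0 + 1, y0 + 1) * (fx * fy)
  }
  array(out, sh)
}

#' Training configuration
#'
#' @param epochs training epochs.
#' @param batch_size samples per optimization step.
#' @param lr ADAM step size (the full-scale reference value is 1e-5;
#'   toy-scale runs typically use a larger step).
#' @param seed RNG seed (shuffling, augmentation).
#' @param augment apply the 18-degree z-rotation augmentation.
#' @return list of class \code{training_config}.
#' @export
training_config <- function(epochs = 10, batch_size = 2, lr = 1e-5,
                            seed = 1L, augment = TRUE) {
  if (lr <= 0) stopf("step size must be > 0")
  structure(list(epochs = epochs, batch_size = batch_size, lr = lr,
                 seed = seed, augment = augment),
            class = "training_config")
}

adam_step <- function(net, G, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.null(net$opt))
    net$opt <- list(t = 0, m = lapply(net$params, function(p) p * 0),
                    v = lapply(net$params, function(p) p * 0))
  net$opt$t <- net$opt$t + 1
  t <- net$opt$t
  for (nm in names(net$params)) {
    g <- G[[nm]]
    net$opt$m[[nm]] <- b1 * net$opt$m[[nm]] + (1 - b1) * g
    net$opt$v[[nm]] <- b2 * net$opt$v[[nm]] + (1 - b2) * g^2
    mhat <- net$opt$m[[nm]] / (1 - b1^t)
    vhat <- net$opt$v[[nm]] / (1 - b2^t)
    net$params[[nm]] <- net$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  net
}

#' Train the dual-task network (toy scale)
#'
#' Seeded, resumable mini-batch training with ADAM, optional 18-degree
#' rotation augmentation, and the eta curriculum from the loss config.
#' Input normalization (per-channel division by the mean training maximum)
#' is computed on the first call and stored on the model.
#'
#' @param model a \code{qpact_net} from [build_network()].
#' @param dataset list of samples, each a list with \code{inputs} (named
#'   per-wavelength volumes), \code{so2} truth and binary \code{seg} truth.
#' @param tcfg a [training_config()].
#' @param lcfg a [loss_config()].
#' @return list with the trained \code{model} and a \code{history}
#'   data.frame of per-epoch component losses.
#' @export
train_qpact <- function(model, dataset, tcfg = training_config(),
                        lcfg = loss_config()) {
  if (length(dataset) == 0) stopf("empty dataset")
  sh <- dim(dataset[[1]]$inputs[[1]])
  if (is.null(model$norm)) {
    mx <- sapply(dataset, function(s)
      vapply(s$inputs, function(v) max(abs(v)), 0))
    model$norm <- pmax(rowMeans(matrix(mx, nrow = length(dataset[[1]]$inputs))),
                       .Machine$double.eps)
  }
  hist <- NULL
  with_seed(tcfg$seed, {
    for (epoch in seq_len(tcfg$epochs)) {
      eta <- curriculum_eta(lcfg, epoch, tcfg$epochs)
      ord <- sample(length(dataset))
      comp <- c(total = 0, reg = 0, seg = 0)
      nsteps <- 0
      for (i0 in seq(1, length(ord), by = tcfg$batch_size)) {
        ids <- ord[i0:min(i0 + tcfg$batch_size - 1, length(ord))]
        Gacc <- NULL
        lsum <- c(total = 0, reg = 0, seg = 0)
        for (id in ids) {
          s <- dataset[[id]]
          if (tcfg$augment) s <- augment_rotation(s, k = sample.int(20, 1) - 1L)
          X <- stack_inputs(model, s$inputs)
          fw <- net_forward(model, X, sh)
          pred <- list(so2 = fw$so2, seg_prob = fw$seg_prob)
          truth <- list(so2 = s$so2, seg = s$seg)
          lo <- composite_loss(pred, truth, lcfg, eta = eta)
          if (!is.finite(lo$total))
            stopf("NaN/Inf loss at epoch %d (reg=%.4g seg=%.4g)",
                  epoch, lo$reg, lo$seg)
          gr <- composite_loss_grad(pred, truth, lcfg, eta = eta)
          G <- net_backward(model, fw, gr$dso2, gr$dseg, sh)
          Gacc <- if (is.null(Gacc)) G else
            mapply(`+`, Gacc, G, SIMPLIFY = FALSE)
          lsum <- lsum + c(lo$total, lo$reg, lo$seg)
        }
        Gacc <- lapply(Gacc, function(g) g / length(ids))
        model <- adam_step(model, Gacc, tcfg$lr)
        comp <- comp + lsum / length(ids)
        nsteps <- nsteps + 1
      }
      hist <- rbind(hist, data.frame(epoch = epoch, eta = eta,
                                     total = comp[["total"]] / nsteps,
                                     reg = comp[["reg"]] / nsteps,
                                     seg = comp[["seg"]] / nsteps))
    }
  })
  list(model = model, history = hist)
}
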