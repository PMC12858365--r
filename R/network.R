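# Dual-task 3D residual encoder-decoder, implemented directly in R.
# Feature maps are stored as (n_voxels x channels) matrices with the spatial
# shape carried separately; 3x3x3 convolutions are evaluated as im2col
# matrix products (BLAS), and every layer has an explicit adjoint so the
# whole network is trainable by backpropagation without an external
# framework. Gradients are verified against finite differences in the test
# suite.

# ---- layer primitives -------------------------------------------------------

conv3_fw <- function(X, sh, W, b)
  conv3_fw_cpp(X, as.integer(sh), W, b)

conv3_bw <- function(dY, X, sh, W)
  list(dX = conv3_bwx_cpp(dY, as.integer(sh), W, ncol(X)),
       dW = conv3_bww_cpp(X, dY, as.integer(sh)),
       db = colSums(dY))

conv1_fw <- function(X, W, b) sweep(X %*% W, 2, b, "+")
conv1_bw <- function(dY, X, W)
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))

lrelu_fw <- function(X, a) { neg <- X < 0; X[neg] <- a * X[neg]; X }
lrelu_bw <- function(dY, X, a) { neg <- X < 0; dY[neg] <- a * dY[neg]; dY }

sigmoid <- function(x) 1 / (1 + exp(-x))

maxpool_fw <- function(X, sh) {
  C <- ncol(X)
  n1 <- sh[1]; n2 <- sh[2]; n3 <- sh[3]
  if (any(sh %% 2 != 0)) stopf("maxpool needs even spatial dims")
  Xa <- array(X, c(n1, n2, n3, C))
  so <- sh %/% 2
  m <- NULL; idx <- NULL
  k <- 0L
  for (oz in 0:1) for (oy in 0:1) for (ox in 0:1) {
    k <- k + 1L
    sub <- Xa[seq(1 + ox, n1, 2), seq(1 + oy, n2, 2), seq(1 + oz, n3, 2), ,
              drop = FALSE]
    sub <- matrix(sub, prod(so), C)
    if (is.null(m)) { m <- sub; idx <- matrix(1L, prod(so), C) }
    else { better <- sub > m; m[better] <- sub[better]; idx[better] <- k }
  }
  list(Y = m, idx = idx, sh_out = so)
}

maxpool_bw <- function(dY, idx, sh, C) {
  n1 <- sh[1]; n2 <- sh[2]; n3 <- sh[3]
  so <- sh %/% 2
  dXa <- array(0, c(n1, n2, n3, C))
  k <- 0L
  for (oz in 0:1) for (oy in 0:1) for (ox in 0:1) {
    k <- k + 1L
    sel <- idx == k
    blk <- array(dY * sel, c(so, C))
    dXa[seq(1 + ox, n1, 2), seq(1 + oy, n2, 2), seq(1 + oz, n3, 2), ] <-
      dXa[seq(1 + ox, n1, 2), seq(1 + oy, n2, 2), seq(1 + oz, n3, 2), ,
          drop = FALSE] + blk
  }
  matrix(dXa, n1 * n2 * n3, C)
}

# 2x2x2 stride-2 transposed convolution: one (Cin x Cout) weight per corner.
upconv_fw <- function(X, sh, Wlist, b) {
  C_out <- ncol(Wlist[[1]])
  so <- sh * 2L
  Ya <- array(0, c(so, C_out))
  k <- 0L
  for (oz in 0:1) for (oy in 0:1) for (ox in 0:1) {
    k <- k + 1L
    Ya[seq(1 + ox, so[1], 2), seq(1 + oy, so[2], 2), seq(1 + oz, so[3], 2), ] <-
      array(X %*% Wlist[[k]], c(sh, C_out))
  }
  list(Y = sweep(matrix(Ya, prod(so), C_out), 2, b, "+"), sh_out = so)
}

upconv_bw <- function(dY, X, sh, Wlist) {
  C_out <- ncol(Wlist[[1]])
  so <- sh * 2L
  dYa <- array(dY, c(so, C_out))
  dX <- matrix(0, nrow(X), ncol(X))
  dW <- vector("list", 8)
  k <- 0L
  for (oz in 0:1) for (oy in 0:1) for (ox in 0:1) {
    k <- k + 1L
    blk <- matrix(dYa[seq(1 + ox, so[1], 2), seq(1 + oy, so[2], 2),
                      seq(1 + oz, so[3], 2), , drop = FALSE],
                  prod(sh), C_out)
    dX <- dX + blk %*% t(Wlist[[k]])
    dW[[k]] <- crossprod(X, blk)
  }
  list(dX = dX, dW = dW, db = colSums(dY))
}

# channel squeeze-excitation followed by a single-channel spatial gate
attention_fw <- function(X, Wc, bc, Ws, bs) {
  z <- colMeans(X)
  s <- sigmoid(drop(z %*% Wc) + bc)         # per-channel scale
  Xc <- sweep(X, 2, s, "*")
  mpre <- drop(Xc %*% Ws) + bs              # spatial gate logits
  m <- sigmoid(mpre)
  list(Y = Xc * m, z = z, s = s, Xc = Xc, m = m)
}

attention_bw <- function(dY, X, cache, Wc, Ws) {
  s <- cache$s; m <- cache$m; Xc <- cache$Xc; z <- cache$z
  nv <- nrow(X)
  dXc <- dY * m
  dm <- rowSums(dY * Xc)
  dmpre <- dm * m * (1 - m)
  dWs <- crossprod(Xc, dmpre)
  dbs <- sum(dmpre)
  dXc <- dXc + outer(dmpre, drop(Ws))
  ds <- colSums(dXc * X)
  dspre <- ds * s * (1 - s)
  dWc <- outer(z, dspre)
  dbc <- dspre
  dz <- drop(Wc %*% dspre)
  dX <- sweep(dXc, 2, s, "*") + matrix(dz / nv, nv, length(dz), byrow = TRUE)
  list(dX = dX, dWc = dWc, dbc = dbc, dWs = matrix(dWs, ncol = 1), dbs = dbs)
}

# ---- network assembly -------------------------------------------------------

#' Network configuration for the dual-task estimator
#'
#' Residual encoder with one residual block per level (two 3x3x3
#' convolutions with leaky ReLU, 1x1x1 shortcut), 2x2x2 max pooling
#' between levels, combined channel + spatial attention at the bottleneck,
#' and two mirror-image decoders (2x2x2 stride-2 transposed convolutions,
#' encoder skip concatenation, residual blocks) ending in 1x1x1
#' convolutions with sigmoid activations: one head regresses the sO2
#' volume, the other predicts the target-structure segmentation
#' probability.
#'
#' @param levels encoder levels; input spatial dims must be divisible by
#'   \code{2^(levels-1)}.
#' @param base_channels channels at the first level (doubled per level).
#' @param input_channels input wavelengths (3).
#' @param leaky_slope negative slope of leaky ReLU.
#' @param attention enable the bottleneck attention module.
#' @return list of class \code{network_config}.
#' @export
network_config <- function(levels = 5, base_channels = 16,
                           input_channels = 3, leaky_slope = 0.1,
                           attention = TRUE) {
  structure(list(levels = levels, base_channels = base_channels,
                 input_channels = input_channels, leaky_slope = leaky_slope,
                 attention = attention),
            class = "network_config")
}

he_init <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)

#' Build the dual-task network
#'
#' Parameter initialization is seeded; two builds with the same config and
#' seed are identical.
#'
#' @param config a [network_config()].
#' @param seed initialization seed.
#' @return object of class \code{qpact_net}.
#' @export
build_network <- function(config = network_config(), seed = 1L) {
  L <- config$levels
  B <- config$base_channels
  chans <- B * 2^(seq_len(L) - 1)
  P <- list()
  with_seed(seed, {
    addblock <- function(pf, Cin, Cout) {
      P[[paste0(pf, "_c1_W")]] <<- he_init(27 * Cin, Cout, 27 * Cin)
      P[[paste0(pf, "_c1_b")]] <<- numeric(Cout)
      P[[paste0(pf, "_c2_W")]] <<- he_init(27 * Cout, Cout, 27 * Cout)
      P[[paste0(pf, "_c2_b")]] <<- numeric(Cout)
      P[[paste0(pf, "_sc_W")]] <<- he_init(Cin, Cout, Cin)
      P[[paste0(pf, "_sc_b")]] <<- numeric(Cout)
    }
    Cin <- config$input_channels
    for (l in seq_len(L)) {
      addblock(paste0("enc", l), Cin, chans[l])
      Cin <- chans[l]
    }
    if (config$attention) {
      Cb <- chans[L]
      P[["att_Wc"]] <- he_init(Cb, Cb, Cb)
      P[["att_bc"]] <- numeric(Cb)
      P[["att_Ws"]] <- he_init(Cb, 1, Cb)
      P[["att_bs"]] <- 0
    }
    for (head in c("so2", "seg")) {
      for (l in rev(seq_len(L - 1))) {
        for (k in 1:8)
          P[[paste0(head, "_up", l, "_W", k)]] <-
            he_init(chans[l + 1], chans[l], chans[l + 1])
        P[[paste0(head, "_up", l, "_b")]] <- numeric(chans[l])
        addblock(paste0(head, "_dec", l), 2 * chans[l], chans[l])
      }
      P[[paste0(head, "_out_W")]] <- he_init(chans[1], 1, chans[1])
      P[[paste0(head, "_out_b")]] <- 0
    }
  })
  structure(list(params = P, config = config, norm = NULL, opt = NULL),
            class = "qpact_net")
}

resblock_fw <- function(P, pf, X, sh, a) {
  h1p <- conv3_fw(X, sh, P[[paste0(pf, "_c1_W")]], P[[paste0(pf, "_c1_b")]])
  h1 <- lrelu_fw(h1p, a)
  h2 <- conv3_fw(h1, sh, P[[paste0(pf, "_c2_W")]], P[[paste0(pf, "_c2_b")]])
  sc <- conv1_fw(X, P[[paste0(pf, "_sc_W")]], P[[paste0(pf, "_sc_b")]])
  pre <- h2 + sc
  list(Y = lrelu_fw(pre, a), X = X, h1p = h1p, h1 = h1, pre = pre)
}

resblock_bw <- function(P, G, pf, dY, cache, sh, a) {
  d <- lrelu_bw(dY, cache$pre, a)
  sc <- conv1_bw(d, cache$X, P[[paste0(pf, "_sc_W")]])
  G[[paste0(pf, "_sc_W")]] <- G[[paste0(pf, "_sc_W")]] + sc$dW
  G[[paste0(pf, "_sc_b")]] <- G[[paste0(pf, "_sc_b")]] + sc$db
  c2 <- conv3_bw(d, cache$h1, sh, P[[paste0(pf, "_c2_W")]])
  G[[paste0(pf, "_c2_W")]] <- G[[paste0(pf, "_c2_W")]] + c2$dW
  G[[paste0(pf, "_c2_b")]] <- G[[paste0(pf, "_c2_b")]] + c2$db
  dh1 <- lrelu_bw(c2$dX, cache$h1p, a)
  c1 <- conv3_bw(dh1, cache$X, sh, P[[paste0(pf, "_c1_W")]])
  G[[paste0(pf, "_c1_W")]] <- G[[paste0(pf, "_c1_W")]] + c1$dW
  G[[paste0(pf, "_c1_b")]] <- G[[paste0(pf, "_c1_b")]] + c1$db
  list(G = G, dX = sc$dX + c1$dX)
}

# Forward pass. X: (n_voxels x input_channels) matrix; sh: spatial dims.
net_forward <- function(net, X, sh) {
  cfg <- net$config
  L <- cfg$levels
  a <- cfg$leaky_slope
  if (any(sh %% 2^(L - 1) != 0))
    stopf("input spatial dims %s not divisible by 2^%d; pad the input",
          paste(sh, collapse = "x"), L - 1)
  P <- net$params
  skips <- vector("list", L)
  shs <- vector("list", L)
  caches <- list()
  x <- X; cs <- sh
  for (l in seq_len(L)) {
    cb <- resblock_fw(P, paste0("enc", l), x, cs, a)
    caches[[paste0("enc", l)]] <- cb
    skips[[l]] <- cb$Y; shs[[l]] <- cs
    if (l < L) {
      mp <- maxpool_fw(cb$Y, cs)
      caches[[paste0("pool", l)]] <- mp
      x <- mp$Y; cs <- mp$sh_out
    } else x <- cb$Y
  }
  if (cfg$attention) {
    at <- attention_fw(x, P$att_Wc, P$att_bc, P$att_Ws, P$att_bs)
    caches$att <- c(at, list(Xin = x))
    x <- at$Y
  }
  bottleneck <- x; bsh <- cs
  heads <- list()
  for (head in c("so2", "seg")) {
    x <- bottleneck; cs <- bsh
    for (l in rev(seq_len(L - 1))) {
      Wl <- lapply(1:8, function(k) P[[paste0(head, "_up", l, "_W", k)]])
      up <- upconv_fw(x, cs, Wl, P[[paste0(head, "_up", l, "_b")]])
      caches[[paste0(head, "_up", l)]] <- list(X = x, sh = cs)
      xc <- cbind(skips[[l]], up$Y)
      cs <- up$sh_out
      cb <- resblock_fw(P, paste0(head, "_dec", l), xc, cs, a)
      caches[[paste0(head, "_dec", l)]] <- cb
      x <- cb$Y
    }
    pre <- conv1_fw(x, P[[paste0(head, "_out_W")]], P[[paste0(head, "_out_b")]])
    caches[[paste0(head, "_feat")]] <- x
    caches[[paste0(head, "_pre")]] <- pre
    heads[[head]] <- sigmoid(drop(pre))
  }
  list(so2 = heads$so2, seg_prob = heads$seg, caches = caches,
       skips = skips, shs = shs, bsh = bsh)
}

# Backward pass: dso2/dseg are gradients w.r.t. the post-sigmoid outputs.
net_backward <- function(net, fw, dso2, dseg, sh) {
  cfg <- net$config
  L <- cfg$levels
  a <- cfg$leaky_slope
  P <- net$params
  G <- lapply(P, function(p) if (is.list(p)) lapply(p, function(q) q * 0) else p * 0)
  dskips <- lapply(fw$skips, function(s) s * 0)
  dbottleneck <- NULL
  for (head in c("so2", "seg")) {
    dout <- if (head == "so2") dso2 else dseg
    p <- if (head == "so2") fw$so2 else fw$seg_prob
    dpre <- matrix(dout * p * (1 - p), ncol = 1)
    ob <- conv1_bw(dpre, fw$caches[[paste0(head, "_feat")]],
                   P[[paste0(head, "_out_W")]])
    G[[paste0(head, "_out_W")]] <- G[[paste0(head, "_out_W")]] + ob$dW
    G[[paste0(head, "_out_b")]] <- G[[paste0(head, "_out_b")]] + ob$db
    dx <- ob$dX
    for (l in seq_len(L - 1)) {
      cs <- fw$shs[[l]]
      rb <- resblock_bw(P, G, paste0(head, "_dec", l), dx,
                        fw$caches[[paste0(head, "_dec", l)]], cs, a)
      G <- rb$G
      C1 <- ncol(fw$skips[[l]])
      dskips[[l]] <- dskips[[l]] + rb$dX[, seq_len(C1), drop = FALSE]
      dup <- rb$dX[, C1 + seq_len(ncol(rb$dX) - C1), drop = FALSE]
      uc <- fw$caches[[paste0(head, "_up", l)]]
      Wl <- lapply(1:8, function(k) P[[paste0(head, "_up", l, "_W", k)]])
      ub <- upconv_bw(dup, uc$X, uc$sh, Wl)
      for (k in 1:8)
        G[[paste0(head, "_up", l, "_W", k)]] <-
          G[[paste0(head, "_up", l, "_W", k)]] + ub$dW[[k]]
      G[[paste0(head, "_up", l, "_b")]] <-
        G[[paste0(head, "_up", l, "_b")]] + ub$db
      dx <- ub$dX
    }
    dbottleneck <- if (is.null(dbottleneck)) dx else dbottleneck + dx
  }
  if (cfg$attention) {
    ab <- attention_bw(dbottleneck, fw$caches$att$Xin, fw$caches$att,
                       P$att_Wc, P$att_Ws)
    G$att_Wc <- G$att_Wc + ab$dWc; G$att_bc <- G$att_bc + ab$dbc
    G$att_Ws <- G$att_Ws + ab$dWs; G$att_bs <- G$att_bs + ab$dbs
    dbottleneck <- ab$dX
  }
  dx <- dbottleneck
  for (l in rev(seq_len(L))) {
    if (l < L) {
      mp <- fw$caches[[paste0("pool", l)]]
      dx <- maxpool_bw(dx, mp$idx, fw$shs[[l]], ncol(mp$Y))
    }
    dx <- dx + dskips[[l]]
    rb <- resblock_bw(P, G, paste0("enc", l), dx,
                      fw$caches[[paste0("enc", l)]], fw$shs[[l]], a)
    G <- rb$G
    dx <- rb$dX
  }
  G
}

# Stack per-wavelength input volumes into the (n_voxels x channels) matrix,
# applying the stored normalization.
stack_inputs <- function(net, input_volumes) {
  X <- vapply(input_volumes, as.numeric,
              numeric(length(input_volumes[[1]])))
  if (!is.null(net$norm)) X <- sweep(X, 2, net$norm, "/")
  X
}

#' Predict sO2 and target-structure segmentation
#'
#' Runs the network over the full volume; the binary mask is the
#' segmentation probability thresholded strictly above 0.5 and intersected
#' with the evaluation shell.
#'
#' @param model a trained \code{qpact_net}.
#' @param input_volumes named per-wavelength list of input volumes.
#' @param shell logical shell mask (see [shell_mask()]).
#' @return list of class \code{qpact_estimate}: \code{so2},
#'   \code{seg_prob} volumes in (0,1), binary \code{seg_mask}.
#' @export
predict_qpact <- function(model, input_volumes, shell) {
  sh <- dim(input_volumes[[1]])
  X <- stack_inputs(model, input_volumes)
  fw <- net_forward(model, X, sh)
  so2 <- array(fw$so2, sh)
  segp <- array(fw$seg_prob, sh)
  structure(list(so2 = so2, seg_prob = segp,
                 seg_mask = (segp > 0.5) & shell),
            class = "qpact_estimate")
}

#' Number of trainable parameters
#' @param net a \code{qpact_net}.
#' @return integer count.
#' @export
n_parameters <- function(net) sum(vapply(net$params, length, 0L))
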