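# Post-processing and metric protocol: vessel/tumor separation by
# multiscale vesselness, tumor detection counting, Dice, depth-binned
# vessel sO2 error, tumor sO2 pairs, and superficial-skin exclusion.

# ---- depth and shell ---------------------------------------------------------

#' Depth-from-surface map
#'
#' Euclidean distance (mm) from each tissue voxel to the nearest water
#' voxel (the water-tissue interface), computed with an exact distance
#' transform. Water voxels have depth 0. The same depth definition is used
#' for the segmentation shell, the depth-binned error analysis and the
#' superficial skin exclusion.
#'
#' @param breast_mask logical volume (TRUE = tissue).
#' @param voxel_mm voxel size in mm.
#' @return numeric volume of depths (mm).
#' @export
depth_map <- function(breast_mask, voxel_mm) {
  sh <- dim(breast_mask)
  array(edt3_cpp(as.logical(breast_mask), as.integer(sh)) * voxel_mm, sh)
}

#' Evaluation shell: tissue within a fixed depth of the breast surface
#'
#' Segmentation (and all regional analysis) is restricted to a shell of
#' configurable thickness below the breast surface, because optical
#' attenuation limits recoverable signal at depth. Default 15 mm.
#'
#' @param breast_mask logical tissue mask (nonempty).
#' @param grid a [grid_spec()] (or voxel size via \code{voxel_mm}).
#' @param depth_mm shell thickness (mm).
#' @param voxel_mm voxel size override.
#' @return logical shell mask; the depth map is attached as attribute
#'   \code{depth}.
#' @export
shell_mask <- function(breast_mask, grid = NULL, depth_mm = 15,
                       voxel_mm = grid$voxel_size) {
  if (!any(breast_mask)) stopf("empty breast mask")
  d <- depth_map(breast_mask, voxel_mm)
  out <- breast_mask & d <= depth_mm
  attr(out, "depth") <- d
  out
}

#' Exclude the superficial skin region
#'
#' Removes voxels shallower than \code{exclude_mm} below the outer tissue
#' surface (default 0.6 mm, covering the pigmented epidermis) before
#' evaluating out-of-distribution skin tones. Logical input voxels are set
#' FALSE; numeric input voxels are set NA.
#'
#' @param x logical mask or numeric volume.
#' @param depth depth map from [depth_map()].
#' @param exclude_mm exclusion depth (mm); 0 is the identity.
#' @return filtered object of the same type.
#' @export
skin_exclusion <- function(x, depth, exclude_mm = 0.6) {
  if (exclude_mm <= 0) return(x)
  drop_vox <- depth < exclude_mm
  if (is.logical(x)) x[drop_vox] <- FALSE else x[drop_vox] <- NA_real_
  x
}

# ---- morphology and components ----------------------------------------------

shift3 <- function(a, off) {
  sh <- dim(a)
  out <- array(FALSE, sh)
  src <- dst <- vector("list", 3)
  for (j in 1:3) {
    o <- off[j]
    if (o >= 0) { src[[j]] <- seq_len(sh[j] - o); dst[[j]] <- src[[j]] + o }
    else { src[[j]] <- (1 - o):sh[j]; dst[[j]] <- seq_len(sh[j] + o) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

cross_offsets <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                      c(0, 0, 1), c(0, 0, -1))

erode_ball1 <- function(m) {
  out <- m
  for (o in cross_offsets) out <- out & shift3(m, o)
  out
}

dilate_ball1 <- function(m) {
  out <- m
  for (o in cross_offsets) out <- out | shift3(m, o)
  out
}

#' Connected components of a binary volume (26-connectivity)
#'
#' @param mask logical volume.
#' @return integer volume of component labels (0 = background), with
#'   attribute \code{n_components}.
#' @export
label_components <- function(mask) {
  sh <- dim(mask)
  lab <- label3d_cpp(as.logical(mask), as.integer(sh))
  n <- attr(lab, "n_components")
  lab <- array(lab, sh)
  attr(lab, "n_components") <- n
  lab
}

# ---- Frangi vesselness -------------------------------------------------------

#' Multiscale Frangi vesselness filter (3D, bright tubular structures)
#'
#' Hessian-eigenvalue vesselness with scale-normalized Gaussian
#' derivatives; the response is the maximum over scales. Eigenvalues are
#' sorted by increasing magnitude; voxels whose two large-magnitude
#' eigenvalues are not both negative get zero response.
#'
#' @param vol numeric volume (a binary mask may be passed directly).
#' @param scales Gaussian scales in voxels.
#' @param alpha,beta plate/blob discrimination parameters.
#' @param cpar structureness parameter; default half the maximum Frobenius
#'   norm per scale.
#' @return vesselness volume in [0, 1].
#' @export
frangi_vesselness <- function(vol, scales = c(1, 2, 3), alpha = 0.5,
                              beta = 0.5, cpar = NULL) {
  sh <- dim(vol)
  v <- array(0, sh)
  x <- -as.numeric(vol)  # bright ridges in the black-ridge convention
  gamma2 <- if (is.null(cpar)) NULL else cpar^2
  for (s in sort(scales)) {
    d2 <- function(orders)
      gauss_deriv3_cpp(x, as.integer(sh), s, as.integer(orders))
    ev <- eig3_batch_cpp(d2(c(2, 0, 0)), d2(c(0, 2, 0)), d2(c(0, 0, 2)),
                         d2(c(1, 1, 0)), d2(c(1, 0, 1)), d2(c(0, 1, 1)))
    l1 <- ev[, 1]
    # clipping negative (bright-incompatible) values drives the blobness
    # factor to zero where the ridge polarity is wrong
    l2 <- pmax(ev[, 2], 1e-10); l3 <- pmax(ev[, 3], 1e-10)
    S2 <- ev[, 1]^2 + ev[, 2]^2 + ev[, 3]^2
    # structureness scale fixed from the smallest scale (strongest edges)
    if (is.null(gamma2)) gamma2 <- max(max(S2) / 4, 1e-20)
    Ra2 <- (l2 / l3)^2
    Rb2 <- l1^2 / (l2 * l3)
    vs <- (1 - exp(-Ra2 / (2 * alpha^2))) * exp(-Rb2 / (2 * beta^2)) *
      (1 - exp(-S2 / (2 * gamma2)))
    v <- pmax(v, array(vs, sh))
  }
  v
}

# shift a numeric array by integer offset (zero fill)
shiftn <- function(a, off) {
  sh <- dim(a)
  out <- array(0, sh)
  src <- dst <- vector("list", 3)
  for (j in 1:3) {
    o <- off[j]
    if (o >= 0) { src[[j]] <- seq_len(sh[j] - o); dst[[j]] <- src[[j]] + o }
    else { src[[j]] <- (1 - o):sh[j]; dst[[j]] <- seq_len(sh[j] + o) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Separate vessels from tumors in a binary segmentation
#'
#' Erosion followed by dilation (radius-1 cross structuring element,
#' \code{struct_radius} iterations) disjoins touching structures; 26-connected
#' components of the opened mask are then classified: a component is a
#' vessel if and only if strictly more than 50 percent of its voxels carry
#' thresholded multiscale vesselness evidence, otherwise it is a tumor
#' candidate.
#'
#' @param seg_mask binary segmentation volume.
#' @param scales vesselness scales (voxels).
#' @param vesselness_threshold absolute evidence threshold on the
#'   vesselness response (the input mask has unit amplitude).
#' @param struct_radius opening iterations (0 disables morphology, e.g.
#'   when voxels are coarse relative to vessel radii).
#' @return list with logical \code{vessel_mask} and \code{tumor_mask}
#'   (disjoint; union = post-morphology components).
#' @export
separate_vessels_tumors <- function(seg_mask, scales = c(1, 2, 3),
                                    vesselness_threshold = 0.08,
                                    struct_radius = 1) {
  seg_mask <- seg_mask > 0
  sh <- dim(seg_mask)
  if (!any(seg_mask))
    return(list(vessel_mask = array(FALSE, sh), tumor_mask = array(FALSE, sh)))
  m <- seg_mask
  if (struct_radius > 0) {
    for (i in seq_len(struct_radius)) m <- erode_ball1(m)
    for (i in seq_len(struct_radius)) m <- dilate_ball1(m)
    m <- m & seg_mask
  }
  if (!any(m))
    return(list(vessel_mask = array(FALSE, sh), tumor_mask = array(FALSE, sh)))
  v <- frangi_vesselness(m, scales = scales)
  evidence <- v > vesselness_threshold
  lab <- label_components(m)
  n <- attr(lab, "n_components")
  vessel <- array(FALSE, sh); tumor <- array(FALSE, sh)
  for (k in seq_len(n)) {
    comp <- lab == k
    frac <- sum(evidence & comp) / sum(comp)
    if (frac > 0.5) vessel[comp] <- TRUE else tumor[comp] <- TRUE
  }
  list(vessel_mask = vessel, tumor_mask = tumor)
}

# ---- metrics -----------------------------------------------------------------

#' Dice similarity coefficient
#'
#' \code{2|a n b| / (|a| + |b|)}; defined as 1 when both masks are empty.
#'
#' @param a,b binary volumes of the same shape.
#' @return scalar in [0, 1].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stopf("shape mismatch in dice()")
  a <- a > 0; b <- b > 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Tumor detection counts
#'
#' A true tumor is detected if the overlap between the predicted tumor
#' mask and that tumor instance strictly exceeds \code{min_overlap_voxels}
#' (reference value 500 voxels against a 3808-voxel tumor at 0.25 mm).
#' When the grid resolution differs from the reference, the threshold is
#' scaled to keep the overlap fraction 500/3808 of each true instance's
#' volume constant (\code{scale_threshold = TRUE}). Predicted tumor
#' components that exceed the threshold with no true tumor are false
#' positives.
#'
#' @param pred_tumor_mask binary predicted tumor mask.
#' @param true_tumor_instances integer instance-labeled volume (or binary,
#'   relabeled internally).
#' @param min_overlap_voxels strict detection threshold.
#' @param scale_threshold scale the threshold by instance volume as
#'   fraction 500/3808.
#' @param labeled treat \code{true_tumor_instances} as already
#'   instance-labeled even if it only contains 0/1 (a spiculated tumor may
#'   rasterize into several connected pieces that are still one instance).
#' @return list with \code{tp}, \code{fp}, \code{fn} and a per-tumor
#'   data.frame (instance id, voxels, overlap, threshold, detected).
#' @export
detect_tumors <- function(pred_tumor_mask, true_tumor_instances,
                          min_overlap_voxels = 500,
                          scale_threshold = FALSE, labeled = FALSE) {
  pred <- pred_tumor_mask > 0
  truei <- true_tumor_instances
  if (!labeled && (is.logical(truei) || all(truei %in% c(0, 1))))
    truei <- label_components(truei > 0)
  ids <- setdiff(sort(unique(as.integer(truei))), 0L)
  plab <- label_components(pred)
  np <- attr(plab, "n_components")
  per <- data.frame(instance = integer(0), voxels = integer(0),
                    overlap = integer(0), threshold = numeric(0),
                    detected = logical(0))
  comp_hit <- rep(FALSE, np)
  tp <- 0L
  for (id in ids) {
    inst <- truei == id
    nv <- sum(inst)
    thr <- if (scale_threshold) (500 / 3808) * nv else min_overlap_voxels
    ov <- sum(pred & inst)
    det <- ov > thr
    if (det) {
      tp <- tp + 1L
      hit <- unique(plab[pred & inst]); hit <- hit[hit > 0]
      comp_hit[hit] <- TRUE
    }
    per <- rbind(per, data.frame(instance = id, voxels = nv, overlap = ov,
                                 threshold = thr, detected = det))
  }
  # false positives: predicted components with no above-threshold true hit
  fp <- 0L
  for (k in seq_len(np)) {
    if (comp_hit[k]) next
    comp <- plab == k
    hit_any <- FALSE
    for (id in ids) {
      inst <- truei == id
      thr <- if (scale_threshold) (500 / 3808) * sum(inst) else min_overlap_voxels
      if (sum(comp & inst) > thr) { hit_any <- TRUE; break }
    }
    if (!hit_any) fp <- fp + 1L
  }
  list(tp = tp, fp = fp, fn = length(ids) - tp, per_tumor = per)
}

#' Depth-binned vessel sO2 mean absolute error
#'
#' MAE and standard deviation of |pred - true| over vessel voxels grouped
#' into depth bins \code{[k w, (k+1) w)}. Values are on the normalized
#' 0-1 sO2 scale (an MAE of 0.05 is 5 percentage points).
#'
#' @param pred_so2,true_so2 sO2 volumes.
#' @param vessel_mask logical vessel voxels to evaluate.
#' @param depth depth map (mm) from [depth_map()].
#' @param bin_width_mm bin width (default 3 mm).
#' @return data.frame with columns lower, upper, mae, std, n (empty bins
#'   have n = 0 and NA statistics).
#' @export
depthwise_vessel_mae <- function(pred_so2, true_so2, vessel_mask, depth,
                                 bin_width_mm = 3) {
  sel <- vessel_mask > 0 & !is.na(pred_so2) & !is.na(true_so2)
  err <- abs(pred_so2[sel] - true_so2[sel])
  dd <- depth[sel]
  maxd <- if (length(dd)) max(dd) else 0
  nb <- max(1, ceiling(maxd / bin_width_mm + 1e-12))
  out <- data.frame(lower = (seq_len(nb) - 1) * bin_width_mm,
                    upper = seq_len(nb) * bin_width_mm,
                    mae = NA_real_, std = NA_real_, n = 0L)
  for (k in seq_len(nb)) {
    inb <- dd >= out$lower[k] & dd < out$upper[k]
    out$n[k] <- sum(inb)
    if (out$n[k] > 0) {
      out$mae[k] <- mean(err[inb])
      out$std[k] <- if (out$n[k] > 1) sd(err[inb]) else 0
    }
  }
  out
}

#' Paired true/estimated mean tumor sO2
#'
#' For each true tumor instance matched by a detected predicted component,
#' reports the estimated mean sO2 over the model-identified region and the
#' true mean over the true region. Unmatched predicted components are
#' excluded (they only count as false positives in [detect_tumors()]).
#'
#' @param pred_so2 estimated sO2 volume.
#' @param pred_tumor_mask binary predicted tumor mask.
#' @param true_so2 true sO2 volume.
#' @param true_tumor_instances instance-labeled (or binary) true tumor
#'   volume.
#' @param location_tags optional character tags per instance id.
#' @param min_overlap_voxels,scale_threshold matching rule as in
#'   [detect_tumors()].
#' @return data.frame with columns instance, true_mean, est_mean, location.
#' @export
mean_tumor_so2_pairs <- function(pred_so2, pred_tumor_mask, true_so2,
                                 true_tumor_instances, location_tags = NULL,
                                 min_overlap_voxels = 500,
                                 scale_threshold = FALSE, labeled = FALSE) {
  pred <- pred_tumor_mask > 0
  truei <- true_tumor_instances
  if (!labeled && (is.logical(truei) || all(truei %in% c(0, 1))))
    truei <- label_components(truei > 0)
  ids <- setdiff(sort(unique(as.integer(truei))), 0L)
  plab <- label_components(pred)
  out <- NULL
  for (i in seq_along(ids)) {
    inst <- truei == ids[i]
    thr <- if (scale_threshold) (500 / 3808) * sum(inst) else min_overlap_voxels
    if (sum(pred & inst) <= thr) next
    comps <- unique(plab[pred & inst]); comps <- comps[comps > 0]
    region <- array(plab %in% comps, dim(plab))
    out <- rbind(out, data.frame(
      instance = ids[i],
      true_mean = mean(true_so2[inst], na.rm = TRUE),
      est_mean = mean(pred_so2[region], na.rm = TRUE),
      location = if (is.null(location_tags)) NA_character_
                 else location_tags[i]))
  }
  if (is.null(out))
    out <- data.frame(instance = integer(0), true_mean = numeric(0),
                      est_mean = numeric(0), location = character(0))
  out
}

#' Per-phantom evaluation report
#'
#' Applies the full protocol to one estimate: vessel/tumor separation of
#' the segmentation, vessel Dice against the true artery+vein mask, tumor
#' detection, depth-binned vessel sO2 MAE and mean tumor sO2 pairs.
#'
#' @param estimate a \code{qpact_estimate} (or list with so2 + seg_mask).
#' @param phantom the ground-truth \code{qpact_phantom}.
#' @param bin_width_mm depth bin width.
#' @param exclude_skin_mm superficial exclusion depth (0 disables).
#' @param struct_radius,scales,vesselness_threshold post-processing
#'   parameters (see [separate_vessels_tumors()]).
#' @param scale_threshold scale the detection threshold to the grid (see
#'   [detect_tumors()]).
#' @return list of class \code{evaluation_report}.
#' @export
evaluation_report <- function(estimate, phantom, bin_width_mm = 3,
                              exclude_skin_mm = 0,
                              struct_radius = 1, scales = c(1, 2, 3),
                              vesselness_threshold = 0.08,
                              scale_threshold = TRUE) {
  lc <- label_codes()
  bm <- breast_mask(phantom)
  d <- depth_map(bm, phantom$grid$voxel_size)
  seg <- estimate$seg_mask
  so2 <- estimate$so2
  if (exclude_skin_mm > 0) {
    seg <- skin_exclusion(seg, d, exclude_skin_mm)
    so2 <- skin_exclusion(so2, d, exclude_skin_mm)
  }
  sep <- separate_vessels_tumors(seg, scales = scales,
                                 vesselness_threshold = vesselness_threshold,
                                 struct_radius = struct_radius)
  true_vessel <- phantom$labels == lc[["artery"]] |
    phantom$labels == lc[["vein"]]
  shell <- shell_mask(bm, phantom$grid)
  true_vessel_shell <- true_vessel & shell
  dsc <- dice(sep$vessel_mask, true_vessel_shell)
  # all viable voxels of one inserted tumor form a single instance
  true_tumor <- array((phantom$labels == lc[["tumor_viable"]]) * 1L,
                      dim(phantom$labels))
  det <- detect_tumors(sep$tumor_mask, true_tumor,
                       scale_threshold = scale_threshold, labeled = TRUE)
  mae <- depthwise_vessel_mae(so2, phantom$functional$so2,
                              sep$vessel_mask, d, bin_width_mm)
  pairs <- mean_tumor_so2_pairs(so2, sep$tumor_mask,
                                phantom$functional$so2, true_tumor,
                                location_tags =
                                  phantom$metadata$tumor_location,
                                scale_threshold = scale_threshold,
                                labeled = TRUE)
  structure(list(dice = dsc, detection = det[c("tp", "fp", "fn")],
                 depth_mae = mae, tumor_so2_pairs = pairs,
                 config = list(bin_width_mm = bin_width_mm,
                               exclude_skin_mm = exclude_skin_mm,
                               struct_radius = struct_radius,
                               scales = scales,
                               vesselness_threshold = vesselness_threshold)),
            class = "evaluation_report")
}
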