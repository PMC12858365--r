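# Volume and sensor-data serialization. Volumes go to NIfTI (voxel spacing
# preserved in the header); metadata and traces go to YAML/CSV sidecars so
# every artifact on disk is a standard, tool-readable format.

#' Write / read a phantom bundle
#'
#' Serializes all phantom volumes (labels, functional, per-wavelength
#' optical, acoustic) as NIfTI files in a directory plus a YAML metadata
#' sidecar. The round trip is lossless for all maps.
#'
#' @param ph a \code{qpact_phantom}.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_phantom <- function(ph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h <- ph$grid$voxel_size
  wr <- function(vol, name) {
    img <- RNifti::asNifti(array(as.vector(vol), dim(vol)))
    RNifti::pixdim(img) <- rep(h, 3)
    RNifti::writeNifti(img, file.path(dir, paste0(name, ".nii")))
  }
  wr(ph$labels + 0L, "labels")
  for (nm in names(ph$functional)) wr(ph$functional[[nm]], paste0("func_", nm))
  for (wl in names(ph$optical$mua)) {
    wr(ph$optical$mua[[wl]], paste0("mua_", wl))
    wr(ph$optical$mus[[wl]], paste0("mus_", wl))
  }
  wr(ph$optical$g, "g"); wr(ph$optical$n, "n")
  for (nm in names(ph$acoustic)) wr(ph$acoustic[[nm]], paste0("ac_", nm))
  meta <- ph$metadata
  meta$grid <- list(shape = as.integer(ph$grid$shape), voxel_size = h)
  meta$wavelengths <- ph$config$wavelengths
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' @rdname write_phantom
#' @param check verify the metadata sidecar is present and consistent.
#' @return \code{read_phantom}: a \code{qpact_phantom} (without the
#'   generator config).
#' @export
read_phantom <- function(dir, check = TRUE) {
  metaf <- file.path(dir, "metadata.yaml")
  if (!file.exists(metaf)) stopf("not a phantom bundle (no metadata.yaml): %s", dir)
  meta <- yaml::read_yaml(metaf)
  sh <- as.integer(meta$grid$shape)
  grid <- grid_spec(sh, meta$grid$voxel_size)
  rd <- function(name) {
    f <- file.path(dir, paste0(name, ".nii"))
    if (!file.exists(f)) stopf("phantom bundle %s is missing %s", dir, f)
    v <- RNifti::readNifti(f)
    if (!identical(dim(v), sh)) stopf("corrupt volume (shape mismatch): %s", f)
    array(as.vector(v), sh)
  }
  wls <- as.character(meta$wavelengths)
  ph <- structure(list(
    grid = grid,
    labels = array(as.integer(rd("labels")), sh),
    functional = list(so2 = rd("func_so2"), blood_vf = rd("func_blood_vf"),
                      water_vf = rd("func_water_vf"), fat_vf = rd("func_fat_vf"),
                      melanosome_vf = rd("func_melanosome_vf"),
                      thb = rd("func_thb")),
    optical = list(mua = setNames(lapply(wls, function(w) rd(paste0("mua_", w))), wls),
                   mus = setNames(lapply(wls, function(w) rd(paste0("mus_", w))), wls),
                   g = rd("g"), n = rd("n")),
    acoustic = list(c = rd("ac_c"), rho = rd("ac_rho"),
                    alpha0 = rd("ac_alpha0"), y = rd("ac_y")),
    metadata = meta[setdiff(names(meta), c("grid", "wavelengths"))],
    config = list(wavelengths = as.numeric(meta$wavelengths))),
    class = "qpact_phantom")
  ph
}

#' Write / read a single volume as NIfTI
#'
#' @param vol numeric 3D array.
#' @param path file path (.nii).
#' @param voxel_mm voxel size written to the header.
#' @return the path (write) or the array with attribute \code{voxel_mm}
#'   (read).
#' @export
write_volume <- function(vol, path, voxel_mm) {
  img <- RNifti::asNifti(array(as.vector(vol), dim(vol)))
  RNifti::pixdim(img) <- rep(voxel_mm, length(dim(vol)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.vector(img), dim(img))
  attr(out, "voxel_mm") <- RNifti::pixdim(img)[1]
  out
}

#' Write / read sensor data (traces as CSV, geometry as YAML)
#'
#' @param sensor a \code{sensor_data}.
#' @param dir output directory.
#' @return the directory, invisibly; \code{read_sensor_data} restores the
#'   object (records, dt, positions).
#' @export
write_sensor_data <- function(sensor, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(sensor$records),
            file.path(dir, "traces.csv"), row.names = FALSE)
  write.csv(as.data.frame(sensor$positions),
            file.path(dir, "positions.csv"), row.names = FALSE)
  yaml::write_yaml(list(dt = sensor$dt, noise_sigma = sensor$noise_sigma,
                        n_records = nrow(sensor$records),
                        n_samples = ncol(sensor$records)),
                   file.path(dir, "sensor.yaml"))
  invisible(dir)
}

#' @rdname write_sensor_data
#' @export
read_sensor_data <- function(dir) {
  metaf <- file.path(dir, "sensor.yaml")
  if (!file.exists(metaf)) stopf("not a sensor bundle: %s", dir)
  meta <- yaml::read_yaml(metaf)
  rec <- as.matrix(read.csv(file.path(dir, "traces.csv")))
  dimnames(rec) <- NULL
  if (!identical(dim(rec), c(meta$n_records, meta$n_samples)))
    stopf("corrupt sensor traces in %s", dir)
  pos <- as.matrix(read.csv(file.path(dir, "positions.csv")))
  dimnames(pos) <- NULL
  structure(list(records = rec, dt = meta$dt, positions = pos,
                 noise_sigma = meta$noise_sigma),
            class = "sensor_data")
}
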