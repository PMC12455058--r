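#' Read a 4-D image stack with optional mask
#'
#' Reads a NIfTI volume whose 4th dimension is the acquisition index and
#' returns a voxel-by-acquisition signal table for the voxels inside the
#' mask. The acquisition count must match the protocol length; a
#' mismatch is a schema error, never a silent truncation.
#'
#' @param path NIfTI file path.
#' @param mask optional NIfTI path or logical/numeric array matching the
#'   spatial grid.
#' @param prot optional `dr_protocol` for the length check.
#' @return list with `signals` (matrix, masked voxels x n_acq),
#'   `voxels` (matrix of voxel indices), `dims` (spatial grid).
#' @export
read_images <- function(path, mask = NULL, prot = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4-D image stack")
  if (!is.null(prot) && d[4L] != nrow(prot$table))
    stop(sprintf(
      "image has %d volumes but the protocol has %d acquisitions",
      d[4L], nrow(prot$table)))
  dims <- d[1:3]
  if (is.null(mask)) {
    m <- array(TRUE, dims)
  } else {
    m <- if (is.character(mask)) RNifti::readNifti(mask) else mask
    if (!all(dim(m)[1:3] == dims)) stop("mask grid does not match image")
    m <- array(as.logical(m != 0), dims)
  }
  vox <- which(m, arr.ind = TRUE)
  sig <- matrix(0, nrow(vox), d[4L])
  flat <- matrix(img, prod(dims), d[4L])
  idx <- vox[, 1L] + (vox[, 2L] - 1L) * dims[1L] +
    (vox[, 3L] - 1L) * dims[1L] * dims[2L]
  sig <- flat[idx, , drop = FALSE]
  if (!all(is.finite(sig))) stop("non-finite voxel intensities")
  list(signals = sig, voxels = vox, dims = dims)
}

#' Write a 4-D or 3-D array as NIfTI
#'
#' @param arr numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param pixdim voxel sizes (mm), recycled.
#' @return `path`, invisibly.
#' @export
write_image <- function(arr, path, pixdim = c(1, 1, 1)) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(pixdim, length.out = length(dim(arr)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write parameter maps as NIfTI volumes plus a JSON sidecar
#'
#' One volume per scalar metric, a 3-channel RGB volume, and a sidecar
#' recording the evaluation frequencies, bin preset and mode.
#'
#' @param maps a `parameter_maps` from [map_assembly()] built with
#'   `dims`.
#' @param dir output directory.
#' @param prefix filename prefix.
#' @param meta named list merged into the sidecar.
#' @return the sidecar path, invisibly.
#' @export
write_maps <- function(maps, dir, prefix = "maps", meta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nm <- setdiff(names(maps), "omegas")
  rgb_nm <- c("rgb_r", "rgb_g", "rgb_b")
  for (mn in setdiff(nm, rgb_nm)) {
    if (!is.array(maps[[mn]])) next
    write_image(maps[[mn]], file.path(dir, sprintf("%s_%s.nii.gz",
                                                   prefix, mn)))
  }
  if (all(rgb_nm %in% nm) && is.array(maps$rgb_r)) {
    rgb <- array(c(maps$rgb_r, maps$rgb_g, maps$rgb_b),
                 dim = c(dim(maps$rgb_r), 3L))
    write_image(rgb, file.path(dir, sprintf("%s_rgb.nii.gz", prefix)))
  }
  sidecar <- file.path(dir, sprintf("%s.json", prefix))
  jsonlite::write_json(
    c(list(omega_hz = as.list(maps$omegas / (2 * pi))), meta),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Component-set table I/O
#'
#' Flat TSV with one row per component, columns in the canonical
#' parameter order (w, d_a, d_r, theta, phi, d_0, gamma_a, gamma_r,
#' r_1, r_2), SI units.
#'
#' @param components a `component_set`.
#' @param path file path.
#' @return `path` (write) or a `component_set` (read).
#' @export
write_components <- function(components, path) {
  utils::write.table(as.data.frame(components), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_components
#' @export
read_components <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  do.call(component_set, as.list(df))
}

#' Serialize bootstrap ensembles
#'
#' Per-voxel ensembles are stored in an RDS container (one list entry
#' per voxel, one component table per replicate) with a schema version
#' field; individual solutions can be exported to TSV with
#' [write_components()].
#'
#' @param ensembles list of `bootstrap_ensemble` objects.
#' @param path output `.rds` path.
#' @return `path` (write) or the ensemble list (read).
#' @export
write_ensembles <- function(ensembles, path) {
  saveRDS(list(schema = "dtdspec-ensemble-v1", ensembles = ensembles),
          path)
  invisible(path)
}

#' @rdname write_ensembles
#' @export
read_ensembles <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "dtdspec-ensemble-v1"))
    stop("unrecognized ensemble container schema")
  obj$ensembles
}

#' Run configuration I/O
#'
#' YAML (or JSON) round-trip of the run configuration: paths, inversion
#' settings, bin preset, mesh settings, seed and worker count.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @param config named list.
#' @return the configuration list (read) or `path` (write).
#' @export
read_run_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  else
    yaml::write_yaml(config, path)
  invisible(path)
}
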