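# On-disk formats: NIfTI for images, tensor fields and masks (via RNifti),
# JSON sidecars for provenance (parameters and seeds), a minimal JSON
# gradient-table dialect for DWI series.

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

#' Write / read a tensor field as NIfTI
#'
#' The six unique elements are stored as a 4-D volume (rows, cols, 1, 6) in
#' channel order (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), float64 (lossless); the
#' mask goes to a companion uint8 volume and a JSON sidecar records channel
#' order and any supplied metadata.
#'
#' @param tf a \code{tensor_field}.
#' @param path output path (.nii or .nii.gz).
#' @param meta named list merged into the sidecar.
#' @return \code{path}, invisibly.
#' @export
write_tensor_field <- function(tf, path, meta = list()) {
  stopifnot(inherits(tf, "tensor_field"))
  d <- dim(tf$d)
  arr <- array(tf$d, c(d[1], d[2], 1, 6))
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  mask_path <- sub("\\.nii(\\.gz)?$", "_mask.nii\\1", path)
  mask <- array(as.integer(tf$mask), c(d[1], d[2]))
  RNifti::writeNifti(RNifti::asNifti(mask, datatype = "uint8"), mask_path)
  write_sidecar(path, c(list(channels = c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz"),
                             units = "mm^2/s", mask_file = basename(mask_path)),
                        meta))
  invisible(path)
}

#' @rdname write_tensor_field
#' @export
read_tensor_field <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  stop_if_not(length(dim(arr)) == 4 && dim(arr)[4] == 6,
              sprintf("malformed tensor NIfTI '%s': expected (rows, cols, 1, 6)", path))
  mask_path <- sub("\\.nii(\\.gz)?$", "_mask.nii\\1", path)
  mask <- as.array(RNifti::readNifti(mask_path))
  tensor_field(array(arr, c(dim(arr)[1:2], 6)),
               matrix(mask > 0, dim(arr)[1], dim(arr)[2]))
}

#' Write / read a DWI series as 4-D NIfTI plus a JSON gradient table
#'
#' The image index runs along the 4th axis; the sidecar lists (b, direction,
#' repetition) per index together with the noise level and seed.
#'
#' @param series a \code{dwi_series}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_dwi_series <- function(series, path) {
  stopifnot(inherits(series, "dwi_series"))
  d <- dim(series$images)
  arr <- array(series$images, c(d[1], d[2], 1, d[3]))
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  write_sidecar(path, list(gradient_table = series$meta,
                           noise_sigma = series$noise_sigma,
                           seed = series$seed))
  invisible(path)
}

#' @rdname write_dwi_series
#' @export
read_dwi_series <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  stop_if_not(length(dim(arr)) == 4,
              sprintf("malformed DWI NIfTI '%s': expected a 4-D volume", path))
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  meta <- as.data.frame(side$gradient_table)
  stop_if_not(nrow(meta) == dim(arr)[4],
              "gradient table length does not match the image stack")
  structure(list(images = array(arr, c(dim(arr)[1:2], dim(arr)[4])),
                 meta = meta, noise_sigma = side$noise_sigma,
                 seed = side$seed),
            class = "dwi_series")
}

#' Write a set of cDTI maps as one NIfTI per map
#'
#' MD is stored in mm^2/s on disk (the sidecar records display units of
#' 1e-3 mm^2/s); angular maps in degrees. NA (outside mask / flagged) is
#' stored as NaN.
#'
#' @param maps a \code{cdti_maps}.
#' @param prefix output path prefix; files become \code{<prefix>_md.nii.gz}
#'   etc.
#' @param meta extra sidecar metadata.
#' @return Named vector of the written paths, invisibly.
#' @export
write_cdti_maps <- function(maps, prefix, meta = list()) {
  stopifnot(inherits(maps, "cdti_maps"))
  units <- c(md = "mm^2/s (display 1e-3 mm^2/s)", fa = "dimensionless",
             ha = "degrees", e2a = "degrees")
  paths <- c()
  for (nm in c("md", "fa", "ha", "e2a")) {
    p <- sprintf("%s_%s.nii.gz", prefix, nm)
    RNifti::writeNifti(RNifti::asNifti(maps[[nm]], datatype = "double"), p)
    write_sidecar(p, c(list(map = nm, units = unname(units[nm])), meta))
    paths[nm] <- p
  }
  mp <- sprintf("%s_mask.nii.gz", prefix)
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(maps$mask), dim(maps$mask)),
                                     datatype = "uint8"), mp)
  paths["mask"] <- mp
  invisible(paths)
}
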