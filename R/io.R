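# NIfTI and sidecar I/O. Volumes travel as plain R arrays inside the
# package; RNifti handles serialization with voxel spacing metadata.

#' Write a 3-D/4-D array as NIfTI
#'
#' @param x Numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_mm Voxel spacing, mm (length 3).
#' @export
write_volume <- function(x, path, voxel_mm = c(1, 1, 4)) {
  img <- RNifti::asNifti(x, pixdim = voxel_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  attr(arr, "pixdim") <- RNifti::pixdim(img)
  arr
}

#' Write a phantom (or subject acquisition) to a directory
#'
#' Emits NIfTI volumes for the FLASH triplet, B1 pair and DWI series,
#' FSL-style bval/bvec text files, one NIfTI per tract label plus a JSON
#' atlas manifest (tract name, side, file), and the level mask.
#'
#' @param phantom A `spinal_phantom` from [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vx <- phantom$config$voxel_mm
  write_volume(phantom$flash_pd, file.path(dir, "flash_pd.nii.gz"), vx)
  write_volume(phantom$flash_t1, file.path(dir, "flash_t1.nii.gz"), vx)
  write_volume(phantom$flash_mt, file.path(dir, "flash_mt.nii.gz"), vx)
  write_volume(phantom$b1_low, file.path(dir, "b1_low.nii.gz"), vx)
  write_volume(phantom$b1_high, file.path(dir, "b1_high.nii.gz"), vx)
  write_volume(phantom$dwi, file.path(dir, "dwi.nii.gz"), vx)
  write_scheme(phantom$scheme, file.path(dir, "dwi.bval"),
               file.path(dir, "dwi.bvec"))
  write_atlas(phantom$atlas, dir, vx)
  protocol <- phantom$config$protocol
  jsonlite::write_json(protocol, file.path(dir, "protocol.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write / read a tract atlas (NIfTI labels + JSON manifest)
#'
#' @param atlas A `tract_atlas`.
#' @param dir Directory for the label volumes and `atlas.json`.
#' @param voxel_mm Voxel spacing.
#' @export
write_atlas <- function(atlas, dir, voxel_mm = c(1, 1, 4)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (tract in names(atlas$tracts)) for (side in c("left", "right")) {
    fn <- sprintf("atlas_%s_%s.nii.gz", tract, side)
    write_volume(atlas$tracts[[tract]][[side]], file.path(dir, fn), voxel_mm)
    manifest[[length(manifest) + 1]] <-
      list(tract = tract, side = side, file = fn)
  }
  write_volume(atlas$level_mask * 1, file.path(dir, "level_mask.nii.gz"),
               voxel_mm)
  jsonlite::write_json(list(tracts = manifest,
                            level_mask = "level_mask.nii.gz"),
                       file.path(dir, "atlas.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "atlas.json"),
                             simplifyVector = TRUE)
  tracts <- list()
  for (i in seq_len(nrow(man$tracts))) {
    tr <- man$tracts$tract[i]; sd <- man$tracts$side[i]
    vol <- read_volume(file.path(dir, man$tracts$file[i]))
    attr(vol, "pixdim") <- NULL
    if (is.null(tracts[[tr]])) tracts[[tr]] <- list()
    tracts[[tr]][[sd]] <- vol
  }
  lv <- read_volume(file.path(dir, man$level_mask))
  attr(lv, "pixdim") <- NULL
  structure(list(tracts = tracts, level_mask = lv > 0.5,
                 grid = dim(lv)), class = "tract_atlas")
}
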