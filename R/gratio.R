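# Axon volume fraction and aggregate MR fiber g-ratio maps.

#' Axon volume fraction
#'
#' AVF = (1 - MVF) (1 - Viso) Vic, elementwise. NaN in any parent map
#' propagates (invalid voxels are never silently zero-filled).
#'
#' @param mvf,viso,vic Volumes with values in \[0, 1\] (clamped upstream).
#' @return AVF volume.
#' @export
compute_avf <- function(mvf, viso, vic) {
  stopifnot_same_grid(mvf, viso, vic)
  rng <- range(c(mvf, viso, vic), na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    stop("mvf/viso/vic must be fractions in [0, 1]", call. = FALSE)
  }
  (1 - mvf) * (1 - viso) * vic
}

#' Aggregate MR fiber g-ratio
#'
#' g = sqrt(AVF / (MVF + AVF)): the voxel-aggregate ratio of inner (axon) to
#' outer (axon + myelin) fiber diameter. Voxels with MVF + AVF = 0 carry no
#' fiber signal and are returned as NaN (flagged in the `qc` attribute).
#'
#' @param avf,mvf Non-negative volumes on one grid.
#' @return g-ratio volume in \[0, 1\], with attribute `qc` (logical volume,
#'   TRUE where g is undefined).
#' @export
compute_gratio <- function(avf, mvf) {
  stopifnot_same_grid(avf, mvf)
  if (any(avf < -1e-12 | mvf < -1e-12, na.rm = TRUE)) {
    stop("avf and mvf must be non-negative", call. = FALSE)
  }
  den <- mvf + avf
  g <- sqrt(avf / den)
  undef <- is.finite(den) & den == 0
  g[undef] <- NaN
  attr(g, "qc") <- undef | !is.finite(den)
  g
}

#' One-voxel in-plane erosion of a cord mask
#'
#' Edge voxels of the segmented cord are prone to partial-volume and
#' registration artifacts (spuriously high g at the cord rim), so ROI
#' statistics by default drop the outermost voxel ring. Erosion uses the
#' in-plane 4-neighbourhood only: slices are thick (4 mm) relative to the
#' in-plane resolution and each analysis level is processed per slice.
#'
#' @param mask Logical 3-D array.
#' @return Eroded logical array of the same shape.
#' @export
erode_mask <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (k in seq_len(d[3])) {
    sl <- mask[, , k]
    er <- sl
    er[1, ] <- FALSE; er[d[1], ] <- FALSE
    er[, 1] <- FALSE; er[, d[2]] <- FALSE
    inner_i <- 2:(d[1] - 1); inner_j <- 2:(d[2] - 1)
    er[inner_i, inner_j] <- sl[inner_i, inner_j] &
      sl[inner_i - 1, inner_j] & sl[inner_i + 1, inner_j] &
      sl[inner_i, inner_j - 1] & sl[inner_i, inner_j + 1]
    out[, , k] <- er
  }
  out
}

#' Combine MVF and NODDI maps into microstructure maps with QC
#'
#' @param mvf MVF volume (calibrated, clamped).
#' @param noddi A `noddi_maps` object from [fit_noddi()].
#' @param cord_mask Logical cord mask.
#' @param erode If `TRUE` (default), apply [erode_mask()] to the cord mask
#'   before ROI statistics.
#' @return List with `avf`, `mvf`, `gratio`, `qc_mask` (logical: voxels
#'   valid for ROI statistics) and `roi_mask` (eroded cord mask).
#' @export
microstructure_maps <- function(mvf, noddi, cord_mask, erode = TRUE) {
  avf <- compute_avf(clamp01(mvf), clamp01(noddi$viso), clamp01(noddi$vic))
  g <- compute_gratio(avf, clamp01(mvf))
  roi <- if (erode) erode_mask(cord_mask) else cord_mask
  valid <- is.finite(avf) & is.finite(g) & is.finite(mvf) &
    !noddi$invalid & !noddi$non_identifiable
  list(avf = avf, mvf = clamp01(mvf), gratio = g,
       qc_mask = valid, roi_mask = roi & valid)
}
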