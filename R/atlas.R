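# Atlas-based tract metric extraction and cohort table assembly.

#' Probability-weighted tract metric summary
#'
#' Weighted mean sum(w_i m_i) / sum(w_i) of a metric volume over one tract's
#' probabilistic label, restricted to the atlas level mask, excluding
#' NaN/QC-invalid voxels. This re-implements the standard atlas-based
#' extraction rule (weighted average) used for spinal-cord tract metrics.
#'
#' @param metric Metric volume (may contain NaN for invalid voxels).
#' @param atlas A `tract_atlas` (see [make_atlas()]).
#' @param tract Tract name, one of [tract_names()].
#' @param side `"left"` or `"right"`.
#' @param qc_mask Optional logical volume; voxels FALSE are excluded (e.g.
#'   the eroded-cord QC mask).
#' @return List with `value` (weighted mean) and `effective_n` (sum of
#'   contributing weights).
#' @export
extract_tract_metric <- function(metric, atlas, tract,
                                 side = c("left", "right"),
                                 qc_mask = NULL) {
  side <- match.arg(side)
  if (!inherits(atlas, "tract_atlas")) stop("atlas must be a tract_atlas")
  if (!tract %in% names(atlas$tracts)) {
    stop("unknown tract: ", tract, call. = FALSE)
  }
  w <- atlas$tracts[[tract]][[side]]
  stopifnot_same_grid(metric, w)
  keep <- atlas$level_mask & w > 0 & is.finite(metric)
  if (!is.null(qc_mask)) keep <- keep & qc_mask
  sw <- sum(w[keep])
  if (sw == 0) {
    stop(sprintf("empty ROI: %s (%s) has no valid voxels", tract, side),
         call. = FALSE)
  }
  list(value = sum(w[keep] * metric[keep]) / sw, effective_n = sw)
}

#' Assemble the per-side cohort metric table
#'
#' One record per (subject, side, tract, metric) with the side's group label
#' (affected / unaffected / control) taken from the metadata-derived side
#' assignments, plus clinical covariates.
#'
#' @param subject_maps Named list (by subject id); each element a list with
#'   `avf`, `mvf`, `gratio` volumes, a `qc_mask`, and an `atlas`.
#' @param metadata Subject metadata frame (`subject_id`, `group`,
#'   `laterality`, `mjoa`, `n_levels`), as from [generate_cohort()].
#' @return Long data frame of class `cohort_table`: subject_id, side,
#'   side_group, tract, metric, value, effective_n, mjoa, n_levels.
#' @export
assemble_cohort_table <- function(subject_maps, metadata) {
  sides <- side_assignments(metadata)
  rows <- list()
  for (i in seq_len(nrow(sides))) {
    sid <- sides$subject_id[i]
    maps <- subject_maps[[sid]]
    if (is.null(maps)) stop("missing maps for subject ", sid, call. = FALSE)
    md <- metadata[metadata$subject_id == sid, ]
    for (tract in names(maps$atlas$tracts)) {
      for (metric in c("avf", "mvf", "gratio")) {
        ex <- extract_tract_metric(maps[[metric]], maps$atlas, tract,
                                   sides$side[i], qc_mask = maps$qc_mask)
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = sid, side = sides$side[i],
          side_group = sides$side_group[i], tract = tract, metric = metric,
          value = ex$value, effective_n = ex$effective_n,
          mjoa = md$mjoa, n_levels = md$n_levels,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write / read a cohort table as CSV
#' @param x A `cohort_table`.
#' @param path CSV file path.
#' @export
write_cohort_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}
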