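# MT-saturation mapping: apparent R1, apparent amplitude, apparent MT
# saturation from three differently weighted FLASH volumes, double-angle B1
# correction, and linear calibration of the saturation map to a myelin
# volume fraction.

#' Bundle the three FLASH volumes with their protocol
#'
#' Flip angles are given in degrees at the interface and converted to
#' radians internally (the quadratic alpha^2/2 term of the saturation
#' equation requires radians). TRs are in seconds.
#'
#' @param s_pd,s_t1,s_mt PD-, T1- and MT-weighted signal volumes (arrays on
#'   one grid, arbitrary units).
#' @param alpha_pd,alpha_t1,alpha_mt Nominal excitation flip angles, degrees.
#' @param tr_pd,tr_t1,tr_mt Repetition times, seconds.
#' @return A list of class `flash_triplet`.
#' @export
flash_triplet <- function(s_pd, s_t1, s_mt,
                          alpha_pd = 5, alpha_t1 = 13, alpha_mt = 5,
                          tr_pd = 0.024, tr_t1 = 0.010, tr_mt = 0.024) {
  stopifnot_same_grid(s_pd, s_t1, s_mt)
  deg <- pi / 180
  angles <- c(alpha_pd, alpha_t1, alpha_mt) * deg
  if (any(angles <= 0 | angles >= pi / 2)) {
    stop("flip angles must be in (0, 90) degrees", call. = FALSE)
  }
  if (any(c(tr_pd, tr_t1, tr_mt) <= 0)) stop("TRs must be positive")
  structure(list(s_pd = s_pd, s_t1 = s_t1, s_mt = s_mt,
                 alpha_pd = angles[1], alpha_t1 = angles[2],
                 alpha_mt = angles[3],
                 tr_pd = tr_pd, tr_t1 = tr_t1, tr_mt = tr_mt),
            class = "flash_triplet")
}

#' Apparent longitudinal relaxation rate from a dual-flip FLASH pair
#'
#' R1app = (1/2) (S_T1 a_T1/TR_T1 - S_PD a_PD/TR_PD) /
#'               (S_PD/a_PD - S_T1/a_T1),
#' the rational small-angle inversion of the spoiled FLASH steady state.
#' Voxels where the denominator is not strictly positive (no T1 contrast,
#' e.g. background) are flagged invalid as NaN.
#'
#' @param triplet A [flash_triplet()].
#' @return R1app volume, 1/s, NaN where invalid.
#' @export
compute_r1app <- function(triplet) {
  t <- triplet
  num <- t$s_t1 * t$alpha_t1 / t$tr_t1 - t$s_pd * t$alpha_pd / t$tr_pd
  den <- t$s_pd / t$alpha_pd - t$s_t1 / t$alpha_t1
  out <- 0.5 * num / den
  out[!(den > 0) & !(den == 0 & num == 0)] <- NaN
  out[den == 0 & num == 0] <- 0
  out
}

#' Apparent signal amplitude from a dual-flip FLASH pair
#'
#' Aapp = S_PD S_T1 (TR_PD a_T1/a_PD - TR_T1 a_PD/a_T1) /
#'                  (S_T1 TR_PD a_T1 - S_PD TR_T1 a_PD),
#' scales linearly with a global signal scale (receive gain).
#'
#' @param triplet A [flash_triplet()].
#' @return Aapp volume, same units as the input signals, NaN where invalid.
#' @export
compute_aapp <- function(triplet) {
  t <- triplet
  num <- t$s_pd * t$s_t1 *
    (t$tr_pd * t$alpha_t1 / t$alpha_pd - t$tr_t1 * t$alpha_pd / t$alpha_t1)
  den <- t$s_t1 * t$tr_pd * t$alpha_t1 - t$s_pd * t$tr_t1 * t$alpha_pd
  out <- num / den
  out[den <= 0] <- NaN
  out
}

#' Apparent MT saturation
#'
#' delta_app = (Aapp a_MT / S_MT - 1) R1app TR_MT - a_MT^2 / 2,
#' dimensionless (a fraction; multiply by 100 for percent units). Invariant
#' under a common rescaling of all three FLASH signals.
#'
#' @param s_mt MT-weighted signal volume.
#' @param alpha_mt MT-weighted excitation flip angle, degrees.
#' @param tr_mt MT-weighted TR, seconds.
#' @param a_app,r1app Outputs of [compute_aapp()] and [compute_r1app()].
#' @return delta_app volume, NaN where `s_mt <= 0` or parents invalid.
#' @export
compute_delta_app <- function(s_mt, alpha_mt = 5, tr_mt = 0.024,
                              a_app, r1app) {
  stopifnot_same_grid(s_mt, a_app, r1app)
  a <- alpha_mt * pi / 180
  out <- (a_app * a / s_mt - 1) * r1app * tr_mt - a^2 / 2
  out[s_mt <= 0] <- NaN
  out
}

#' Compute all MTsat maps from a FLASH triplet
#'
#' Convenience wrapper chaining [compute_r1app()], [compute_aapp()] and
#' [compute_delta_app()].
#'
#' @param triplet A [flash_triplet()].
#' @return List with `r1app`, `a_app`, `delta_app`.
#' @export
mtsat_maps <- function(triplet) {
  r1 <- compute_r1app(triplet)
  a <- compute_aapp(triplet)
  d <- compute_delta_app(triplet$s_mt, triplet$alpha_mt * 180 / pi,
                         triplet$tr_mt, a, r1)
  list(r1app = r1, a_app = a, delta_app = d)
}

#' Double-angle B1 mapping
#'
#' Estimates the actual/nominal flip-angle ratio from two acquisitions at
#' nominal flip angles alpha and 2 alpha:
#' actual = arccos(S_2a / (2 S_a)), b1_scale = actual / alpha.
#' Voxels with the ratio outside (0, 1] (noise, background) are flagged and
#' fall back to b1 = 1 with a warning.
#'
#' @param s_low,s_high Signal volumes at the low and doubled flip angle.
#' @param alpha_low Nominal low flip angle, degrees (default 10).
#' @param smooth `"none"`, `"median"` (3x3 in-plane median filter) or
#'   `"polyfit"` (fit a quadratic polynomial in the voxel coordinates over
#'   `mask` and evaluate it everywhere). B1 fields are spatially smooth by
#'   physics, so smoothing the raw double-angle map is standard practice.
#' @param mask Logical volume of voxels trusted for `"polyfit"` smoothing
#'   (default: all unflagged voxels).
#' @return b1_scale volume (dimensionless) with attribute `flagged`, the
#'   logical volume of fallback voxels.
#' @export
estimate_b1 <- function(s_low, s_high, alpha_low = 10,
                        smooth = c("none", "median", "polyfit"),
                        mask = NULL) {
  smooth <- match.arg(smooth)
  stopifnot_same_grid(s_low, s_high)
  ratio <- s_high / (2 * s_low)
  bad <- !is.finite(ratio) | ratio <= 0 | s_low <= 0
  # arccos(1) = 0 is a degenerate (zero actual flip) domain boundary
  bad <- bad | ratio >= 1
  actual <- suppressWarnings(acos(pmin(pmax(ratio, -1), 1)))
  b1 <- actual / (alpha_low * pi / 180)
  b1[bad] <- 1
  if (any(bad & s_low > 0)) {
    warning("double-angle ratio out of (0, 1) in ",
            sum(bad & s_low > 0), " voxels; falling back to B1 = 1",
            call. = FALSE)
  }
  if (smooth == "median") {
    b1 <- median_filter3(b1)
  } else if (smooth == "polyfit") {
    fitmask <- if (is.null(mask)) !bad else (mask & !bad)
    b1 <- polyfit_field(b1, fitmask)
  }
  attr(b1, "flagged") <- bad
  b1
}

# Quadratic polynomial fit of a smooth field over masked voxels, evaluated
# on the whole grid.
polyfit_field <- function(x, mask, degree = 2) {
  d <- dim(x)
  idx <- which(mask)
  if (length(idx) < 10) return(x)
  co <- arrayInd(idx, d)
  basis <- function(co) {
    out <- cbind(1, co[, 1], co[, 2], co[, 3])
    if (degree >= 2) {
      out <- cbind(out, co[, 1]^2, co[, 2]^2, co[, 3]^2,
                   co[, 1] * co[, 2], co[, 1] * co[, 3], co[, 2] * co[, 3])
    }
    out
  }
  fit <- stats::lm.fit(basis(co), x[idx])
  all_co <- arrayInd(seq_len(prod(d)), d)
  pred <- basis(all_co) %*% ifelse(is.na(fit$coefficients), 0,
                                   fit$coefficients)
  array(pred, d)
}

median_filter3 <- function(x) {
  d <- dim(x)
  out <- x
  for (k in seq_len(d[3])) {
    sl <- x[, , k]
    f <- sl
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      ii <- max(1, i - 1):min(d[1], i + 1)
      jj <- max(1, j - 1):min(d[2], j + 1)
      f[i, j] <- stats::median(sl[ii, jj])
    }
    out[, , k] <- f
  }
  out
}

#' B1 correction of the apparent MT saturation
#'
#' Empirical linear-dilution correction from the MTsat literature:
#' delta_corr = delta_app (1 - C) / (1 - C b1_scale), with C = 0.4.
#' Identity at b1_scale = 1. The measured saturation falls roughly linearly
#' with the transmit field (slope -C/(1-C) near nominal), so the correction
#' factor grows with b1_scale to compensate. Voxels with b1_scale >= 1/C
#' (formula pole) are flagged invalid (NaN).
#'
#' @param delta_app Saturation volume from [compute_delta_app()].
#' @param b1_scale Actual/nominal flip-angle ratio volume, > 0.
#' @param C Correction coefficient (default 0.4).
#' @return Corrected saturation volume.
#' @export
correct_delta_b1 <- function(delta_app, b1_scale, C = 0.4) {
  stopifnot_same_grid(delta_app, b1_scale)
  if (any(b1_scale <= 0, na.rm = TRUE)) {
    stop("b1_scale must be positive", call. = FALSE)
  }
  out <- delta_app * (1 - C) / (1 - C * b1_scale)
  out[b1_scale >= 1 / C] <- NaN
  out
}

#' Calibrate MT saturation to myelin volume fraction via a g-ratio anchor
#'
#' Assumes a linear proportional relationship MVF = c * delta and solves for
#' the scalar c > 0 such that the mean aggregate g-ratio over a designated
#' calibration region (a homogeneous white-matter block standing in for the
#' corpus callosum) equals `g_target`. The region mean g is strictly
#' decreasing in c wherever delta > 0 and vic > 0, so the root is unique;
#' it is found by bracketed root finding on c in [1e-3, 100].
#'
#' @param delta Saturation volume (B1-corrected).
#' @param vic,viso NODDI volume-fraction maps on the same grid.
#' @param calib_mask Logical volume selecting the calibration region.
#' @param g_target Target mean g-ratio in the region (default 0.7).
#' @param bracket Search interval for c.
#' @return List with `c` (calibration factor), `mvf` (clamped c * delta over
#'   the whole volume), `achieved` (post-calibration region-mean g),
#'   `clamped_fraction` (QC: share of in-mask voxels clamped).
#' @export
calibrate_mvf <- function(delta, vic, viso, calib_mask, g_target = 0.7,
                          bracket = c(1e-3, 100)) {
  stopifnot_same_grid(delta, vic, viso, calib_mask)
  idx <- which(calib_mask & is.finite(delta) & is.finite(vic) &
                 is.finite(viso))
  if (length(idx) == 0) stop("calibration mask is empty", call. = FALSE)
  d <- delta[idx]; vi <- vic[idx]; vo <- viso[idx]
  mean_g <- function(c_) {
    mvf <- clamp01(c_ * d)
    avf <- (1 - mvf) * (1 - vo) * vi
    g <- sqrt(avf / (mvf + avf))
    mean(g, na.rm = TRUE)
  }
  g_lo <- mean_g(bracket[1])   # small c -> little myelin -> g near 1
  g_hi <- mean_g(bracket[2])
  if (!is.finite(g_lo) || !is.finite(g_hi) ||
      g_target > g_lo || g_target < g_hi) {
    stop(sprintf(paste0("g_target %.4f unreachable: attainable region-mean ",
                        "g range is [%.4f, %.4f]"),
                 g_target, g_hi, g_lo), call. = FALSE)
  }
  root <- stats::uniroot(function(c_) mean_g(c_) - g_target,
                         interval = bracket, tol = 1e-10)
  c_hat <- root$root
  mvf <- clamp01(c_hat * delta)
  list(c = c_hat, mvf = mvf, achieved = mean_g(c_hat),
       clamped_fraction = mean(c_hat * delta[idx] > 1 | delta[idx] < 0))
}
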