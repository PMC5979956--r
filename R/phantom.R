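# Digital spinal-cord phantom.
#
# A straight cylindrical cord (craniocaudal fibers) with a central gray-matter
# core, a white-matter annulus carrying left/right dorsal-column and lateral
# corticospinal tract territories, a surrounding CSF ring, and a separate
# homogeneous white-matter calibration block (standing in for the corpus
# callosum region used to anchor the MVF calibration). The atlas labels are
# generated jointly with the phantom on the same grid, i.e. a perfect
# registration stand-in.

#' Phantom configuration
#'
#' @param nx,ny,nz Grid size in voxels (in-plane 1 mm, 4 mm slices by
#'   default, matching a typical cervical-cord protocol).
#' @param voxel_mm Voxel dimensions, mm.
#' @param cord_radius,gm_radius Cord and gray-matter core radii, voxels.
#' @param csf_ring CSF ring thickness outside the cord, voxels.
#' @param level_slices Slice indices forming the analysis-level mask (the
#'   C3-level stand-in); default the middle slice.
#' @param tissue Named list of per-tissue ground-truth parameters (`wm`,
#'   `gm`, `csf`), each with `mvf`, `vic`, `viso`, `kappa`, `r1` (1/s) and
#'   `pd` (a.u.).
#' @param delta_per_mvf True MT saturation per unit MVF: the phantom's
#'   delta_true = mvf_true * delta_per_mvf (linear myelin-MTsat coupling).
#' @param b1_amp Amplitude of the linear left-right B1 gradient;
#'   b1_scale = 1 + b1_amp * 2 (x - cx) / nx. 0 gives a uniform B1 = 1.
#' @param b1_map_snr_factor SNR advantage of the B1-mapping EPI pair over
#'   the imaging acquisitions (default 32): B1 maps are acquired at much
#'   coarser resolution, so their effective per-(resampled-)voxel noise is
#'   lower by roughly the voxel-volume ratio.
#' @param mt_b1_exponent Exponent a in the transmit-field dependence of the
#'   deposited MT saturation, delta_eff = delta_true * b1^a (default 4/3).
#'   Combined with the 1/b1^2 readout bias of the saturation inversion this
#'   yields the residual linear B1 dependence with slope -C/(1-C), C = 0.4,
#'   that the empirical correction in [correct_delta_b1()] removes.
#' @param affected_side `"none"`, `"left"`, `"right"` or `"bilateral"`:
#'   which white-matter side carries the disease effect.
#' @param vic_reduction Relative reduction of vic_true on affected sides.
#' @param mvf_change Relative change of mvf_true on affected sides
#'   (default 0: myelin preserved).
#' @param snr Signal-to-noise ratio at which Rician noise is added (defined
#'   on the white-matter b = 0 / PD-weighted signal); `Inf` for noise-free.
#' @param protocol FLASH/B1 protocol: flip angles in degrees, TRs in
#'   seconds (PD/MT-weighted: TR 24 ms flip 5 deg; T1-weighted: TR 10 ms
#'   flip 13 deg; B1 double-angle pair 10/20 deg).
#' @param scheme A [diffusion_scheme()]; default 1 b=0 + 20 directions at
#'   each of b = 1000 and 2000 s/mm^2.
#' @param d_par,d_iso NODDI diffusivities used in the forward model, mm^2/s.
#' @param flash_model `"rational"` (analytic, exactly inverted by the MTsat
#'   equations) or `"exponential"` (realism mode, small bias).
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(nx = 18, ny = 18, nz = 3, voxel_mm = c(1, 1, 4),
                           cord_radius = 6.5, gm_radius = 2.3, csf_ring = 1.5,
                           level_slices = NULL,
                           tissue = list(
                             wm = list(mvf = 0.32, vic = 0.58, viso = 0.04,
                                       kappa = 24, r1 = 1.05, pd = 800),
                             gm = list(mvf = 0.14, vic = 0.45, viso = 0.08,
                                       kappa = 3, r1 = 0.85, pd = 850),
                             csf = list(mvf = 0, vic = 0, viso = 1,
                                        kappa = 0, r1 = 0.25, pd = 1000)
                           ),
                           delta_per_mvf = 1 / 16, b1_amp = 0.05,
                           b1_map_snr_factor = 32, mt_b1_exponent = 4 / 3,
                           affected_side = "none", vic_reduction = 0,
                           mvf_change = 0, snr = Inf,
                           protocol = list(alpha_pd = 5, alpha_t1 = 13,
                                           alpha_mt = 5, tr_pd = 0.024,
                                           tr_t1 = 0.010, tr_mt = 0.024,
                                           b1_angle = 10),
                           scheme = default_scheme(),
                           d_par = 1.7e-3, d_iso = 3.0e-3,
                           flash_model = "rational") {
  if (is.null(level_slices)) level_slices <- ceiling(nz / 2)
  if (!affected_side %in% c("none", "left", "right", "bilateral")) {
    stop("affected_side must be none/left/right/bilateral", call. = FALSE)
  }
  if (cord_radius + csf_ring >= min(nx, ny) / 2 - 0.5) {
    stop("grid too small for the requested cord + CSF geometry",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "phantom_config")
}

# Angular tract territories, degrees from the dorsal (+y) axis; the 3 degree
# midline gap keeps left and right labels disjoint at probability >= 0.5.
.tract_sectors <- list(
  fasciculus_gracilis = c(3, 28),
  fasciculus_cuneatus = c(30, 60),
  lateral_cst         = c(62, 110)
)

#' Tract names known to the synthetic atlas
#' @export
tract_names <- function() names(.tract_sectors)

#' Build the probabilistic left/right tract atlas for a phantom grid
#'
#' Probabilities are the fraction of 5x5 in-plane subvoxel samples falling in
#' the tract territory (an annular sector of the white-matter band), giving
#' soft edges like a real probabilistic atlas.
#'
#' @param config A [phantom_config()].
#' @return Object of class `tract_atlas`: `tracts[[name]][[side]]` are 3-D
#'   probability arrays, `level_mask` a logical array selecting the analysis
#'   level.
#' @export
make_atlas <- function(config) {
  cx <- (config$nx + 1) / 2
  cy <- (config$ny + 1) / 2
  r_in <- config$gm_radius + 0.2
  r_out <- config$cord_radius - 1.0
  sub <- (seq_len(5) - 3) / 5
  off <- expand.grid(dx = sub, dy = sub)
  dims <- c(config$nx, config$ny, config$nz)
  tracts <- lapply(.tract_sectors, function(sector) {
    lapply(c(left = "left", right = "right"), function(side) {
      p_slice <- matrix(0, config$nx, config$ny)
      for (i in seq_len(config$nx)) for (j in seq_len(config$ny)) {
        x <- i - cx + off$dx
        y <- j - cy + off$dy
        r <- sqrt(x^2 + y^2)
        ang <- atan2(x, y) * 180 / pi        # 0 at dorsal (+y)
        onside <- if (side == "left") ang < 0 else ang > 0
        inside <- r >= r_in & r <= r_out & onside &
          abs(ang) >= sector[1] & abs(ang) <= sector[2]
        p_slice[i, j] <- mean(inside)
      }
      array(rep(p_slice, config$nz), dim = dims)
    })
  })
  level_mask <- array(FALSE, dims)
  level_mask[, , config$level_slices] <- TRUE
  structure(list(tracts = tracts, level_mask = level_mask,
                 grid = dims), class = "tract_atlas")
}

# label codes for truth$labels
.label_codes <- c(background = 0, wm = 1, gm = 2, csf = 3, calib = 4)

#' Generate one digital spinal-cord phantom
#'
#' Simulates, on a single co-registered grid, the three FLASH volumes
#' (PD-, T1- and MT-weighted), the double-angle B1 mapping pair, and the
#' 41-volume two-shell diffusion series, from voxelwise ground truth that is
#' retained for recovery testing. Forward models are exactly those inverted
#' by the mapping modules.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return Object of class `spinal_phantom` with fields `flash_pd`,
#'   `flash_t1`, `flash_mt`, `b1_low`, `b1_high`, `dwi` (4-D array),
#'   `scheme`, `atlas`, `truth` and `masks`.
#' @export
generate_phantom <- function(config, seed = 1) {
  if (!inherits(config, "phantom_config")) {
    stop("config must be a phantom_config()", call. = FALSE)
  }
  dims <- c(config$nx, config$ny, config$nz)
  if (length(config$scheme$bvals) < 7) {
    stop("diffusion scheme too small to support tensor initialization",
         call. = FALSE)
  }
  cx <- (config$nx + 1) / 2
  cy <- (config$ny + 1) / 2
  xg <- array(rep(seq_len(config$nx), times = config$ny * config$nz), dims)
  yg <- array(rep(rep(seq_len(config$ny), each = config$nx), config$nz), dims)
  r <- sqrt((xg - cx)^2 + (yg - cy)^2)

  labels <- array(.label_codes[["background"]], dims)
  labels[r <= config$cord_radius + config$csf_ring] <- .label_codes[["csf"]]
  labels[r <= config$cord_radius] <- .label_codes[["wm"]]
  labels[r <= config$gm_radius] <- .label_codes[["gm"]]
  # calibration block: homogeneous WM square in a cord-free corner
  cal <- array(FALSE, dims)
  cal[1:3, 1:3, ] <- TRUE
  labels[cal] <- .label_codes[["calib"]]
  side <- array(0L, dims)           # -1 left, +1 right (of the cord)
  side[xg < cx] <- -1L
  side[xg > cx] <- 1L

  # ground-truth parameter maps
  truth <- list()
  for (fld in c("mvf", "vic", "viso", "kappa", "r1", "pd")) {
    m <- array(0, dims)
    m[labels == .label_codes[["wm"]]] <- config$tissue$wm[[fld]]
    m[labels == .label_codes[["calib"]]] <- config$tissue$wm[[fld]]
    m[labels == .label_codes[["gm"]]] <- config$tissue$gm[[fld]]
    m[labels == .label_codes[["csf"]]] <- config$tissue$csf[[fld]]
    truth[[fld]] <- m
  }
  # disease effect: axon loss (vic down), myelin optionally changed, on the
  # affected white-matter side(s)
  aff <- array(FALSE, dims)
  if (config$affected_side %in% c("left", "bilateral")) {
    aff[labels == .label_codes[["wm"]] & side < 0] <- TRUE
  }
  if (config$affected_side %in% c("right", "bilateral")) {
    aff[labels == .label_codes[["wm"]] & side > 0] <- TRUE
  }
  truth$vic[aff] <- truth$vic[aff] * (1 - config$vic_reduction)
  truth$mvf[aff] <- truth$mvf[aff] * (1 - config$mvf_change)
  truth$delta <- truth$mvf * config$delta_per_mvf
  truth$b1 <- 1 + config$b1_amp * 2 * (xg - cx) / config$nx
  truth$fiber_dir <- c(0, 0, 1)     # craniocaudal, uniform
  truth$labels <- labels
  truth$side <- side
  truth$affected <- aff
  stopifnot(all(truth$mvf +
                  (1 - truth$mvf) * (1 - truth$viso) * truth$vic <= 1 + 1e-12))

  p <- config$protocol
  deg <- pi / 180
  tis <- labels > 0
  b1 <- truth$b1
  sim_flash <- function(alpha_deg, tr, delta) {
    s <- array(0, dims)
    s[tis] <- flash_mt_forward(truth$pd[tis], truth$r1[tis], delta[tis],
                               alpha = b1[tis] * alpha_deg * deg, tr = tr,
                               model = config$flash_model)
    s
  }
  zero <- array(0, dims)
  flash_pd <- sim_flash(p$alpha_pd, p$tr_pd, zero)
  flash_t1 <- sim_flash(p$alpha_t1, p$tr_t1, zero)
  # deposited saturation scales with the transmit field
  delta_eff <- truth$delta * b1^config$mt_b1_exponent
  flash_mt <- sim_flash(p$alpha_mt, p$tr_mt, delta_eff)
  b1_low <- array(0, dims); b1_high <- array(0, dims)
  b1_low[tis] <- truth$pd[tis] * sin(b1[tis] * p$b1_angle * deg)
  b1_high[tis] <- truth$pd[tis] * sin(b1[tis] * 2 * p$b1_angle * deg)

  # diffusion series: voxels sharing a parameter tuple share a signal vector
  nvol <- length(config$scheme$bvals)
  dwi <- array(0, c(dims, nvol))
  key <- paste(signif(truth$vic, 10), signif(truth$viso, 10),
               signif(truth$kappa, 10), signif(truth$pd, 10))
  key[!tis] <- NA
  for (k in unique(key[tis])) {
    vox <- which(!is.na(key) & key == k)
    i1 <- vox[1]
    sig <- noddi_forward(list(vic = truth$vic[i1], viso = truth$viso[i1],
                              kappa = truth$kappa[i1], dir = truth$fiber_dir),
                         config$scheme, config$d_par, config$d_iso)
    for (v in seq_len(nvol)) {
      plane <- dwi[, , , v, drop = FALSE]
      plane[vox] <- truth$pd[i1] * sig[v]
      dwi[, , , v] <- plane
    }
  }

  # Rician noise: sigma = (WM reference signal) / SNR per modality
  if (is.finite(config$snr)) {
    wm_ref_dwi <- config$tissue$wm$pd
    wm_ref_flash <- flash_mt_forward(config$tissue$wm$pd,
                                     config$tissue$wm$r1, 0,
                                     alpha = p$alpha_pd * deg, tr = p$tr_pd)
    sf <- wm_ref_flash / config$snr
    sd_ <- wm_ref_dwi / config$snr
    flash_pd <- add_rician_noise(flash_pd, sf, derive_seed(seed, 11))
    flash_t1 <- add_rician_noise(flash_t1, sf, derive_seed(seed, 12))
    flash_mt <- add_rician_noise(flash_mt, sf, derive_seed(seed, 13))
    sb1 <- sd_ / config$b1_map_snr_factor
    b1_low <- add_rician_noise(b1_low, sb1, derive_seed(seed, 14))
    b1_high <- add_rician_noise(b1_high, sb1, derive_seed(seed, 15))
    dwi <- add_rician_noise(dwi, sd_, derive_seed(seed, 16))
  }

  masks <- list(
    cord = labels %in% .label_codes[c("wm", "gm")],
    wm = labels == .label_codes[["wm"]],
    gm = labels == .label_codes[["gm"]],
    csf = labels == .label_codes[["csf"]],
    calib = labels == .label_codes[["calib"]]
  )
  masks <- lapply(masks, function(m) array(m, dims))

  structure(list(flash_pd = flash_pd, flash_t1 = flash_t1,
                 flash_mt = flash_mt, b1_low = b1_low, b1_high = b1_high,
                 dwi = dwi, scheme = config$scheme, atlas = make_atlas(config),
                 truth = truth, masks = masks, config = config, seed = seed),
            class = "spinal_phantom")
}

#' Cohort specification
#'
#' @param n_patients,n_controls Subject counts (>= 0, total > 0).
#' @param laterality Character vector, one of `"left"`, `"right"`,
#'   `"bilateral"` per patient. Default: 11 left, 2 right, 7 bilateral
#'   (27 affected / 13 unaffected sides; controls contribute 2 sides each).
#' @param affected_avf_reduction Relative reduction of vic_true (hence AVF)
#'   in affected-side white matter, in \[0, 1).
#' @param mvf_change Relative MVF change on affected sides (default 0:
#'   myelin preserved).
#' @param snr SNR of the simulated acquisitions (default 30).
#' @param seed Master seed.
#' @param base_config [phantom_config()] shared by all subjects.
#' @param subject_cv Between-subject coefficient of variation applied to the
#'   white-matter vic, mvf, r1 and pd truths (biological variability).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 20, n_controls = 5,
                        laterality = c(rep("left", 11), rep("right", 2),
                                       rep("bilateral", 7)),
                        affected_avf_reduction = 0.15, mvf_change = 0,
                        snr = 30, seed = 1,
                        base_config = phantom_config(),
                        subject_cv = 0.03) {
  if (n_patients < 0 || n_controls < 0) stop("counts must be >= 0")
  if (n_patients + n_controls == 0) stop("empty cohort", call. = FALSE)
  if (length(laterality) != n_patients) {
    stop("laterality must have one entry per patient", call. = FALSE)
  }
  if (affected_avf_reduction < 0 || affected_avf_reduction >= 1) {
    stop("affected_avf_reduction must be in [0, 1)", call. = FALSE)
  }
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a cohort of phantoms with a patient/control structure
#'
#' Patients carry the affected-side axon loss defined by the spec; controls
#' are unaffected. Each subject gets independently jittered white-matter
#' truths (between-subject variability) and an independent noise stream, all
#' derived from the single master seed.
#'
#' @param spec A [cohort_spec()].
#' @return List with `subjects` (named list of [generate_phantom()] outputs),
#'   `metadata` (one row per subject: subject_id, group, laterality, mJOA,
#'   n_levels) and `sides` (one row per spinal-cord side with its group
#'   label: affected / unaffected / control).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec()")
  ids <- c(sprintf("P%02d", seq_len(spec$n_patients)),
           sprintf("C%02d", seq_len(spec$n_controls)))
  groups <- c(rep("patient", spec$n_patients),
              rep("control", spec$n_controls))
  lat <- c(spec$laterality, rep("none", spec$n_controls))

  subjects <- vector("list", length(ids))
  names(subjects) <- ids
  meta <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sseed <- derive_seed(spec$seed, 100, i)
    jit <- with_seed(derive_seed(sseed, 1), stats::rnorm(5, 0, spec$subject_cv))
    cfg <- spec$base_config
    wm <- cfg$tissue$wm
    wm$vic <- min(wm$vic * (1 + jit[1]), 0.95)
    wm$mvf <- min(wm$mvf * (1 + jit[2]), 0.9)
    wm$r1 <- wm$r1 * (1 + jit[3])
    wm$pd <- wm$pd * (1 + jit[4])
    wm$viso <- min(max(wm$viso * (1 + jit[5]), 0), 0.5)
    cfg$tissue$wm <- wm
    cfg$affected_side <- if (groups[i] == "patient") lat[i] else "none"
    cfg$vic_reduction <- if (groups[i] == "patient")
      spec$affected_avf_reduction else 0
    cfg$mvf_change <- if (groups[i] == "patient") spec$mvf_change else 0
    cfg$snr <- spec$snr
    subjects[[i]] <- generate_phantom(cfg, seed = derive_seed(sseed, 2))
    mjoa <- if (groups[i] == "patient") {
      min(max(round(with_seed(derive_seed(sseed, 3),
                              stats::rnorm(1, 15.6, 1.6))), 0), 18)
    } else NA_real_
    nlev <- if (groups[i] == "patient") {
      with_seed(derive_seed(sseed, 4), sample(1:3, 1))
    } else 0L
    meta[[i]] <- data.frame(subject_id = ids[i], group = groups[i],
                            laterality = lat[i], mjoa = mjoa,
                            n_levels = nlev, stringsAsFactors = FALSE)
  }
  metadata <- do.call(rbind, meta)
  sides <- side_assignments(metadata)
  list(subjects = subjects, metadata = metadata, sides = sides)
}

#' Per-side group assignment from subject metadata
#'
#' Unilateral patients contribute one affected and one unaffected side;
#' bilateral patients two affected sides; controls two control sides.
#'
#' @param metadata Data frame with `subject_id`, `group`, `laterality`.
#' @return Data frame with one row per (subject, side) and a `side_group`
#'   column in {affected, unaffected, control}.
#' @export
side_assignments <- function(metadata) {
  need <- c("subject_id", "group", "laterality")
  if (!all(need %in% names(metadata))) {
    stop("metadata must have subject_id, group, laterality", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(metadata)), function(i) {
    m <- metadata[i, ]
    sg <- if (m$group == "control") {
      c(left = "control", right = "control")
    } else if (m$laterality == "bilateral") {
      c(left = "affected", right = "affected")
    } else if (m$laterality == "left") {
      c(left = "affected", right = "unaffected")
    } else if (m$laterality == "right") {
      c(left = "unaffected", right = "affected")
    } else {
      stop("missing side assignment for patient ", m$subject_id,
           call. = FALSE)
    }
    data.frame(subject_id = m$subject_id, side = names(sg), side_group = sg,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
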