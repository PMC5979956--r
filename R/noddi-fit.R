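# Voxelwise NODDI fitting: b0 normalization, log-linear tensor
# initialization of the fiber direction, coarse grid search over
# (vic, viso, ODI), then bounded nonlinear refinement on transformed
# parameters (logit for the fractions, log for kappa, spherical angles for
# the direction). Fully deterministic: no unseeded randomness anywhere.

#' NODDI fitting options
#'
#' @param d_par Intrinsic parallel diffusivity, mm^2/s (default 1.7e-3, the
#'   standard brain parameterization; override for cord-specific values).
#' @param d_iso Free-water diffusivity, mm^2/s (default 3.0e-3).
#' @param grid_depth Grid points per axis of the (vic, viso, ODI) search
#'   lattice (default 8, i.e. an 8x8x8 lattice).
#' @param kappa_max Upper bound on the Watson concentration in the
#'   refinement (default 128).
#' @param refine_dir If `TRUE` (default) the fiber direction is refined
#'   jointly with the scalar parameters; if `FALSE` it stays fixed at the
#'   tensor initialization (faster).
#' @param eval_max,iter_max Optimizer budget per voxel.
#' @return List of class `noddi_options`.
#' @export
noddi_options <- function(d_par = 1.7e-3, d_iso = 3.0e-3, grid_depth = 8,
                          kappa_max = 128, refine_dir = TRUE,
                          eval_max = 300, iter_max = 150) {
  structure(as.list(environment()), class = "noddi_options")
}

#' Log-linear diffusion tensor fit for initialization
#'
#' Weighted linear least squares on log signals (weights proportional to the
#' signal, the usual variance stabilization), returning the principal
#' eigenvector and an FA-like anisotropy per voxel. Used only to initialize
#' the nonlinear NODDI fit.
#'
#' @param dwi 4-D array (x, y, z, volume).
#' @param scheme A [diffusion_scheme()].
#' @param mask Logical 3-D array of voxels to fit.
#' @return List with `dir` (n_voxel x 3 matrix, antipodally resolved to
#'   non-negative z), `fa` (anisotropy vector), `voxels` (linear indices).
#' @export
tensor_init <- function(dwi, scheme, mask) {
  vox <- which(mask)
  if (length(vox) == 0) stop("mask is empty", call. = FALSE)
  b <- scheme$bvals
  g <- scheme$bvecs
  X <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  if (qr(X[!scheme$b0, , drop = FALSE])$rank < 7) {
    stop("diffusion scheme is rank-deficient for a tensor fit ",
         "(need >= 6 non-collinear b > 0 directions)", call. = FALSE)
  }
  nvol <- length(b)
  dmat <- matrix(aperm(dwi, c(4, 1, 2, 3)), nrow = nvol)[, vox, drop = FALSE]
  dir <- matrix(0, length(vox), 3)
  fa <- numeric(length(vox))
  for (i in seq_along(vox)) {
    y <- dmat[, i]
    ok <- y > 0
    if (sum(ok) < 7) { dir[i, ] <- c(0, 0, 1); fa[i] <- NA_real_; next }
    w <- y[ok]                      # weight ~ signal
    fit <- stats::lm.wfit(X[ok, , drop = FALSE], log(y[ok]), w^2)
    D <- matrix(c(fit$coefficients[2], fit$coefficients[5],
                  fit$coefficients[6], fit$coefficients[5],
                  fit$coefficients[3], fit$coefficients[7],
                  fit$coefficients[6], fit$coefficients[7],
                  fit$coefficients[4]), 3, 3)
    e <- eigen(D, symmetric = TRUE)
    ev <- e$values
    md <- mean(ev)
    fa[i] <- sqrt(3 / 2) * sqrt(sum((ev - md)^2) / max(sum(ev^2), 1e-30))
    v <- e$vectors[, 1]
    if (v[3] < 0) v <- -v           # antipodal convention: z >= 0
    dir[i, ] <- v
  }
  list(dir = dir, fa = fa, voxels = vox)
}

# Per-scheme shell bookkeeping precomputed once per fit: volume indices,
# stick-response Legendre coefficients and free-water attenuation per shell.
.shell_data <- function(scheme, d_par, d_iso) {
  lapply(scheme$shells, function(shell) {
    idx <- which(!scheme$b0 & abs(scheme$bvals - shell) <= 50)
    list(b = shell, idx = idx,
         h = (2 * (0:.watson_L) + 1) / 2 *
           stick_response_coefs(shell * d_par),
         iso = exp(-shell * d_iso))
  })
}

# Objective + analytic gradient for one voxel's refinement, on transformed
# parameters p = (logit vic, logit viso, log kappa[, theta, phi]). A small
# closure cache shares the forward computation between the objective and
# gradient calls that nlminb makes at the same point.
.noddi_engine <- function(y, shells, bvecs, cosang0, dpar, refine_dir,
                          sse_b0) {
  last_p <- NULL
  last <- NULL
  compute <- function(p) {
    vic <- inv_logit(p[1]); viso <- inv_logit(p[2]); kap <- exp(p[3])
    if (refine_dir) {
      st <- sin(p[4]); ct <- cos(p[4]); sp <- sin(p[5]); cp <- cos(p[5])
      cs_all <- as.vector(bvecs %*% c(st * cp, st * sp, ct))
      dcs_th <- as.vector(bvecs %*% c(ct * cp, ct * sp, -st))
      dcs_ph <- as.vector(bvecs %*% c(-st * sp, st * cp, 0))
    } else cs_all <- cosang0
    wi <- watson_internals(kap, deriv = TRUE)
    sse <- sse_b0
    g <- numeric(length(p))
    for (sh in shells) {
      cs <- cs_all[sh$idx]
      c2 <- cs * cs
      ev <- eval_even_series_d(wi$ratio * sh$h, c2)
      a_ic <- ev$v
      da_dk <- eval_even_series(wi$dratio * sh$h, c2)
      q <- wi$tau * c2 + (1 - wi$tau) * (1 - c2) / 2
      dperp <- dpar * (1 - vic)
      a_ec <- exp(-sh$b * (dperp + (dpar - dperp) * q))
      s <- (1 - viso) * (vic * a_ic + (1 - vic) * a_ec) + viso * sh$iso
      r <- s - y[sh$idx]
      sse <- sse + sum(r * r)
      ds_vic <- (1 - viso) *
        (a_ic - a_ec + (1 - vic) * a_ec * sh$b * dpar * (1 - q))
      ds_viso <- sh$iso - (vic * a_ic + (1 - vic) * a_ec)
      ds_kap <- (1 - viso) * (vic * da_dk -
        (1 - vic) * a_ec * sh$b * dpar * vic *
          wi$dtau * (c2 - (1 - c2) / 2))
      g[1] <- g[1] + 2 * sum(r * ds_vic) * vic * (1 - vic)
      g[2] <- g[2] + 2 * sum(r * ds_viso) * viso * (1 - viso)
      g[3] <- g[3] + 2 * sum(r * ds_kap) * kap
      if (refine_dir) {
        ds_c2 <- (1 - viso) * (vic * ev$d -
          (1 - vic) * a_ec * sh$b * dpar * vic *
            (wi$tau - (1 - wi$tau) / 2))
        common <- 4 * r * ds_c2 * cs
        g[4] <- g[4] + sum(common * dcs_th[sh$idx])
        g[5] <- g[5] + sum(common * dcs_ph[sh$idx])
      }
    }
    list(sse = sse, grad = g)
  }
  get_at <- function(p) {
    if (is.null(last_p) || !identical(p, last_p)) {
      last <<- compute(p)
      last_p <<- p
    }
    last
  }
  list(obj = function(p) get_at(p)$sse,
       grad = function(p) get_at(p)$grad)
}

#' Fit the NODDI model voxelwise
#'
#' Per voxel, minimizes the least-squares misfit between the b0-normalized
#' signal and the three-compartment forward model over (vic, viso, kappa,
#' direction). Initialization: principal eigenvector of a weighted
#' log-linear tensor fit for the direction, and the best cell of a
#' `grid_depth`^3 lattice over (vic, viso, ODI); refinement by `nlminb` on
#' transformed parameters.
#'
#' @param dwi 4-D array (x, y, z, volume) of diffusion signals.
#' @param scheme A [diffusion_scheme()]; must have >= 2 shells.
#' @param mask Logical 3-D array selecting voxels to fit.
#' @param options A [noddi_options()].
#' @return Object of class `noddi_maps`: 3-D arrays `vic`, `viso`, `odi`,
#'   `kappa`, `rmse` (NaN outside the mask / invalid voxels), 4-D `dir`,
#'   and logical arrays `invalid` (mean b0 <= 0) and `non_identifiable`
#'   (viso > 0.95: vic carries no signal, e.g. pure CSF).
#' @export
fit_noddi <- function(dwi, scheme, mask, options = noddi_options()) {
  dims <- dim(dwi)[1:3]
  if (dim(dwi)[4] != length(scheme$bvals)) {
    stop("dwi volume count does not match the scheme", call. = FALSE)
  }
  if (length(scheme$shells) < 2) {
    stop("NODDI needs at least 2 b > 0 shells", call. = FALSE)
  }
  vox <- which(mask)
  if (length(vox) == 0) stop("mask is empty", call. = FALSE)

  nvol <- length(scheme$bvals)
  dmat <- matrix(aperm(dwi, c(4, 1, 2, 3)), nrow = nvol)[, vox, drop = FALSE]
  b0_mean <- colMeans(dmat[scheme$b0, , drop = FALSE])
  valid <- b0_mean > 0
  ti <- tensor_init(dwi, scheme, mask)

  gd <- options$grid_depth
  gridv <- seq_len(gd) / (gd + 1)
  odi_grid <- gridv
  kappa_grid <- 1 / tan(odi_grid * pi / 2)
  shells <- .shell_data(scheme, options$d_par, options$d_iso)
  # Watson internals and series coefficients for the kappa lattice are
  # voxel-independent: compute once per fit.
  wi_grid <- lapply(kappa_grid, watson_internals)
  coef_grid <- lapply(wi_grid, function(wi) {
    lapply(shells, function(sh) wi$ratio * sh$h)
  })

  maps <- list(vic = array(NaN, dims), viso = array(NaN, dims),
               odi = array(NaN, dims), kappa = array(NaN, dims),
               rmse = array(NaN, dims),
               dir = array(NaN, c(dims, 3)),
               invalid = array(FALSE, dims),
               non_identifiable = array(FALSE, dims))
  maps$invalid[vox[!valid]] <- TRUE

  dpar <- options$d_par
  for (i in seq_along(vox)) {
    if (!valid[i]) next
    y <- dmat[, i] / b0_mean[i]
    dir0 <- ti$dir[i, ]
    cosang <- as.vector(scheme$bvecs %*% dir0)

    # coarse lattice search. For fixed kappa and direction the model is
    # affine in viso: m = T(vic) - viso * (T(vic) - iso), so the SSE over
    # the whole (vic, viso) plane reduces to three quadratic-form vectors.
    best <- NULL; best_sse <- Inf
    sse_b0 <- sum((1 - y[scheme$b0])^2)
    for (ik in seq_along(kappa_grid)) {
      kap <- kappa_grid[ik]
      tau <- wi_grid[[ik]]$tau
      A <- B <- C <- numeric(gd)     # per-vic accumulators across shells
      for (is in seq_along(shells)) {
        sh <- shells[[is]]
        cs <- cosang[sh$idx]
        a_ic <- eval_even_series(coef_grid[[ik]][[is]], cs * cs)
        ang <- tau * cs^2 + (1 - tau) * (1 - cs^2) / 2
        d_perp <- dpar * (1 - gridv)
        # extra-neurite factor for each vic on the grid: n_idx x gd
        Eec <- exp(-sh$b * (matrix(d_perp, length(sh$idx), gd,
                                   byrow = TRUE) +
                              outer(ang, dpar - d_perp)))
        Tm <- a_ic %o% gridv + Eec * matrix(1 - gridv, length(sh$idx), gd,
                                            byrow = TRUE)
        R1 <- Tm - y[sh$idx]         # residual at viso = 0
        U <- Tm - sh$iso
        A <- A + colSums(R1^2)
        B <- B + colSums(R1 * U)
        C <- C + colSums(U^2)
      }
      # sse(vic, viso) = A - 2 viso B + viso^2 C  (gd x gd)
      sse_k <- sse_b0 + outer(A, rep(1, gd)) -
        2 * outer(B, gridv) + outer(C, gridv^2)
      m <- arrayInd(which.min(sse_k), dim(sse_k))
      if (sse_k[m] < best_sse) {
        best_sse <- sse_k[m]
        best <- c(gridv[m[1]], gridv[m[2]], kap)
      }
    }

    # bounded refinement on transformed parameters with analytic gradient
    th0 <- acos(min(max(dir0[3], -1), 1))
    ph0 <- atan2(dir0[2], dir0[1])
    kmax <- options$kappa_max
    par0 <- c(logit(best[1]), logit(best[2]),
              log(min(max(best[3], 1e-3), kmax)))
    lower <- c(-12, -12, log(1e-3))
    upper <- c(12, 12, log(kmax))
    if (options$refine_dir) {
      par0 <- c(par0, th0, ph0)
      lower <- c(lower, -Inf, -Inf)
      upper <- c(upper, Inf, Inf)
    }
    eng <- .noddi_engine(y, shells, scheme$bvecs, cosang, dpar,
                         options$refine_dir, sse_b0)
    fit <- stats::nlminb(par0, eng$obj, gradient = eng$grad,
                         lower = lower, upper = upper,
                         control = list(eval.max = options$eval_max,
                                        iter.max = options$iter_max))
    p <- fit$par
    vic <- inv_logit(p[1]); viso <- inv_logit(p[2])
    kap <- min(exp(p[3]), kmax)
    d <- if (options$refine_dir) {
      c(sin(p[4]) * cos(p[5]), sin(p[4]) * sin(p[5]), cos(p[4]))
    } else dir0
    if (d[3] < 0) d <- -d
    v <- vox[i]
    maps$vic[v] <- vic
    maps$viso[v] <- viso
    maps$kappa[v] <- kap
    maps$odi[v] <- (2 / pi) * atan(1 / kap)
    maps$rmse[v] <- sqrt(fit$objective / nvol)
    maps$dir[v] <- d[1]
    maps$dir[v + prod(dims)] <- d[2]
    maps$dir[v + 2 * prod(dims)] <- d[3]
    if (viso > 0.95) maps$non_identifiable[v] <- TRUE
  }
  structure(maps, class = "noddi_maps")
}
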