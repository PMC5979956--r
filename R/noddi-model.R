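#' Three-compartment NODDI signal model (forward)
#'
#' Normalized diffusion signal for the neurite orientation dispersion and
#' density model: a Watson-dispersed stick (intra-neurite, volume fraction
#' `vic` of the tissue compartment), a tortuosity-coupled anisotropic
#' Gaussian (extra-neurite), and free isotropic water (`viso`):
#'
#'   S = (1 - viso) * (vic * A_ic + (1 - vic) * A_ec) + viso * exp(-b d_iso)
#'
#' with extra-neurite perpendicular diffusivity d_perp = d_par (1 - vic)
#' (tortuosity) and the extra-neurite tensor averaged over the same Watson
#' orientation distribution as the sticks.
#'
#' @param params List with `vic`, `viso` (fractions in \[0,1\]), `kappa`
#'   (Watson concentration >= 0) and `dir` (unit 3-vector, mean fiber
#'   direction).
#' @param scheme A [diffusion_scheme()].
#' @param d_par Intrinsic parallel diffusivity, mm^2/s (default 1.7e-3).
#' @param d_iso Free-water diffusivity, mm^2/s (default 3.0e-3).
#' @return Normalized signal vector, one value per scheme volume; exactly 1
#'   for b = 0 volumes.
#' @export
noddi_forward <- function(params, scheme, d_par = 1.7e-3, d_iso = 3.0e-3) {
  vic <- params$vic; viso <- params$viso; kappa <- params$kappa
  dir <- params$dir
  stopifnot(vic >= 0, vic <= 1, viso >= 0, viso <= 1, kappa >= 0)
  dir <- dir / sqrt(sum(dir^2))
  b <- scheme$bvals
  cosang <- as.vector(scheme$bvecs %*% dir)
  tau <- watson_tau(kappa)
  d_perp <- d_par * (1 - vic)
  s <- numeric(length(b))
  s[scheme$b0] <- 1
  for (shell in scheme$shells) {
    idx <- which(!scheme$b0 & abs(b - shell) <= 50)
    c_sh <- cosang[idx]
    a_ic <- watson_kernel(kappa, shell, d_par, c_sh)
    # Watson-averaged extra-neurite tensor: g' <D> g
    gdg <- d_perp + (d_par - d_perp) *
      (tau * c_sh^2 + (1 - tau) * (1 - c_sh^2) / 2)
    a_ec <- exp(-shell * gdg)
    s[idx] <- (1 - viso) * (vic * a_ic + (1 - vic) * a_ec) +
      viso * exp(-shell * d_iso)
  }
  s
}
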