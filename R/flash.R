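#' FLASH steady-state signal with MT saturation
#'
#' Forward model for a spoiled gradient-echo (FLASH) acquisition in the
#' small-flip-angle regime, with an optional per-TR magnetization-transfer
#' saturation `delta`:
#'
#'   S = pd * alpha * r1 * tr / (r1 * tr + alpha^2 / 2 + delta)
#'
#' Setting `delta = 0` gives the usual rational FLASH approximation used for
#' the PD- and T1-weighted volumes. This rational form is exactly the algebra
#' inverted by the MTsat mapping equations, so noise-free round trips are
#' exact. `model = "exponential"` instead uses the exact spoiled steady state
#' S = pd sin(a) (1 - E1) / (1 - cos(a) (1 - delta) E1), E1 = exp(-tr r1),
#' a realism mode that introduces a small, documented bias in the inversion.
#'
#' @param pd Signal amplitude (proton density x receive gain), a.u.
#' @param r1 Longitudinal relaxation rate, 1/s.
#' @param delta MT saturation per TR (dimensionless fraction), default 0.
#' @param alpha Excitation flip angle in radians (small-angle regime).
#' @param tr Repetition time, seconds; must be > 0.
#' @param model `"rational"` (default) or `"exponential"`.
#' @return Signal, same shape as the broadcast inputs.
#' @export
flash_mt_forward <- function(pd, r1, delta = 0, alpha, tr,
                             model = c("rational", "exponential")) {
  model <- match.arg(model)
  if (any(tr <= 0)) stop("tr must be positive", call. = FALSE)
  if (any(alpha <= 0 | alpha >= pi / 2)) {
    stop("alpha must be in (0, pi/2) radians", call. = FALSE)
  }
  if (model == "rational") {
    pd * alpha * r1 * tr / (r1 * tr + alpha^2 / 2 + delta)
  } else {
    e1 <- exp(-tr * r1)
    pd * sin(alpha) * (1 - e1) / (1 - cos(alpha) * (1 - delta) * e1)
  }
}

#' Add Rician noise to magnitude MR data
#'
#' Magnitude MRI noise model: the output is `|x + n1 + i n2|` with n1, n2
#' independent Gaussian(0, sigma). `sigma = 0` returns the input unchanged
#' (bit for bit). The caller's RNG state is not disturbed.
#'
#' @param x Numeric vector/array of noise-free magnitudes.
#' @param sigma Noise scale (Gaussian SD per channel), >= 0.
#' @param seed Integer seed for the draw.
#' @return Noisy magnitudes, same shape as `x`.
#' @export
add_rician_noise <- function(x, sigma, seed) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(x)
  with_seed(seed, {
    n <- length(x)
    re <- x + stats::rnorm(n, 0, sigma)
    im <- stats::rnorm(n, 0, sigma)
    out <- sqrt(re^2 + im^2)
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  })
}
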