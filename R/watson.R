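# Watson-dispersed stick response.
#
# The intra-neurite compartment is a stick (zero perpendicular diffusivity)
# whose orientation n follows a Watson distribution W(n) ~ exp(kappa (mu.n)^2)
# about the mean fiber direction mu. The measured attenuation for a gradient
# direction g is the spherical average
#
#   A(kappa, t, c) = E_W[ exp(-t (g.n)^2) ],   t = b * d_par,  c = mu.g.
#
# By the Funk-Hecke theorem this is an even-order Legendre series
#
#   A = sum_l (2l+1)/2 * [G_l(kappa)/G_0(kappa)] * H_l(t) * P_l(c)
#
# with G_l(a) = int_{-1}^{1} e^{a x^2} P_l(x) dx and H_l(t) = G_l(-t). The
# H_l of the smooth kernel e^{-t x^2} decay super-geometrically, so the series
# truncated at l = 24 is exact to machine precision for clinical b-values at
# ANY kappa (including the stick limit), provided the coefficient ratios
# G_l/G_0 are computed stably. They are evaluated by fixed Gauss-Legendre
# quadrature on the overflow-free integrand e^{kappa (x^2-1)}; for very large
# kappa the integrand collapses into boundary layers at x = +/-1 and a
# Gauss-Laguerre form in s = kappa (1 - x^2) is used instead.

.watson_L <- 24L
.watson_even <- seq(1L, .watson_L + 1L, by = 2L)
.watson_odd <- seq(2L, .watson_L + 1L, by = 2L)

.watson_cache <- new.env(parent = emptyenv())

# Legendre polynomials P_0..P_L at x (vector) via the three-term recurrence.
legendre_table <- function(x, L = .watson_L) {
  out <- matrix(0, length(x), L + 1)
  out[, 1] <- 1
  if (L >= 1) out[, 2] <- x
  if (L >= 2) for (l in 1:(L - 1)) {
    out[, l + 2] <- ((2 * l + 1) * x * out[, l + 1] - l * out[, l]) / (l + 1)
  }
  out
}

watson_nodes <- function() {
  if (is.null(.watson_cache$gl)) {
    gl <- pracma::gaussLegendre(200, 0, 1)
    .watson_cache$gl <- gl
    .watson_cache$P_gl <- legendre_table(gl$x)
    lag <- pracma::gaussLaguerre(48)
    .watson_cache$lag <- lag
    # monomial coefficients of P_0..P_L: M[l+1, k+1] is the x^k coefficient
    M <- matrix(0, .watson_L + 1, .watson_L + 1)
    M[1, 1] <- 1
    M[2, 2] <- 1
    for (l in 1:(.watson_L - 1)) {
      M[l + 2, ] <- ((2 * l + 1) * c(0, M[l + 1, -(.watson_L + 1)]) -
                       l * M[l, ]) / (l + 1)
    }
    .watson_cache$mono <- M
  }
  .watson_cache
}

# Evaluate an even-order Legendre series sum coef_l P_l(c) at |c| <= 1 by
# converting to a polynomial in c^2 and applying Horner's scheme. For the
# smooth kernels used here (degree <= 24) this is both faster and amply
# accurate; the series is dominated by the super-geometric decay of the
# stick-response coefficients.
eval_even_series <- function(coef, c2) {
  mono <- as.vector(crossprod(watson_nodes()$mono, coef))
  b <- mono[.watson_even]   # even powers only
  acc <- rep(b[length(b)], length(c2))
  for (j in (length(b) - 1):1) acc <- acc * c2 + b[j]
  acc
}

# As eval_even_series but also returns the derivative with respect to c^2.
eval_even_series_d <- function(coef, c2) {
  mono <- as.vector(crossprod(watson_nodes()$mono, coef))
  b <- mono[.watson_even]
  n <- length(b)
  acc <- rep(b[n], length(c2))
  dacc <- numeric(length(c2))
  for (j in (n - 1):1) {
    dacc <- dacc * c2 + acc
    acc <- acc * c2 + b[j]
  }
  list(v = acc, d = dacc)
}

# Even-order coefficient ratios G_l(kappa)/G_0(kappa) plus the second moment
# tau = E[(mu.n)^2], computed from one shared set of quadrature weights.
# With deriv = TRUE also returns d(ratio)/d(kappa) and d(tau)/d(kappa)
# (available on the Gauss-Legendre branch, kappa <= 500, which covers the
# whole fitting range).
watson_internals <- function(kappa, deriv = FALSE) {
  cache <- watson_nodes()
  if (kappa <= 500) {
    x2m1 <- cache$gl$x^2 - 1
    w <- cache$gl$w * exp(kappa * x2m1)
    g <- as.vector(crossprod(cache$P_gl, w))
    m0 <- sum(w)
    m2 <- sum(w * cache$gl$x^2)
    tau <- m2 / m0
    if (deriv) {
      dg <- as.vector(crossprod(cache$P_gl, w * x2m1))
      r <- g / g[1]
      r[.watson_odd] <- 0
      dr <- (dg - r * dg[1]) / g[1]
      dr[.watson_odd] <- 0
      dtau <- (sum(w * cache$gl$x^2 * x2m1) - tau * sum(w * x2m1)) / m0
      return(list(ratio = r, tau = tau, dratio = dr, dtau = dtau))
    }
  } else {
    if (deriv) stop("derivatives only available for kappa <= 500")
    s <- cache$lag$x
    x <- sqrt(pmax(1 - s / kappa, 0))
    ok <- x > 0
    P <- legendre_table(x[ok])
    ws <- cache$lag$w[ok] / x[ok]
    g <- as.vector(crossprod(P, ws))
    tau <- sum(ws * x[ok]^2) / sum(ws)
  }
  r <- g / g[1]
  r[.watson_odd] <- 0   # odd orders vanish by symmetry
  list(ratio = r, tau = tau)
}

watson_coef_ratio <- function(kappa) watson_internals(kappa)$ratio

# Legendre coefficients H_l(t) = int_{-1}^{1} e^{-t x^2} P_l(x) dx,
# memoized on t (a fitting run touches only one t per shell).
stick_response_coefs <- function(t) {
  key <- sprintf("h_%.12g", t)
  h <- .watson_cache[[key]]
  if (is.null(h)) {
    cache <- watson_nodes()
    w <- cache$gl$w * exp(-t * cache$gl$x^2)
    h <- 2 * as.vector(crossprod(cache$P_gl, w))
    h[.watson_odd] <- 0
    .watson_cache[[key]] <- h
  }
  h
}

#' Watson-dispersed stick signal kernel
#'
#' Attenuation of a stick compartment with Watson orientation dispersion,
#' as a function of the angle between the mean fiber direction and the
#' diffusion gradient. `kappa = 0` gives a fully dispersed (isotropic)
#' response independent of angle; `kappa -> Inf` converges to the single
#' stick `exp(-b * d_par * cos_angle^2)`.
#'
#' @param kappa Watson concentration parameter, >= 0 (scalar).
#' @param b b-value, s/mm^2 (scalar).
#' @param d_par Intrinsic parallel diffusivity, mm^2/s (scalar).
#' @param cos_angle Cosine(s) of the angle between fiber and gradient.
#' @return Attenuation value(s) in (0, 1], same length as `cos_angle`.
#' @export
watson_kernel <- function(kappa, b, d_par, cos_angle) {
  stopifnot(kappa >= 0, b >= 0, d_par >= 0)
  if (b * d_par == 0) return(rep(1, length(cos_angle)))
  lseq <- 0:.watson_L
  coef <- (2 * lseq + 1) / 2 * watson_coef_ratio(kappa) *
    stick_response_coefs(b * d_par)
  as.vector(legendre_table(cos_angle) %*% coef)
}

# tau(kappa) = E_W[(mu.n)^2]; 1/3 at kappa = 0, -> 1 as kappa -> Inf.
# Used for the Watson-averaged extra-neurite diffusion tensor.
watson_tau <- function(kappa) watson_internals(kappa)$tau
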