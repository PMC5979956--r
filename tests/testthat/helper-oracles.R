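# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths.

# Brute-force spherical quadrature of the Watson-dispersed stick signal:
# dense Gauss-Legendre x uniform-azimuth product rule on the sphere.
watson_quadrature_oracle <- function(kappa, b, d_par, cos_angle, n = 200) {
  gl <- pracma::gaussLegendre(n, -1, 1)
  phi <- (seq_len(2 * n) - 0.5) * pi / n
  u <- gl$x
  su <- sqrt(1 - u^2)
  vapply(cos_angle, function(ca) {
    sa <- sqrt(max(1 - ca^2, 0))
    w <- exp(kappa * (u^2 - 1))      # overflow-free Watson weight
    num <- 0; den <- 0
    for (p in phi) {
      gdotn <- ca * u + sa * su * cos(p)
      num <- num + sum(gl$w * w * exp(-b * d_par * gdotn^2))
      den <- den + sum(gl$w * w)
    }
    num / den
  }, numeric(1))
}

# One-way ANOVA F by explicit sums of squares (brute-force formula oracle).
anova_f_oracle <- function(values) {
  all <- unlist(values)
  grand <- mean(all)
  ssb <- sum(vapply(values, function(v) length(v) * (mean(v) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(values, function(v) sum((v - mean(v))^2), numeric(1)))
  k <- length(values); n <- length(all)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Pearson chi-square by explicit (O - E)^2 / E.
chisq_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# small noise-free phantom shared by several tests (uniform B1, no noise)
clean_phantom <- function(nz = 1, seed = 1, ...) {
  generate_phantom(phantom_config(nz = nz, b1_amp = 0, snr = Inf, ...),
                   seed = seed)
}

# region-mean g-ratio implied by ground truth over a mask
truth_mean_g <- function(phantom, mask) {
  tr <- phantom$truth
  avf <- (1 - tr$mvf) * (1 - tr$viso) * tr$vic
  g <- sqrt(avf / (tr$mvf + avf))
  mean(g[mask])
}

# build a 4-D dwi array from a list/matrix of per-voxel signal vectors laid
# out along x (one row of voxels)
signals_to_dwi <- function(sig_matrix) {
  n <- nrow(sig_matrix)
  array(aperm(array(t(sig_matrix), c(ncol(sig_matrix), n, 1, 1)),
              c(2, 3, 4, 1)),
        c(n, 1, 1, ncol(sig_matrix)))
}
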