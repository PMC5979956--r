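# MTsat mapping: inversion round trips, scale invariances, B1 estimation
# and correction, MVF calibration.

protocol_forward <- function(pd, r1, delta) {
  deg <- pi / 180
  list(s_pd = flash_mt_forward(pd, r1, 0, alpha = 5 * deg, tr = 0.024),
       s_t1 = flash_mt_forward(pd, r1, 0, alpha = 13 * deg, tr = 0.010),
       s_mt = flash_mt_forward(pd, r1, delta, alpha = 5 * deg, tr = 0.024))
}

test_that("apparent maps round-trip the forward model on a parameter grid", {
  for (pd in c(500, 1000)) for (r1 in c(0.6, 1.0, 1.4)) {
    for (delta in c(0, 0.01, 0.03)) {
      s <- protocol_forward(pd, r1, delta)
      tri <- flash_triplet(s$s_pd, s$s_t1, s$s_mt)
      r1app <- compute_r1app(tri)
      a_app <- compute_aapp(tri)
      d_app <- compute_delta_app(s$s_mt, 5, 0.024, a_app, r1app)
      expect_equal(r1app, r1, tolerance = 1e-6)
      expect_equal(a_app, pd, tolerance = 1e-6 * pd)
      expect_lt(abs(d_app - delta), 1e-6)
    }
  }
})

test_that("delta_app is invariant under global signal rescaling", {
  s <- protocol_forward(800, 1.05, 0.02)
  for (c_ in c(0.1, 10)) {
    tri <- flash_triplet(c_ * s$s_pd, c_ * s$s_t1, c_ * s$s_mt)
    d <- compute_delta_app(c_ * s$s_mt, 5, 0.024, compute_aapp(tri),
                           compute_r1app(tri))
    expect_equal(d, 0.02, tolerance = 1e-9)
  }
  # a_app scales linearly, r1app not at all
  tri10 <- flash_triplet(10 * s$s_pd, 10 * s$s_t1, 10 * s$s_mt)
  tri1 <- flash_triplet(s$s_pd, s$s_t1, s$s_mt)
  expect_equal(compute_aapp(tri10), 10 * compute_aapp(tri1))
  expect_equal(compute_r1app(tri10), compute_r1app(tri1))
})

test_that("degenerate equal-protocol inputs are flagged, not zero-filled", {
  s <- array(100, c(2, 2, 1))
  tri <- flash_triplet(s, s, s, alpha_pd = 5, alpha_t1 = 5,
                       tr_pd = 0.024, tr_t1 = 0.024)
  expect_equal(compute_r1app(tri), array(0, c(2, 2, 1)))  # 0/0 identity case
  expect_true(all(is.nan(compute_aapp(tri))))
  # negative-denominator voxels (e.g. background noise) become NaN
  tri2 <- flash_triplet(array(1, c(2, 2, 1)), array(100, c(2, 2, 1)),
                        array(1, c(2, 2, 1)))
  expect_true(all(is.nan(compute_r1app(tri2))))
})

test_that("double-angle B1 estimation recovers the actual/nominal ratio", {
  deg <- pi / 180
  # nominal flips achieved exactly
  s10 <- array(500 * sin(10 * deg), c(4, 4, 1))
  s20 <- array(500 * sin(20 * deg), c(4, 4, 1))
  expect_equal(estimate_b1(s10, s20), array(1, c(4, 4, 1)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # actual flips 12 / 24 degrees at nominal 10 / 20
  s12 <- array(500 * sin(12 * deg), c(4, 4, 1))
  s24 <- array(500 * sin(24 * deg), c(4, 4, 1))
  b1 <- estimate_b1(s12, s24)
  expect_equal(as.vector(b1), rep(1.2, 16), tolerance = 1e-3)
  # s_high = 2 s_low: arccos(1) = 0, degenerate, falls back flagged
  expect_warning(b1d <- estimate_b1(s10, 2 * s10), "falling back")
  expect_true(all(attr(b1d, "flagged")))
  expect_equal(as.vector(b1d), rep(1, 16))
})

test_that("polynomial B1 smoothing recovers a smooth field under noise", {
  cfg <- phantom_config(nz = 1, b1_amp = 0.2, snr = 30)
  ph <- generate_phantom(cfg, seed = 21)
  tissue <- ph$masks$cord | ph$masks$calib | ph$masks$csf
  b1 <- suppressWarnings(estimate_b1(ph$b1_low, ph$b1_high,
                                     smooth = "polyfit", mask = tissue))
  m <- ph$masks$cord
  expect_lt(max(abs(b1[m] - ph$truth$b1[m])), 0.1)
  expect_lt(mean(abs(b1[m] - ph$truth$b1[m])), 0.04)
  # smoothed map is far closer to the truth than the raw voxelwise map
  raw <- suppressWarnings(estimate_b1(ph$b1_low, ph$b1_high))
  expect_lt(mean(abs(b1[m] - ph$truth$b1[m])),
            mean(abs(raw[m] - ph$truth$b1[m])))
})

test_that("B1-corrected saturation recovers the truth under a B1 gradient", {
  # noise-free but with a +/-10% transmit gradient: the empirical C = 0.4
  # correction must undo the net B1 dependence to first order
  ph <- generate_phantom(phantom_config(nz = 1, b1_amp = 0.1, snr = Inf),
                         seed = 4)
  mt <- mtsat_maps(flash_triplet(ph$flash_pd, ph$flash_t1, ph$flash_mt))
  b1 <- estimate_b1(ph$b1_low, ph$b1_high)
  dcor <- correct_delta_b1(mt$delta_app, b1)
  m <- ph$masks$cord
  expect_lt(max(abs(dcor[m] / ph$truth$delta[m] - 1)), 0.02)
  # uncorrected saturation carries several-percent B1 bias
  expect_gt(max(abs(mt$delta_app[m] / ph$truth$delta[m] - 1)), 0.04)
})

test_that("B1 correction of delta has the stated form and limits", {
  d <- array(0.02, c(2, 2, 1))
  one <- array(1, c(2, 2, 1))
  expect_equal(correct_delta_b1(d, one), d)
  expect_equal(as.vector(correct_delta_b1(d, 1.2 * one)),
               rep(0.02 * 0.6 / 0.52, 4), tolerance = 1e-5)
  # the compensation factor grows with b1 at fixed measured delta
  vals <- vapply(c(0.8, 0.9, 1, 1.1, 1.2),
                 function(b) correct_delta_b1(0.02, array(b, c(1, 1, 1)))[1],
                 numeric(1))
  expect_true(all(diff(vals) > 0))
  # pole region flagged invalid
  expect_true(is.nan(correct_delta_b1(0.02, array(2.6, c(1, 1, 1)))[1]))
  expect_error(correct_delta_b1(d, -one), "positive")
})

test_that("MVF calibration drives the region-mean g to the target", {
  dims <- c(4, 4, 2)
  delta <- array(0.02, dims)
  vic <- array(0.58, dims)
  viso <- array(0.04, dims)
  mask <- array(TRUE, dims)
  cal <- calibrate_mvf(delta, vic, viso, mask, g_target = 0.7)
  expect_equal(cal$achieved, 0.7, tolerance = 1e-4)
  expect_true(cal$c > 0)
  expect_equal(cal$mvf, clamp01(cal$c * delta))
  # scale equivariance: doubling delta halves c, MVF unchanged
  cal2 <- calibrate_mvf(2 * delta, vic, viso, mask, g_target = 0.7)
  expect_equal(cal2$c, cal$c / 2, tolerance = 1e-6)
  expect_equal(cal2$mvf, cal$mvf, tolerance = 1e-8)
})

test_that("region-mean g is strictly decreasing in the calibration factor", {
  delta <- array(runif(8, 0.01, 0.03), c(2, 2, 2))
  vic <- array(runif(8, 0.4, 0.7), c(2, 2, 2))
  viso <- array(runif(8, 0, 0.2), c(2, 2, 2))
  g_of_c <- function(c_) {
    mvf <- clamp01(c_ * delta)
    avf <- (1 - mvf) * (1 - viso) * vic
    mean(sqrt(avf / (mvf + avf)))
  }
  cs <- c(0.5, 1, 2, 5, 10, 20)
  expect_true(all(diff(vapply(cs, g_of_c, numeric(1))) < 0))
})

test_that("unreachable calibration targets error with the attainable range", {
  dims <- c(2, 2, 1)
  zero_delta <- array(0, dims)
  vic <- array(0.6, dims); viso <- array(0.05, dims)
  expect_error(
    calibrate_mvf(zero_delta, vic, viso, array(TRUE, dims), g_target = 0.7),
    "unreachable")
  expect_error(
    calibrate_mvf(array(0.02, dims), vic, viso, array(FALSE, dims)),
    "empty")
})
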