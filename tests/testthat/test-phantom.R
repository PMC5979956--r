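# Synthetic phantom: forward models, noise model, determinism, cohort
# structure.

test_that("default two-shell scheme has 41 volumes: 1 b=0 + 20 + 20", {
  sch <- default_scheme()
  expect_length(sch$bvals, 41)
  expect_equal(sum(sch$b0), 1)
  expect_equal(sum(abs(sch$bvals - 1000) < 50), 20)
  expect_equal(sum(abs(sch$bvals - 2000) < 50), 20)
  nrm <- sqrt(rowSums(sch$bvecs[!sch$b0, ]^2))
  expect_equal(nrm, rep(1, 40), tolerance = 1e-12)
})

test_that("scheme round-trips through FSL bval/bvec files", {
  sch <- default_scheme()
  bv <- tempfile(); bc <- tempfile()
  write_scheme(sch, bv, bc)
  expect_length(readLines(bv), 1)          # one whitespace-separated row
  sch2 <- read_scheme(bv, bc)
  expect_equal(sch2$bvals, sch$bvals)
  expect_equal(sch2$bvecs, sch$bvecs, tolerance = 1e-12)
})

test_that("FLASH forward model is linear in amplitude and monotone", {
  s1 <- flash_mt_forward(1000, 1, 0.02, alpha = 5 * pi / 180, tr = 0.024)
  s2 <- flash_mt_forward(2000, 1, 0.02, alpha = 5 * pi / 180, tr = 0.024)
  expect_equal(s2, 2 * s1)
  # strictly decreasing in delta
  d <- seq(0, 0.05, 0.01)
  s <- flash_mt_forward(1000, 1, d, alpha = 5 * pi / 180, tr = 0.024)
  expect_true(all(diff(s) < 0))
  # delta = 0 reduces to the rational FLASH approximation
  expect_equal(flash_mt_forward(1000, 1, 0, alpha = 0.1, tr = 0.024),
               1000 * 0.1 * 0.024 / (0.024 + 0.005))
  expect_error(flash_mt_forward(1, 1, 0, alpha = 0.1, tr = 0),
               "tr must be positive")
})

test_that("MT-weighted FLASH signal inverts to the simulated saturation", {
  a_mt <- 5 * pi / 180
  s <- flash_mt_forward(1000, 1.0, 0.02, alpha = a_mt, tr = 0.024)
  # invert via the saturation equation with the true amplitude and rate
  delta <- (1000 * a_mt / s - 1) * 1.0 * 0.024 - a_mt^2 / 2
  expect_equal(delta, 0.02, tolerance = 1e-6)
})

test_that("Rician noise: identity at sigma 0, Rayleigh mean, determinism", {
  x <- matrix(runif(100), 10)
  expect_identical(add_rician_noise(x, 0, 1), x)
  z <- add_rician_noise(numeric(2e4), 1, seed = 99)
  expect_equal(mean(z), sqrt(pi / 2), tolerance = 0.02)
  expect_identical(add_rician_noise(x, 0.5, 7), add_rician_noise(x, 0.5, 7))
  expect_false(identical(add_rician_noise(x, 0.5, 7),
                         add_rician_noise(x, 0.5, 8)))
  expect_error(add_rician_noise(x, -1, 1), "sigma")
})

test_that("same config and seed give byte-identical phantoms", {
  cfg <- phantom_config(nz = 1, snr = 30)
  p1 <- generate_phantom(cfg, seed = 3)
  p2 <- generate_phantom(cfg, seed = 3)
  expect_identical(p1$dwi, p2$dwi)
  expect_identical(p1$flash_mt, p2$flash_mt)
  p3 <- generate_phantom(cfg, seed = 4)
  expect_false(identical(p1$dwi, p3$dwi))
})

test_that("phantom truth satisfies its volume-fraction invariants", {
  ph <- generate_phantom(phantom_config(nz = 2, affected_side = "left",
                                        vic_reduction = 0.3), seed = 2)
  tr <- ph$truth
  expect_true(all(tr$mvf >= 0 & tr$mvf < 1))
  expect_true(all(tr$vic >= 0 & tr$vic <= 1))
  expect_true(all(tr$viso >= 0 & tr$viso <= 1))
  avf <- (1 - tr$mvf) * (1 - tr$viso) * tr$vic
  expect_true(all(tr$mvf + avf <= 1 + 1e-12))
  expect_equal(sum(tr$fiber_dir^2), 1)
})

test_that("noise-free phantom inverts to true R1, amplitude and saturation", {
  ph <- clean_phantom(nz = 1)
  mt <- mtsat_maps(flash_triplet(ph$flash_pd, ph$flash_t1, ph$flash_mt))
  m <- ph$masks$cord | ph$masks$calib
  expect_lt(max(abs(mt$r1app[m] - ph$truth$r1[m])), 1e-6)
  expect_lt(max(abs(mt$a_app[m] / ph$truth$pd[m] - 1)), 1e-6)
  expect_lt(max(abs(mt$delta_app[m] - ph$truth$delta[m])), 1e-6)
})

test_that("cohort has the paper-matching side structure", {
  spec <- cohort_spec(n_patients = 20, n_controls = 5, snr = Inf,
                      base_config = phantom_config(nz = 1), seed = 11)
  ch <- generate_cohort(spec)
  expect_length(ch$subjects, 25)
  expect_equal(sum(ch$metadata$group == "patient"), 20)
  expect_equal(sum(ch$metadata$group == "control"), 5)
  tab <- table(ch$sides$side_group)
  expect_equal(unname(tab[["affected"]]), 27)    # 11 L + 2 R + 2 x 7 bilateral
  expect_equal(unname(tab[["unaffected"]]), 13)
  expect_equal(unname(tab[["control"]]), 10)
})

test_that("null-effect cohort draws patients and controls identically", {
  spec <- cohort_spec(n_patients = 1, n_controls = 1, laterality = "left",
                      affected_avf_reduction = 0, mvf_change = 0,
                      snr = Inf, subject_cv = 0,
                      base_config = phantom_config(nz = 1), seed = 5)
  ch <- generate_cohort(spec)
  expect_equal(ch$subjects[[1]]$truth$vic, ch$subjects[[2]]$truth$vic)
  expect_equal(ch$subjects[[1]]$truth$mvf, ch$subjects[[2]]$truth$mvf)
})

test_that("affected-side axon loss reads back from the truth maps", {
  spec <- cohort_spec(n_patients = 1, n_controls = 1, laterality = "left",
                      affected_avf_reduction = 0.2, snr = Inf,
                      subject_cv = 0, base_config = phantom_config(nz = 1),
                      seed = 5)
  ch <- generate_cohort(spec)
  pat <- ch$subjects[["P01"]]; con <- ch$subjects[["C01"]]
  lcst <- pat$atlas$tracts$lateral_cst$left > 0.5
  expect_equal(mean(pat$truth$vic[lcst]), 0.8 * mean(con$truth$vic[lcst]),
               tolerance = 1e-12)
  # unaffected side untouched
  rcst <- pat$atlas$tracts$lateral_cst$right > 0.5
  expect_equal(mean(pat$truth$vic[rcst]), mean(con$truth$vic[rcst]))
})

test_that("degenerate cohort specs are rejected", {
  expect_error(cohort_spec(n_patients = 0, n_controls = 0, laterality = character(0)),
               "empty cohort")
  expect_error(cohort_spec(n_patients = 3, laterality = c("left", "right")),
               "laterality")
  expect_error(cohort_spec(affected_avf_reduction = 1), "0, 1")
})
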