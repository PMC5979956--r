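# NODDI forward model and voxelwise fitting.

sch <- default_scheme()

test_that("forward model normalizes b=0 to 1 and stays in [0, 1]", {
  s <- noddi_forward(list(vic = 0.6, viso = 0.1, kappa = 8,
                          dir = c(0, 0, 1)), sch)
  expect_equal(s[sch$b0], 1)
  expect_true(all(s >= 0 & s <= 1))
})

test_that("pure free water decays mono-exponentially at d_iso", {
  for (vic in c(0, 0.5, 1)) {
    s <- noddi_forward(list(vic = vic, viso = 1, kappa = 4,
                            dir = c(0, 0, 1)), sch)
    expect_equal(s[abs(sch$bvals - 1000) < 50], rep(exp(-3), 20),
                 tolerance = 1e-4)
    expect_equal(s[abs(sch$bvals - 2000) < 50], rep(exp(-6), 20),
                 tolerance = 1e-4)
  }
})

test_that("tensor initialization finds the stick axis and isotropy", {
  # single stick along z
  sig_z <- exp(-sch$bvals * 1.7e-3 * (sch$bvecs[, 3])^2)
  dwi <- signals_to_dwi(rbind(sig_z, sig_z))
  mask <- array(TRUE, c(2, 1, 1))
  ti <- tensor_init(dwi, sch, mask)
  expect_gt(abs(ti$dir[1, 3]), cos(2 * pi / 180))
  expect_true(all(ti$dir[, 3] >= 0))          # antipodal convention
  # isotropic signal: anisotropy ~ 0
  sig_iso <- exp(-sch$bvals * 1.0e-3)
  ti2 <- tensor_init(signals_to_dwi(rbind(sig_iso, sig_iso)), sch, mask)
  expect_lt(max(ti2$fa), 0.05)
  # oblique stick: direction recovered up to sign
  d <- c(1, 2, 2) / 3
  sig_d <- exp(-sch$bvals * 1.7e-3 * as.vector(sch$bvecs %*% d)^2)
  ti3 <- tensor_init(signals_to_dwi(rbind(sig_d, sig_d)), sch, mask)
  expect_gt(abs(sum(ti3$dir[1, ] * d)), cos(2 * pi / 180))
})

test_that("tensor initialization rejects deficient schemes", {
  bad <- diffusion_scheme(c(0, 1000, 1000, 1000, 1000, 1000, 1000),
                          rbind(c(0, 0, 0),
                                matrix(rep(c(0, 0, 1), 6), ncol = 3,
                                       byrow = TRUE)))
  dwi <- array(1, c(1, 1, 1, 7))
  expect_error(tensor_init(dwi, bad, array(TRUE, c(1, 1, 1))),
               "rank-deficient")
})

test_that("noise-free voxel is recovered within 0.01 in every parameter", {
  truth <- list(vic = 0.6, viso = 0.1, kappa = 1 / tan(0.2 * pi / 2),
                dir = c(0, 0, 1))       # odi = 0.2
  sig <- noddi_forward(truth, sch)
  dwi <- signals_to_dwi(matrix(sig, 1))
  fit <- fit_noddi(dwi, sch, array(TRUE, c(1, 1, 1)))
  expect_equal(fit$vic[1], 0.6, tolerance = 0.01)
  expect_equal(fit$viso[1], 0.1, tolerance = 0.01)
  expect_equal(fit$odi[1], 0.2, tolerance = 0.01)
  expect_gt(abs(fit$dir[1, 1, 1, 3]), cos(2 * pi / 180))
})

test_that("noise-free recovery error is below 0.01 on a parameter lattice", {
  pars <- expand.grid(vic = c(0.3, 0.55, 0.8), viso = c(0.05, 0.3),
                      odi = c(0.1, 0.35))
  sig <- t(apply(pars, 1, function(p) {
    noddi_forward(list(vic = p[["vic"]], viso = p[["viso"]],
                       kappa = 1 / tan(p[["odi"]] * pi / 2),
                       dir = c(0, 0, 1)), sch)
  }))
  fit <- fit_noddi(signals_to_dwi(sig), sch,
                   array(TRUE, c(nrow(pars), 1, 1)))
  expect_lt(max(abs(fit$vic[, 1, 1] - pars$vic)), 0.01)
  expect_lt(max(abs(fit$viso[, 1, 1] - pars$viso)), 0.01)
  expect_lt(max(abs(fit$odi[, 1, 1] - pars$odi)), 0.01)
})

test_that("pure-CSF voxels are flagged non-identifiable", {
  sig <- noddi_forward(list(vic = 0.5, viso = 1, kappa = 4,
                            dir = c(0, 0, 1)), sch)
  fit <- fit_noddi(signals_to_dwi(matrix(sig, 1)), sch,
                   array(TRUE, c(1, 1, 1)))
  expect_gte(fit$viso[1], 0.95)
  expect_true(fit$non_identifiable[1])
})

test_that("fitting is deterministic and validates its inputs", {
  sig <- noddi_forward(list(vic = 0.6, viso = 0.1, kappa = 8,
                            dir = c(0, 0, 1)), sch)
  noisy <- add_rician_noise(sig, 1 / 30, seed = 3)
  dwi <- signals_to_dwi(matrix(noisy, 1))
  mask <- array(TRUE, c(1, 1, 1))
  f1 <- fit_noddi(dwi, sch, mask)
  f2 <- fit_noddi(dwi, sch, mask)
  expect_identical(f1$vic, f2$vic)
  expect_identical(f1$kappa, f2$kappa)
  expect_error(fit_noddi(dwi[, , , 1:10, drop = FALSE], sch, mask),
               "volume count")
  expect_error(fit_noddi(dwi, sch, array(FALSE, c(1, 1, 1))), "empty")
  one_shell <- diffusion_scheme(c(0, rep(1000, 20)),
                                rbind(c(0, 0, 0), sch$bvecs[2:21, ]))
  expect_error(fit_noddi(dwi[, , , 1:21, drop = FALSE], one_shell, mask),
               "2 b > 0 shells")
})

test_that("voxels with non-positive b0 are flagged invalid", {
  sig <- noddi_forward(list(vic = 0.6, viso = 0.1, kappa = 8,
                            dir = c(0, 0, 1)), sch)
  dwi <- signals_to_dwi(rbind(sig, 0 * sig))
  fit <- fit_noddi(dwi, sch, array(TRUE, c(2, 1, 1)))
  expect_false(fit$invalid[1])
  expect_true(fit$invalid[2])
  expect_true(is.nan(fit$vic[2]))
})

test_that("recovery error grows with noise level", {
  truth <- list(vic = 0.6, viso = 0.1, kappa = 8, dir = c(0, 0, 1))
  sig <- noddi_forward(truth, sch)
  nvox <- 100
  rmse <- vapply(c(0, 1 / 50, 1 / 15), function(sigma) {
    noisy <- t(vapply(seq_len(nvox), function(i) {
      add_rician_noise(sig, sigma, seed = derive_seed(500, i))
    }, numeric(length(sig))))
    fit <- fit_noddi(signals_to_dwi(noisy), sch,
                     array(TRUE, c(nvox, 1, 1)),
                     noddi_options(refine_dir = FALSE))
    sqrt(mean((fit$vic[, 1, 1] - truth$vic)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) > 0))
})
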