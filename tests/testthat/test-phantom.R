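test_that("phantom generation is deterministic given the spec", {
  s <- small_spec(seed = 4)
  a <- generate_geometry(s)
  b <- generate_geometry(s)
  expect_identical(a$labels, b$labels)
  pha <- nerve_phantom(s)
  phb <- nerve_phantom(s)
  expect_identical(pha$dwi$data, phb$dwi$data)
})

test_that("single-fascicle straight phantom has constant per-slice labels", {
  s <- small_spec(seed = 2, n_fascicles = 1, fr_target = 0.3,
                  fascicle_drift_amplitude = 0)
  g <- generate_geometry(s)
  labs <- setdiff(unique(as.vector(g$labels)), 0L)
  expect_setequal(labs, 1:3)  # fascicle, perineurium, epineurium
  counts <- apply(g$labels, 3, function(sl) table(factor(sl, levels = 0:3)))
  for (z in 2:dim(g$labels)[3]) expect_equal(counts[, z], counts[, 1])
})

test_that("compartment labels partition the nerve on every slice", {
  ph <- straight_phantom()
  lab <- ph$labels$labels
  K <- ph$spec$n_fascicles
  for (z in seq_len(dim(lab)[3])) {
    sl <- lab[, , z]
    n_nerve <- sum(sl > 0)
    n_parts <- sum(sl %in% seq_len(K)) + sum(sl == K + 1) + sum(sl == K + 2)
    expect_identical(n_parts, n_nerve)
  }
})

test_that("infeasible fascicle packing fails with an informative error", {
  expect_error(
    generate_geometry(small_spec(seed = 1, fr_target = 0.9,
                                 n_fascicles = 12)),
    "cannot place fascicles")
})

test_that("ground-truth tensor field matches the compartment physics", {
  ph <- straight_phantom()
  spec <- ph$spec
  fmask <- compartment_mask(ph$labels, "fascicle")
  emask <- compartment_mask(ph$labels, "epineurium")
  idx_f <- which(fmask, arr.ind = TRUE)[1, ]
  idx_e <- which(emask, arr.ind = TRUE)[1, ]
  # fascicle voxel, zero drift: principal axis along z, FA of the triple
  expect_equal(ph$field$evecs[idx_f[1], idx_f[2], idx_f[3], , 1],
               c(0, 0, 1))
  expect_equal(ph$field$evals[idx_f[1], idx_f[2], idx_f[3], ],
               spec$compartment_tensors$fascicle)
  expect_equal(round(compute_fa(spec$compartment_tensors$fascicle), 2),
               0.43)
  # epineurium is isotropic
  expect_equal(compute_fa(ph$field$evals[idx_e[1], idx_e[2], idx_e[3], ]), 0)
  # background: no tensor, no signal
  expect_equal(ph$field$s0[ph$labels$labels == 0],
               rep(0, sum(ph$labels$labels == 0)))
})

test_that("noiseless signals follow the mono-exponential forward model", {
  ph <- straight_phantom()
  sch <- ph$scheme
  fmask <- compartment_mask(ph$labels, "fascicle")
  v <- which(fmask, arr.ind = TRUE)[1, ]
  sig <- ph$dwi$data[v[1], v[2], v[3], ]
  # b = 0 gives s0 exactly
  expect_equal(sig[sch$bvals == 0], ph$spec$s0[["fascicle"]])
  # attenuation along the fibre axis: exp(-b * D_axial)
  # any direction: S = s0 exp(-b g' D g) with the voxel's ground-truth D
  d6 <- ph$field$d6[v[1], v[2], v[3], ]
  D <- matrix(c(d6[1], d6[4], d6[5],
                d6[4], d6[2], d6[6],
                d6[5], d6[6], d6[3]), 3, 3) * 1e-3
  # zero drift: principal axis along z, so D_zz is the axial eigenvalue
  expect_equal(D[3, 3] * 1e3, ph$spec$compartment_tensors$fascicle[1])
  for (along in c(2, 7, 13)) {
    g <- sch$bvecs[, along]
    expected <- ph$spec$s0[["fascicle"]] *
      exp(-sch$bvals[along] * drop(t(g) %*% D %*% g))
    expect_equal(sig[along], expected, tolerance = 1e-12)
  }
  along <- 2
  # doubling b doubles the log-attenuation
  sch2 <- gradient_scheme(c(0, rep(2300, 19)), sch$bvecs)
  dwi2 <- simulate_dwi(ph$field, sch2, ph$spec, noiseless = TRUE)
  la1 <- log(sig[along] / sig[sch$bvals == 0])
  la2 <- log(dwi2$data[v[1], v[2], v[3], along] /
               dwi2$data[v[1], v[2], v[3], sch$bvals == 0])
  expect_equal(la2 / la1, 2, tolerance = 1e-10)
})

test_that("Rician noise has the expected moments", {
  expect_identical(add_rician_noise(c(1, 5, 10), 0), c(1, 5, 10))
  set.seed(123)
  # zero signal: Rayleigh mean sigma * sqrt(pi/2)
  draws <- add_rician_noise(rep(0, 4e4), 1)
  expect_equal(mean(draws), sqrt(pi / 2), tolerance = 0.02)
  # high SNR: mean approx S + sigma^2 / (2 S)
  S <- 50
  draws2 <- add_rician_noise(rep(S, 4e4), 2)
  expect_equal(mean(draws2), S + 4 / (2 * S), tolerance = 1e-3)
  expect_true(all(add_rician_noise(rep(0, 100), 3) >= 0))
})

test_that("SNR estimation recovers the calibrated noise level", {
  ph <- cached_phantom("noisy14", small_spec(seed = 21))
  fmask <- compartment_mask(ph$labels, "fascicle")
  bg <- array(ph$labels$labels == 0, dim(ph$labels$labels))
  snr <- estimate_snr(ph$dwi, fmask, bg)
  expect_equal(snr, 14, tolerance = 2 / 14)
  # doubling sigma halves the SNR
  ph2 <- nerve_phantom(small_spec(seed = 21,
                                  noise_sigma = 2 * ph$spec$noise_sigma))
  snr2 <- estimate_snr(ph2$dwi, fmask, bg)
  expect_equal(snr2 / snr, 0.5, tolerance = 0.1)
  # noiseless background has zero variance
  ph0 <- straight_phantom()
  bg0 <- array(ph0$labels$labels == 0, dim(ph0$labels$labels))
  expect_error(estimate_snr(ph0$dwi, fmask, bg0), "zero background")
})

test_that("region fits on the noiseless phantom recover ground truth", {
  ph <- straight_phantom()
  for (comp in c("fascicle", "perineurium", "epineurium")) {
    fit <- fit_tensor_region(ph$dwi, compartment_mask(ph$labels, comp))
    es <- eigendecompose(fit)
    expect_equal(es$values, ph$spec$compartment_tensors[[comp]],
                 tolerance = 1e-9)
  }
})

test_that("phantoms write a complete sidecar bundle", {
  ph <- straight_phantom()
  dir <- withr::local_tempdir()
  files <- write_phantom(ph, dir)
  expect_true(all(file.exists(files)))
  sp <- jsonlite::read_json(files[["spec"]])
  expect_equal(sp$seed, ph$spec$seed)
  sch2 <- read_gradient_table(files[["bval"]], files[["bvec"]])
  expect_equal(sch2$bvals, ph$scheme$bvals)
  lab2 <- RNifti::readNifti(files[["labels"]])
  expect_equal(array(as.integer(lab2), dim(lab2)), ph$labels$labels)
})
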