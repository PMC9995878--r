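test_that("noiseless log-linear fits recover the generating tensor", {
  sch <- default_scheme()
  D <- diffusion_tensor(c(0.8, 0.4, 0.4, 0, 0, 0), s0 = 100)
  fit <- fit_tensor_lls(forward_signals(D, sch), sch)
  expect_equal(fit$components, D$components, tolerance = 1e-9)
  expect_equal(fit$s0, 100, tolerance = 1e-9)

  # property: any random positive-definite tensor round-trips
  set.seed(42)
  for (i in 1:20) {
    Dr <- random_pd_tensor()
    fr <- fit_tensor_lls(forward_signals(Dr, sch), sch)
    expect_equal(fr$components, Dr$components, tolerance = 1e-9)
    expect_equal(fr$s0, Dr$s0, tolerance = 1e-8)
  }

  # weighted variant agrees on noiseless data
  fw <- fit_tensor_lls(forward_signals(D, sch), sch, weighted = TRUE)
  expect_equal(fw$components, D$components, tolerance = 1e-9)
})

test_that("degenerate signal patterns fit to the expected tensors", {
  sch <- default_scheme()
  # no attenuation at all -> zero tensor
  flat <- fit_tensor_lls(rep(100, sch$n_meas), sch)
  expect_equal(unname(flat$components), rep(0, 6), tolerance = 1e-10)
  expect_equal(flat$s0, 100)
  # isotropic attenuation -> 0.5 * identity (in 1e-9 m^2/s)
  s <- ifelse(sch$bvals > 0, 100 * exp(-1150 * 0.0005), 100)
  iso <- fit_tensor_lls(s, sch)
  expect_equal(unname(iso$components), c(0.5, 0.5, 0.5, 0, 0, 0),
               tolerance = 1e-9)
  # non-positive signals are floored with a warning and counted
  s2 <- forward_signals(diffusion_tensor(c(0.8, 0.4, 0.4, 0, 0, 0), 100),
                        sch)
  s2[5] <- 0
  expect_warning(f2 <- fit_tensor_lls(s2, sch), "floored")
  expect_equal(f2$n_floored, 1L)
  expect_error(fit_tensor_lls(rep(0, sch$n_meas), sch), "non-positive")
})

test_that("region fits average signals before fitting", {
  sch <- default_scheme()
  D <- diffusion_tensor(c(0.9, 0.5, 0.3, 0.05, 0, 0), s0 = 100)
  sig <- forward_signals(D, sch)
  # homogeneous region == single voxel
  arr <- array(rep(sig, each = 8), c(2, 2, 2, sch$n_meas))
  dwi <- dwi_volume(arr, c(1, 1, 1), sch)
  fit <- fit_tensor_region(dwi, array(TRUE, c(2, 2, 2)))
  expect_equal(fit$components, D$components, tolerance = 1e-9)
  # two voxels with s0 100 and 200, same D -> same D, s0 = 150
  D2 <- diffusion_tensor(D$components, s0 = 200)
  arr2 <- array(0, c(2, 1, 1, sch$n_meas))
  arr2[1, 1, 1, ] <- sig
  arr2[2, 1, 1, ] <- forward_signals(D2, sch)
  dwi2 <- dwi_volume(arr2, c(1, 1, 1), sch)
  f2 <- fit_tensor_region(dwi2, cbind(1:2, 1, 1))
  expect_equal(f2$components, D$components, tolerance = 1e-9)
  expect_equal(f2$s0, 150, tolerance = 1e-9)
  expect_error(fit_tensor_region(dwi2, cbind(integer(0), integer(0),
                                             integer(0))), "empty")
  expect_error(fit_tensor_region(dwi2, cbind(5, 1, 1)), "outside")
})

test_that("eigendecomposition sorts, sign-normalises and reconstructs", {
  es <- eigendecompose(diag(c(0.9, 0.5, 0.3)))
  expect_equal(es$values, c(0.9, 0.5, 0.3))
  expect_equal(abs(es$vectors[, 1]), c(1, 0, 0))
  expect_gte(es$vectors[which.max(abs(es$vectors[, 1])), 1], 0)
  # rotation invariance of eigenvalues and reconstruction identity
  set.seed(7)
  for (i in 1:10) {
    vals <- sort(stats::runif(3, 0, 1.5), decreasing = TRUE)
    Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    M <- Q %*% diag(vals) %*% t(Q)
    es <- eigendecompose(M)
    expect_equal(es$values, vals, tolerance = 1e-10)
    rec <- es$vectors %*% diag(es$values) %*% t(es$vectors)
    expect_equal(rec, M, tolerance = 1e-8)
    expect_equal(crossprod(es$vectors), diag(3), tolerance = 1e-8)
  }
  # isotropic: degenerate eigenvalues allowed
  iso <- eigendecompose(0.7 * diag(3))
  expect_equal(iso$values, rep(0.7, 3))
})

test_that("diffusion indices reproduce their defining formulas", {
  # values from the emulated study's fascicle table, nerve sample 1
  v <- c(0.77, 0.40, 0.37)
  expect_equal(round(compute_md(v), 2), 0.51)
  expect_equal(round(compute_fa(v), 2), 0.41)
  expect_equal(round(compute_axial_radial_ratio(v), 2), 2.00)
  # perineurium table, nerve sample 1
  expect_equal(round(compute_md(c(1.06, 0.74, 0.55)), 2), 0.78)
  # limiting cases
  expect_equal(compute_md(c(1, 1, 1)), 1)
  expect_equal(compute_fa(c(1, 0, 0)), 1)
  expect_equal(compute_fa(c(0.3, 0.3, 0.3)), 0)
  expect_equal(compute_fa(c(0, 0, 0)), 0)
  expect_equal(compute_axial_radial_ratio(c(2, 1, 1)), 2)
  expect_equal(compute_axial_radial_ratio(c(0.5, 0.5, 0.5)), 1)
  expect_error(compute_axial_radial_ratio(c(1, 0, 0)), "degenerate")
  # clamping keeps FA in [0, 1] and feeds MD the clamped values
  expect_equal(compute_md(c(0.6, 0.3, -0.3)), 0.3)
  expect_lte(compute_fa(c(0.6, 0.1, -0.5)), 1)
  idc <- dti_indices(c(0.6, 0.3, -0.1))
  expect_true(idc$clamped)
})

test_that("indices are rotation-invariant and scale-equivariant", {
  set.seed(99)
  for (i in 1:10) {
    vals <- sort(stats::runif(3, 0.01, 1.5), decreasing = TRUE)
    Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    M <- Q %*% diag(vals) %*% t(Q)
    es <- eigendecompose(M)
    expect_equal(compute_md(es), mean(vals), tolerance = 1e-10)
    expect_equal(compute_fa(es), compute_fa(vals), tolerance = 1e-10)
    expect_equal(compute_axial_radial_ratio(es),
                 compute_axial_radial_ratio(vals), tolerance = 1e-10)
    # scale equivariance
    c_scale <- stats::runif(1, 0.1, 5)
    expect_equal(compute_md(c_scale * vals), c_scale * mean(vals))
    expect_equal(compute_fa(c_scale * vals), compute_fa(vals),
                 tolerance = 1e-12)
    expect_equal(compute_axial_radial_ratio(c_scale * vals),
                 compute_axial_radial_ratio(vals), tolerance = 1e-12)
  }
  # FA bounds on arbitrary non-negative triples; zero iff all equal
  set.seed(100)
  for (i in 1:50) {
    v <- stats::runif(3, 0, 2)
    fa <- compute_fa(v)
    expect_gte(fa, 0); expect_lte(fa, 1)
    if (fa < 1e-12) expect_lt(diff(range(v)), 1e-10)
  }
})

test_that("voxelwise volume fits match per-voxel fits", {
  sch <- default_scheme()
  set.seed(5)
  dims <- c(3, 3, 2)
  arr <- array(0, c(dims, sch$n_meas))
  tensors <- list()
  for (i in seq_len(prod(dims))) {
    tensors[[i]] <- random_pd_tensor()
    arr[arrayInd(i, dims)[1], arrayInd(i, dims)[2], arrayInd(i, dims)[3], ] <-
      forward_signals(tensors[[i]], sch)
  }
  dwi <- dwi_volume(arr, c(1, 1, 1), sch)
  fit <- fit_dti_volume(dwi)
  for (i in seq_len(prod(dims))) {
    ai <- arrayInd(i, dims)
    es <- eigendecompose(tensors[[i]])
    expect_equal(fit$evals[ai[1], ai[2], ai[3], ], es$values,
                 tolerance = 1e-8)
    expect_equal(fit$fa[ai[1], ai[2], ai[3]], compute_fa(es),
                 tolerance = 1e-8)
    expect_equal(fit$s0[ai[1], ai[2], ai[3]], tensors[[i]]$s0,
                 tolerance = 1e-6)
  }
})
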