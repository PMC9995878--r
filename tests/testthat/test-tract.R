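make_uniform_field <- function(dims = c(10, 10, 20), fa_val = 0.5) {
  e1 <- array(0, c(dims, 3))
  e1[, , , 3] <- 1
  fa <- array(fa_val, dims)
  list(e1 = e1, fa = fa, vs = c(1, 1, 1))
}

test_that("a uniform z-aligned field yields straight slab-spanning lines", {
  f <- make_uniform_field()
  seeds <- rbind(c(5.5, 5.5, 10.5), c(2.5, 7.5, 10.5))
  sl <- track_streamlines(f$e1, f$fa, seeds, f$vs)
  expect_length(sl$streamlines, 2)
  for (i in 1:2) {
    pts <- sl$streamlines[[i]]
    # straight: x and y never change
    expect_lt(max(abs(pts[, 1] - seeds[i, 1])), 1e-9)
    expect_lt(max(abs(pts[, 2] - seeds[i, 2])), 1e-9)
    # spans the slab within one step of its full extent
    expect_gt(diff(range(pts[, 3])), 20 - 2 * sl$step_mm)
    # consecutive spacing equals the step length
    d <- sqrt(rowSums(diff(pts)^2))
    expect_equal(d, rep(sl$step_mm, length(d)), tolerance = 1e-6)
  }
  expect_true(all(sl$termination == "out_of_volume"))
})

test_that("a low-FA barrier terminates tracks with the low_fa reason", {
  f <- make_uniform_field()
  f$fa[, , 15] <- 0.05
  sl <- track_streamlines(f$e1, f$fa, rbind(c(5.5, 5.5, 5.5)), f$vs)
  pts <- sl$streamlines[[1]]
  expect_lt(max(pts[, 3]), 15.01)
  expect_equal(unname(sl$termination[1, "forward"]), "low_fa")
})

test_that("tracking is invariant to global eigenvector sign flips", {
  ph <- straight_phantom()
  fit <- fit_dti_volume(ph$dwi, compartment_mask(ph$labels, "nerve"))
  e1 <- fit$evecs[, , , , 1]
  fmask <- compartment_mask(ph$labels, "fascicle")
  smask <- array(FALSE, dim(fmask))
  mid <- ceiling(dim(fmask)[3] / 2)
  smask[, , mid] <- fmask[, , mid]
  seeds <- seed_points(smask, ph$dwi$voxel_size, every = 20L)
  a <- track_streamlines(e1, fit$fa, seeds, ph$dwi$voxel_size)
  b <- track_streamlines(-e1, fit$fa, seeds, ph$dwi$voxel_size)
  # same geometry; the flipped field traverses each line in reverse order
  expect_length(b$streamlines, length(a$streamlines))
  for (i in seq_along(a$streamlines)) {
    pa <- a$streamlines[[i]]
    pb <- b$streamlines[[i]]
    rev_pb <- pb[rev(seq_len(nrow(pb))), , drop = FALSE]
    expect_true(isTRUE(all.equal(pa, pb, tolerance = 1e-10,
                                 check.attributes = FALSE)) ||
                  isTRUE(all.equal(pa, rev_pb, tolerance = 1e-10,
                                   check.attributes = FALSE)))
  }
  # determinism
  c2 <- track_streamlines(e1, fit$fa, seeds, ph$dwi$voxel_size)
  expect_identical(a$streamlines, c2$streamlines)
})

test_that("seeds below the FA threshold give an empty result", {
  f <- make_uniform_field(fa_val = 0.05)
  expect_warning(sl <- track_streamlines(f$e1, f$fa,
                                         rbind(c(5.5, 5.5, 5.5)), f$vs),
                 "no seeds")
  expect_length(sl$streamlines, 0)
})

test_that("eigenvector colouring maps axes to red/green/blue", {
  expect_equal(eigenvector_rgb(c(0, 0, 1)), c(0, 0, 1))
  expect_equal(eigenvector_rgb(c(1, 0, 0)), c(1, 0, 0))
  expect_equal(eigenvector_rgb(c(-1, 0, 0)), c(1, 0, 0))
  expect_equal(eigenvector_rgb(rep(1, 3) / sqrt(3)), rep(0.577, 3),
               tolerance = 1e-3)
})

test_that("ellipsoid glyphs encode eigenvalue anisotropy", {
  dims <- c(2, 1, 1)
  evals <- array(0, c(dims, 3))
  evecs <- array(0, c(dims, 3, 3))
  # voxel 1: default fascicle tensor along z; voxel 2: zero tensor
  evals[1, 1, 1, ] <- c(0.81, 0.41, 0.37)
  evecs[1, 1, 1, , ] <- cbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  g <- ellipsoid_field(evals, evecs, c(1, 1, 1))
  expect_equal(nrow(g), 1)  # zero tensor skipped
  expect_equal(g$a1 / g$a3, 0.81 / 0.37, tolerance = 1e-12)
  expect_equal(c(g$red, g$green, g$blue), c(0, 0, 1))
  # isotropic tensor becomes a sphere
  evals[2, 1, 1, ] <- c(0.3, 0.3, 0.3)
  evecs[2, 1, 1, , ] <- diag(3)
  g2 <- ellipsoid_field(evals, evecs, c(1, 1, 1))
  sph <- g2[2, ]
  expect_equal(sph$a1, sph$a2)
  expect_equal(sph$a2, sph$a3)
})

test_that("TRK files round-trip streamline geometry", {
  f <- make_uniform_field()
  seeds <- rbind(c(5.5, 5.5, 10.5), c(2.5, 7.5, 3.5))
  sl <- track_streamlines(f$e1, f$fa, seeds, f$vs)
  path <- withr::local_tempfile(fileext = ".trk")
  write_trk(sl, path, dim(f$fa), f$vs)
  back <- read_trk(path)
  expect_equal(back$n, length(sl$streamlines))
  expect_equal(back$voxel_size, f$vs)
  for (i in seq_along(sl$streamlines))
    expect_equal(back$streamlines[[i]],
                 unname(sl$streamlines[[i]]), tolerance = 1e-6)
})

test_that("fascicle-seeded streamlines stay within fascicular tissue", {
  ph <- straight_phantom()
  fit <- fit_dti_volume(ph$dwi, compartment_mask(ph$labels, "nerve"))
  fmask <- compartment_mask(ph$labels, "fascicle")
  smask <- array(FALSE, dim(fmask))
  mid <- ceiling(dim(fmask)[3] / 2)
  smask[, , mid] <- fmask[, , mid]
  seeds <- seed_points(smask, ph$dwi$voxel_size, every = 4L)
  sl <- track_streamlines(fit$evecs[, , , , 1], fit$fa, seeds,
                          ph$dwi$voxel_size)
  aud <- streamline_label_audit(sl, ph$labels)
  expect_gte(aud$all_inside, 0.95)
})
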