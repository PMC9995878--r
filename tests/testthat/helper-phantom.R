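# Shared fixtures, built in code at test time.

# A reduced phantom spec for fast tests: same physics and study-scale
# proportions, smaller grid (fewer, coarser in-plane voxels and 8 slices).
small_spec <- function(seed = 1, ...) {
  phantom_spec(grid = c(64, 32, 8), voxel_size = c(0.14, 0.14, 0.625),
               seed = seed, ...)
}

# Cache phantoms across tests within a run (they are deterministic).
.phantom_cache <- new.env(parent = emptyenv())
cached_phantom <- function(key, spec, noiseless = FALSE) {
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- nerve_phantom(spec, noiseless = noiseless)
  .phantom_cache[[key]]
}

# Straight-extrusion noiseless phantom at test scale.
straight_phantom <- function() {
  cached_phantom("straight",
                 small_spec(seed = 11, fascicle_drift_amplitude = 0),
                 noiseless = TRUE)
}

# Random positive-definite tensor with eigenvalues in a diffusivity-like
# range (1e-9 m^2/s).
random_pd_tensor <- function() {
  vals <- sort(stats::runif(3, 0.05, 1.2), decreasing = TRUE)
  A <- matrix(stats::rnorm(9), 3, 3)
  Q <- qr.Q(qr(A))
  M <- Q %*% diag(vals) %*% t(Q)
  diffusion_tensor(c(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3]),
                   s0 = stats::runif(1, 50, 200))
}

# Forward-simulate noiseless signals from a tensor under a scheme.
forward_signals <- function(tensor, scheme) {
  M <- tensor_matrix(tensor) * 1e-3  # mm^2/s
  g <- scheme$bvecs
  expo <- -scheme$bvals * colSums(g * (M %*% g))
  tensor$s0 * exp(expo)
}
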