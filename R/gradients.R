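#' Diffusion gradient scheme
#'
#' Bundles the b-values and unit gradient directions of a diffusion-weighted
#' acquisition. The scheme must contain at least one non-diffusion-weighted
#' (b = 0) measurement and at least six non-coplanar diffusion directions,
#' otherwise the log-linear tensor system is singular.
#'
#' @param bvals Numeric vector of b-values in s/mm^2 (non-negative).
#' @param bvecs 3 x n numeric matrix of gradient directions (FSL column
#'   convention). Columns with b > 0 must have unit norm (to 1e-6); columns
#'   with b = 0 may be zero vectors.
#' @param max_condition Largest acceptable condition number of the
#'   (b-normalised) design matrix; schemes above it are rejected as too
#'   ill-conditioned for a tensor fit.
#' @return An object of class `gradient_scheme` with elements `bvals`,
#'   `bvecs` and `n_meas`.
#' @examples
#' sch <- default_scheme()
#' sch$n_meas
#' @export
gradient_scheme <- function(bvals, bvecs, max_condition = 100) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L)
    stop("bvecs must be a 3 x n matrix (FSL column convention)")
  if (ncol(bvecs) != length(bvals))
    stop("bvals and bvecs disagree on the number of measurements")
  if (any(!is.finite(bvals)) || any(bvals < 0))
    stop("b-values must be finite and non-negative")
  nrm <- sqrt(colSums(bvecs^2))
  dwi <- bvals > 0
  if (any(abs(nrm[dwi] - 1) > 1e-6))
    stop("gradient directions with b > 0 must have unit norm")
  if (any(nrm[!dwi] > 1e-6 & abs(nrm[!dwi] - 1) > 1e-6))
    stop("b = 0 directions must be zero or unit vectors")
  scheme <- structure(
    list(bvals = bvals, bvecs = bvecs, n_meas = length(bvals)),
    class = "gradient_scheme"
  )
  if (!any(bvals == 0))
    stop("insufficient gradient scheme: no b = 0 measurement")
  if (sum(dwi) < 6)
    stop("insufficient gradient scheme: fewer than 6 diffusion directions")
  X <- build_design_matrix(scheme, .normalise_b = TRUE)
  if (qr(X)$rank < 7L)
    stop("insufficient gradient scheme: design matrix rank < 7")
  kappa <- kappa(X, exact = TRUE)
  if (kappa >= max_condition)
    stop(sprintf(
      "insufficient gradient scheme: design condition number %.1f >= %g",
      kappa, max_condition))
  scheme
}

#' @export
print.gradient_scheme <- function(x, ...) {
  ub <- sort(unique(x$bvals))
  cat(sprintf("gradient scheme: %d measurements (%d at b = 0), b in {%s} s/mm^2\n",
              x$n_meas, sum(x$bvals == 0), paste(ub, collapse = ", ")))
  invisible(x)
}

#' Build the log-linear design matrix of a gradient scheme
#'
#' Row i is
#' \code{[-b gx^2, -b gy^2, -b gz^2, -2 b gx gy, -2 b gx gz, -2 b gy gz, 1]}
#' so that the inner product with \code{c(dxx, dyy, dzz, dxy, dxz, dyz, log s0)}
#' equals \code{log S_i} under the mono-exponential tensor model. b is taken
#' in s/mm^2, so the regression coefficients come out in mm^2/s;
#' [fit_tensor_lls()] rescales them to 1e-9 m^2/s (= 1e-3 mm^2/s), the
#' reporting unit used throughout the package.
#'
#' @param scheme A [gradient_scheme()].
#' @param .normalise_b Internal: scale b by its maximum (used for
#'   condition-number checks so the test is scale-free).
#' @return Numeric matrix with `scheme$n_meas` rows and 7 columns.
#' @export
build_design_matrix <- function(scheme, .normalise_b = FALSE) {
  b <- scheme$bvals
  if (.normalise_b && max(b) > 0) b <- b / max(b)
  g <- scheme$bvecs
  X <- cbind(-b * g[1, ]^2,
             -b * g[2, ]^2,
             -b * g[3, ]^2,
             -2 * b * g[1, ] * g[2, ],
             -2 * b * g[1, ] * g[3, ],
             -2 * b * g[2, ] * g[3, ],
             1)
  colnames(X) <- c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz", "log_s0")
  if (qr(X)$rank < 7L)
    stop("insufficient gradient scheme: design matrix rank < 7")
  X
}

#' Read an FSL-style gradient table
#'
#' @param bval_path,bvec_path Paths to whitespace-delimited text files
#'   (1 x n and 3 x n).
#' @param ... Passed on to [gradient_scheme()].
#' @return A [gradient_scheme()].
#' @export
read_gradient_table <- function(bval_path, bvec_path, ...) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- scan(bvec_path, quiet = TRUE)
  if (length(bv) != 3L * length(bvals))
    stop("bvec file does not hold 3 rows of ", length(bvals), " entries")
  bvecs <- matrix(bv, nrow = 3, byrow = TRUE)
  gradient_scheme(bvals, bvecs, ...)
}

#' Write an FSL-style gradient table
#'
#' @param scheme A [gradient_scheme()].
#' @param bval_path,bvec_path Output paths.
#' @return Invisibly, the scheme.
#' @export
write_gradient_table <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "),
             bval_path)
  writeLines(apply(scheme$bvecs, 1, function(r)
    paste(format(r, digits = 15, trim = TRUE), collapse = " ")), bvec_path)
  invisible(scheme)
}

#' The package's 19-direction acquisition scheme
#'
#' Nineteen unit directions at b = 1150 s/mm^2 plus one b = 0 measurement,
#' matching the study design this package emulates. The directions were
#' generated once by seeded electrostatic-repulsion minimisation
#' ([repulsion_directions()]) and are shipped as an FSL bval/bvec pair under
#' `inst/extdata`.
#'
#' @param b Diffusion weighting in s/mm^2 for the 19 directions.
#' @return A [gradient_scheme()] with 20 measurements.
#' @export
default_scheme <- function(b = 1150) {
  bvec <- system.file("extdata", "nerve19.bvec", package = "nervedti",
                      mustWork = TRUE)
  bv <- matrix(scan(bvec, quiet = TRUE), nrow = 3, byrow = TRUE)
  gradient_scheme(c(0, rep(b, ncol(bv))), cbind(c(0, 0, 0), bv))
}

#' Generate evenly spread gradient directions by electrostatic repulsion
#'
#' Minimises the antipodally symmetric Coulomb energy
#' \eqn{\sum_{i<j} 1/|u_i-u_j|^2 + 1/|u_i+u_j|^2} by projected gradient
#' descent on the unit sphere, from a seeded random start. Deterministic for
#' a fixed seed.
#'
#' @param n Number of directions.
#' @param seed RNG seed for the starting configuration.
#' @param iters Descent iterations.
#' @return A 3 x n matrix of unit column vectors.
#' @export
repulsion_directions <- function(n, seed = 1, iters = 2000) {
  stopifnot(n >= 6)
  set.seed(seed)
  u <- matrix(stats::rnorm(3 * n), nrow = 3)
  u <- sweep(u, 2, sqrt(colSums(u^2)), "/")
  max_step <- 0.05
  for (it in seq_len(iters)) {
    grad <- matrix(0, 3, n)
    for (i in seq_len(n)) {
      d1 <- u[, i] - u
      d2 <- u[, i] + u
      r1 <- colSums(d1^2); r1[i] <- Inf
      r2 <- colSums(d2^2)
      # dE/du_i of sum 1/r^2 terms: -2 (u_i - u_j)/r1^2 - 2 (u_i + u_j)/r2^2
      g <- -2 * (d1 %*% (1 / r1^2)) - 2 * (d2 %*% (1 / r2^2))
      g <- g - sum(g * u[, i]) * u[, i]         # tangent projection
      gn <- sqrt(sum(g^2))
      if (gn > max_step) g <- g * (max_step / gn)
      grad[, i] <- g
    }
    u <- u - grad
    u <- sweep(u, 2, sqrt(colSums(u^2)), "/")
  }
  # deterministic orientation: first nonzero-largest component positive
  for (i in seq_len(n)) {
    k <- which.max(abs(u[, i]))
    if (u[k, i] < 0) u[, i] <- -u[, i]
  }
  u
}

#' Optimal diffusion weighting for a two-point experiment
#'
#' For a two-point acquisition (b1 = 0, b2 = b) the diffusion weighting that
#' minimises the variance of the estimated diffusivity D is b = 1.1 / D.
#'
#' @param d Diffusivity in 1e-9 m^2/s (> 0).
#' @return Optimal b in s/mm^2.
#' @examples
#' optimal_b(1.1)   # 1000
#' optimal_b(0.957) # ~1149, the rationale for acquiring at b = 1150
#' @export
optimal_b <- function(d) {
  if (any(!is.finite(d)) || any(d <= 0))
    stop("diffusivity must be positive")
  # d in 1e-3 mm^2/s -> b in s/mm^2
  1.1 / (d * 1e-3)
}

#' Acquisition parameters of a pulsed gradient spin-echo sequence
#'
#' @param delta Gradient pulse duration, ms.
#' @param Delta Gradient pulse separation, ms.
#' @param G0 Gradient amplitude, T/m.
#' @param TE,TR Echo and repetition times, ms.
#' @param fov Field of view per axis, mm (length 3).
#' @param matrix_size Sample counts per axis (length 3).
#' @param gamma Proton gyromagnetic ratio, rad s^-1 T^-1.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(delta = 3, Delta = 27, G0 = 0.26,
                               TE = 36, TR = 880,
                               fov = c(9, 4.5, 10),
                               matrix_size = c(256, 128, 16),
                               gamma = 2.675e8) {
  stopifnot(delta > 0, Delta > 0, G0 > 0, TE > 0, TR > 0,
            all(fov > 0), all(matrix_size > 0),
            length(fov) == 3, length(matrix_size) == 3)
  if (delta >= Delta) stop("delta must be smaller than Delta")
  structure(list(delta = delta, Delta = Delta, G0 = G0, TE = TE, TR = TR,
                 fov = fov, matrix_size = matrix_size, gamma = gamma,
                 voxel_size = fov / matrix_size),
            class = "acquisition_params")
}

#' Stejskal-Tanner b-value of a PGSE sequence
#'
#' \eqn{b = (\gamma G_0 \delta)^2 (\Delta - \delta/3)}, evaluated in SI and
#' returned in s/mm^2.
#'
#' @param acq An [acquisition_params()].
#' @return b in s/mm^2.
#' @examples
#' b_value_pgse(acquisition_params())  # ~1132 for the default sequence
#' @export
b_value_pgse <- function(acq) {
  stopifnot(inherits(acq, "acquisition_params"))
  delta <- acq$delta * 1e-3
  Delta <- acq$Delta * 1e-3
  b_si <- (acq$gamma * acq$G0 * delta)^2 * (Delta - delta / 3)  # s/m^2
  b_si / 1e6
}
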