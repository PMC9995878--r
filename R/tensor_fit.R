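#' Construct a diffusion tensor object
#'
#' @param components Named or positional numeric vector
#'   (dxx, dyy, dzz, dxy, dxz, dyz) in 1e-9 m^2/s.
#' @param s0 Fitted non-diffusion-weighted signal (> 0, arbitrary units).
#' @param n_floored Number of non-positive signals floored during the fit.
#' @return An object of class `diffusion_tensor`.
#' @export
diffusion_tensor <- function(components, s0 = 1, n_floored = 0L) {
  components <- as.numeric(components)
  stopifnot(length(components) == 6, all(is.finite(components)),
            is.finite(s0), s0 > 0)
  names(components) <- c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz")
  structure(list(components = components, s0 = s0,
                 n_floored = as.integer(n_floored)),
            class = "diffusion_tensor")
}

#' @export
print.diffusion_tensor <- function(x, ...) {
  cat("diffusion tensor (1e-9 m^2/s), s0 =", format(x$s0, digits = 4), "\n")
  print(round(tensor_matrix(x), 4))
  invisible(x)
}

#' 3 x 3 symmetric matrix form of a diffusion tensor
#'
#' @param t A [diffusion_tensor()].
#' @return A 3 x 3 numeric matrix in 1e-9 m^2/s.
#' @export
tensor_matrix <- function(t) {
  d <- t$components
  matrix(c(d["dxx"], d["dxy"], d["dxz"],
           d["dxy"], d["dyy"], d["dyz"],
           d["dxz"], d["dyz"], d["dzz"]), 3, 3)
}

#' Fit a diffusion tensor by log-linear least squares
#'
#' Ordinary (unweighted) least squares of \code{log(signals)} against the
#' seven-column design of [build_design_matrix()]. A weighted variant
#' (weights proportional to the squared signal, the usual first-order
#' variance correction for log-transformed magnitude data) is available via
#' `weighted = TRUE`.
#'
#' Non-positive signals cannot enter the log; they are replaced by a floor
#' (default: smallest positive signal times 1e-3) and counted in the
#' returned object's `n_floored` field.
#'
#' @param signals Numeric vector, one per measurement, same order as the
#'   scheme.
#' @param scheme A [gradient_scheme()].
#' @param weighted Use signal-squared weights instead of OLS.
#' @param floor Replacement value for non-positive signals, or `NULL` for
#'   the default rule.
#' @return A [diffusion_tensor()] in 1e-9 m^2/s with fitted `s0`.
#' @export
fit_tensor_lls <- function(signals, scheme, weighted = FALSE, floor = NULL) {
  signals <- as.numeric(signals)
  if (length(signals) != scheme$n_meas)
    stop("signal vector length does not match the gradient scheme")
  if (all(signals <= 0)) stop("all signals are non-positive")
  n_floored <- sum(signals <= 0)
  if (n_floored > 0) {
    if (is.null(floor)) floor <- min(signals[signals > 0]) * 1e-3
    warning(sprintf("%d non-positive signal(s) floored at %g",
                    n_floored, floor))
    signals[signals <= 0] <- floor
  }
  X <- build_design_matrix(scheme)
  y <- log(signals)
  if (weighted) {
    w <- signals^2
    beta <- qr.coef(qr(X * sqrt(w)), y * sqrt(w))
  } else {
    beta <- qr.coef(qr(X), y)
  }
  # coefficients are in mm^2/s; report in 1e-9 m^2/s (= 1e-3 mm^2/s)
  diffusion_tensor(beta[1:6] * 1e3, s0 = exp(unname(beta[7])),
                   n_floored = n_floored)
}

#' Fit one tensor from region-averaged signals
#'
#' Averages the signal over the region voxels for each measurement first and
#' then fits a single tensor to the averaged signal vector (signal averaging
#' before fitting, which suppresses noise far more effectively than
#' averaging voxelwise tensors).
#'
#' @param dwi A [dwi_volume()].
#' @param mask Logical 3D array or integer matrix of voxel indices
#'   (rows = voxels, columns = x, y, z; 1-based).
#' @param ... Passed to [fit_tensor_lls()].
#' @return A [diffusion_tensor()].
#' @export
fit_tensor_region <- function(dwi, mask, ...) {
  sig <- region_mean_signals(dwi, mask)
  fit_tensor_lls(sig, dwi$scheme, ...)
}

# mean signal per measurement over a voxel set
region_mean_signals <- function(dwi, mask) {
  dm <- dim(dwi$data)
  if (is.logical(mask)) {
    if (!identical(dim(mask), dm[1:3]))
      stop("mask dimensions do not match the volume")
    idx <- which(mask)
  } else {
    mask <- as.matrix(mask)
    if (ncol(mask) != 3) stop("index mask must have 3 columns (x, y, z)")
    if (nrow(mask) == 0) stop("empty region mask")
    if (any(mask < 1) || any(mask[, 1] > dm[1]) ||
        any(mask[, 2] > dm[2]) || any(mask[, 3] > dm[3]))
      stop("mask indices outside the volume")
    idx <- mask[, 1] + dm[1] * (mask[, 2] - 1) + dm[1] * dm[2] * (mask[, 3] - 1)
  }
  if (length(idx) == 0) stop("empty region mask")
  flat <- matrix(dwi$data, nrow = prod(dm[1:3]), ncol = dm[4])
  colMeans(flat[idx, , drop = FALSE])
}

#' 4D diffusion-weighted volume
#'
#' @param data 4D non-negative array indexed (x, y, z, measurement).
#' @param voxel_size Voxel edge lengths in mm (length 3).
#' @param scheme The [gradient_scheme()] of the acquisition.
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, voxel_size, scheme) {
  stopifnot(length(dim(data)) == 4, length(voxel_size) == 3,
            all(voxel_size > 0))
  if (dim(data)[4] != scheme$n_meas)
    stop("4th dimension must equal the scheme's number of measurements")
  if (any(data < 0)) stop("signals must be non-negative")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 scheme = scheme),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("DWI volume %d x %d x %d, %d measurements, voxels %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(format(x$voxel_size, digits = 3), collapse = " x ")))
  invisible(x)
}

#' Voxelwise tensor fit over a volume
#'
#' Fits every voxel in `mask` (default: voxels whose b = 0 mean signal is
#' positive) by the same log-linear system as [fit_tensor_lls()], vectorised
#' as a single multi-response least-squares solve.
#'
#' @param dwi A [dwi_volume()].
#' @param mask Logical 3D array selecting voxels to fit, or `NULL`.
#' @return A list of class `dti_fit`: `evals` (x,y,z,3 array, descending,
#'   1e-9 m^2/s), `evecs` (x,y,z,3,3; `[ , , , , k]` is the k-th
#'   eigenvector), `md`, `fa`, `axial_radial_ratio`, `s0` (3D arrays, `NA`
#'   outside the mask), `mask`, and `n_clamped` (voxels with negative
#'   eigenvalues clamped for the indices).
#' @export
fit_dti_volume <- function(dwi, mask = NULL) {
  dm <- dim(dwi$data)
  b0 <- dwi$scheme$bvals == 0
  if (is.null(mask)) {
    m <- apply(dwi$data[, , , b0, drop = FALSE], 1:3, mean)
    mask <- m > 0
  }
  stopifnot(identical(dim(mask), dm[1:3]))
  idx <- which(mask)
  if (length(idx) == 0) stop("empty fitting mask")
  flat <- matrix(dwi$data, nrow = prod(dm[1:3]), ncol = dm[4])[idx, ,
                                                               drop = FALSE]
  floor_val <- {
    pos <- flat[flat > 0]
    if (length(pos) == 0) stop("all signals are non-positive")
    min(pos) * 1e-3
  }
  flat[flat <= 0] <- floor_val
  X <- build_design_matrix(dwi$scheme)
  beta <- qr.coef(qr(X), t(log(flat)))  # 7 x nvox
  D6 <- t(beta[1:6, , drop = FALSE]) * 1e3
  s0v <- exp(beta[7, ])

  nv <- length(idx)
  evals <- matrix(NA_real_, nv, 3)
  evecs <- array(NA_real_, c(nv, 3, 3))
  for (i in seq_len(nv)) {
    es <- eigendecompose(diffusion_tensor(D6[i, ], s0 = s0v[i]))
    evals[i, ] <- es$values
    evecs[i, , ] <- es$vectors
  }
  vals <- pmax(evals, 0)
  n_clamped <- sum(rowSums(evals < 0) > 0)
  md_v <- rowMeans(vals)
  num <- rowSums((vals - md_v)^2)
  den <- rowSums(vals^2)
  fa_v <- ifelse(den > 0, sqrt(1.5 * num / den), 0)
  rad <- (vals[, 2] + vals[, 3]) / 2
  ratio_v <- ifelse(rad > 0, vals[, 1] / rad, NA_real_)

  blank3 <- array(NA_real_, dm[1:3])
  out_evals <- array(NA_real_, c(dm[1:3], 3))
  out_evecs <- array(NA_real_, c(dm[1:3], 3, 3))
  for (k in 1:3) {
    a <- blank3; a[idx] <- evals[, k]; out_evals[, , , k] <- a
    for (j in 1:3) {
      a <- blank3; a[idx] <- evecs[, j, k]; out_evecs[, , , j, k] <- a
    }
  }
  md <- blank3; md[idx] <- md_v
  fa <- blank3; fa[idx] <- fa_v
  ratio <- blank3; ratio[idx] <- ratio_v
  s0 <- blank3; s0[idx] <- s0v
  structure(list(evals = out_evals, evecs = out_evecs, md = md, fa = fa,
                 axial_radial_ratio = ratio, s0 = s0, mask = mask,
                 n_clamped = n_clamped),
            class = "dti_fit")
}

#' Diagonalise a diffusion tensor
#'
#' Eigenvalues are returned in descending order; each eigenvector is
#' sign-normalised so that its largest-magnitude component is positive,
#' making the output deterministic. Negative eigenvalues (possible in noisy
#' fits) pass through unchanged; clamping happens in [dti_indices()].
#'
#' @param t A [diffusion_tensor()] or a symmetric 3 x 3 matrix.
#' @return An object of class `eigen_system` with `values` (length 3,
#'   descending) and `vectors` (3 x 3, column k is the k-th eigenvector).
#' @export
eigendecompose <- function(t) {
  M <- if (inherits(t, "diffusion_tensor")) tensor_matrix(t) else as.matrix(t)
  stopifnot(all(is.finite(M)), nrow(M) == 3, ncol(M) == 3)
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  V <- es$vectors
  for (k in 1:3) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  structure(list(values = es$values, vectors = V), class = "eigen_system")
}

#' @export
print.eigen_system <- function(x, ...) {
  cat("eigenvalues (1e-9 m^2/s):", format(x$values, digits = 4), "\n")
  invisible(x)
}

.eigvals <- function(es) {
  if (inherits(es, "eigen_system")) es$values else as.numeric(es)
}

#' Mean diffusivity
#'
#' \eqn{MD = (D_1 + D_2 + D_3) / 3}.
#'
#' @param es An `eigen_system` or a numeric eigenvalue triple.
#' @param clamp Clamp negative eigenvalues to zero first (default `TRUE`).
#' @return MD in 1e-9 m^2/s.
#' @examples
#' compute_md(c(0.77, 0.40, 0.37))  # 0.51 to 2 d.p.
#' @export
compute_md <- function(es, clamp = TRUE) {
  v <- .eigvals(es)
  if (clamp) v <- pmax(v, 0)
  mean(v)
}

#' Fractional anisotropy
#'
#' \eqn{FA = \sqrt{3/2}\,\sqrt{\sum_i (D_i - MD)^2} / \sqrt{\sum_i D_i^2}},
#' evaluated on eigenvalues clamped at zero so that the result stays in
#' \[0, 1\]. An all-zero triple has FA defined as 0.
#'
#' @inheritParams compute_md
#' @return FA, dimensionless in \[0, 1\].
#' @examples
#' compute_fa(c(0.77, 0.40, 0.37))  # 0.41 to 2 d.p.
#' compute_fa(c(1, 0, 0))           # 1
#' @export
compute_fa <- function(es, clamp = TRUE) {
  v <- .eigvals(es)
  if (clamp) v <- pmax(v, 0)
  den <- sum(v^2)
  if (den == 0) return(0)
  md <- mean(v)
  sqrt(1.5 * sum((v - md)^2) / den)
}

#' Axial-to-radial diffusivity ratio
#'
#' \eqn{D_\parallel / D_\perp = D_1 / ((D_2 + D_3)/2)}.
#'
#' @inheritParams compute_md
#' @return Dimensionless ratio (>= 0).
#' @examples
#' compute_axial_radial_ratio(c(2, 1, 1))  # 2
#' @export
compute_axial_radial_ratio <- function(es, clamp = TRUE) {
  v <- .eigvals(es)
  if (clamp) v <- pmax(v, 0)
  rad <- (v[2] + v[3]) / 2
  if (rad <= 0) stop("degenerate radial diffusivity")
  v[1] / rad
}

#' All diffusion tensor indices of an eigen system
#'
#' @inheritParams compute_md
#' @return A list with `md`, `fa`, `axial_radial_ratio` and `clamped`
#'   (whether any eigenvalue was negative).
#' @export
dti_indices <- function(es, clamp = TRUE) {
  v <- .eigvals(es)
  list(md = compute_md(v, clamp),
       fa = compute_fa(v, clamp),
       axial_radial_ratio = compute_axial_radial_ratio(v, clamp),
       clamped = any(v < 0))
}
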