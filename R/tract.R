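#' Deterministic first-eigenvector streamline tracking
#'
#' Euler integration along the principal eigenvector field, bidirectionally
#' from each seed. At each step the local e1 (nearest-neighbour lookup by
#' default) is sign-aligned with the previous step direction — eigenvectors
#' are line fields, so a global sign flip leaves the geometry unchanged.
#' Tracking stops when FA drops below `fa_min`, the turning angle exceeds
#' `angle_max`, the position leaves the volume, or `max_steps` is reached.
#'
#' @param e1 Array (x, y, z, 3) of first-eigenvector components.
#' @param fa 3D FA array (NA treated as 0).
#' @param seeds Matrix of seed positions in mm (rows = seeds, columns =
#'   x, y, z), e.g. from [seed_points()].
#' @param voxel_size Voxel edge lengths in mm.
#' @param step_mm Step length; default half the smallest voxel edge.
#' @param fa_min FA termination threshold.
#' @param angle_max Maximum turning angle per step, degrees.
#' @param max_steps Maximum steps per direction.
#' @return An object of class `streamline_set`: a list with `streamlines`
#'   (each a matrix of mm positions) and `termination` (two-column
#'   character matrix: stop reason of the backward/forward ends, one of
#'   `low_fa`, `high_angle`, `out_of_volume`, `max_steps`).
#' @export
track_streamlines <- function(e1, fa, seeds, voxel_size,
                              step_mm = NULL, fa_min = 0.15,
                              angle_max = 60, max_steps = 2000) {
  dm <- dim(fa)
  stopifnot(identical(dim(e1)[1:3], dm), dim(e1)[4] == 3)
  seeds <- matrix(as.numeric(seeds), ncol = 3)
  if (is.null(step_mm)) step_mm <- 0.5 * min(voxel_size)
  fa[is.na(fa)] <- 0
  cos_max <- cos(angle_max * pi / 180)
  nvox <- prod(dm)
  e1_flat <- matrix(e1, nvox, 3)
  ext <- dm * voxel_size

  vox_of <- function(p) {
    # 1-based voxel index of mm positions (rows of p); NA outside
    ix <- floor(p[, 1] / voxel_size[1]) + 1L
    iy <- floor(p[, 2] / voxel_size[2]) + 1L
    iz <- floor(p[, 3] / voxel_size[3]) + 1L
    ok <- ix >= 1L & ix <= dm[1] & iy >= 1L & iy <= dm[2] &
      iz >= 1L & iz <= dm[3]
    lin <- ifelse(ok, ix + dm[1] * (iy - 1L) + dm[1] * dm[2] * (iz - 1L),
                  NA_integer_)
    lin
  }

  seed_lin <- vox_of(seeds)
  valid <- !is.na(seed_lin) & fa[ifelse(is.na(seed_lin), 1L, seed_lin)] >= fa_min
  if (!any(valid)) {
    warning("no seeds above the FA threshold")
    return(structure(list(streamlines = list(),
                          termination = matrix(character(0), 0, 2)),
                     class = "streamline_set"))
  }
  seeds <- seeds[valid, , drop = FALSE]
  ns <- nrow(seeds)

  half_track <- function(dir_sign) {
    # integrate all seeds at once in one direction; returns per-seed list
    # of positions (excluding the seed itself) and the stop reason
    pos <- seeds
    prev <- e1_flat[vox_of(seeds), , drop = FALSE] * dir_sign
    active <- rep(TRUE, ns)
    reason <- rep(NA_character_, ns)
    paths <- vector("list", ns)
    for (i in seq_len(ns)) paths[[i]] <- matrix(numeric(0), 0, 3)
    for (step in seq_len(max_steps)) {
      if (!any(active)) break
      idx <- which(active)
      lin <- vox_of(pos[idx, , drop = FALSE])
      out <- is.na(lin)
      low <- !out & fa[ifelse(is.na(lin), 1L, lin)] < fa_min
      v <- matrix(0, length(idx), 3)
      v[!out & !low, ] <- e1_flat[lin[!out & !low], , drop = FALSE]
      dots <- rowSums(v * prev[idx, , drop = FALSE])
      v <- v * ifelse(dots < 0, -1, 1)
      dots <- abs(dots)
      turn <- !out & !low & dots < cos_max
      stopped <- out | low | turn
      reason[idx[out]] <- "out_of_volume"
      reason[idx[low & !out]] <- "low_fa"
      reason[idx[turn]] <- "high_angle"
      active[idx[stopped]] <- FALSE
      go <- idx[!stopped]
      if (length(go)) {
        vv <- v[!stopped, , drop = FALSE]
        nrm <- sqrt(rowSums(vv^2))
        zero <- nrm < 1e-12
        if (any(zero)) {
          reason[go[zero]] <- "low_fa"
          active[go[zero]] <- FALSE
          go <- go[!zero]; vv <- vv[!zero, , drop = FALSE]
          nrm <- nrm[!zero]
        }
        if (length(go)) {
          vv <- vv / nrm
          newp <- pos[go, , drop = FALSE] + step_mm * vv
          for (j in seq_along(go))
            paths[[go[j]]] <- rbind(paths[[go[j]]], newp[j, ])
          pos[go, ] <- newp
          prev[go, ] <- vv
        }
      }
    }
    reason[is.na(reason)] <- "max_steps"
    list(paths = paths, reason = reason)
  }

  fw <- half_track(+1)
  bw <- half_track(-1)
  streamlines <- vector("list", ns)
  for (i in seq_len(ns)) {
    back <- bw$paths[[i]]
    streamlines[[i]] <- rbind(back[rev(seq_len(nrow(back))), , drop = FALSE],
                              seeds[i, , drop = FALSE],
                              fw$paths[[i]])
  }
  keep <- vapply(streamlines, nrow, integer(1)) >= 2
  structure(list(streamlines = streamlines[keep],
                 termination = cbind(backward = bw$reason,
                                     forward = fw$reason)[keep, ,
                                                          drop = FALSE],
                 step_mm = step_mm),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  n <- length(x$streamlines)
  if (n == 0) { cat("empty streamline set\n"); return(invisible(x)) }
  len <- vapply(x$streamlines, nrow, integer(1))
  cat(sprintf("%d streamlines, %d-%d points (step %.3g mm)\n",
              n, min(len), max(len), x$step_mm))
  invisible(x)
}

#' Seed positions at the centres of masked voxels
#'
#' @param mask Logical 3D array.
#' @param voxel_size Voxel edge lengths in mm.
#' @param every Keep every `every`-th masked voxel (subsampling).
#' @return Matrix of mm positions (rows = seeds).
#' @export
seed_points <- function(mask, voxel_size, every = 1L) {
  idx <- which(mask, arr.ind = TRUE)
  idx <- idx[seq(1, nrow(idx), by = every), , drop = FALSE]
  sweep(idx - 0.5, 2, voxel_size, "*")
}

#' Direction-encoded colour of a principal eigenvector
#'
#' The conventional DTI colour map: red for x, green for y, blue for z,
#' with intensity the absolute eigenvector component.
#'
#' @param e1 Unit 3-vector (or matrix with rows of unit vectors).
#' @return RGB triple(s) in \[0, 1\].
#' @examples
#' eigenvector_rgb(c(0, 0, 1))  # blue: fibre along the nerve axis
#' @export
eigenvector_rgb <- function(e1) {
  if (is.matrix(e1)) pmin(abs(e1), 1) else pmin(abs(as.numeric(e1)), 1)
}

#' Diffusion-ellipsoid glyph field
#'
#' One glyph per retained voxel: semi-axes proportional to the (clamped)
#' eigenvalues, orientation from the eigenvectors, colour from the first
#' eigenvector direction. Isotropic voxels become spheres (the epineurium
#' shows as small dots); zero tensors are skipped.
#'
#' @param evals Array (x, y, z, 3) of eigenvalues, descending.
#' @param evecs Array (x, y, z, 3, 3); `[ , , , , k]` the k-th eigenvector.
#' @param voxel_size Voxel edge lengths in mm.
#' @param subsample Keep every `subsample`-th voxel per axis (>= 1).
#' @param scale Semi-axis length per unit eigenvalue (mm per 1e-9 m^2/s).
#' @return A `data.frame` with glyph centre (mm), semi-axes, the flattened
#'   rotation matrix (`r11`..`r33`, columns = eigenvectors) and `rgb`
#'   colour channels.
#' @export
ellipsoid_field <- function(evals, evecs, voxel_size, subsample = 1L,
                            scale = 0.25) {
  stopifnot(subsample >= 1)
  dm <- dim(evals)[1:3]
  xs <- seq(1, dm[1], by = subsample)
  ys <- seq(1, dm[2], by = subsample)
  zs <- seq(1, dm[3], by = subsample)
  rows <- list()
  for (iz in zs) for (iy in ys) for (ix in xs) {
    v <- pmax(evals[ix, iy, iz, ], 0)
    if (all(is.na(v)) || sum(v, na.rm = TRUE) == 0) next
    V <- evecs[ix, iy, iz, , ]
    e1 <- V[, 1]
    rgb <- eigenvector_rgb(e1 / sqrt(sum(e1^2)))
    rows[[length(rows) + 1L]] <- data.frame(
      x = (ix - 0.5) * voxel_size[1],
      y = (iy - 0.5) * voxel_size[2],
      z = (iz - 0.5) * voxel_size[3],
      a1 = scale * v[1], a2 = scale * v[2], a3 = scale * v[3],
      r11 = V[1, 1], r21 = V[2, 1], r31 = V[3, 1],
      r12 = V[1, 2], r22 = V[2, 2], r32 = V[3, 2],
      r13 = V[1, 3], r23 = V[2, 3], r33 = V[3, 3],
      red = rgb[1], green = rgb[2], blue = rgb[3])
  }
  if (length(rows) == 0)
    return(data.frame())
  do.call(rbind, rows)
}

#' Write streamlines in TrackVis TRK format
#'
#' Minimal TRK v2 writer (little-endian, 1000-byte header, voxel-mm point
#' coordinates, no per-point scalars or per-track properties).
#'
#' @param sl A `streamline_set`.
#' @param path Output file.
#' @param dim Volume dimensions (3 integers).
#' @param voxel_size Voxel edge lengths in mm.
#' @return Invisibly, the path.
#' @export
write_trk <- function(sl, path, dim, voxel_size) {
  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(s, n) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(n - length(raw))), con)
  }
  wchar("TRACK", 6)
  writeBin(as.integer(dim), con, size = 2, endian = "little")
  writeBin(as.numeric(voxel_size), con, size = 4, endian = "little")
  writeBin(numeric(3), con, size = 4, endian = "little")       # origin
  writeBin(0L, con, size = 2, endian = "little")               # n_scalars
  writeBin(raw(10 * 20), con)
  writeBin(0L, con, size = 2, endian = "little")               # n_properties
  writeBin(raw(10 * 20), con)
  vox2ras <- diag(c(voxel_size, 1))
  writeBin(as.numeric(t(vox2ras)), con, size = 4, endian = "little")
  writeBin(raw(444), con)                                      # reserved
  wchar("LPS", 4)                                              # voxel_order
  writeBin(raw(4), con)                                        # pad2
  writeBin(c(1, 0, 0, 0, 1, 0), con, size = 4, endian = "little")
  writeBin(raw(2), con)                                        # pad1
  writeBin(raw(6), con)                                        # invert flags
  writeBin(length(sl$streamlines), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")               # version
  writeBin(1000L, con, size = 4, endian = "little")            # hdr_size
  for (pts in sl$streamlines) {
    writeBin(nrow(pts), con, size = 4, endian = "little")
    writeBin(as.numeric(t(pts)), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a TRK streamline file
#'
#' Counterpart of [write_trk()] for round-trip checks and downstream use.
#'
#' @param path TRK file.
#' @return A list with `streamlines` (matrices of mm positions), `dim`,
#'   `voxel_size`, `n`.
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 6))
  if (!startsWith(magic, "TRACK")) stop("not a TRK file")
  dim <- readBin(con, "integer", 3, size = 2, endian = "little")
  voxel_size <- readBin(con, "numeric", 3, size = 4, endian = "little")
  invisible(readBin(con, "numeric", 3, size = 4, endian = "little"))
  n_scalars <- readBin(con, "integer", 1, size = 2, endian = "little")
  invisible(readBin(con, "raw", 200))
  n_props <- readBin(con, "integer", 1, size = 2, endian = "little")
  invisible(readBin(con, "raw", 200))
  invisible(readBin(con, "numeric", 16, size = 4, endian = "little"))
  invisible(readBin(con, "raw", 444 + 4 + 4))
  invisible(readBin(con, "numeric", 6, size = 4, endian = "little"))
  invisible(readBin(con, "raw", 2 + 6))
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  invisible(readBin(con, "integer", 2, size = 4, endian = "little"))
  streamlines <- vector("list", n)
  for (i in seq_len(n)) {
    np <- readBin(con, "integer", 1, size = 4, endian = "little")
    pts <- readBin(con, "numeric", np * (3 + n_scalars), size = 4,
                   endian = "little")
    streamlines[[i]] <- matrix(pts, ncol = 3 + n_scalars,
                               byrow = TRUE)[, 1:3, drop = FALSE]
    if (n_props > 0)
      invisible(readBin(con, "numeric", n_props, size = 4,
                        endian = "little"))
  }
  list(streamlines = streamlines, dim = dim, voxel_size = voxel_size, n = n)
}

#' Fraction of streamline length inside a label set
#'
#' Audits a streamline set against a label map: for each streamline, the
#' fraction of its points whose voxel carries one of the wanted labels, and
#' the fraction of streamlines entirely inside. Used to verify that
#' fascicle-seeded tracks stay within fascicular tissue.
#'
#' @param sl A `streamline_set`.
#' @param labels A `compartment_labels`.
#' @param compartments Character vector of compartment selectors (see
#'   [compartment_mask()]); a point inside any of them counts.
#' @return A list with `per_streamline` (fractions) and `all_inside`
#'   (fraction of streamlines never leaving the label set).
#' @export
streamline_label_audit <- function(sl, labels,
                                   compartments = c("fascicle",
                                                    "perineurium")) {
  mask <- Reduce(`|`, lapply(compartments, compartment_mask, labels = labels))
  dm <- dim(mask)
  vs <- labels$voxel_size
  frac <- vapply(sl$streamlines, function(pts) {
    ix <- pmin(pmax(floor(pts[, 1] / vs[1]) + 1L, 1L), dm[1])
    iy <- pmin(pmax(floor(pts[, 2] / vs[2]) + 1L, 1L), dm[2])
    iz <- pmin(pmax(floor(pts[, 3] / vs[3]) + 1L, 1L), dm[3])
    mean(mask[cbind(ix, iy, iz)])
  }, numeric(1))
  list(per_streamline = frac, all_inside = mean(frac == 1))
}
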