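#' Cross-sectional area of a slice mask
#'
#' Voxel count times in-plane voxel area. Boundary voxels count by label
#' identity; no sub-voxel polygon estimation.
#'
#' @param mask Logical 2D slice mask (or anything `sum()`-able to a voxel
#'   count).
#' @param voxel_size Voxel edge lengths in mm (the first two entries give
#'   the in-plane area).
#' @return Area in mm^2 (0 with a warning for an empty mask).
#' @export
compute_csa <- function(mask, voxel_size) {
  n <- sum(mask)
  if (n == 0) {
    warning("empty mask: CSA = 0")
    return(0)
  }
  n * voxel_size[1] * voxel_size[2]
}

#' Per-slice fascicular morphometry
#'
#' Computes, for one slice of a compartment label map, the fascicle count,
#' per-fascicle and nerve cross-sectional areas, and the compartment
#' ratios: fascicular ratio FR = summed fascicle CSA / nerve CSA, and the
#' analogous perineurium and epineurium ratios. The nerve CSA (union of all
#' intra-nerve labels) is always the denominator, so the three ratios sum
#' to at most 1 (exactly 1 when the labels partition the nerve, as phantom
#' maps do).
#'
#' @param labels A `compartment_labels` (or a list with `labels`, `legend`,
#'   `voxel_size`).
#' @param slice Slice index (1-based).
#' @param nerve_id Identifier copied into the output row.
#' @return A one-row `data.frame` with columns `nerve_id`, `slice`,
#'   `n_fascicles`, `nerve_csa`, `fascicle_csa_total`, `fascicle_csa_mean`,
#'   `fascicular_ratio`, `perineurium_ratio`, `epineurium_ratio`.
#' @export
compute_ratios <- function(labels, slice, nerve_id = "phantom") {
  lg <- labels$legend
  K <- sum(grepl("^fascicle_", names(lg)))
  sl <- labels$labels[, , slice]
  vs <- labels$voxel_size
  f_present <- intersect(seq_len(K), unique(as.vector(sl)))
  nerve_n <- sum(sl %in% unname(lg))
  if (nerve_n == 0) stop("nerve CSA is zero on slice ", slice)
  area <- vs[1] * vs[2]
  nerve_csa <- nerve_n * area
  f_csa <- vapply(f_present, function(k) sum(sl == k) * area, numeric(1))
  peri_csa <- sum(sl == unname(lg["perineurium"])) * area
  epi_csa <- sum(sl == unname(lg["epineurium"])) * area
  data.frame(nerve_id = nerve_id, slice = slice,
             n_fascicles = length(f_present),
             nerve_csa = nerve_csa,
             fascicle_csa_total = sum(f_csa),
             fascicle_csa_mean = if (length(f_csa)) mean(f_csa) else 0,
             fascicular_ratio = sum(f_csa) / nerve_csa,
             perineurium_ratio = peri_csa / nerve_csa,
             epineurium_ratio = epi_csa / nerve_csa)
}

#' Morphometry table over all slices
#'
#' @inheritParams compute_ratios
#' @param slices Slice indices to include (default: all). Slices excluded
#'   by quality control are simply left off this list.
#' @return A `data.frame` with one row per slice.
#' @export
morphometry_table <- function(labels, slices = NULL, nerve_id = "phantom") {
  if (is.null(slices)) slices <- seq_len(dim(labels$labels)[3])
  do.call(rbind, lapply(slices, function(s)
    compute_ratios(labels, s, nerve_id = nerve_id)))
}

#' Region-averaged signal vector of a compartment
#'
#' Arithmetic mean of the signal over the compartment's voxels, per
#' measurement, over a slice range. This is the input to
#' [fit_tensor_region()]-style fitting: averaging signals before the fit.
#'
#' @param dwi A [dwi_volume()].
#' @param labels A `compartment_labels`.
#' @param compartment Compartment selector, see [compartment_mask()].
#' @param slices Slice indices to include (default all).
#' @return Numeric vector of length `scheme$n_meas`.
#' @export
extract_region_signals <- function(dwi, labels, compartment, slices = NULL) {
  mask <- compartment_mask(labels, compartment)
  if (!is.null(slices)) {
    keep <- array(FALSE, dim(mask))
    keep[, , slices] <- TRUE
    mask <- mask & keep
  }
  if (!any(mask))
    stop("compartment '", compartment, "' absent in the selected slices; ",
         "available: ", paste(names(labels$legend), collapse = ", "))
  region_mean_signals(dwi, mask)
}

#' Per-slice, per-compartment tensor fits of a labelled volume
#'
#' For each included slice and each compartment (every fascicle, the
#' perineurium, the epineurium, and the whole nerve), averages the signal
#' over the compartment's voxels on that slice, fits one tensor, and
#' tabulates eigenvalues and indices.
#'
#' @param dwi A [dwi_volume()].
#' @param labels A `compartment_labels`.
#' @param slices Slice indices (default all).
#' @param nerve_id Identifier for the output.
#' @return A `data.frame` with columns `nerve_id`, `slice`, `compartment`,
#'   `label`, `d1`, `d2`, `d3`, `md`, `fa`, `axial_radial_ratio`,
#'   `n_voxels`.
#' @export
compartment_indices <- function(dwi, labels, slices = NULL,
                                nerve_id = "phantom") {
  if (is.null(slices)) slices <- seq_len(dim(labels$labels)[3])
  lg <- labels$legend
  K <- sum(grepl("^fascicle_", names(lg)))
  comps <- c(stats::setNames(as.list(seq_len(K)),
                             paste0("fascicle_", seq_len(K))),
             list(perineurium = unname(lg["perineurium"]),
                  epineurium = unname(lg["epineurium"]),
                  nerve = NA))
  rows <- list()
  for (s in slices) {
    sl <- labels$labels[, , s]
    for (nm in names(comps)) {
      want <- if (nm == "nerve") unname(lg) else comps[[nm]]
      in_c <- sl %in% want
      n_vox <- sum(in_c)
      if (n_vox == 0) next
      mask <- array(FALSE, dim(labels$labels))
      mask[, , s] <- in_c
      fit <- fit_tensor_region(dwi, mask)
      es <- eigendecompose(fit)
      idc <- dti_indices(es)
      rows[[length(rows) + 1L]] <- data.frame(
        nerve_id = nerve_id, slice = s, compartment = sub("_[0-9]+$", "", nm),
        label = if (nm == "nerve") NA_integer_ else comps[[nm]],
        d1 = es$values[1], d2 = es$values[2], d3 = es$values[3],
        md = idc$md, fa = idc$fa, axial_radial_ratio = idc$axial_radial_ratio,
        n_voxels = n_vox)
    }
  }
  do.call(rbind, rows)
}
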