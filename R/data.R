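#' Published per-compartment diffusion tensor index table
#'
#' The per-nerve mean eigenvalues (D1 >= D2 >= D3, 1e-9 m^2/s) and derived
#' indices (MD, FA, D||/D-perp) of the five ex vivo median nerve samples
#' the package's phantom emulates, per compartment (fascicles,
#' interfascicular epineurium, perineurium) plus the whole-nerve summary
#' row. `nerve` is `"1"`..`"5"` or `"mean"` for the across-sample summary.
#' The default phantom's compartment tensors are the `mean` rows of this
#' table.
#'
#' Note that the tabulated MD/FA/ratio columns are means of per-fascicle
#' (or per-slice) index values, not indices of the tabulated mean
#' eigenvalues; the two agree only approximately (compare
#' `compute_fa(c(0.77, 0.40, 0.37))` with the corresponding FA cell).
#'
#' @return A `data.frame` with columns `compartment`, `nerve`, `d1`, `d2`,
#'   `d3`, `md`, `fa`, `axial_radial_ratio`, `n_slices`.
#' @export
printed_indices <- function() {
  utils::read.delim(system.file("extdata", "compartment_tables.tsv",
                                package = "nervedti", mustWork = TRUE),
                    colClasses = c(nerve = "character"))
}
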