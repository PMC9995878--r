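#!/usr/bin/env Rscript
# Step 2 -- fit diffusion tensors and tabulate per-compartment indices.
#
# Reads the phantom written by 01_simulate_phantom.R, fits every nerve
# voxel by log-linear least squares, and fits each compartment from its
# region-averaged signals per slice (signal averaging before fitting).
# Compares the region fits with the simulation ground truth and writes
# results/compartment_indices.tsv.

library(nervedti)

scheme <- read_gradient_table("results/phantom/dwi.bval",
                              "results/phantom/dwi.bvec")
img <- RNifti::readNifti("results/phantom/dwi.nii.gz")
spec_js <- jsonlite::read_json("results/phantom/phantom_spec.json",
                               simplifyVector = TRUE)
spec <- do.call(phantom_spec, spec_js)
labels <- generate_geometry(spec)  # deterministic: same spec, same map
dwi <- dwi_volume(unclass(img), spec$voxel_size, scheme)

tab <- compartment_indices(dwi, labels, nerve_id = "phantom42")
utils::write.table(tab, "results/compartment_indices.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

cat("Region-averaged fits vs ground truth (slice means):\n")
for (comp in c("fascicle", "perineurium", "epineurium")) {
  d <- tab[tab$compartment == comp, ]
  truth <- spec$compartment_tensors[[comp]]
  cat(sprintf("  %-12s D = (%.3f, %.3f, %.3f) truth (%.2f, %.2f, %.2f)  FA %.3f (truth %.3f)\n",
              comp, mean(d$d1), mean(d$d2), mean(d$d3),
              truth[1], truth[2], truth[3],
              mean(d$fa), compute_fa(truth)))
}
nerve <- tab[tab$compartment == "nerve", ]
cat(sprintf("  %-12s FA %.3f (mixes all compartments, hence below fascicle FA)\n",
            "nerve", mean(nerve$fa)))

vox <- fit_dti_volume(dwi, compartment_mask(labels, "fascicle"))
cat(sprintf("\nVoxelwise fascicle FA: %.3f -- above the region-averaged %.3f:\n",
            mean(vox$fa[compartment_mask(labels, "fascicle")]),
            mean(tab$fa[tab$compartment == "fascicle"])))
cat("the Rician noise floor inflates voxelwise anisotropy; region\n")
cat("averaging before fitting suppresses it.\n")
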