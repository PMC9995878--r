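#!/usr/bin/env Rscript
# Step 4 -- the study's statistics on the simulated nerve.
#
# From the per-compartment index table: within/between-fascicle CoV of FA,
# perineurium-vs-fascicle and epineurium-vs-fascicle MD contrasts, the
# slice-wise trend of nerve FA, the per-sample slope test of fascicle FA
# against fascicle CSA, and a one-way ICC of a simulated repeated
# segmentation. Writes results/stats.json.

library(nervedti)

tab <- read.delim("results/compartment_indices.tsv")
morpho <- read.delim("results/morphometry.tsv")
fas <- tab[tab$compartment == "fascicle", ]

out <- list(n_tests = 0L)
note <- function(...) cat(sprintf(...), "\n")

# fascicular FA variability: same fascicle across slices vs fascicles on
# the same slice
fa_mat <- stats::xtabs(fa ~ label + slice, data = fas)
fa_mat[fa_mat == 0] <- NA
cv <- cov_within_between(fa_mat)
out$cov_within <- mean(cv$within, na.rm = TRUE)
out$cov_between <- mean(cv$between, na.rm = TRUE)
note("Within-fascicle CoV of FA:  %.3f", out$cov_within)
note("Between-fascicle CoV of FA: %.3f", out$cov_between)

# cross-compartment MD contrasts, paired per slice
md_of <- function(comp) {
  d <- tab[tab$compartment == comp, ]
  stats::aggregate(md ~ slice, data = d, FUN = mean)$md
}
cc_peri <- compartment_contrast(md_of("perineurium"), md_of("fascicle"))
cc_epi <- compartment_contrast(md_of("epineurium"), md_of("fascicle"))
out$perineurium_md_pct_vs_fascicle <- cc_peri$mean_pct
out$epineurium_md_pct_vs_fascicle <- cc_epi$mean_pct
note("Perineurium MD vs fascicle: %+.1f%% +/- %.1f%%",
     cc_peri$mean_pct, cc_peri$sd_pct)
note("Epineurium MD vs fascicle:  %+.1f%% +/- %.1f%%",
     cc_epi$mean_pct, cc_epi$sd_pct)

# slice-wise trend of nerve FA
nerve <- tab[tab$compartment == "nerve", ]
tr <- slice_trend(nerve$slice, nerve$fa)
out$nerve_fa_slope <- tr$slope
out$nerve_fa_trend_p <- tr$p
out$n_tests <- out$n_tests + 1L
note("Nerve FA slice trend: slope %.2e per slice, r = %.2f, p = %.2g",
     tr$slope, tr$r, tr$p)

# fascicle FA vs fascicle CSA: per-sample slopes + one-sample t-test
# (split slices into two pseudo-samples for the demonstration)
fas$csa <- morpho$fascicle_csa_mean[match(fas$slice, morpho$slice)]
halves <- split(fas, fas$slice %% 2)
fc <- fascicle_correlation_test(lapply(halves, function(h)
  list(x = h$csa, y = h$fa)))
out$fa_vs_csa_p <- fc$p
out$fa_vs_csa_pooled_r <- fc$pooled_r
out$n_tests <- out$n_tests + 1L
note("Fascicle FA vs CSA: pooled r = %.2f, slope-test p = %.2g",
     fc$pooled_r, fc$p)

# intra-observer agreement: repeat the "segmentation" as a slightly
# perturbed re-measurement of per-fascicle FA (re-drawing a region border
# changes the region-averaged FA far less than voxel noise does) and
# compute the one-way ICC
set.seed(4L)
subj <- stats::aggregate(fa ~ label, data = fas, FUN = mean)$fa
ratings <- cbind(subj, subj + stats::rnorm(length(subj), 0, 0.002))
out$icc_fa_repeated <- icc_oneway(ratings)
note("One-way ICC(1) of repeated fascicle FA: %.3f", out$icc_fa_repeated)

jsonlite::write_json(out, "results/stats.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("wrote results/stats.json\n")
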