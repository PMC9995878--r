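#' Pipeline run configuration
#'
#' Assembles (and validates lightly) the configuration of a full analysis
#' run: either a phantom simulation or paths to an acquired dataset, plus
#' fit, morphometry, statistics and tracking options. Can be read from a
#' YAML file; explicit arguments override file values.
#'
#' @param config_file Optional YAML file with any of the fields below.
#' @param phantom `NULL` to read data from `paths`, or a list of
#'   [phantom_spec()] arguments (possibly empty for defaults).
#' @param paths List with `dwi`, `bval`, `bvec`, `labels`, `legend`
#'   (ignored when `phantom` is set).
#' @param output_dir Where the run writes its outputs.
#' @param fit Options: `weighted` (logical).
#' @param slices Slice include-list (`NULL` = all): slices excluded by
#'   visual quality control are simply left off.
#' @param tracking Options passed to [track_streamlines()] plus
#'   `seed_every` (seed subsampling) and `seed_slice` (`NULL` = middle).
#' @param seed Integer seed recorded in every output sidecar.
#' @param nerve_id Identifier used in output tables.
#' @return A list of class `run_config`.
#' @export
run_config <- function(config_file = NULL, phantom = list(), paths = NULL,
                       output_dir = tempfile("nervedti_run"),
                       fit = list(weighted = FALSE), slices = NULL,
                       tracking = list(), seed = 1L, nerve_id = "phantom") {
  cfg <- list(phantom = phantom, paths = paths, output_dir = output_dir,
              fit = fit, slices = slices, tracking = tracking,
              seed = as.integer(seed), nerve_id = nerve_id)
  if (!is.null(config_file)) {
    file_cfg <- yaml::read_yaml(config_file)
    # file values fill fields not given explicitly as arguments
    given <- c(phantom = !missing(phantom), paths = !missing(paths),
               output_dir = !missing(output_dir), fit = !missing(fit),
               slices = !missing(slices), tracking = !missing(tracking),
               seed = !missing(seed), nerve_id = !missing(nerve_id))
    for (nm in names(file_cfg))
      if (nm %in% names(given) && !given[[nm]]) cfg[[nm]] <- file_cfg[[nm]]
  }
  if (is.null(cfg$phantom) && is.null(cfg$paths))
    stop("config needs either a phantom spec or input paths")
  if (is.null(cfg$phantom)) {
    need <- c("dwi", "bval", "bvec", "labels", "legend")
    missing_p <- setdiff(need, names(cfg$paths))
    if (length(missing_p))
      stop("paths missing: ", paste(missing_p, collapse = ", "))
    for (p in unlist(cfg$paths[need]))
      if (!file.exists(p)) stop("input file not found: ", p)
  }
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  plain <- unclass(cfg)
  plain$output_dir <- NULL  # hash the science, not the destination
  yaml::write_yaml(plain, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full nerve DTI analysis pipeline
#'
#' Stages: (1) phantom simulation or data loading; (2) voxelwise and
#' per-slice region-averaged tensor fits; (3) morphometry; (4) statistics
#' (within/between-fascicle CoV of FA, cross-compartment contrasts, slice
#' trend of nerve FA, fascicle-level correlation tests); (5) streamline
#' tracking and ellipsoid glyph export. Every table is written as TSV, the
#' summary as JSON carrying the seed and a configuration hash; a stage
#' failure propagates with the stage name, retaining outputs written so
#' far.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the report, the file manifest, and the
#'   in-memory stage results.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  files <- character(0)
  tsv <- function(df, name) {
    p <- file.path(cfg$output_dir, name)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    files[name] <<- p
    p
  }
  warnings_seen <- 0L

  # -- stage: data -----------------------------------------------------
  dat <- stage("phantom", {
    if (!is.null(cfg$phantom)) {
      spec <- do.call(phantom_spec, c(cfg$phantom,
                                      if (!("seed" %in% names(cfg$phantom)))
                                        list(seed = cfg$seed)))
      ph <- nerve_phantom(spec)
      files <- c(files, write_phantom(ph, file.path(cfg$output_dir,
                                                    "phantom")))
      list(dwi = ph$dwi, labels = ph$labels, field = ph$field,
           scheme = ph$scheme, spec = spec)
    } else {
      scheme <- read_gradient_table(cfg$paths$bval, cfg$paths$bvec)
      img <- RNifti::readNifti(cfg$paths$dwi)
      vs <- RNifti::pixdim(img)[1:3]
      lab_img <- RNifti::readNifti(cfg$paths$labels)
      legend <- unlist(jsonlite::read_json(cfg$paths$legend))
      labels <- structure(list(labels = array(as.integer(lab_img),
                                              dim(lab_img)),
                               legend = legend, voxel_size = vs),
                          class = "compartment_labels")
      list(dwi = dwi_volume(unclass(img), vs, scheme), labels = labels,
           field = NULL, scheme = scheme, spec = NULL)
    }
  })
  slices <- cfg$slices %||% seq_len(dim(dat$labels$labels)[3])

  # -- stage: fit ------------------------------------------------------
  fits <- stage("fit", {
    nerve_mask <- compartment_mask(dat$labels, "nerve")
    vox <- fit_dti_volume(dat$dwi, mask = nerve_mask)
    warnings_seen <<- warnings_seen + vox$n_clamped
    per_comp <- compartment_indices(dat$dwi, dat$labels, slices = slices,
                                    nerve_id = cfg$nerve_id)
    tsv(per_comp, "compartment_indices.tsv")
    list(voxelwise = vox, per_comp = per_comp)
  })

  # -- stage: morphometry ---------------------------------------------
  morpho <- stage("morphometry", {
    m <- morphometry_table(dat$labels, slices = slices,
                           nerve_id = cfg$nerve_id)
    tsv(m, "morphometry.tsv")
    m
  })

  # -- stage: stats ----------------------------------------------------
  stats_out <- stage("stats", {
    pc <- fits$per_comp
    fas <- pc[pc$compartment == "fascicle", ]
    res <- list()
    if (length(unique(fas$label)) >= 2 && length(unique(fas$slice)) >= 2) {
      tab <- stats::xtabs(fa ~ label + slice, data = fas, sparse = FALSE)
      tab[tab == 0] <- NA  # absent fascicle-slice cells
      cv <- cov_within_between(tab)
      res$cov_within_mean <- mean(cv$within, na.rm = TRUE)
      res$cov_between_mean <- mean(cv$between, na.rm = TRUE)
    }
    by_slice <- function(comp, col) {
      d <- pc[pc$compartment == comp, ]
      stats::aggregate(d[[col]], list(slice = d$slice), mean)$x
    }
    peri_md <- by_slice("perineurium", "md")
    fasc_md <- by_slice("fascicle", "md")
    if (length(peri_md) == length(fasc_md) && length(fasc_md) > 1) {
      cc <- compartment_contrast(peri_md, fasc_md)
      res$perineurium_vs_fascicle_md_pct <- cc$mean_pct
      res$perineurium_vs_fascicle_md_sd <- cc$sd_pct
    }
    nerve_fa <- pc[pc$compartment == "nerve", ]
    if (nrow(nerve_fa) >= 3) {
      tr <- slice_trend(nerve_fa$slice, nerve_fa$fa)
      res$nerve_fa_slope <- tr$slope
      res$nerve_fa_trend_r <- tr$r
      res$nerve_fa_trend_p <- tr$p
    }
    # fascicle-level correlation: FA vs fascicle CSA, slopes tested vs 0
    fas_csa <- merge(fas,
                     stats::aggregate(
                       fascicle_csa_mean ~ slice, data = morpho, FUN = mean),
                     by = "slice")
    if (nrow(fas_csa) >= 6) {
      halves <- split(fas_csa, fas_csa$slice %% 2)  # two pseudo-samples
      if (length(halves) >= 2 && all(vapply(halves, nrow, 1L) >= 3)) {
        fc <- tryCatch(
          fascicle_correlation_test(lapply(halves, function(h)
            list(x = h$fascicle_csa_mean, y = h$fa))),
          error = function(e) NULL, warning = function(w) NULL)
        if (!is.null(fc)) {
          res$fa_vs_csa_p <- fc$p
          res$fa_vs_csa_pooled_r <- fc$pooled_r
        }
      }
    }
    res
  })

  # -- stage: tract ----------------------------------------------------
  tract <- stage("tract", {
    trk <- cfg$tracking
    seed_slice <- trk$seed_slice %||% ceiling(dim(dat$labels$labels)[3] / 2)
    fmask <- compartment_mask(dat$labels, "fascicle")
    smask <- array(FALSE, dim(fmask))
    smask[, , seed_slice] <- fmask[, , seed_slice]
    seeds <- seed_points(smask, dat$dwi$voxel_size,
                         every = trk$seed_every %||% 4L)
    e1 <- fits$voxelwise$evecs[, , , , 1]
    sl <- track_streamlines(e1, fits$voxelwise$fa, seeds,
                            dat$dwi$voxel_size,
                            step_mm = trk$step_mm %||% NULL,
                            fa_min = trk$fa_min %||% 0.15,
                            angle_max = trk$angle_max %||% 60,
                            max_steps = trk$max_steps %||% 2000)
    trk_path <- file.path(cfg$output_dir, "streamlines.trk")
    write_trk(sl, trk_path, dim(fits$voxelwise$fa), dat$dwi$voxel_size)
    files["streamlines.trk"] <- trk_path
    glyphs <- ellipsoid_field(fits$voxelwise$evals, fits$voxelwise$evecs,
                              dat$dwi$voxel_size,
                              subsample = trk$glyph_subsample %||% 4L)
    tsv(glyphs, "ellipsoids.tsv")
    list(streamlines = sl, n_streamlines = length(sl$streamlines))
  })

  report <- list(
    package_version = as.character(utils::packageVersion("nervedti")),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    nerve_id = cfg$nerve_id,
    n_slices = length(slices),
    n_voxels_fit = sum(fits$voxelwise$mask),
    n_clamped_voxels = fits$voxelwise$n_clamped,
    n_warnings = warnings_seen,
    n_streamlines = tract$n_streamlines,
    stats = stats_out)
  rp <- file.path(cfg$output_dir, "report.json")
  jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files["report.json"] <- rp
  invisible(list(report = report, files = files,
                 data = dat, fits = fits, morphometry = morpho,
                 stats = stats_out, tract = tract))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
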