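#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean; scale-invariant under
#' common positive rescaling.
#'
#' @param values Numeric vector (length >= 2, mean != 0).
#' @param na.rm Drop missing values.
#' @return Dimensionless CoV.
#' @export
coefficient_of_variation <- function(values, na.rm = FALSE) {
  if (na.rm) values <- values[!is.na(values)]
  m <- mean(values)
  if (m == 0) stop("coefficient of variation undefined for zero mean")
  stats::sd(values) / m
}

#' Within- and between-fascicle coefficients of variation
#'
#' From a fascicle x slice table of an index (typically FA): the
#' within-fascicle CoV follows each fascicle across sequential slices; the
#' between-fascicle CoV compares fascicles on the same slice.
#'
#' @param fa_table Numeric matrix, rows = fascicles, columns = slices.
#'   Missing cells (fascicle absent on a slice) are skipped and counted.
#' @return A list with `within` (per fascicle), `between` (per slice) and
#'   `n_missing`.
#' @export
cov_within_between <- function(fa_table) {
  fa_table <- as.matrix(fa_table)
  if (nrow(fa_table) < 2 || ncol(fa_table) < 2)
    stop("need at least 2 fascicles and 2 slices")
  within <- apply(fa_table, 1, coefficient_of_variation, na.rm = TRUE)
  between <- apply(fa_table, 2, coefficient_of_variation, na.rm = TRUE)
  list(within = within, between = between,
       n_missing = sum(is.na(fa_table)))
}

#' One-way intraclass correlation coefficient
#'
#' ICC(1) from the one-way random-effects ANOVA decomposition of an
#' n-subject x k-rating table:
#' \deqn{ICC(1) = (MS_B - MS_W) / (MS_B + (k-1) MS_W)}
#' where \eqn{MS_B} and \eqn{MS_W} are the between- and within-subject mean
#' squares. The single-rater form ICC(1,1) is the default; the averaged-
#' ratings form ICC(1,k) = (MS_B - MS_W)/MS_B is available via `type`.
#' Values can be negative; they are not clipped unless `clip = TRUE`.
#'
#' @param table Numeric matrix, rows = subjects (n >= 2), columns =
#'   repeated ratings (k >= 2), no missing cells.
#' @param type `"ICC1"` (single rating) or `"ICC1k"` (mean of k ratings).
#' @param clip Clip the result into \[0, 1\].
#' @return The ICC estimate.
#' @export
icc_oneway <- function(table, type = c("ICC1", "ICC1k"), clip = FALSE) {
  type <- match.arg(type)
  table <- as.matrix(table)
  n <- nrow(table); k <- ncol(table)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 ratings")
  if (anyNA(table)) stop("rating table must have no missing cells")
  grand <- mean(table)
  if (sum((table - grand)^2) == 0)
    stop("zero total variance: ICC undefined")
  row_means <- rowMeans(table)
  ssb <- k * sum((row_means - grand)^2)
  ssw <- sum((table - row_means)^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  icc <- switch(type,
                ICC1 = (msb - msw) / (msb + (k - 1) * msw),
                ICC1k = (msb - msw) / msb)
  if (clip) icc <- min(max(icc, 0), 1)
  icc
}

#' Linear trend of an index along the nerve
#'
#' Ordinary least-squares regression of an index (e.g. nerve FA) on slice
#' position: slope, Pearson r, and the two-sided t-test p-value for a
#' non-zero slope. A constant series returns slope 0, r 0, p 1 (no trend
#' detectable); a constant slice axis is an error.
#'
#' @param slice Ordered numeric slice positions (length >= 3).
#' @param value Index values, same length.
#' @return A list with `slope`, `intercept`, `r`, `p`, `n`.
#' @export
slice_trend <- function(slice, value) {
  stopifnot(length(slice) == length(value))
  if (length(slice) < 3) stop("need at least 3 slices for a trend")
  if (stats::sd(slice) == 0) stop("slice positions are constant")
  if (stats::sd(value) == 0)
    return(list(slope = 0, intercept = value[1], r = 0, p = 1,
                n = length(slice)))
  fit <- stats::lm(value ~ slice)
  # summary.lm warns on exact fits; those are legitimate inputs here
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = unname(stats::cor(slice, value)),
       p = unname(sm$coefficients[2, 4]),
       n = length(slice))
}

#' Per-sample regression slopes with a one-sample t-test
#'
#' The study design for fascicle-level correlation testing: fit an OLS
#' slope of y on x within each nerve sample, then test the collection of
#' slopes against zero with a one-sample t-test. A pooled Pearson r over
#' all pairs is reported alongside. Samples with a constant x are dropped
#' with a warning. If the slopes have zero variance the t statistic is
#' unbounded; p is reported as 0 (below machine tolerance) unless the
#' common slope is itself 0, in which case p = 1.
#'
#' @param per_nerve_pairs Named list; each element a list or data.frame
#'   with components `x` and `y` (>= 3 pairs each).
#' @return A list with `slopes` (named), `t`, `df`, `p`, `pooled_r`,
#'   `n_dropped`.
#' @export
fascicle_correlation_test <- function(per_nerve_pairs) {
  if (length(per_nerve_pairs) < 2)
    stop("need at least 2 nerve samples")
  slopes <- c(); dropped <- 0L
  all_x <- c(); all_y <- c()
  nms <- names2(per_nerve_pairs)
  for (i in seq_along(per_nerve_pairs)) {
    nm <- nms[i]
    p <- per_nerve_pairs[[i]]
    x <- as.numeric(p$x); y <- as.numeric(p$y)
    if (length(x) < 3 || length(x) != length(y))
      stop("sample '", nm, "' needs >= 3 (x, y) pairs")
    if (stats::sd(x) == 0) {
      warning("sample '", nm, "' has constant x; dropped")
      dropped <- dropped + 1L
      next
    }
    slopes[nm] <- unname(stats::coef(stats::lm(y ~ x))[2])
    all_x <- c(all_x, x); all_y <- c(all_y, y)
  }
  if (length(slopes) < 2)
    stop("fewer than 2 usable samples after dropping degenerate ones")
  if (stats::sd(slopes) == 0) {
    t_stat <- if (mean(slopes) == 0) 0 else sign(mean(slopes)) * Inf
    p_val <- if (mean(slopes) == 0) 1 else 0
  } else {
    tt <- stats::t.test(slopes, mu = 0)
    t_stat <- unname(tt$statistic)
    p_val <- tt$p.value
  }
  pooled_r <- if (stats::sd(all_x) > 0 && stats::sd(all_y) > 0)
    stats::cor(all_x, all_y) else NA_real_
  list(slopes = slopes, t = t_stat, df = length(slopes) - 1L, p = p_val,
       pooled_r = pooled_r, n_dropped = dropped)
}

names2 <- function(x) {
  nm <- names(x)
  if (is.null(nm)) nm <- paste0("sample_", seq_along(x))
  nm[nm == ""] <- paste0("sample_", which(nm == ""))
  nm
}

#' Paired per-slice percent contrast between two compartments
#'
#' Per slice, 100 (a - b) / b; returns the mean and SD across slices. This
#' is how cross-compartment differences such as "the perineurium had a
#' 50.6% higher MD than the fascicles" are summarised.
#'
#' @param per_slice_a,per_slice_b Numeric vectors paired by slice; `b`
#'   must be non-zero everywhere.
#' @return A list with `mean_pct`, `sd_pct`, `n`.
#' @export
compartment_contrast <- function(per_slice_a, per_slice_b) {
  stopifnot(length(per_slice_a) == length(per_slice_b))
  if (any(per_slice_b == 0)) stop("reference compartment has zero values")
  pct <- 100 * (per_slice_a - per_slice_b) / per_slice_b
  list(mean_pct = mean(pct), sd_pct = stats::sd(pct), n = length(pct))
}
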