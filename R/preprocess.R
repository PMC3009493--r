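#' Log2-transform a raw-scale expression matrix
#'
#' Values are clamped from below at `floor` before taking log2, so
#' non-positive raw intensities never reach the logarithm. With the default
#' `floor = 1` a raw value of 0 maps to 0 on the log2 scale.
#'
#' @param m A raw-scale [exprmat].
#' @param floor Positive clamp applied before the log (default 1).
#' @param force Transform even if `m` is already flagged log2.
#' @return The log2-scale [exprmat].
#' @export
log2_transform <- function(m, floor = 1, force = FALSE) {
  stopifnot(inherits(m, "exprmat"))
  if (m$scale == "log2" && !force)
    stop("matrix is already on the log2 scale (use force = TRUE to override)")
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0)
    stop("'floor' must be a single positive number")
  v <- log2(pmax(m$values, floor))
  exprmat(v, scale = "log2", labels = m$labels, description = m$description)
}

#' Filter features by minimum expression
#'
#' A feature (miRNA) is retained iff its log2 expression reaches `cutoff`
#' (inclusive) in at least `min_count` samples. The two filtering modes used
#' for bead-array tumor panels are expressed through the arguments:
#' a minimal-cutoff filter (drop miRNAs that never reach 7.25 on the log2
#' scale) is `cutoff = 7.25, min_count = 1`; a prevalence filter (at least 8
#' on the log2 scale in at least 10% of cell lines) is
#' `cutoff = 8, min_count = ceiling(0.10 * ncol(m))`.
#'
#' @param m A log2-scale [exprmat].
#' @param cutoff Expression threshold on the log2 scale, compared with `>=`.
#' @param min_count Minimum number of samples at or above `cutoff`
#'   (integer >= 1, default 1).
#' @return The filtered [exprmat]; feature order is preserved.
#' @export
filter_min_expression <- function(m, cutoff, min_count = 1L) {
  stopifnot(inherits(m, "exprmat"))
  if (m$scale != "log2")
    stop("filter_min_expression expects a log2-scale matrix")
  min_count <- as.integer(min_count)
  if (is.na(min_count) || min_count < 1L || min_count > ncol(m$values))
    stop("'min_count' must be an integer in [1, number of samples]")
  keep <- rowSums(m$values >= cutoff) >= min_count
  if (!any(keep)) stop("empty matrix after filtering")
  subset_exprmat(m, features = feature_ids(m)[keep])
}

#' Center and scale each feature to mean 0, standard deviation 1
#'
#' Standardization is per feature (miRNA), using the sample standard
#' deviation (n - 1 denominator). The fitted centers and scales are attached
#' as attributes `"center"` and `"scale"` so they can be applied to held-out
#' samples with [apply_standardization()] — test data must never contribute
#' to the standardization fit.
#'
#' @param m An [exprmat].
#' @return The standardized [exprmat] with `center`/`scale` attributes.
#' @export
standardize_features <- function(m) {
  stopifnot(inherits(m, "exprmat"))
  v <- m$values
  ctr <- rowMeans(v)
  sdv <- apply(v, 1L, stats::sd)
  zero <- sdv == 0 | !is.finite(sdv)
  if (any(zero))
    stop("zero-variance feature(s): ",
         paste(feature_ids(m)[zero], collapse = ", "))
  out <- exprmat((v - ctr) / sdv, scale = m$scale, labels = m$labels,
                 description = m$description)
  attr(out, "center") <- ctr
  attr(out, "scale") <- sdv
  out
}

#' Apply a previously fitted standardization to new samples
#'
#' @param m An [exprmat] whose features are a subset of those the
#'   standardization was fitted on.
#' @param fit Either a standardized [exprmat] returned by
#'   [standardize_features()] or a list with `center` and `scale` vectors
#'   named by feature id.
#' @return The transformed [exprmat].
#' @export
apply_standardization <- function(m, fit) {
  stopifnot(inherits(m, "exprmat"))
  ctr <- if (inherits(fit, "exprmat")) attr(fit, "center") else fit$center
  sdv <- if (inherits(fit, "exprmat")) attr(fit, "scale") else fit$scale
  if (is.null(ctr) || is.null(sdv))
    stop("'fit' carries no center/scale information")
  miss <- setdiff(feature_ids(m), names(ctr))
  if (length(miss))
    stop("no standardization fitted for feature(s): ",
         paste(miss, collapse = ", "))
  fid <- feature_ids(m)
  exprmat((m$values - ctr[fid]) / sdv[fid], scale = m$scale,
          labels = m$labels, description = m$description)
}
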