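#' Class and overall centroids with pooled within-class dispersions
#'
#' For feature i with values x_ij over n samples in K classes (class k having
#' the n_k samples C_k): the overall centroid is the mean over all samples,
#' the class centroid the mean over C_k, and the pooled within-class standard
#' deviation is
#' `s_i^2 = (1 / (n - K)) * sum_k sum_{j in C_k} (x_ij - xbar_ik)^2`.
#' The fudge constant `s_0` is the median of the `s_i`, guarding the
#' standardization of near-constant features.
#'
#' @param m A labeled [exprmat]; K >= 2 classes, every class with >= 2
#'   samples.
#' @return An object of class `"centroid_stats"`: list with
#'   `overall_centroid`, `class_centroids` (features x classes), `s_i`,
#'   `s_0`, `n`, `n_k`, `classes`.
#' @export
compute_centroids <- function(m) {
  stopifnot(inherits(m, "exprmat"))
  lab <- ordered_labels(m)
  classes <- sort(unique(lab))
  K <- length(classes)
  if (K < 2L) stop("need at least 2 classes, got ", K)
  n_k <- vapply(classes, function(k) sum(lab == k), integer(1L))
  small <- classes[n_k < 2L]
  if (length(small))
    stop("class(es) with fewer than 2 samples: ",
         paste(small, collapse = ", "))
  v <- m$values
  n <- ncol(v)
  overall <- rowMeans(v)
  cls_cent <- vapply(classes, function(k)
    rowMeans(v[, lab == k, drop = FALSE]), numeric(nrow(v)))
  if (nrow(v) == 1L) cls_cent <- matrix(cls_cent, nrow = 1L,
                                        dimnames = list(rownames(v), classes))
  ss <- numeric(nrow(v))
  for (k in classes)
    ss <- ss + rowSums((v[, lab == k, drop = FALSE] - cls_cent[, k])^2)
  s_i <- sqrt(ss / (n - K))
  names(s_i) <- rownames(v)
  structure(list(overall_centroid = overall,
                 class_centroids = cls_cent,
                 s_i = s_i,
                 s_0 = stats::median(s_i),
                 n = n, n_k = n_k, classes = classes),
            class = "centroid_stats")
}

# m_k standardizer; the "difference" form sqrt(1/n_k - 1/n) is the variance
# of (xbar_ik - xbar_i) under a common within-class sd, the "sum" form the
# conservative variant some shrunken-centroid implementations use
mk_values <- function(cs, mk_form = c("difference", "sum")) {
  mk_form <- match.arg(mk_form)
  if (mk_form == "difference") sqrt(1 / cs$n_k - 1 / cs$n)
  else sqrt(1 / cs$n_k + 1 / cs$n)
}

#' Standardized relative difference of class centroids
#'
#' `d_ik = (xbar_ik - xbar_i) / (m_k * (s_i + s_0))`, the gap between class
#' and overall centroid in units of its standard error. A feature is
#' predictive of class k when |d_ik| is large.
#'
#' @param cs A `"centroid_stats"` from [compute_centroids()].
#' @param mk_form `"difference"` for `m_k = sqrt(1/n_k - 1/n)` (default) or
#'   `"sum"` for `sqrt(1/n_k + 1/n)`.
#' @return Features x classes numeric matrix of d_ik.
#' @export
relative_difference <- function(cs, mk_form = c("difference", "sum")) {
  stopifnot(inherits(cs, "centroid_stats"))
  if (any(cs$n_k >= cs$n))
    stop("a class contains every sample; need K >= 2 non-trivial classes")
  denom_i <- cs$s_i + cs$s_0
  if (any(denom_i <= 0))
    stop("s_i + s_0 must be positive for every feature")
  m_k <- mk_values(cs, mk_form)
  sweep(cs$class_centroids - cs$overall_centroid, 2L, m_k, "/") / denom_i
}

#' Soft-threshold shrinkage of relative differences
#'
#' `d'_ik = sign(d_ik) * max(|d_ik| - delta, 0)`. Differences below the
#' shrinkage threshold are zeroed; the rest move toward zero by delta.
#'
#' @param d Features x classes matrix of relative differences.
#' @param delta Shrinkage threshold, >= 0.
#' @return Matrix of shrunken relative differences, same shape as `d`.
#' @export
shrink <- function(d, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta < 0)
    stop("'delta' must be a single number >= 0")
  sign(d) * pmax(abs(d) - delta, 0)
}

#' Features surviving shrinkage
#'
#' A feature is relevant at threshold delta iff it has a nonzero shrunken
#' relative difference for at least one class. The selected set shrinks (is
#' non-increasing) as delta grows.
#'
#' @param dprime Features x classes matrix of shrunken relative differences
#'   (rownames are feature ids).
#' @return Character vector of selected feature ids, in row order.
#' @export
select_features <- function(dprime) {
  keep <- apply(abs(dprime), 1L, max) > 0
  if (!any(keep))
    stop("delta too large: no feature has a nonzero shrunken difference")
  rownames(dprime)[keep]
}

#' Remove correlated (redundant) features
#'
#' Features are ranked by `max_k |d_ik|` (descending; ties broken by
#' lexicographic id) and scanned in rank order: a feature is kept iff its
#' absolute Pearson correlation across the training samples with every
#' already-kept feature is at most `rho`. When two features are correlated
#' beyond `rho`, the one with the smaller relative difference is thereby the
#' one removed. At `rho = 1` nothing is removed and the uncorrelated
#' shrunken centroid classifier reduces to the plain shrunken centroid
#' classifier.
#'
#' @param features Character vector of candidate feature ids (the shrinkage
#'   survivors).
#' @param m The training [exprmat] (correlations are computed on its rows).
#' @param d Features x classes matrix of (unshrunken) relative differences.
#' @param rho Correlation threshold in \[0, 1\].
#' @param use_shrunken Rank by `max_k |d'_ik|` of a shrunken matrix instead;
#'   `d` is then taken to be already shrunken.
#' @param cor_matrix Optional precomputed correlation matrix over (at least)
#'   `features`; avoids recomputation in cross-validation loops.
#' @return Character vector of retained feature ids (subset of `features`,
#'   original order of `features` preserved).
#' @export
decorrelate <- function(features, m, d, rho, use_shrunken = FALSE,
                        cor_matrix = NULL) {
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || rho < 0 ||
      rho > 1)
    stop("'rho' must be a single number in [0, 1]")
  if (!length(features)) stop("empty feature set")
  if (is.null(cor_matrix)) {
    stopifnot(inherits(m, "exprmat"))
    vals <- m$values[features, , drop = FALSE]
    sds <- apply(vals, 1L, stats::sd)
    if (any(sds == 0))
      stop("zero-variance feature(s) in candidate set: ",
           paste(features[sds == 0], collapse = ", "))
    cor_matrix <- stats::cor(t(vals))
  } else {
    if (!all(features %in% rownames(cor_matrix)))
      stop("'cor_matrix' does not cover all candidate features")
    cor_matrix <- cor_matrix[features, features, drop = FALSE]
    if (anyNA(cor_matrix))
      stop("zero-variance feature(s) in candidate set")
  }
  strength <- apply(abs(d[features, , drop = FALSE]), 1L, max)
  ord <- order(-strength, features)
  kept_idx <- integer(0L)
  for (i in ord) {
    if (!length(kept_idx) ||
        all(abs(cor_matrix[i, kept_idx]) <= rho))
      kept_idx <- c(kept_idx, i)
  }
  features[sort(kept_idx)]
}

#' Fit a shrunken / uncorrelated shrunken centroid classifier
#'
#' The full fit: centroid statistics, relative differences, soft-threshold
#' shrinkage at `delta`, feature selection, correlation pruning at `rho`
#' (skipped entirely for `method = "sc"`), and the shrunken class centroids
#' `xbar'_ik = xbar_i + m_k * (s_i + s_0) * d'_ik` for the retained features.
#'
#' @param m A labeled training [exprmat].
#' @param delta Shrinkage threshold, >= 0.
#' @param rho Correlation threshold in \[0, 1\] (default 1).
#' @param prior `"empirical"` (`pi_k = n_k / n`, default) or `"uniform"`
#'   (`1 / K`).
#' @param method `"usc"` (default) applies the decorrelation scan; `"sc"`
#'   never computes correlations. With `rho = 1` the two give identical
#'   models.
#' @param mk_form Passed to [relative_difference()].
#' @param use_shrunken Passed to [decorrelate()].
#' @return An object of class `"usc_model"`.
#' @export
usc_fit <- function(m, delta, rho = 1, prior = c("empirical", "uniform"),
                    method = c("usc", "sc"),
                    mk_form = c("difference", "sum"),
                    use_shrunken = FALSE) {
  prior <- match.arg(prior)
  method <- match.arg(method)
  mk_form <- match.arg(mk_form)
  cs <- compute_centroids(m)
  d <- relative_difference(cs, mk_form)
  dprime <- shrink(d, delta)
  selected <- select_features(dprime)
  if (method == "usc") {
    rank_d <- if (use_shrunken) dprime else d
    selected <- decorrelate(selected, m, rank_d, rho,
                            use_shrunken = use_shrunken)
  }
  build_usc_model(cs, dprime, selected, prior, delta, rho, method, mk_form)
}

# assemble a usc_model from precomputed centroid stats; shared by usc_fit and
# the cross-validation grid loop
build_usc_model <- function(cs, dprime, selected, prior, delta, rho, method,
                            mk_form) {
  priors <- if (prior == "empirical") cs$n_k / cs$n
            else stats::setNames(rep(1 / length(cs$classes),
                                     length(cs$classes)), cs$classes)
  m_k <- mk_values(cs, mk_form)
  shr <- cs$overall_centroid[selected] +
    (cs$s_i[selected] + cs$s_0) *
    sweep(dprime[selected, , drop = FALSE], 2L, m_k, "*")
  structure(list(selected_features = selected,
                 class_labels = cs$classes,
                 shrunken_centroids = shr,
                 overall_centroid = cs$overall_centroid[selected],
                 s_i = cs$s_i[selected],
                 s_0 = cs$s_0,
                 priors = priors,
                 delta = delta,
                 rho = if (method == "sc") NA_real_ else rho,
                 method = method,
                 mk_form = mk_form,
                 n = cs$n, n_k = cs$n_k),
            class = "usc_model")
}

#' @export
print.usc_model <- function(x, ...) {
  cat(sprintf(paste0("usc_model (%s): %d features, %d classes, delta = %g",
                     "%s\n"),
              toupper(x$method), length(x$selected_features),
              length(x$class_labels), x$delta,
              if (is.na(x$rho)) "" else sprintf(", rho = %g", x$rho)))
  invisible(x)
}

#' Discriminant scores of new samples
#'
#' For sample x* and class k:
#' `delta_k(x*) = sum_i (x*_i - xbar'_ik)^2 / (s_i + s_0)^2 - 2 log pi_k`,
#' the standardized squared distance to the shrunken class centroid with a
#' correction for the class prior. Lower is better.
#'
#' @param model A `"usc_model"`.
#' @param newdata An [exprmat] or numeric matrix (features x samples)
#'   containing every selected feature of the model.
#' @return Samples x classes matrix of discriminant scores.
#' @export
discriminant_scores <- function(model, newdata) {
  stopifnot(inherits(model, "usc_model"))
  v <- if (inherits(newdata, "exprmat")) newdata$values else newdata
  if (!is.matrix(v)) v <- matrix(v, ncol = 1L,
                                 dimnames = list(names(v), "sample1"))
  miss <- setdiff(model$selected_features, rownames(v))
  if (length(miss))
    stop("newdata lacks selected feature(s): ", paste(miss, collapse = ", "))
  v <- v[model$selected_features, , drop = FALSE]
  denom <- (model$s_i + model$s_0)^2
  scores <- vapply(model$class_labels, function(k) {
    colSums((v - model$shrunken_centroids[, k])^2 / denom) -
      2 * log(model$priors[[k]])
  }, numeric(ncol(v)))
  if (ncol(v) == 1L)
    scores <- matrix(scores, nrow = 1L,
                     dimnames = list(colnames(v), model$class_labels))
  scores
}

#' Classify new samples with a fitted (U)SC model
#'
#' Each sample is assigned the class with the minimum discriminant score;
#' exact ties go to the lexicographically first class label and are flagged.
#'
#' @param object A `"usc_model"`.
#' @param newdata An [exprmat] or numeric matrix (features x samples).
#' @param ... Unused.
#' @return A data.frame with columns `sample_id`, `class`, `tie`, plus one
#'   `score.<class>` column per class.
#' @export
predict.usc_model <- function(object, newdata, ...) {
  scores <- discriminant_scores(object, newdata)
  cls <- object$class_labels  # sorted by compute_centroids
  idx <- apply(scores, 1L, which.min)
  mins <- scores[cbind(seq_len(nrow(scores)), idx)]
  tie <- rowSums(scores <= mins + 1e-12 * pmax(1, abs(mins))) > 1L
  out <- data.frame(sample_id = rownames(scores),
                    class = cls[idx],
                    tie = tie,
                    stringsAsFactors = FALSE)
  sc <- as.data.frame(scores)
  names(sc) <- paste0("score.", cls)
  rownames(out) <- NULL
  cbind(out, sc, row.names = NULL)
}

#' Save / load a fitted model as JSON
#'
#' The layout is a direct serialization of the `"usc_model"` fields:
#' `selected_features`, `class_labels`, `shrunken_centroids` (row-major with
#' dimnames), `overall_centroid`, `s_i`, `s_0`, `priors`, `delta`, `rho`,
#' `method`, `mk_form`, `n`, `n_k`.
#'
#' @param model A `"usc_model"`.
#' @param path File path.
#' @return `path` invisibly (write); the model (read).
#' @export
write_usc_model <- function(model, path) {
  stopifnot(inherits(model, "usc_model"))
  x <- list(selected_features = model$selected_features,
            class_labels = model$class_labels,
            shrunken_centroids = as.list(as.data.frame(
              model$shrunken_centroids)),
            overall_centroid = as.list(model$overall_centroid),
            s_i = as.list(model$s_i),
            s_0 = model$s_0,
            priors = as.list(model$priors),
            delta = model$delta,
            rho = model$rho,
            method = model$method,
            mk_form = model$mk_form,
            n = model$n,
            n_k = as.list(model$n_k))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_usc_model
#' @export
read_usc_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  shr <- as.matrix(as.data.frame(x$shrunken_centroids, check.names = FALSE))
  rownames(shr) <- x$selected_features
  structure(list(selected_features = x$selected_features,
                 class_labels = x$class_labels,
                 shrunken_centroids = shr,
                 overall_centroid = stats::setNames(
                   unlist(x$overall_centroid), x$selected_features),
                 s_i = stats::setNames(unlist(x$s_i), x$selected_features),
                 s_0 = x$s_0,
                 priors = unlist(x$priors),
                 delta = x$delta,
                 rho = if (is.null(x$rho)) NA_real_ else x$rho,
                 method = x$method,
                 mk_form = x$mk_form,
                 n = x$n,
                 n_k = unlist(x$n_k)),
            class = "usc_model")
}
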