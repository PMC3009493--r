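#' Expression matrix with feature/sample identifiers and optional labels
#'
#' The container every stage of the pipeline operates on: a numeric matrix of
#' expression values with miRNA identifiers on the rows and sample identifiers
#' on the columns, a flag recording whether the values are on the raw or log2
#' scale, and (optionally) a class label per sample.
#'
#' @param values Numeric matrix, features (rows) x samples (columns), with
#'   unique, non-empty rownames and colnames.
#' @param scale Either `"raw"` or `"log2"`; which scale `values` is on.
#' @param labels Optional named character vector mapping sample ids to class
#'   labels. Every name must be a column of `values`.
#' @param description Optional character vector of per-feature annotations
#'   (the GCT `Description` column), recycled/defaulted to `""`.
#' @return An object of class `"exprmat"`: a list with elements `values`,
#'   `scale`, `labels`, `description`.
#' @examples
#' v <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("miR-1", "miR-2", "miR-3"), c("s1", "s2")))
#' m <- exprmat(v, scale = "log2", labels = c(s1 = "colon", s2 = "lung"))
#' dim(m)
#' @export
exprmat <- function(values, scale = c("raw", "log2"), labels = NULL,
                    description = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid) || any(!nzchar(fid)) || any(!nzchar(sid)))
    stop("'values' must have non-empty rownames (features) and colnames (samples)")
  if (anyDuplicated(fid))
    stop("duplicate feature ids: ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample ids: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (anyNA(values))
    stop("expression matrix contains missing values")
  if (!is.null(labels)) {
    labels <- validate_labels(labels, sid)
  }
  if (is.null(description)) {
    description <- rep("", nrow(values))
  } else {
    description <- as.character(description)
    if (length(description) == 1L) description <- rep(description, nrow(values))
    if (length(description) != nrow(values))
      stop("'description' must have one entry per feature")
  }
  names(description) <- fid
  structure(list(values = values, scale = scale, labels = labels,
                 description = description),
            class = "exprmat")
}

validate_labels <- function(labels, sample_ids) {
  labels <- unlist(labels)
  if (is.null(names(labels)) || any(!nzchar(names(labels))))
    stop("'labels' must be a named vector (names are sample ids)")
  bad <- setdiff(names(labels), sample_ids)
  if (length(bad))
    stop("labeled sample ids absent from the matrix: ",
         paste(bad, collapse = ", "))
  stats::setNames(as.character(labels), names(labels))
}

#' @export
dim.exprmat <- function(x) dim(x$values)

#' @export
print.exprmat <- function(x, ...) {
  cat(sprintf("exprmat: %d features x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat(sprintf("labels: %d labeled samples, %d classes (%s)\n",
                length(x$labels), length(tab),
                paste(names(tab), collapse = ", ")))
  }
  invisible(x)
}

#' Feature and sample identifiers of an expression matrix
#'
#' @param m An [exprmat].
#' @return Character vector of identifiers.
#' @export
feature_ids <- function(m) rownames(m$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(m) colnames(m$values)

#' Restrict an expression matrix to a feature and/or sample subset
#'
#' Order of the retained rows/columns follows the order given in `features` /
#' `samples`; labels and descriptions are subset consistently.
#'
#' @param m An [exprmat].
#' @param features,samples Character vectors of ids to keep (`NULL` keeps all).
#' @return The restricted [exprmat].
#' @export
subset_exprmat <- function(m, features = NULL, samples = NULL) {
  stopifnot(inherits(m, "exprmat"))
  if (is.null(features)) features <- feature_ids(m)
  if (is.null(samples)) samples <- sample_ids(m)
  miss_f <- setdiff(features, feature_ids(m))
  miss_s <- setdiff(samples, sample_ids(m))
  if (length(miss_f)) stop("unknown features: ", paste(miss_f, collapse = ", "))
  if (length(miss_s)) stop("unknown samples: ", paste(miss_s, collapse = ", "))
  v <- m$values[features, samples, drop = FALSE]
  lab <- m$labels
  if (!is.null(lab)) {
    lab <- lab[names(lab) %in% samples]
    if (!length(lab)) lab <- NULL
  }
  exprmat(v, scale = m$scale, labels = lab,
          description = m$description[features])
}

#' Attach per-sample class labels to an expression matrix
#'
#' @param m An [exprmat].
#' @param labels Named character vector, sample id -> class label.
#' @param require_all If `TRUE` (default) every sample of `m` must be labeled.
#' @return `m` with labels attached.
#' @export
set_labels <- function(m, labels, require_all = TRUE) {
  stopifnot(inherits(m, "exprmat"))
  labels <- validate_labels(labels, sample_ids(m))
  if (require_all) {
    unlabeled <- setdiff(sample_ids(m), names(labels))
    if (length(unlabeled))
      stop("unlabeled samples: ", paste(unlabeled, collapse = ", "))
  }
  m$labels <- labels[names(labels)[names(labels) %in% sample_ids(m)]]
  m
}

# labels in matrix column order; errors if any sample is unlabeled
ordered_labels <- function(m) {
  if (is.null(m$labels)) stop("expression matrix has no sample labels")
  lab <- m$labels[sample_ids(m)]
  if (anyNA(lab))
    stop("unlabeled samples: ",
         paste(setdiff(sample_ids(m), names(m$labels)), collapse = ", "))
  stats::setNames(as.character(lab), sample_ids(m))
}

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}
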