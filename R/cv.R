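#' Stratified fold assignment
#'
#' Each class's samples are shuffled and dealt to folds cyclically (from a
#' random starting fold), so within every class the fold sizes differ by at
#' most one. A class with a single sample cannot be held out without
#' vanishing from the training split, so its sample is pinned to training in
#' every split: its fold is `NA` and a warning is emitted.
#'
#' @param labels Named character vector, sample id -> class label.
#' @param n_folds Number of folds (default 4; at least 2).
#' @param seed Integer seed; the assignment is a deterministic function of
#'   `(labels, n_folds, seed)`.
#' @return Named integer vector of fold numbers in `1..n_folds` (or `NA` for
#'   pinned samples), in the order of `labels`.
#' @export
make_folds <- function(labels, n_folds = 4L, seed) {
  if (is.null(names(labels)) || any(!nzchar(names(labels))))
    stop("'labels' must be a named vector")
  n_folds <- as.integer(n_folds)
  if (is.na(n_folds) || n_folds < 2L) stop("'n_folds' must be >= 2")
  classes <- sort(unique(as.character(labels)))
  folds <- stats::setNames(rep(NA_integer_, length(labels)), names(labels))
  singletons <- character(0L)
  with_seed(seed, {
    for (k in classes) {
      ids <- names(labels)[labels == k]
      if (length(ids) == 1L) {
        singletons <- c(singletons, ids)
        next
      }
      ids <- sample(ids)
      start <- sample.int(n_folds, 1L)
      folds[ids] <- ((start - 1L + seq_along(ids) - 1L) %% n_folds) + 1L
    }
  })
  if (length(singletons))
    warning("single-sample class(es); pinned to training in every split: ",
            paste(singletons, collapse = ", "))
  folds
}

#' Repeated stratified k-fold cross-validation over the (delta, rho) grid
#'
#' For every repeat a fresh stratified fold assignment is drawn (seed
#' `seed + repeat - 1`); for every fold, the classifier is fitted on the
#' remaining folds at every grid cell and the held-out fold's classification
#' error rate is recorded. Standardization (when enabled) and all centroid
#' statistics are refitted inside each training split, so no information
#' leaks from the held-out fold. Grid cells where fitting fails (e.g. delta
#' so large that no feature survives) are recorded with error 1 and flagged.
#'
#' @param m A labeled [exprmat] (log2 or standardized scale).
#' @param delta_grid Non-empty vector of shrinkage thresholds >= 0
#'   (default `seq(0, 2, by = 0.1)`).
#' @param rho_grid Non-empty vector of correlation thresholds in \[0, 1\]
#'   (default `seq(0.5, 1, by = 0.1)`).
#' @param repeats Number of CV repetitions (default 10).
#' @param n_folds Number of folds (default 4).
#' @param seed Integer seed.
#' @param standardize Refit feature standardization inside every training
#'   split and apply it to the held-out fold (default `TRUE`). Features
#'   constant within a training split are dropped for that split.
#' @param prior,method,mk_form Passed to the fit (see [usc_fit()]).
#' @return An object of class `"usc_cv"`: list with `delta_grid`, `rho_grid`,
#'   `mean_error` (|delta| x |rho| matrix), `failed` (logical matrix: cell
#'   failed in every split), `per_repeat_errors` (repeats x folds x |delta| x
#'   |rho| array), `seed`.
#' @export
cross_validate <- function(m, delta_grid = seq(0, 2, by = 0.1),
                           rho_grid = seq(0.5, 1, by = 0.1),
                           repeats = 10L, n_folds = 4L, seed,
                           standardize = TRUE,
                           prior = c("empirical", "uniform"),
                           method = c("usc", "sc"),
                           mk_form = c("difference", "sum")) {
  stopifnot(inherits(m, "exprmat"))
  prior <- match.arg(prior); method <- match.arg(method)
  mk_form <- match.arg(mk_form)
  delta_grid <- as.numeric(unlist(delta_grid))
  rho_grid <- as.numeric(unlist(rho_grid))
  if (!length(delta_grid) || any(delta_grid < 0))
    stop("'delta_grid' must be non-empty with values >= 0")
  if (!length(rho_grid) || any(rho_grid < 0 | rho_grid > 1))
    stop("'rho_grid' must be non-empty with values in [0, 1]")
  delta_grid <- sort(unique(delta_grid))
  rho_grid <- sort(unique(rho_grid))
  lab <- ordered_labels(m)
  if (ncol(m$values) < n_folds)
    stop("fewer samples than folds")
  nd <- length(delta_grid); nr <- length(rho_grid)
  err <- array(NA_real_, c(repeats, n_folds, nd, nr))
  valid <- matrix(FALSE, repeats, n_folds)
  warned <- FALSE
  for (r in seq_len(repeats)) {
    folds <- withCallingHandlers(
      make_folds(lab, n_folds, seed = seed + r - 1L),
      warning = function(w) {
        if (warned) invokeRestart("muffleWarning")
        warned <<- TRUE
      })
    for (f in seq_len(n_folds)) {
      test_ids <- names(folds)[!is.na(folds) & folds == f]
      if (!length(test_ids)) next
      valid[r, f] <- TRUE
      train_ids <- setdiff(names(folds), test_ids)
      err[r, f, , ] <- cv_split_errors(m, lab, train_ids, test_ids,
                                       delta_grid, rho_grid, standardize,
                                       prior, method, mk_form)
    }
  }
  if (!any(valid)) stop("no usable cross-validation split")
  # a fit failure in a split is NA in the raw array and counts as error 1.0
  # in the grid mean; a cell failing in every usable split is flagged
  mean_error <- apply(err, c(3L, 4L), function(x)
    mean(ifelse(is.na(x[valid]), 1, x[valid])))
  dimnames(mean_error) <- list(delta = format(delta_grid),
                               rho = format(rho_grid))
  failed <- apply(err, c(3L, 4L), function(x) all(is.na(x[valid])))
  if (all(failed))
    stop("cross-validation failed at every grid cell")
  structure(list(delta_grid = delta_grid, rho_grid = rho_grid,
                 mean_error = mean_error, failed = failed,
                 per_repeat_errors = err, valid_splits = valid,
                 seed = seed, repeats = repeats, n_folds = n_folds),
            class = "usc_cv")
}

# held-out error rates for one train/test split over the whole grid;
# NA marks a cell whose fit failed in this split
cv_split_errors <- function(m, lab, train_ids, test_ids, delta_grid,
                            rho_grid, standardize, prior, method, mk_form) {
  nd <- length(delta_grid); nr <- length(rho_grid)
  out <- matrix(NA_real_, nd, nr)
  m_tr <- subset_exprmat(m, samples = train_ids)
  m_te <- subset_exprmat(m, samples = test_ids)
  if (standardize) {
    sds <- apply(m_tr$values, 1L, stats::sd)
    keep <- sds > 0
    if (!any(keep)) return(out)
    if (!all(keep)) {
      m_tr <- subset_exprmat(m_tr, features = feature_ids(m_tr)[keep])
      m_te <- subset_exprmat(m_te, features = feature_ids(m_te)[keep])
    }
    m_tr <- standardize_features(m_tr)
    m_te <- apply_standardization(m_te, m_tr)
  }
  m_tr <- set_labels(m_tr, lab[train_ids])
  grid_errors(m_tr, m_te, lab[test_ids], delta_grid, rho_grid, prior,
              method, mk_form)
}

# grid of held-out error rates for one prepared (standardized, labeled)
# training matrix and test matrix
grid_errors <- function(m_tr, m_te, lab_te, delta_grid, rho_grid, prior,
                        method, mk_form) {
  nd <- length(delta_grid); nr <- length(rho_grid)
  out <- matrix(NA_real_, nd, nr)
  cs <- tryCatch(compute_centroids(m_tr), error = function(e) NULL)
  if (is.null(cs)) return(out)  # e.g. a class reduced to one training sample
  d <- relative_difference(cs, mk_form)
  cormat <- if (method == "usc") {
    sds <- apply(m_tr$values, 1L, stats::sd)
    cm <- stats::cor(t(m_tr$values))
    cm[sds == 0, ] <- NA; cm[, sds == 0] <- NA
    cm
  } else NULL
  for (di in seq_len(nd)) {
    dprime <- shrink(d, delta_grid[di])
    sel_all <- tryCatch(select_features(dprime), error = function(e) NULL)
    if (is.null(sel_all)) next  # empty feature set: whole row stays failed
    for (ri in seq_len(nr)) {
      sel <- if (method == "usc") {
        tryCatch(decorrelate(sel_all, m_tr, d, rho_grid[ri],
                             cor_matrix = cormat),
                 error = function(e) NULL)
      } else sel_all
      if (is.null(sel)) next
      model <- build_usc_model(cs, dprime, sel, prior, delta_grid[di],
                               rho_grid[ri], method, mk_form)
      pred <- predict(model, m_te)
      out[di, ri] <- mean(pred$class != lab_te[pred$sample_id])
    }
  }
  out
}

#' @export
print.usc_cv <- function(x, ...) {
  best <- select_params(x)
  cat(sprintf(paste0("usc_cv: %d repeats x %d folds, %d x %d grid; minimum ",
                     "mean error %.4f at (delta = %g, rho = %g)\n"),
              x$repeats, x$n_folds, length(x$delta_grid), length(x$rho_grid),
              min(x$mean_error[!x$failed]), best["delta"], best["rho"]))
  invisible(x)
}

#' Optimal (delta, rho) from a cross-validation grid
#'
#' The cell with minimum mean classification error; ties are broken toward
#' larger delta, then smaller rho (the most parsimonious model).
#'
#' @param cv A `"usc_cv"` from [cross_validate()].
#' @return Named numeric vector `c(delta = ..., rho = ...)`.
#' @export
select_params <- function(cv) {
  stopifnot(inherits(cv, "usc_cv"))
  ok <- !cv$failed & !is.na(cv$mean_error)
  if (!any(ok)) stop("no non-failed grid cell")
  best <- min(cv$mean_error[ok])
  hits <- which(ok & cv$mean_error <= best + 1e-12, arr.ind = TRUE)
  dl <- cv$delta_grid[hits[, 1L]]
  rh <- cv$rho_grid[hits[, 2L]]
  pick <- order(-dl, rh)[1L]
  c(delta = dl[pick], rho = rh[pick])
}

#' Strict cross-validation: biclustering and network selection inside splits
#'
#' [cross_validate()] tunes the classifier on a training set that was already
#' reduced by biclustering + network selection run once on the full training
#' data, mirroring the pipeline's flow. For leakage-free benchmarking this
#' variant re-runs the whole selection stack — standardization, trinary
#' discretization, graph construction, bicluster search and network
#' selection — inside every training split, so held-out samples never
#' influence any stage. Splits where selection fails (no potential bicluster,
#' or a class reduced below two training samples) are recorded as failures.
#'
#' @inheritParams cross_validate
#' @param net A [cm_network].
#' @param bicluster_args Named list of overrides for [find_biclusters()] /
#'   [discretize()] / [build_graph()] parameters: `t`, `p_c`, `d`, `k`,
#'   `n_keep`, `max_overlap`.
#' @param any_mirna Passed to [build_training_set()].
#' @return A `"usc_cv"`, as for [cross_validate()].
#' @export
sfss_cross_validate <- function(m, net, delta_grid = seq(0, 2, by = 0.1),
                                rho_grid = seq(0.5, 1, by = 0.1),
                                repeats = 10L, n_folds = 4L, seed,
                                bicluster_args = list(),
                                any_mirna = FALSE,
                                prior = c("empirical", "uniform"),
                                method = c("usc", "sc"),
                                mk_form = c("difference", "sum")) {
  stopifnot(inherits(m, "exprmat"), inherits(net, "cm_network"))
  prior <- match.arg(prior); method <- match.arg(method)
  mk_form <- match.arg(mk_form)
  delta_grid <- sort(unique(as.numeric(unlist(delta_grid))))
  rho_grid <- sort(unique(as.numeric(unlist(rho_grid))))
  lab <- ordered_labels(m)
  ba <- bicluster_args
  nd <- length(delta_grid); nr <- length(rho_grid)
  err <- array(NA_real_, c(repeats, n_folds, nd, nr))
  valid <- matrix(FALSE, repeats, n_folds)
  for (r in seq_len(repeats)) {
    folds <- suppressWarnings(make_folds(lab, n_folds, seed = seed + r - 1L))
    for (f in seq_len(n_folds)) {
      test_ids <- names(folds)[!is.na(folds) & folds == f]
      if (!length(test_ids)) next
      valid[r, f] <- TRUE
      train_ids <- setdiff(names(folds), test_ids)
      sel <- tryCatch({
        m_tr <- standardize_features(subset_exprmat(m, samples = train_ids))
        m_te <- apply_standardization(subset_exprmat(m, samples = test_ids),
                                      m_tr)
        tm <- discretize(m_tr, t = ba$t %||% 1)
        g <- build_graph(tm, p_c = ba$p_c %||% 0.9)
        bs <- suppressWarnings(
          find_biclusters(g, d = ba$d %||% 30L, k = ba$k %||% 3L,
                          n_keep = ba$n_keep %||% 20L,
                          max_overlap = ba$max_overlap %||% 0.25))
        red <- build_training_set(bs, set_labels(m_tr, lab[train_ids]),
                                  net, any_mirna = any_mirna)
        list(tr = red$matrix, te = m_te)
      }, error = function(e) NULL)
      if (is.null(sel)) next
      err[r, f, , ] <- grid_errors(sel$tr, sel$te, lab[test_ids],
                                   delta_grid, rho_grid, prior, method,
                                   mk_form)
    }
  }
  if (!any(valid)) stop("no usable cross-validation split")
  mean_error <- apply(err, c(3L, 4L), function(x)
    mean(ifelse(is.na(x[valid]), 1, x[valid])))
  dimnames(mean_error) <- list(delta = format(delta_grid),
                               rho = format(rho_grid))
  failed <- apply(err, c(3L, 4L), function(x) all(is.na(x[valid])))
  if (all(failed))
    stop("cross-validation failed at every grid cell")
  structure(list(delta_grid = delta_grid, rho_grid = rho_grid,
                 mean_error = mean_error, failed = failed,
                 per_repeat_errors = err, valid_splits = valid,
                 seed = seed, repeats = repeats, n_folds = n_folds),
            class = "usc_cv")
}

#' Serialize a cross-validation result to JSON
#'
#' @param cv A `"usc_cv"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_result <- function(cv, path) {
  stopifnot(inherits(cv, "usc_cv"))
  x <- list(delta_grid = cv$delta_grid, rho_grid = cv$rho_grid,
            mean_error = apply(cv$mean_error, 1L, as.numeric,
                               simplify = FALSE),
            failed = apply(cv$failed, 1L, as.logical, simplify = FALSE),
            seed = cv$seed, repeats = cv$repeats, n_folds = cv$n_folds)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
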