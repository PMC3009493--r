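#' Bicluster: a feature subset co-expressed in a sample subset
#'
#' @param features Character vector of feature ids (non-empty).
#' @param samples Character vector of sample ids (non-empty).
#' @param score Numeric score (sum of bipartite-graph weights over the
#'   feature x sample block); `NA` if not yet scored.
#' @return An object of class `"bicluster"`.
#' @export
bicluster <- function(features, samples, score = NA_real_) {
  features <- as.character(features); samples <- as.character(samples)
  if (!length(features) || !length(samples))
    stop("a bicluster needs at least one feature and one sample")
  if (anyDuplicated(features) || anyDuplicated(samples))
    stop("duplicate ids in bicluster")
  structure(list(features = sort(features), samples = sort(samples),
                 score = as.numeric(score)),
            class = "bicluster")
}

#' @export
print.bicluster <- function(x, ...) {
  cat(sprintf("bicluster: %d features x %d samples, score %.4g\n",
              length(x$features), length(x$samples), x$score))
  invisible(x)
}

#' Discretize a standardized matrix to trinary up/unchanged/down calls
#'
#' Entry-wise: +1 if x >= t, -1 if x <= -t, 0 otherwise. Only meaningful on a
#' per-feature standardized matrix (mean 0, sd 1), which is checked.
#'
#' @param m A standardized [exprmat].
#' @param t Positive response threshold in standard-deviation units
#'   (default 1).
#' @return An object of class `"trinary"`: list with `values` (integer matrix
#'   in \{-1, 0, +1\}, same dimnames as `m`).
#' @export
discretize <- function(m, t = 1) {
  stopifnot(inherits(m, "exprmat"))
  if (!is.numeric(t) || length(t) != 1L || t <= 0)
    stop("'t' must be a single positive number")
  mu <- rowMeans(m$values)
  sdv <- apply(m$values, 1L, stats::sd)
  if (max(abs(mu)) > 1e-6 || max(abs(sdv - 1)) > 1e-6)
    stop("matrix is not standardized (per-feature mean 0, sd 1); ",
         "run standardize_features() first")
  v <- matrix(0L, nrow(m$values), ncol(m$values),
              dimnames = dimnames(m$values))
  v[m$values >= t] <- 1L
  v[m$values <= -t] <- -1L
  structure(list(values = v), class = "trinary")
}

#' Construct a trinary matrix from explicit up/unchanged/down calls
#'
#' For discretizations produced outside [discretize()] (or fixtures built in
#' tests): values must already be in \{-1, 0, +1\} with unique dimnames.
#'
#' @param values Integer/numeric matrix with entries in \{-1, 0, +1\} and
#'   unique, non-empty rownames and colnames.
#' @return An object of class `"trinary"`.
#' @export
trinary_matrix <- function(values) {
  if (!is.matrix(values) || !all(values %in% c(-1, 0, 1)))
    stop("'values' must be a matrix with entries in {-1, 0, +1}")
  if (is.null(rownames(values)) || is.null(colnames(values)) ||
      anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("'values' must have unique rownames and colnames")
  storage.mode(values) <- "integer"
  structure(list(values = values), class = "trinary")
}

#' Build the weighted bipartite feature--sample response graph
#'
#' Features are left vertices, samples right vertices. A (feature, sample)
#' pair where the trinary call is nonzero is a "response". Under a uniform
#' background density and an assumed within-bicluster response probability
#' `p_c`, the log-likelihood-ratio weights are `log(p_c / p_hat)` for a
#' responding pair and `log((1 - p_c) / (1 - p_hat))` for a non-responding
#' pair, where `p_hat` is the observed response density. A bicluster's score
#' is then the sum of its block's weights, so heavy subgraphs are blocks that
#' are unexpectedly dense.
#'
#' Vertices are ordered lexicographically by id so that all downstream
#' tie-breaking is deterministic.
#'
#' @param tm A `"trinary"` matrix from [discretize()].
#' @param p_c Assumed response probability inside a bicluster, in
#'   (`p_hat`, 1); default 0.9.
#' @return An object of class `"bipartite_graph"`: list with `resp` (logical
#'   matrix), `sign` (integer matrix), `w_present`, `w_absent`, `p_hat`,
#'   `p_c`.
#' @export
build_graph <- function(tm, p_c = 0.9) {
  stopifnot(inherits(tm, "trinary"))
  if (!is.numeric(p_c) || length(p_c) != 1L || p_c <= 0.5 || p_c >= 1)
    stop("'p_c' must be a single number in (0.5, 1)")
  v <- tm$values
  ord_f <- order(rownames(v)); ord_s <- order(colnames(v))
  v <- v[ord_f, ord_s, drop = FALSE]
  p_hat <- mean(v != 0L)
  if (p_hat > 0 && p_c <= p_hat)
    stop(sprintf("p_c (%.3g) must exceed the observed density p_hat (%.3g)",
                 p_c, p_hat))
  # with no responses at all the weights are never used downstream; a
  # nominal density keeps them finite
  p_eff <- if (p_hat == 0) 1 / (2 * length(v)) else p_hat
  structure(list(resp = v != 0L,
                 sign = v,
                 w_present = log(p_c / p_eff),
                 w_absent = log((1 - p_c) / (1 - p_eff)),
                 p_hat = p_hat,
                 p_c = p_c),
            class = "bipartite_graph")
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat(sprintf(paste0("bipartite_graph: %d features x %d samples, density ",
                     "%.3f, weights (+%.3f / %.3f)\n"),
              nrow(x$resp), ncol(x$resp), x$p_hat, x$w_present, x$w_absent))
  invisible(x)
}

#' Score a bicluster on the bipartite response graph
#'
#' Sum over every (feature, sample) pair of the block of the pair's weight:
#' `w_present` for responding pairs, `w_absent` otherwise.
#'
#' @param b A [bicluster].
#' @param g A `"bipartite_graph"` from [build_graph()].
#' @return The block score (numeric scalar).
#' @export
score_bicluster <- function(b, g) {
  stopifnot(inherits(b, "bicluster"), inherits(g, "bipartite_graph"))
  if (!all(b$features %in% rownames(g$resp)))
    stop("bicluster features absent from graph")
  if (!all(b$samples %in% colnames(g$resp)))
    stop("bicluster samples absent from graph")
  blk <- g$resp[b$features, b$samples, drop = FALSE]
  n_present <- sum(blk)
  n_present * g$w_present + (length(blk) - n_present) * g$w_absent
}

#' Find heavy biclusters by seed enumeration and greedy local improvement
#'
#' The search has three phases. (a) Seeding: for every sample vertex whose
#' degree (number of responding features) is at most `d`, all subsets of its
#' neighbor features of size 2..`k` are enumerated; each subset's candidate
#' bicluster pairs the subset with every sample responding on all of its
#' features, and the `n_keep` highest-scoring candidates per vertex are kept.
#' (b) Local improvement: each candidate is improved by repeatedly applying
#' the single feature/sample addition or removal that most increases the
#' block score, until no move improves it (block sizes never drop below
#' `min_features` x `min_samples`). (c) Non-redundant emission: improved
#' blocks are sorted by score (descending, ties by id) and emitted greedily,
#' skipping any block whose Jaccard overlap on the union of its feature and
#' sample sets with an already-emitted block exceeds `max_overlap`.
#'
#' All tie-breaking is lexicographic in vertex id, so the output is a
#' deterministic function of the input.
#'
#' @param g A `"bipartite_graph"` from [build_graph()].
#' @param d Maximum degree of a sample vertex used for seeding (default 30).
#' @param k Maximum seed subset size (default 3).
#' @param n_keep Candidates kept per seeding vertex (default 20).
#' @param max_overlap Maximum pairwise Jaccard overlap among emitted
#'   biclusters, in \[0, 1\] (default 0.25).
#' @param min_features,min_samples Minimum block dimensions (default 2 x 2).
#' @return List of [bicluster] objects, sorted by score (decreasing).
#' @export
find_biclusters <- function(g, d = 30L, k = 3L, n_keep = 20L,
                            max_overlap = 0.25,
                            min_features = 2L, min_samples = 2L) {
  stopifnot(inherits(g, "bipartite_graph"))
  if (max_overlap < 0 || max_overlap > 1)
    stop("'max_overlap' must be in [0, 1]")
  if (k < 2L) stop("'k' must be at least 2")
  resp <- g$resp
  p <- nrow(resp); n <- ncol(resp)
  if (!any(resp)) {
    warning("graph has no present edges; no biclusters found")
    return(list())
  }
  W <- matrix(g$w_absent, p, n, dimnames = dimnames(resp))
  W[resp] <- g$w_present

  ## (a) seeds
  deg <- colSums(resp)
  eligible <- which(deg >= 2L & deg <= d)
  if (!length(eligible)) {
    warning("no sample vertex with degree in [2, d]; no seeds available")
    return(list())
  }
  cand <- list()
  for (j in eligible) {
    nbrs <- which(resp[, j])
    vc <- enumerate_seeds(resp, nbrs, k, min_samples)
    if (!length(vc)) next
    sc <- vapply(vc, function(x) length(x$f) * length(x$s) * g$w_present,
                 numeric(1L))
    keyv <- vapply(vc, function(x) paste(x$f, collapse = ","), character(1L))
    ord <- order(-sc, keyv)
    cand <- c(cand, vc[ord[seq_len(min(n_keep, length(ord)))]])
  }
  if (!length(cand)) {
    warning("no seed produced a candidate block; no biclusters found")
    return(list())
  }
  # drop duplicate seed blocks before the (costlier) improvement phase
  keys <- vapply(cand, function(x)
    paste(paste(x$f, collapse = ","), paste(x$s, collapse = ","), sep = "|"),
    character(1L))
  cand <- cand[!duplicated(keys)]

  ## (b) greedy local improvement
  improved <- lapply(cand, function(x)
    improve_block(x$f, x$s, W, min_features, min_samples))
  keys <- vapply(improved, function(x)
    paste(paste(x$f, collapse = ","), paste(x$s, collapse = ","), sep = "|"),
    character(1L))
  ok <- !duplicated(keys)
  improved <- improved[ok]; keys <- keys[ok]

  ## (c) sorted, non-redundant emission
  scores <- vapply(improved, `[[`, numeric(1L), "score")
  ord <- order(-scores, keys)
  emitted <- list()
  emitted_elems <- list()
  for (i in ord) {
    el <- c(paste0("f\r", improved[[i]]$f), paste0("s\r", improved[[i]]$s))
    overlaps <- vapply(emitted_elems, function(e)
      length(intersect(e, el)) / length(union(e, el)), numeric(1L))
    if (length(overlaps) && any(overlaps > max_overlap)) next
    emitted_elems[[length(emitted_elems) + 1L]] <- el
    emitted[[length(emitted) + 1L]] <-
      bicluster(rownames(resp)[improved[[i]]$f],
                colnames(resp)[improved[[i]]$s],
                improved[[i]]$score)
  }
  emitted
}

# depth-first enumeration of neighbor-feature subsets of size 2..k with
# support pruning; returns list of list(f = feature idx, s = sample idx)
enumerate_seeds <- function(resp, nbrs, k, min_samples) {
  out <- vector("list", 0L)
  n <- ncol(resp)
  recurse <- function(chosen, support, start) {
    if (length(chosen) >= 2L && length(support) >= min_samples)
      out[[length(out) + 1L]] <<- list(f = chosen, s = support)
    if (length(chosen) == k) return(invisible())
    for (a in seq_along(nbrs)) {
      if (a < start) next
      f <- nbrs[a]
      sup <- support[resp[f, support]]
      if (length(sup) < min_samples) next
      recurse(c(chosen, f), sup, a + 1L)
    }
  }
  recurse(integer(0L), seq_len(n), 1L)
  out
}

# hill-climb a block by single add/remove moves; score strictly increases
# each move and is bounded above by the sum of positive weights, so this
# terminates
improve_block <- function(f_idx, s_idx, W, min_features, min_samples) {
  p <- nrow(W); n <- ncol(W)
  in_f <- logical(p); in_f[f_idx] <- TRUE
  in_s <- logical(n); in_s[s_idx] <- TRUE
  score <- sum(W[f_idx, s_idx])
  tol <- 1e-9
  repeat {
    fs <- which(in_f); ss <- which(in_s)
    row_tot <- rowSums(W[, ss, drop = FALSE])  # effect of feature moves
    col_tot <- colSums(W[fs, , drop = FALSE])  # effect of sample moves
    best_gain <- tol; best_move <- NULL
    g_add_f <- row_tot; g_add_f[in_f] <- -Inf
    i <- which.max(g_add_f)
    if (g_add_f[i] > best_gain) { best_gain <- g_add_f[i]
                                  best_move <- c(1L, i) }
    if (length(fs) > min_features) {
      g_rem_f <- -row_tot; g_rem_f[!in_f] <- -Inf
      i <- which.max(g_rem_f)
      if (g_rem_f[i] > best_gain) { best_gain <- g_rem_f[i]
                                    best_move <- c(2L, i) }
    }
    g_add_s <- col_tot; g_add_s[in_s] <- -Inf
    i <- which.max(g_add_s)
    if (g_add_s[i] > best_gain) { best_gain <- g_add_s[i]
                                  best_move <- c(3L, i) }
    if (length(ss) > min_samples) {
      g_rem_s <- -col_tot; g_rem_s[!in_s] <- -Inf
      i <- which.max(g_rem_s)
      if (g_rem_s[i] > best_gain) { best_gain <- g_rem_s[i]
                                    best_move <- c(4L, i) }
    }
    if (is.null(best_move)) break
    switch(best_move[1L],
           in_f[best_move[2L]] <- TRUE,
           in_f[best_move[2L]] <- FALSE,
           in_s[best_move[2L]] <- TRUE,
           in_s[best_move[2L]] <- FALSE)
    score <- score + best_gain
  }
  list(f = which(in_f), s = which(in_s), score = score)
}

#' Write biclusters to a TSV file
#'
#' One row per bicluster: `score`, comma-joined `features`, comma-joined
#' `samples`.
#'
#' @param bs List of [bicluster] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_biclusters <- function(bs, path) {
  df <- data.frame(
    score = vapply(bs, `[[`, numeric(1L), "score"),
    features = vapply(bs, function(b) paste(b$features, collapse = ","),
                      character(1L)),
    samples = vapply(bs, function(b) paste(b$samples, collapse = ","),
                     character(1L)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read biclusters from a TSV file written by [write_biclusters()]
#'
#' @param path Input path.
#' @return List of [bicluster] objects.
#' @export
read_biclusters <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("numeric", "character", "character"),
                          quote = "", comment.char = "")
  lapply(seq_len(nrow(df)), function(i)
    bicluster(strsplit(df$features[i], ",", fixed = TRUE)[[1L]],
              strsplit(df$samples[i], ",", fixed = TRUE)[[1L]],
              df$score[i]))
}
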