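# tissue names used for synthetic class labels, echoing the tumor types a
# miRNA tumor-of-origin panel distinguishes
tissue_pool <- c("colon", "lung", "breast", "kidney", "ovary", "pancreas",
                 "prostate", "uterus", "bladder", "leukemia", "melanoma",
                 "mesothelioma")

#' Simulate a multiclass expression matrix with class-specific markers
#'
#' Background expression is i.i.d. standard normal (emulating standardized
#' log-scale residuals). Each class owns `p_info` informative features
#' (disjoint across classes), shifted upward by `effect` in that class's
#' samples only — the classic additive marker model in which intra-class
#' similarity is high and inter-class similarity low.
#'
#' @param K Number of classes (default 5).
#' @param p Number of features (default 100).
#' @param n_k Samples per class (default 20).
#' @param p_info Informative features per class (default 5;
#'   `p_info * K <= p`).
#' @param effect Mean shift of informative features in their class, in
#'   background-sd units (default 3).
#' @param seed Integer seed; output is bit-reproducible given the seed.
#' @return List with `matrix` (a labeled [exprmat], `p x K*n_k`), `labels`
#'   (named character vector) and `truth` (list: `info_features`, a class ->
#'   feature-id list, and `feature_class`, the feature-id -> class map).
#' @export
simulate_classification_data <- function(K = 5L, p = 100L, n_k = 20L,
                                         p_info = 5L, effect = 3, seed) {
  K <- as.integer(K); p <- as.integer(p); n_k <- as.integer(n_k)
  p_info <- as.integer(p_info)
  if (K < 2L) stop("'K' must be >= 2")
  if (p_info * K > p) stop("'p_info' * 'K' must not exceed 'p'")
  if (effect < 0) stop("'effect' must be >= 0")
  classes <- if (K <= length(tissue_pool)) tissue_pool[seq_len(K)]
             else c(tissue_pool, paste0("tumor", seq_len(K - length(tissue_pool))))
  n <- K * n_k
  fid <- sprintf("miR-%03d", seq_len(p))
  sid <- sprintf("s%03d", seq_len(n))
  labels <- stats::setNames(rep(classes, each = n_k), sid)
  v <- with_seed(seed, matrix(stats::rnorm(p * n), p, n,
                              dimnames = list(fid, sid)))
  info <- lapply(seq_len(K), function(c_idx)
    fid[((c_idx - 1L) * p_info + 1L):(c_idx * p_info)])
  names(info) <- classes
  for (k in classes)
    v[info[[k]], labels == k] <- v[info[[k]], labels == k] + effect
  feature_class <- stats::setNames(rep(names(info), lengths(info)),
                                   unlist(info))
  m <- exprmat(v, scale = "log2", labels = labels)
  list(matrix = m, labels = labels,
       truth = list(info_features = info, feature_class = feature_class))
}

#' Simulate an expression matrix with planted biclusters
#'
#' Background N(0, `noise_sd`); each block shifts a contiguous (and, across
#' blocks, disjoint) set of features x samples by its `shift`.
#'
#' @param p,n Matrix dimensions.
#' @param blocks List of length-3 numeric vectors
#'   `c(n_features, n_samples, shift)`; blocks are placed consecutively and
#'   must fit inside the matrix.
#' @param noise_sd Background standard deviation (default 1).
#' @param seed Integer seed.
#' @return List with `matrix` (an [exprmat]) and `truth` (list of per-block
#'   `features` / `samples` id vectors).
#' @export
simulate_planted_biclusters <- function(p, n, blocks, noise_sd = 1, seed) {
  p <- as.integer(p); n <- as.integer(n)
  if (!is.list(blocks)) blocks <- list(blocks)
  sizes_f <- vapply(blocks, function(b) as.integer(b[1L]), integer(1L))
  sizes_s <- vapply(blocks, function(b) as.integer(b[2L]), integer(1L))
  if (sum(sizes_f) > p || sum(sizes_s) > n)
    stop("planted blocks exceed matrix dimensions")
  fid <- sprintf("miR-%03d", seq_len(p))
  sid <- sprintf("s%03d", seq_len(n))
  v <- with_seed(seed, matrix(stats::rnorm(p * n, sd = noise_sd), p, n,
                              dimnames = list(fid, sid)))
  truth <- vector("list", length(blocks))
  f0 <- 0L; s0 <- 0L
  for (b in seq_along(blocks)) {
    fi <- fid[f0 + seq_len(sizes_f[b])]
    si <- sid[s0 + seq_len(sizes_s[b])]
    v[fi, si] <- v[fi, si] + blocks[[b]][3L]
    truth[[b]] <- list(features = fi, samples = si)
    f0 <- f0 + sizes_f[b]; s0 <- s0 + sizes_s[b]
  }
  list(matrix = exprmat(v, scale = "log2"), truth = truth)
}

#' Simulate a cancer--miRNA network consistent with planted class markers
#'
#' Every true (class, informative-miRNA) pair becomes an edge independently
#' with probability `coverage`; every other (class, miRNA) pair becomes a
#' spurious edge with probability `false_edge_rate`.
#'
#' @param truth Either the `truth` element returned by
#'   [simulate_classification_data()] or a named character vector mapping
#'   feature id -> class.
#' @param coverage Probability a true association appears in the network,
#'   in \[0, 1\] (default 1).
#' @param false_edge_rate Probability of each spurious (class, miRNA) edge,
#'   in \[0, 1\] (default 0).
#' @param seed Integer seed.
#' @param mirnas Universe of miRNA ids eligible for spurious edges; defaults
#'   to the ids appearing in `truth`.
#' @return A [cm_network] (possibly empty, if `coverage = 0` and
#'   `false_edge_rate = 0`).
#' @export
simulate_network <- function(truth, coverage = 1, false_edge_rate = 0, seed,
                             mirnas = NULL) {
  if (is.list(truth) && !is.null(truth$feature_class))
    truth <- truth$feature_class
  if (is.null(names(truth)))
    stop("'truth' must map feature ids (names) to classes")
  if (coverage < 0 || coverage > 1 || false_edge_rate < 0 ||
      false_edge_rate > 1)
    stop("'coverage' and 'false_edge_rate' must be in [0, 1]")
  classes <- sort(unique(as.character(truth)))
  if (is.null(mirnas)) mirnas <- sort(unique(names(truth)))
  all_pairs <- expand.grid(cancer_type = classes, mirna = mirnas,
                           stringsAsFactors = FALSE)
  is_true <- truth[all_pairs$mirna] == all_pairs$cancer_type &
    !is.na(truth[all_pairs$mirna])
  keep <- with_seed(seed, {
    u <- stats::runif(nrow(all_pairs))
    ifelse(is_true, u < coverage, u < false_edge_rate)
  })
  edges <- all_pairs[keep, , drop = FALSE]
  edges$direction <- ifelse(is_true[keep], "up", "unknown")
  cm_network(edges)
}
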