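# shared fixture builders; everything is generated in code at test time

# small expression matrix with explicit values
make_exprmat <- function(values, labels = NULL, scale = "log2") {
  exprmat(values, scale = scale, labels = labels)
}

# the 2-feature / 4-sample worked fixture (two classes of two samples)
worked_fixture_2f <- function() {
  v <- matrix(c(1, 3, 5, 7,
                2, 2, 4, 6),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("miR-A", "miR-B"),
                              c("s1", "s2", "s3", "s4")))
  exprmat(v, scale = "log2",
          labels = c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
}

# the 3-class / 2-feature worked fixture (two samples per class)
worked_fixture_3k <- function() {
  v <- matrix(c(0, 2, 3, 5, 7, 9,
                4, 6, 1, 3, 2, 4),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("miR-A", "miR-B"),
                              paste0("s", 1:6)))
  exprmat(v, scale = "log2",
          labels = stats::setNames(rep(c("A", "B", "C"), each = 2),
                                   paste0("s", 1:6)))
}

# random trinary instance with a planted all-up block, for oracle checks
planted_trinary <- function(p, n, block_f, block_s, noise = 0.08,
                            seed = 1) {
  v <- matrix(0L, p, n,
              dimnames = list(sprintf("f%02d", seq_len(p)),
                              sprintf("s%02d", seq_len(n))))
  set.seed(seed)
  v[] <- sample(c(-1L, 0L, 1L), p * n, TRUE,
                c(noise, 1 - 2 * noise, noise))
  v[seq_len(block_f), seq_len(block_s)] <- 1L
  trinary_matrix(v)
}

# exhaustive best score over all >=2x2 feature x sample submatrices
exhaustive_best_score <- function(g) {
  W <- matrix(g$w_absent, nrow(g$resp), ncol(g$resp))
  W[g$resp] <- g$w_present
  p <- nrow(W); n <- ncol(W)
  fsub <- unlist(lapply(2:p, function(k) utils::combn(p, k, simplify = FALSE)),
                 recursive = FALSE)
  ssub <- unlist(lapply(2:n, function(k) utils::combn(n, k, simplify = FALSE)),
                 recursive = FALSE)
  best <- -Inf
  for (fs in fsub) {
    rw <- colSums(W[fs, , drop = FALSE])
    for (ss in ssub) {
      sc <- sum(rw[ss])
      if (sc > best) best <- sc
    }
  }
  best
}

# Jaccard overlap on the union of (tagged) feature and sample sets
jaccard_elements <- function(f1, s1, f2, s2) {
  a <- c(paste0("f:", f1), paste0("s:", s1))
  b <- c(paste0("f:", f2), paste0("s:", s2))
  length(intersect(a, b)) / length(union(a, b))
}

# random bicluster + labels + network for brute-force membership checks
random_selection_case <- function(seed) {
  set.seed(seed)
  feats <- sprintf("miR-%02d", sample(20, sample(2:6, 1)))
  n_s <- sample(3:8, 1)
  samps <- sprintf("s%02d", sample(30, n_s))
  classes <- c("colon", "lung", "breast", "kidney")
  labels <- stats::setNames(sample(classes, n_s, TRUE), samps)
  n_e <- sample(0:15, 1)
  net <- cm_network(data.frame(
    cancer_type = sample(classes, max(n_e, 1), TRUE),
    mirna = sprintf("miR-%02d", sample(20, max(n_e, 1), TRUE))))
  if (n_e == 0)
    net <- cm_network(data.frame(cancer_type = character(0),
                                 mirna = character(0)))
  list(b = bicluster(feats, samps), net = net, labels = labels)
}
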