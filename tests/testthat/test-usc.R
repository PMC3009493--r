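test_that("centroid statistics match hand calculations on the worked fixture", {
  m <- worked_fixture_2f()
  cs <- compute_centroids(m)
  # feature miR-A: values A:(1,3), B:(5,7)
  expect_equal(unname(cs$overall_centroid["miR-A"]), 4)
  expect_equal(unname(cs$class_centroids["miR-A", ]), c(2, 6))
  # pooled variance: ((-1)^2 + 1^2 + (-1)^2 + 1^2) / (4 - 2) = 2
  expect_equal(unname(cs$s_i["miR-A"]), sqrt(2), tolerance = 1e-12)
  # feature miR-B: values A:(2,2), B:(4,6)
  expect_equal(unname(cs$overall_centroid["miR-B"]), 3.5)
  expect_equal(unname(cs$class_centroids["miR-B", ]), c(2, 5))
  expect_equal(unname(cs$s_i["miR-B"]), 1, tolerance = 1e-12)
  expect_equal(cs$s_0, (1 + sqrt(2)) / 2, tolerance = 1e-12)
  expect_equal(unname(cs$n_k), c(2L, 2L))
})

test_that("degenerate class structures are rejected", {
  v <- matrix(rnorm(8), 2, 4,
              dimnames = list(c("f1", "f2"), paste0("s", 1:4)))
  expect_error(compute_centroids(
    exprmat(v, scale = "log2",
            labels = c(s1 = "A", s2 = "A", s3 = "A", s4 = "A"))),
    "at least 2 classes")
  expect_error(compute_centroids(
    exprmat(v, scale = "log2",
            labels = c(s1 = "A", s2 = "A", s3 = "A", s4 = "B"))),
    "fewer than 2 samples")
})

test_that("overall centroid is the class-size weighted mean of class centroids", {
  sim <- simulate_classification_data(K = 3, p = 10, n_k = 4, p_info = 2,
                                      effect = 2, seed = 31)
  # unbalance the classes by dropping two samples of the first class
  keep <- sample_ids(sim$matrix)[-(1:2)]
  m <- subset_exprmat(sim$matrix, samples = keep)
  cs <- compute_centroids(m)
  recomputed <- as.numeric(cs$class_centroids %*% cs$n_k / cs$n)
  expect_equal(recomputed, unname(cs$overall_centroid), tolerance = 1e-12)
})

test_that("relative differences match the hand-derived one-feature case", {
  # one feature, values A:(1,3), B:(5,7): s_0 = s_i = sqrt(2),
  # m_k = sqrt(1/2 - 1/4) = 0.5, d_A = (2 - 4) / (0.5 * 2 * sqrt(2))
  v <- matrix(c(1, 3, 5, 7), 1, 4,
              dimnames = list("miR-A", paste0("s", 1:4)))
  m <- exprmat(v, scale = "log2",
               labels = c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
  d <- relative_difference(compute_centroids(m))
  expect_equal(unname(d["miR-A", "A"]), -sqrt(2), tolerance = 1e-12)
  expect_equal(unname(d["miR-A", "B"]), sqrt(2), tolerance = 1e-12)
})

test_that("relative differences on the two-feature fixture match hand values to 1e-9", {
  m <- worked_fixture_2f()
  d <- relative_difference(compute_centroids(m))
  s0 <- (1 + sqrt(2)) / 2
  mk <- 0.5
  expect_equal(unname(d["miR-A", "A"]), (2 - 4) / (mk * (sqrt(2) + s0)),
               tolerance = 1e-9)
  expect_equal(unname(d["miR-B", "A"]), (2 - 3.5) / (mk * (1 + s0)),
               tolerance = 1e-9)
  # antisymmetry for two balanced classes, and sign agreement
  expect_equal(d[, "A"], -d[, "B"], tolerance = 1e-12)
  expect_true(all(sign(d) ==
                    sign(compute_centroids(m)$class_centroids - c(4, 3.5))))
  # the sqrt(1/n_k + 1/n) variant is exposed
  d_sum <- relative_difference(compute_centroids(m), mk_form = "sum")
  expect_equal(unname(d_sum["miR-A", "A"]),
               (2 - 4) / (sqrt(1 / 2 + 1 / 4) * (sqrt(2) + s0)),
               tolerance = 1e-9)
})

test_that("soft thresholding follows the closed form exactly", {
  d <- matrix(c(0.9, -0.2, 0, 1.7), 2, 2,
              dimnames = list(c("f1", "f2"), c("A", "B")))
  expect_equal(unname(shrink(d, 0.3)),
               matrix(c(0.6, 0, 0, 1.4), 2, 2), tolerance = 1e-12)
  expect_equal(shrink(d, 0), d)
  expect_error(shrink(d, -0.1), "0")
  # |d'| = max(|d| - delta, 0) elementwise on random input
  set.seed(32)
  d <- matrix(rnorm(200), 50, 4)
  for (delta in c(0.1, 0.5, 1.5))
    expect_equal(abs(shrink(d, delta)), pmax(abs(d) - delta, 0),
                 tolerance = 1e-12)
})

test_that("feature selection matches a brute-force recount and shrinks with delta", {
  set.seed(33)
  d <- matrix(rnorm(200), 50, 4,
              dimnames = list(sprintf("f%02d", 1:50), paste0("k", 1:4)))
  deltas <- seq(0, 2.8, length.out = 20)
  prev <- Inf
  prev_set <- rownames(d)
  for (delta in deltas) {
    dp <- shrink(d, delta)
    sel <- tryCatch(select_features(dp), error = function(e) character(0))
    # brute force: a feature survives iff any |d_ik| > delta
    brute <- rownames(d)[vapply(seq_len(nrow(d)), function(i)
      any(abs(d[i, ]) > delta), logical(1))]
    expect_identical(sel, brute)
    expect_lte(length(sel), prev)
    expect_true(all(sel %in% prev_set))  # nesting of the shrinkage path
    prev <- length(sel)
    prev_set <- sel
  }
  expect_error(select_features(shrink(d, 99)), "too large")
})

test_that("decorrelation drops the weaker of two identical features", {
  set.seed(34)
  base <- rnorm(10)
  v <- rbind(f_weak = base, f_strong = base, f_other = rnorm(10))
  colnames(v) <- paste0("s", 1:10)
  m <- exprmat(v, scale = "log2")
  d <- matrix(c(0.5, 2.0, 1.0), 3, 1,
              dimnames = list(rownames(v), "A"))
  kept <- decorrelate(rownames(v), m, d, rho = 0.9)
  expect_true("f_strong" %in% kept)
  expect_false("f_weak" %in% kept)
  # rho = 1 keeps everything (SC equivalence)
  expect_identical(decorrelate(rownames(v), m, d, rho = 1), rownames(v))
  expect_error(decorrelate(rownames(v), m, d, rho = 1.5), "rho")
})

test_that("greedy decorrelation equals a brute-force scan and output pairs obey rho", {
  set.seed(35)
  v <- matrix(rnorm(12 * 15), 12, 15,
              dimnames = list(sprintf("f%02d", 1:12), sprintf("s%02d", 1:15)))
  v[2, ] <- v[1, ] + rnorm(15, sd = 0.1)   # strongly correlated pair
  v[5, ] <- -v[4, ] + rnorm(15, sd = 0.2)  # strong negative correlation
  m <- exprmat(v, scale = "log2")
  d <- matrix(rnorm(12 * 3), 12, 3,
              dimnames = list(rownames(v), c("A", "B", "C")))
  for (rho in c(0.3, 0.6, 0.9)) {
    kept <- decorrelate(rownames(v), m, d, rho)
    # brute-force re-walk of the specified scan order
    strength <- apply(abs(d), 1, max)
    ord <- rownames(v)[order(-strength, rownames(v))]
    cm <- cor(t(v))
    brute <- character(0)
    for (f in ord)
      if (!length(brute) || all(abs(cm[f, brute]) <= rho))
        brute <- c(brute, f)
    expect_setequal(kept, brute)
    cm_kept <- abs(cm[kept, kept])
    diag(cm_kept) <- 0
    expect_lte(max(cm_kept), rho)
  }
  v[3, ] <- 5  # constant feature: correlation undefined
  expect_error(decorrelate(rownames(v), exprmat(v, scale = "log2"), d, 0.9),
               "zero-variance")
})

test_that("fit with delta 0, rho 1 reproduces the raw class centroids", {
  sim <- simulate_classification_data(K = 3, p = 30, n_k = 6, p_info = 3,
                                      effect = 2, seed = 36)
  fit <- usc_fit(sim$matrix, delta = 0, rho = 1)
  cs <- compute_centroids(sim$matrix)
  expect_identical(fit$selected_features, feature_ids(sim$matrix))
  expect_equal(fit$shrunken_centroids, cs$class_centroids, tolerance = 1e-9)
  expect_error(usc_fit(sim$matrix, delta = 1e6), "too large")
  # empirical priors sum to one and follow class sizes
  expect_equal(sum(fit$priors), 1)
  expect_equal(unname(fit$priors), rep(1 / 3, 3))
})

test_that("shrunken centroids and discriminant scores match hand values on the 3-class fixture", {
  m <- worked_fixture_3k()
  delta <- 0.2
  fit <- usc_fit(m, delta = delta, rho = 1, prior = "uniform")
  # hand derivation: both features have class centroids with within-class
  # sums of squares 2 per class -> s_i = sqrt(6 / 3) = sqrt(2) = s_0;
  # m_k = sqrt(1/2 - 1/6) = sqrt(1/3)
  s <- sqrt(2); s0 <- sqrt(2); mk <- sqrt(1 / 3)
  xbar <- c(26 / 6, 20 / 6)
  cents <- rbind(c(1, 4, 8), c(5, 2, 3))
  d <- (cents - xbar) / (mk * (s + s0))
  dp <- sign(d) * pmax(abs(d) - delta, 0)
  shr <- xbar + mk * (s + s0) * dp
  expect_equal(unname(fit$shrunken_centroids), unname(shr),
               tolerance = 1e-9)
  # discriminant scores for x* = (4, 3), uniform priors
  xstar <- matrix(c(4, 3), 2, 1, dimnames = list(c("miR-A", "miR-B"), "t1"))
  sc <- discriminant_scores(fit, xstar)
  for (k in 1:3) {
    hand <- sum((c(4, 3) - shr[, k])^2 / (s + s0)^2) - 2 * log(1 / 3)
    expect_equal(unname(sc[1, k]), hand, tolerance = 1e-9)
  }
})

test_that("prediction takes the minimum-score class, ties flagged lexicographically", {
  # one feature, two balanced classes: x* at the midpoint ties
  v <- matrix(c(1, 3, 5, 7), 1, 4,
              dimnames = list("miR-A", paste0("s", 1:4)))
  m <- exprmat(v, scale = "log2",
               labels = c(s1 = "B", s2 = "B", s3 = "A", s4 = "A"))
  fit <- usc_fit(m, delta = 0, rho = 1)
  mid <- mean(fit$shrunken_centroids["miR-A", ])
  xstar <- matrix(mid, 1, 1, dimnames = list("miR-A", "t1"))
  pred <- predict(fit, xstar)
  expect_true(pred$tie)
  expect_identical(pred$class, "A")  # lexicographically first
  # a sample at a pure shrunken centroid goes to that class
  x2 <- matrix(fit$shrunken_centroids["miR-A", "B"], 1, 1,
               dimnames = list("miR-A", "t2"))
  expect_identical(predict(fit, x2)$class, "B")
  expect_error(predict(fit, matrix(0, 1, 1,
                                   dimnames = list("other", "t"))),
               "lacks selected feature")
})

test_that("on a one-feature two-class problem the decision boundary is the centroid midpoint", {
  set.seed(37)
  v <- matrix(c(rnorm(6, 0), rnorm(6, 4)), 1, 12,
              dimnames = list("miR-A", sprintf("s%02d", 1:12)))
  m <- exprmat(v, scale = "log2",
               labels = stats::setNames(rep(c("low", "high"), each = 6),
                                        colnames(v)))
  fit <- usc_fit(m, delta = 0.1, rho = 1, prior = "uniform")
  mid <- mean(fit$shrunken_centroids["miR-A", ])
  eps <- 1e-6
  x <- matrix(c(mid - eps, mid + eps), 1, 2,
              dimnames = list("miR-A", c("below", "above")))
  pred <- predict(fit, x)
  low_side <- fit$shrunken_centroids["miR-A", "low"] < mid
  expect_identical(pred$class,
                   if (low_side) c("low", "high") else c("high", "low"))
})

test_that("USC at rho = 1 predicts identically to the SC path", {
  for (seed in 41:45) {
    sim <- simulate_classification_data(K = 4, p = 40, n_k = 6, p_info = 3,
                                        effect = 2, seed = seed)
    te <- simulate_classification_data(K = 4, p = 40, n_k = 3, p_info = 3,
                                       effect = 2, seed = seed + 100)
    for (delta in c(0, 0.4, 0.8)) {
      usc <- usc_fit(sim$matrix, delta = delta, rho = 1, method = "usc")
      sc <- usc_fit(sim$matrix, delta = delta, method = "sc")
      expect_identical(usc$selected_features, sc$selected_features)
      expect_equal(usc$shrunken_centroids, sc$shrunken_centroids,
                   tolerance = 1e-12)
      expect_identical(predict(usc, te$matrix)$class,
                       predict(sc, te$matrix)$class)
    }
  }
})

test_that("predictions are invariant to feature order and to affine rescaling with refit", {
  sim <- simulate_classification_data(K = 3, p = 20, n_k = 8, p_info = 3,
                                      effect = 2.5, seed = 46)
  te <- simulate_classification_data(K = 3, p = 20, n_k = 4, p_info = 3,
                                     effect = 2.5, seed = 146)
  fit <- usc_fit(sim$matrix, delta = 0.3, rho = 0.9)
  base <- predict(fit, te$matrix)$class
  # permute feature order
  perm <- sample(feature_ids(sim$matrix))
  fit_p <- usc_fit(subset_exprmat(sim$matrix, features = perm),
                   delta = 0.3, rho = 0.9)
  expect_identical(predict(fit_p, te$matrix)$class, base)
  # affine rescale train and test identically, refit
  scale_tr <- sim$matrix; scale_te <- te$matrix
  scale_tr$values <- 2.5 * scale_tr$values + 7
  scale_te$values <- 2.5 * scale_te$values + 7
  fit_a <- usc_fit(scale_tr, delta = 0.3, rho = 0.9)
  expect_identical(predict(fit_a, scale_te)$class, base)
})

test_that("well-separated classes are classified nearly perfectly", {
  sim <- simulate_classification_data(K = 4, p = 50, n_k = 15, p_info = 4,
                                      effect = 3, seed = 47)
  te <- simulate_classification_data(K = 4, p = 50, n_k = 50, p_info = 4,
                                     effect = 3, seed = 147)
  fit <- usc_fit(sim$matrix, delta = 0.5, rho = 0.9)
  pred <- predict(fit, te$matrix)
  acc <- mean(pred$class == te$labels[pred$sample_id])
  expect_gte(acc, 0.95)
})
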