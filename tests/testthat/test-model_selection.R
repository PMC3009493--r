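test_that("exactly divisible classes give perfectly balanced stratified folds", {
  labels <- stats::setNames(rep(c("A", "B"), each = 4), paste0("s", 1:8))
  folds <- make_folds(labels, n_folds = 4, seed = 1)
  expect_setequal(unique(folds), 1:4)
  for (f in 1:4)
    expect_identical(as.integer(table(labels[folds == f])), c(1L, 1L))
  # deterministic given the seed
  expect_identical(folds, make_folds(labels, n_folds = 4, seed = 1))
  expect_false(identical(folds, make_folds(labels, n_folds = 4, seed = 2)))
})

test_that("single-sample classes are pinned to training with a warning", {
  labels <- c(s1 = "A", s2 = "A", s3 = "A", s4 = "A", s5 = "rare")
  expect_warning(folds <- make_folds(labels, n_folds = 4, seed = 3),
                 "pinned to training")
  expect_true(is.na(folds["s5"]))
  expect_false(anyNA(folds[paste0("s", 1:4)]))
})

test_that("within every class fold sizes differ by at most one", {
  set.seed(4)
  for (rep in 1:100) {
    n <- sample(8:40, 1)
    k <- sample(2:5, 1)
    labels <- stats::setNames(sample(LETTERS[1:k], n, TRUE),
                              sprintf("s%03d", 1:n))
    folds <- suppressWarnings(make_folds(labels, n_folds = 4, seed = rep))
    for (cl in unique(labels)) {
      cnt <- table(factor(folds[labels == cl & !is.na(folds)], levels = 1:4))
      if (sum(cnt) > 0) expect_lte(max(cnt) - min(cnt), 1)
    }
    # every non-pinned sample is in exactly one fold
    expect_true(all(folds[!is.na(folds)] %in% 1:4))
  }
})

test_that("cross-validation is deterministic and its mean is the fold-error mean", {
  sim <- simulate_classification_data(K = 3, p = 30, n_k = 8, p_info = 3,
                                      effect = 3, seed = 51)
  cv <- cross_validate(sim$matrix, delta_grid = c(0, 0.5, 1),
                       rho_grid = c(0.7, 1), repeats = 3, n_folds = 4,
                       seed = 9)
  cv2 <- cross_validate(sim$matrix, delta_grid = c(0, 0.5, 1),
                        rho_grid = c(0.7, 1), repeats = 3, n_folds = 4,
                        seed = 9)
  expect_identical(cv$mean_error, cv2$mean_error)
  expect_identical(cv$per_repeat_errors, cv2$per_repeat_errors)
  expect_true(all(cv$mean_error >= 0 & cv$mean_error <= 1))
  # aggregation identity: grid mean equals the mean over usable splits with
  # failed cells counted as error 1
  for (di in seq_along(cv$delta_grid))
    for (ri in seq_along(cv$rho_grid)) {
      raw <- cv$per_repeat_errors[, , di, ri][cv$valid_splits]
      expect_equal(unname(cv$mean_error[di, ri]),
                   mean(ifelse(is.na(raw), 1, raw)), tolerance = 1e-12)
    }
  # separable data: some cell reaches zero mean error
  expect_equal(min(cv$mean_error), 0)
})

test_that("every split uses disjoint, exhaustive train/test sample sets", {
  labels <- stats::setNames(rep(LETTERS[1:3], times = c(6, 5, 4)),
                            sprintf("s%02d", 1:15))
  for (r in 1:5) {
    folds <- make_folds(labels, n_folds = 4, seed = 100 + r)
    for (f in 1:4) {
      test_ids <- names(folds)[folds == f & !is.na(folds)]
      train_ids <- setdiff(names(folds), test_ids)
      expect_length(intersect(test_ids, train_ids), 0)
      expect_setequal(c(test_ids, train_ids), names(labels))
    }
  }
})

test_that("an unreachable delta grid flags every cell and then errors", {
  sim <- simulate_classification_data(K = 3, p = 20, n_k = 6, p_info = 2,
                                      effect = 2, seed = 52)
  expect_error(cross_validate(sim$matrix, delta_grid = 1e6, rho_grid = 1,
                              repeats = 2, n_folds = 4, seed = 1),
               "every grid cell")
  # a grid with one workable and one failing delta flags only the latter
  cv <- cross_validate(sim$matrix, delta_grid = c(0.2, 1e6), rho_grid = 1,
                       repeats = 2, n_folds = 4, seed = 1)
  expect_false(cv$failed[1, 1])
  expect_true(cv$failed[2, 1])
  expect_equal(unname(cv$mean_error[2, 1]), 1)
})

test_that("parameter selection is the error argmin with parsimony tie-breaks", {
  grid_cv <- function(me, failed = NULL) {
    dg <- c(0.1, 0.3, 0.5); rg <- c(0.8, 0.9)
    if (is.null(failed)) failed <- matrix(FALSE, 3, 2)
    structure(list(delta_grid = dg, rho_grid = rg, mean_error = me,
                   failed = failed), class = "usc_cv")
  }
  me <- matrix(c(0.4, 0.2, 0.5, 0.3, 0.6, 0.7), 3, 2)
  expect_equal(select_params(grid_cv(me)), c(delta = 0.3, rho = 0.8))
  # tie between (0.1, 0.9) and (0.3, 0.9): larger delta wins
  me <- matrix(c(0.5, 0.5, 0.5, 0.1, 0.1, 0.5), 3, 2)
  expect_equal(select_params(grid_cv(me)), c(delta = 0.3, rho = 0.9))
  # random grids: returned cell attains the global minimum
  set.seed(53)
  for (i in 1:25) {
    me <- matrix(runif(6), 3, 2)
    sel <- select_params(grid_cv(me))
    expect_equal(me[match(sel["delta"], c(0.1, 0.3, 0.5)),
                    match(sel["rho"], c(0.8, 0.9))],
                 min(me), tolerance = 1e-12)
  }
  # failed cells are never selected
  me <- matrix(c(0, 0.2, 0.5, 0.5, 0.5, 0.5), 3, 2)
  failed <- matrix(c(TRUE, rep(FALSE, 5)), 3, 2)
  expect_equal(select_params(grid_cv(me, failed))[["delta"]], 0.3)
})

test_that("CV-selected delta tracks the oracle held-out optimum on synthetic data", {
  hits <- 0L
  delta_grid <- seq(0, 2, by = 0.25)
  for (run in 1:10) {
    sim <- simulate_classification_data(K = 3, p = 40, n_k = 10, p_info = 4,
                                        effect = 2, seed = 200 + run)
    te <- simulate_classification_data(K = 3, p = 40, n_k = 50, p_info = 4,
                                       effect = 2, seed = 300 + run)
    cv <- cross_validate(sim$matrix, delta_grid = delta_grid, rho_grid = 1,
                         repeats = 3, n_folds = 4, seed = 400 + run)
    sel <- select_params(cv)
    n_te <- ncol(te$matrix$values)
    oracle_err <- vapply(delta_grid, function(delta) {
      fit <- tryCatch(usc_fit(sim$matrix, delta = delta, rho = 1),
                      error = function(e) NULL)
      if (is.null(fit)) return(1)
      pred <- predict(fit, te$matrix)
      mean(pred$class != te$labels[pred$sample_id])
    }, numeric(1))
    # hit when the chosen delta is within one grid step of an oracle
    # minimizer, or its oracle error is within the one-sample granularity
    # of the minimum
    minimizers <- delta_grid[oracle_err <= min(oracle_err) + 1e-9]
    if (min(abs(sel[["delta"]] - minimizers)) <= 0.25 ||
        oracle_err[match(sel[["delta"]], delta_grid)] <=
          min(oracle_err) + 1 / n_te + 1e-9)
      hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("strict CV re-runs selection per split and still finds a working grid", {
  sim <- simulate_classification_data(K = 3, p = 30, n_k = 8, p_info = 3,
                                      effect = 3, seed = 55)
  net <- simulate_network(sim$truth, coverage = 1, false_edge_rate = 0,
                          seed = 56)
  cv <- sfss_cross_validate(sim$matrix, net,
                            delta_grid = c(0, 0.5, 1), rho_grid = c(0.8, 1),
                            repeats = 2, n_folds = 4, seed = 57)
  expect_s3_class(cv, "usc_cv")
  expect_true(all(cv$mean_error >= 0 & cv$mean_error <= 1))
  expect_false(all(cv$failed))
  # deterministic
  cv2 <- sfss_cross_validate(sim$matrix, net,
                             delta_grid = c(0, 0.5, 1), rho_grid = c(0.8, 1),
                             repeats = 2, n_folds = 4, seed = 57)
  expect_identical(cv$mean_error, cv2$mean_error)
  # separable data still reaches a low-error cell without leakage
  expect_lte(min(cv$mean_error), 0.2)
})
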