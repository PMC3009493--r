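#' Run the full simultaneous feature/sample selection pipeline
#'
#' Executes the whole flow on one training (and optionally one test) data
#' set: preprocessing (optional log2 transform and minimum-expression
#' filter), per-feature standardization, trinary discretization, bipartite
#' response graph, bicluster search, network-based selection of potential
#' biclusters and their relevant samples, repeated fourfold cross-validation
#' of the classifier over the (delta, rho) grid, final fit at the selected
#' parameters, and classification of the test samples. Every source of
#' randomness derives from the single top-level seed, so a rerun with the
#' same configuration reproduces every artifact byte for byte.
#'
#' @param config A configuration list, or the path of a YAML/JSON file
#'   holding one. Top-level keys (all but `data` optional):
#' \describe{
#'   \item{seed}{integer, default 1.}
#'   \item{data}{either `simulate: {K, p, n_k, p_info, effect, coverage,
#'     false_edge_rate, test_n_k}` or file paths `expression` (GCT),
#'     `labels` (CLS/TSV), `network` (TSV), optional `test_expression`,
#'     `test_labels`, and `scale` (`"raw"`/`"log2"`, default `"raw"`).}
#'   \item{preprocess}{`log2` (default: transform iff data is raw-scale),
#'     `floor` (1), `cutoff`, `min_count` (filter only runs when `cutoff`
#'     given).}
#'   \item{bicluster}{`t` (1), `p_c` (0.9), `d` (30), `k` (3), `n_keep` (20),
#'     `max_overlap` (0.25).}
#'   \item{selection}{`any_mirna` (FALSE).}
#'   \item{cv}{`delta_grid` (0..2 by 0.1), `rho_grid` (0.5..1 by 0.1),
#'     `repeats` (10), `n_folds` (4).}
#'   \item{classifier}{`prior` ("empirical"), `method` ("usc"), `mk_form`
#'     ("difference").}
#' }
#' @param output_dir Directory for artifacts (created if needed); `NULL`
#'   skips writing.
#' @return Invisibly, a list with `selection`, `cv`, `params`, `model`,
#'   `predictions`, `report`.
#' @export
run_sfss <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config error: file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config error: 'config' must be a list or path")
  cfg_hash <- config_hash(config)
  dat <- config$data
  if (is.null(dat) || (is.null(dat$simulate) &&
                       (is.null(dat$expression) || is.null(dat$labels) ||
                        is.null(dat$network))))
    stop("config error: 'data' needs either a 'simulate' block or ",
         "'expression' + 'labels' + 'network' paths")
  seed <- as.integer(config$seed %||% 1L)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## -- load or simulate -------------------------------------------------
  test <- NULL
  inputs <- stage("load", {
    if (!is.null(dat$simulate)) {
      s <- dat$simulate
      tr <- simulate_classification_data(
        K = s$K %||% 5L, p = s$p %||% 100L, n_k = s$n_k %||% 20L,
        p_info = s$p_info %||% 5L, effect = s$effect %||% 3,
        seed = seed)
      te <- simulate_classification_data(
        K = s$K %||% 5L, p = s$p %||% 100L, n_k = s$test_n_k %||% 5L,
        p_info = s$p_info %||% 5L, effect = s$effect %||% 3,
        seed = seed + 1L)
      net <- simulate_network(tr$truth, coverage = s$coverage %||% 1,
                              false_edge_rate = s$false_edge_rate %||% 0,
                              seed = seed + 2L)
      list(train = tr$matrix, test = te$matrix, net = net,
           truth = tr$truth)
    } else {
      m <- read_gct(dat$expression,
                    scale = dat$scale %||% "raw")
      lab <- read_labels(dat$labels, sample_ids = sample_ids(m))
      m <- set_labels(m, lab)
      te <- NULL
      if (!is.null(dat$test_expression)) {
        te <- read_gct(dat$test_expression, scale = dat$scale %||% "raw")
        if (!is.null(dat$test_labels))
          te <- set_labels(te, read_labels(dat$test_labels,
                                           sample_ids = sample_ids(te)))
      }
      list(train = m, test = te, net = read_network(dat$network),
           truth = NULL)
    }
  })
  train <- inputs$train; test <- inputs$test; net <- inputs$net

  ## -- preprocess --------------------------------------------------------
  pp <- config$preprocess
  pre <- stage("preprocess", {
    do_log2 <- pp$log2 %||% (train$scale == "raw")
    if (do_log2) {
      train <- log2_transform(train, floor = pp$floor %||% 1)
      if (!is.null(test)) test <- log2_transform(test, floor = pp$floor %||% 1)
    }
    if (!is.null(pp$cutoff)) {
      train <- filter_min_expression(train, cutoff = pp$cutoff,
                                     min_count = pp$min_count %||% 1L)
      if (!is.null(test))
        test <- subset_exprmat(test, features = feature_ids(train))
    }
    std <- standardize_features(train)
    list(std = std,
         test_std = if (!is.null(test))
           apply_standardization(subset_exprmat(test,
                                                features = feature_ids(train)),
                                 std))
  })
  std <- pre$std; test_std <- pre$test_std

  ## -- biclustering ------------------------------------------------------
  bc <- config$bicluster
  bicl <- stage("bicluster", {
    tm <- discretize(std, t = bc$t %||% 1)
    g <- build_graph(tm, p_c = bc$p_c %||% 0.9)
    find_biclusters(g, d = bc$d %||% 30L, k = bc$k %||% 3L,
                    n_keep = bc$n_keep %||% 20L,
                    max_overlap = bc$max_overlap %||% 0.25)
  })

  ## -- network selection -------------------------------------------------
  sel <- stage("network_selection",
               build_training_set(bicl, std, net,
                                  any_mirna = isTRUE(config$selection$any_mirna)))

  ## -- cross-validation --------------------------------------------------
  cvc <- config$cv
  clf <- config$classifier
  cv <- stage("cross_validation", {
    if (isTRUE(cvc$strict)) {
      # leakage-free benchmarking: re-run the selection stack in every split
      sfss_cross_validate(std, net,
                          delta_grid = cvc$delta_grid %||% seq(0, 2, 0.1),
                          rho_grid = cvc$rho_grid %||% seq(0.5, 1, 0.1),
                          repeats = cvc$repeats %||% 10L,
                          n_folds = cvc$n_folds %||% 4L,
                          seed = seed + 1000L,
                          bicluster_args = bc %||% list(),
                          any_mirna = isTRUE(config$selection$any_mirna),
                          prior = clf$prior %||% "empirical",
                          method = clf$method %||% "usc",
                          mk_form = clf$mk_form %||% "difference")
    } else {
      cross_validate(sel$matrix,
                     delta_grid = cvc$delta_grid %||% seq(0, 2, 0.1),
                     rho_grid = cvc$rho_grid %||% seq(0.5, 1, 0.1),
                     repeats = cvc$repeats %||% 10L,
                     n_folds = cvc$n_folds %||% 4L,
                     seed = seed + 1000L,
                     prior = clf$prior %||% "empirical",
                     method = clf$method %||% "usc",
                     mk_form = clf$mk_form %||% "difference")
    }
  })
  params <- select_params(cv)

  ## -- final fit and prediction ------------------------------------------
  model <- stage("fit",
                 usc_fit(sel$matrix, delta = params[["delta"]],
                         rho = params[["rho"]],
                         prior = clf$prior %||% "empirical",
                         method = clf$method %||% "usc",
                         mk_form = clf$mk_form %||% "difference"))
  predictions <- NULL
  accuracy <- NULL
  if (!is.null(test_std)) {
    predictions <- stage("predict", predict(model, test_std))
    if (!is.null(test_std$labels)) {
      truth_lab <- test_std$labels[predictions$sample_id]
      predictions$true_class <- as.character(truth_lab)
      accuracy <- mean(predictions$class == predictions$true_class)
    }
  }

  report <- list(seed = seed,
                 config_hash = cfg_hash,
                 n_biclusters = sel$report$n_biclusters,
                 n_potential = sel$report$n_potential,
                 n_selected_features = sel$report$n_features,
                 n_selected_samples = sel$report$n_samples,
                 classes_kept = sel$report$classes_kept,
                 classes_dropped = sel$report$classes_dropped,
                 delta = params[["delta"]],
                 rho = params[["rho"]],
                 cv_min_error = min(cv$mean_error[!cv$failed]),
                 test_accuracy = accuracy)

  result <- list(selection = sel, biclusters = bicl, cv = cv,
                 params = params, model = model,
                 predictions = predictions, report = report)

  if (!is.null(output_dir)) {
    stage("write_artifacts", {
      dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
      write_biclusters(bicl, file.path(output_dir, "biclusters.tsv"))
      write_selection_report(sel, file.path(output_dir,
                                            "selection_report.json"))
      write_cv_result(cv, file.path(output_dir, "cv_result.json"))
      write_usc_model(model, file.path(output_dir, "model.json"))
      if (!is.null(predictions))
        utils::write.table(predictions,
                           file.path(output_dir, "predictions.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(report, file.path(output_dir, "run_report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           null = "null")
    })
  }
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small deterministic polynomial hash of the configuration, recorded in every
# artifact so runs can be matched to their settings
config_hash <- function(config) {
  keys <- names(config)
  s <- paste(deparse(if (is.null(keys)) config else config[order(keys)]),
             collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
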