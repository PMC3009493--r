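#' Is a bicluster supported by the cancer--miRNA network?
#'
#' A bicluster is "potential" when at least one of its miRNAs has literature
#' evidence of dysregulation in the cancer type of at least one of its
#' samples, i.e. some (class(sample), miRNA) pair of the bicluster is an edge
#' of the network. Edge direction is ignored; only association matters.
#'
#' @param b A [bicluster].
#' @param net A [cm_network].
#' @param labels Named character vector, sample id -> class label; must cover
#'   every sample of `b`.
#' @return `TRUE` or `FALSE`.
#' @export
is_potential <- function(b, net, labels) {
  stopifnot(inherits(b, "bicluster"), inherits(net, "cm_network"))
  miss <- setdiff(b$samples, names(labels))
  if (length(miss))
    stop("unlabeled sample(s) in bicluster: ", paste(miss, collapse = ", "))
  classes <- unique(as.character(labels[b$samples]))
  pairs <- expand.grid(cancer_type = classes, mirna = b$features,
                       stringsAsFactors = FALSE)
  any(net_has_edge(net, pairs$cancer_type, pairs$mirna))
}

#' Keep the network-relevant samples of a potential bicluster
#'
#' A sample is relevant to the bicluster when its class is adjacent in the
#' network to at least one of the bicluster's miRNAs. All miRNAs of the
#' bicluster are retained: members of one bicluster are likely co-regulated,
#' so the whole feature set carries signal even when only some of its members
#' have direct literature support. By default the adjacency test is
#' per-bicluster (against this bicluster's own miRNAs); `any_mirna = TRUE`
#' relaxes it to "the sample's class appears anywhere in the network".
#'
#' @inheritParams is_potential
#' @param any_mirna Use the looser class-appears-anywhere rule
#'   (default `FALSE`).
#' @return A list with `features` (all of `b$features`) and `samples` (the
#'   relevant subset of `b$samples`).
#' @export
select_relevant <- function(b, net, labels, any_mirna = FALSE) {
  stopifnot(inherits(b, "bicluster"), inherits(net, "cm_network"))
  miss <- setdiff(b$samples, names(labels))
  if (length(miss))
    stop("unlabeled sample(s) in bicluster: ", paste(miss, collapse = ", "))
  cls <- as.character(labels[b$samples])
  if (any_mirna) {
    keep <- net_canon(cls) %in% net_canon(net$edges$cancer_type)
  } else {
    classes <- unique(cls)
    hit <- vapply(classes, function(u)
      any(net_has_edge(net, rep(u, length(b$features)), b$features)),
      logical(1L))
    keep <- cls %in% classes[hit]
  }
  list(features = b$features, samples = b$samples[keep])
}

#' Assemble the reduced training set from potential biclusters
#'
#' Biclusters without any cancer--miRNA network support are discarded; from
#' each remaining (potential) bicluster all miRNAs and only the
#' network-relevant samples are taken, and the union over biclusters defines
#' the reduced training matrix. Classes that lose every sample are dropped
#' and listed in the report.
#'
#' @param bs Non-empty list of [bicluster] objects over `m`'s ids.
#' @param m The labeled [exprmat] the biclusters came from.
#' @param net A [cm_network].
#' @param labels Optional named label vector; defaults to `m`'s labels.
#' @param any_mirna Passed to [select_relevant()].
#' @return A list of class `"sfss_selection"` with:
#'   * `matrix` — the reduced labeled [exprmat] (selected features x samples),
#'   * `report` — counts of input/potential biclusters, selected
#'     miRNAs/samples, kept and dropped classes.
#' @export
build_training_set <- function(bs, m, net, labels = NULL, any_mirna = FALSE) {
  stopifnot(inherits(m, "exprmat"), inherits(net, "cm_network"))
  if (!length(bs)) stop("no biclusters supplied")
  if (is.null(labels)) labels <- ordered_labels(m)
  potential <- vapply(bs, is_potential, logical(1L), net = net,
                      labels = labels)
  if (!any(potential))
    stop("no cancer-miRNA evidence found: no bicluster is potential")
  sel <- lapply(bs[potential], select_relevant, net = net, labels = labels,
                any_mirna = any_mirna)
  feats <- sort(unique(unlist(lapply(sel, `[[`, "features"))))
  samps <- sort(unique(unlist(lapply(sel, `[[`, "samples"))))
  input_classes <- sort(unique(as.character(labels[sample_ids(m)])))
  kept_classes <- sort(unique(as.character(labels[samps])))
  dropped <- setdiff(input_classes, kept_classes)
  out <- subset_exprmat(m, features = feats, samples = samps)
  out <- set_labels(out, labels[samps])
  report <- list(n_biclusters = length(bs),
                 n_potential = sum(potential),
                 n_features = length(feats),
                 n_samples = length(samps),
                 classes_kept = kept_classes,
                 classes_dropped = dropped)
  structure(list(matrix = out, report = report), class = "sfss_selection")
}

#' @export
print.sfss_selection <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("sfss_selection: %d/%d potential biclusters -> ",
                     "%d miRNAs x %d samples, %d classes kept"),
              r$n_potential, r$n_biclusters, r$n_features, r$n_samples,
              length(r$classes_kept)))
  if (length(r$classes_dropped))
    cat(sprintf(" (%d dropped: %s)", length(r$classes_dropped),
                paste(r$classes_dropped, collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Write a selection report as JSON
#'
#' @param sel An `"sfss_selection"` from [build_training_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(sel, path) {
  stopifnot(inherits(sel, "sfss_selection"))
  jsonlite::write_json(sel$report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
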