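#' Bipartite cancer--miRNA association network
#'
#' A bipartite graph G = (U, V, E): U the cancer types, V the miRNAs, and an
#' edge (u, v) whenever miRNA v is reported dysregulated in cancer type u.
#' Each edge optionally carries a dysregulation direction in
#' `{"up", "down", "mixed", "unknown"}`. Identifiers are matched
#' case-insensitively after whitespace trimming, since literature-derived
#' names vary in case; duplicate edges are collapsed and conflicting
#' directions for the same edge collapse to `"mixed"`.
#'
#' @param edges A data.frame with columns `cancer_type`, `mirna` and
#'   optionally `direction`.
#' @return An object of class `"cm_network"`: a list with `cancer_types`,
#'   `mirnas` (character vectors) and `edges` (data.frame with canonical-case
#'   `cancer_type`, `mirna`, `direction`).
#' @export
cm_network <- function(edges) {
  if (!is.data.frame(edges))
    stop("'edges' must be a data.frame")
  need <- c("cancer_type", "mirna")
  if (!all(need %in% names(edges)))
    stop("'edges' needs columns cancer_type and mirna")
  if (!nrow(edges)) {
    # an edgeless network is legal in memory (every bicluster is then
    # non-potential); only the file reader insists on at least one edge
    return(structure(list(cancer_types = character(0L),
                          mirnas = character(0L),
                          edges = data.frame(cancer_type = character(0L),
                                             mirna = character(0L),
                                             direction = character(0L),
                                             stringsAsFactors = FALSE)),
                     class = "cm_network"))
  }
  u <- trimws(as.character(edges$cancer_type))
  v <- trimws(as.character(edges$mirna))
  if (any(!nzchar(u)) || any(!nzchar(v)))
    stop("empty cancer_type or mirna identifier")
  dir <- if ("direction" %in% names(edges)) {
    trimws(tolower(as.character(edges$direction)))
  } else rep("unknown", length(u))
  dir[is.na(dir) | !nzchar(dir)] <- "unknown"
  known <- c("up", "down", "mixed", "unknown")
  if (any(!dir %in% known)) {
    warning("unknown direction token(s) treated as 'unknown': ",
            paste(unique(dir[!dir %in% known]), collapse = ", "))
    dir[!dir %in% known] <- "unknown"
  }
  cu <- net_canon(u); cv <- net_canon(v)
  # first-seen spelling is the canonical display form
  u_disp <- u[!duplicated(cu)]; names(u_disp) <- cu[!duplicated(cu)]
  v_disp <- v[!duplicated(cv)]; names(v_disp) <- cv[!duplicated(cv)]
  key <- paste(cu, cv, sep = "\r")
  dir_merged <- vapply(split(dir, key), function(d) {
    d <- setdiff(unique(d), "unknown")
    if (!length(d)) "unknown"
    else if (length(d) == 1L) d
    else "mixed"
  }, character(1L))
  uk <- unique(key)
  parts <- do.call(rbind, strsplit(uk, "\r", fixed = TRUE))
  out <- data.frame(cancer_type = unname(u_disp[parts[, 1L]]),
                    mirna = unname(v_disp[parts[, 2L]]),
                    direction = unname(dir_merged[uk]),
                    stringsAsFactors = FALSE)
  out <- out[order(net_canon(out$cancer_type), net_canon(out$mirna)), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(list(cancer_types = sort(unname(u_disp)),
                 mirnas = sort(unname(v_disp)),
                 edges = out),
            class = "cm_network")
}

# canonical form used for all identifier matching
net_canon <- function(x) tolower(trimws(x))

#' @export
print.cm_network <- function(x, ...) {
  cat(sprintf("cm_network: %d cancer types x %d miRNAs, %d edges\n",
              length(x$cancer_types), length(x$mirnas), nrow(x$edges)))
  invisible(x)
}

# fast membership test: is (class, mirna) an edge? vectorized over pairs
net_has_edge <- function(net, cancer_type, mirna) {
  key <- paste(net_canon(net$edges$cancer_type), net_canon(net$edges$mirna),
               sep = "\r")
  paste(net_canon(cancer_type), net_canon(mirna), sep = "\r") %in% key
}

#' Read a cancer--miRNA network edge table
#'
#' Tab-separated with columns `cancer_type`, `mirna` and optional `direction`.
#' A header row is detected by its first field being `cancer_type` (any case).
#'
#' @param path Path to the TSV file.
#' @return A [cm_network].
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("network file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (tolower(trimws(fields[[1L]][1L])) == "cancer_type")
    fields <- fields[-1L]
  if (!length(fields)) stop("network file has no edges: ", path)
  nfield <- lengths(fields)
  if (any(nfield < 2L | nfield > 3L))
    stop("network parse error at line ", which(nfield < 2L | nfield > 3L)[1L],
         ": expected 2 or 3 tab-separated fields")
  cm_network(data.frame(
    cancer_type = vapply(fields, `[[`, character(1L), 1L),
    mirna = vapply(fields, `[[`, character(1L), 2L),
    direction = vapply(fields, function(f)
      if (length(f) >= 3L) f[[3L]] else "unknown", character(1L)),
    stringsAsFactors = FALSE))
}

#' Write a cancer--miRNA network edge table
#'
#' @param net A [cm_network].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "cm_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
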