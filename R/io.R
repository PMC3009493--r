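#' Read a GCT v1.2 expression matrix
#'
#' Parses the GenePattern GCT format: line 1 is the version tag `#1.2`, line 2
#' declares `<nrows><TAB><ncols>`, line 3 is the header
#' `Name<TAB>Description<TAB><sample ids...>`, and each following line is one
#' feature. Any malformed line is reported with its line number. Missing cells
#' (`""`, `NA`, `NaN`) are rejected unless `impute = TRUE`, in which case they
#' are replaced by the row mean of the observed values.
#'
#' @param path Path to a GCT file.
#' @param impute Impute missing cells by the feature (row) mean instead of
#'   failing. Default `FALSE`.
#' @param scale Scale flag to record on the result; GCT carries no scale
#'   metadata so the caller must say (default `"raw"`).
#' @return An [exprmat] with the `Description` column kept as feature metadata.
#' @export
read_gct <- function(path, impute = FALSE, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]  # drop trailing blanks
  if (length(lines) < 3L) stop("GCT parse error: fewer than 3 lines")
  if (trimws(lines[1L]) != "#1.2")
    stop("GCT parse error at line 1: expected version tag '#1.2', got '",
         lines[1L], "'")
  dims <- strsplit(trimws(lines[2L]), "\t|[ ]+")[[1L]]
  dims <- suppressWarnings(as.integer(dims))
  if (length(dims) != 2L || anyNA(dims) || any(dims < 1L))
    stop("GCT parse error at line 2: expected '<nrows>\\t<ncols>'")
  nr <- dims[1L]; nc <- dims[2L]
  header <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
  if (length(header) != nc + 2L)
    stop("GCT parse error at line 3: header has ", length(header) - 2L,
         " sample columns, dimension line declares ", nc)
  sample_id <- header[-(1:2)]
  body <- lines[-(1:3)]
  if (length(body) != nr)
    stop("GCT dimension mismatch: declared ", nr, " rows, found ",
         length(body))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  bad <- which(nfield != nc + 2L)
  if (length(bad))
    stop("GCT parse error at line ", bad[1L] + 3L, ": expected ", nc + 2L,
         " fields, found ", nfield[bad[1L]])
  feat <- vapply(fields, `[[`, character(1L), 1L)
  desc <- vapply(fields, `[[`, character(1L), 2L)
  if (anyDuplicated(feat))
    stop("GCT parse error: duplicate feature ids: ",
         paste(unique(feat[duplicated(feat)]), collapse = ", "))
  vals <- matrix(NA_real_, nr, nc, dimnames = list(feat, sample_id))
  for (i in seq_len(nr)) {
    raw <- fields[[i]][-(1:2)]
    miss <- raw == "" | toupper(raw) %in% c("NA", "NAN")
    x <- suppressWarnings(as.numeric(raw))
    if (any(is.na(x) & !miss))
      stop("GCT parse error at line ", i + 3L, ": non-numeric cell '",
           raw[which(is.na(x) & !miss)[1L]], "'")
    if (any(miss)) {
      if (!impute)
        stop("GCT parse error at line ", i + 3L,
             ": missing value (set impute = TRUE to use row means)")
      if (all(miss))
        stop("GCT parse error at line ", i + 3L, ": all values missing")
      x[miss] <- mean(x[!miss])
    }
    vals[i, ] <- x
  }
  exprmat(vals, scale = scale, description = desc)
}

#' Write a GCT v1.2 expression matrix
#'
#' @param m An [exprmat].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gct <- function(m, path) {
  stopifnot(inherits(m, "exprmat"))
  v <- m$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(v), ncol(v), sep = "\t"),
               paste(c("Name", "Description", colnames(v)), collapse = "\t")),
             con)
  desc <- m$description
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], desc[i],
            format(v[i, ], digits = 15, trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, character(1L))
  writeLines(body, con)
  invisible(path)
}

#' Read sample class labels (CLS or two-column TSV)
#'
#' The CLS dialect is GenePattern's: line 1 `"<n> <K> 1"`, line 2
#' `"# <class names>"`, line 3 space-separated 0-based class indices, one per
#' sample. CLS files carry no sample ids, so ids are taken from `sample_ids`
#' (or default to `s1..sn`, matching positional joining against a GCT file).
#' If the declared class count K disagrees with the number of distinct indices
#' actually used, a warning is emitted and K is inferred from usage.
#' The TSV dialect is two columns, `sample_id<TAB>class`, no header required
#' (a `sample_id`/`sample` header row is skipped if present).
#'
#' @param path Path to the label file.
#' @param format `"auto"` (by extension), `"cls"` or `"tsv"`.
#' @param sample_ids Optional character vector of sample ids for the CLS
#'   dialect, in file column order.
#' @return Named character vector, sample id -> class label.
#' @export
read_labels <- function(path, format = c("auto", "cls", "tsv"),
                        sample_ids = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cls$", path, ignore.case = TRUE)) "cls" else "tsv"
  }
  if (format == "cls") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 3L) stop("CLS parse error: fewer than 3 lines")
    hd <- as.integer(strsplit(trimws(lines[1L]), "[ \t]+")[[1L]])
    if (length(hd) < 2L || anyNA(hd[1:2]))
      stop("CLS parse error at line 1: expected '<n> <K> 1'")
    n <- hd[1L]; k_declared <- hd[2L]
    cls_line <- sub("^#\\s*", "", trimws(lines[2L]))
    class_names <- strsplit(cls_line, "[ \t]+")[[1L]]
    idx <- strsplit(trimws(lines[3L]), "[ \t]+")[[1L]]
    if (length(idx) != n)
      stop("CLS parse error: declared ", n, " samples, line 3 has ",
           length(idx))
    num <- suppressWarnings(as.integer(idx))
    if (anyNA(num)) {
      # class-name tokens instead of numeric indices
      bad <- setdiff(idx, class_names)
      if (length(bad))
        stop("CLS parse error: unknown class token '", bad[1L], "'")
      lab <- idx
    } else {
      if (any(num < 0L | num >= length(class_names)))
        stop("CLS parse error: class index out of range [0, ",
             length(class_names) - 1L, "]")
      lab <- class_names[num + 1L]
    }
    k_used <- length(unique(lab))
    if (k_used != k_declared)
      warning("CLS declares ", k_declared, " classes but ", k_used,
              " are used; inferring K = ", k_used)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
    if (length(sample_ids) != n)
      stop("'sample_ids' must have length ", n)
    return(stats::setNames(lab, sample_ids))
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(tab) != 2L)
    stop("label TSV must have exactly 2 columns, found ", ncol(tab))
  if (nrow(tab) && tolower(tab[1L, 1L]) %in% c("sample_id", "sample"))
    tab <- tab[-1L, , drop = FALSE]
  if (!nrow(tab)) stop("label TSV is empty")
  if (anyDuplicated(tab[[1L]]))
    stop("duplicate sample ids in label file")
  stats::setNames(tab[[2L]], tab[[1L]])
}
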