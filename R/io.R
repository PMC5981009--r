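# single TSV dialect: tab-delimited, '.' decimal, LF endings, UTF-8,
# numbers at 15 significant digits (so numeric round trips stay below 1e-12)
.fmt <- function(x) formatC(x, digits = 15, format = "g")

#' Write a labeled square matrix as TSV
#'
#' @param m numeric or logical square matrix with dimnames.
#' @param path output file.
#' @export
write_matrix <- function(m, path) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  labs <- rownames(m)
  if (is.null(labs)) labs <- sprintf("node%02d", seq_len(nrow(m)))
  body <- if (is.logical(m)) matrix(as.integer(m), nrow(m)) else
    matrix(.fmt(m), nrow(m))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("", labs), collapse = "\t"), con, sep = "\n",
             useBytes = TRUE)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(labs[i], body[i, ]), collapse = "\t"), con, sep = "\n",
               useBytes = TRUE)
  invisible(path)
}

#' Read a labeled square matrix from TSV
#'
#' @param path input file.
#' @param symmetric check symmetry (within `tol`) and fail if violated.
#' @param binary require all entries in `{0, 1}` and return a logical matrix.
#' @param tol symmetry tolerance.
#' @export
read_matrix <- function(path, symmetric = TRUE, binary = FALSE, tol = 1e-8) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  df <- read.delim(path, check.names = FALSE, row.names = 1,
                   fileEncoding = "UTF-8")
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("format error: matrix is not square: ", path)
  if (!is.numeric(m)) stop("parse error: non-numeric cell in ", path)
  colnames(m) <- colnames(df)
  if (!identical(rownames(m), colnames(m)))
    m <- m[, rownames(m), drop = FALSE]
  if (symmetric && max(abs(m - t(m))) > tol)
    stop("format error: matrix is not symmetric: ", path)
  if (binary) {
    if (!all(m %in% c(0, 1)))
      stop("format error: binary matrix contains values outside {0,1}: ", path)
    m <- m == 1
  }
  m
}

#' Write a cohort panel as per-subject TSVs plus a manifest
#'
#' Each subject's matrix is written with time points as rows and nodes as
#' columns under a header of node labels; the manifest lists subject ids,
#' relative paths and the TR.
#'
#' @param panel a `bold_panel`.
#' @param dir output directory (created if missing).
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "bold_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- dimnames(panel$data)[[2]]
  paths <- character(length(panel$subject_ids))
  for (s in seq_along(panel$subject_ids)) {
    ts <- t(panel_ts(panel, s))        # time x nodes
    paths[s] <- paste0(panel$subject_ids[s], ".tsv")
    con <- file(file.path(dir, paths[s]), open = "wb")
    writeLines(paste(nodes, collapse = "\t"), con, useBytes = TRUE)
    for (t_ in seq_len(nrow(ts)))
      writeLines(paste(.fmt(ts[t_, ]), collapse = "\t"), con, useBytes = TRUE)
    close(con)
  }
  manifest <- data.frame(subject = panel$subject_ids, path = paths,
                         TR_s = panel$TR_s)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(file.path(dir, "manifest.tsv"))
}

#' Read a cohort panel from a manifest
#'
#' Columns are realigned by node label to the first subject's ordering, so
#' files with permuted columns load consistently.
#'
#' @param manifest path to a `manifest.tsv` written by [write_panel()].
#' @return a `bold_panel`.
#' @export
read_panel <- function(manifest) {
  if (!file.exists(manifest)) stop("format error: no such manifest: ", manifest)
  man <- read.delim(manifest, stringsAsFactors = FALSE)
  dir <- dirname(manifest)
  mats <- list()
  nodes <- NULL
  for (r in seq_len(nrow(man))) {
    p <- file.path(dir, man$path[r])
    if (!file.exists(p))
      stop("format error: missing subject file: ", p)
    df <- read.delim(p, check.names = FALSE, fileEncoding = "UTF-8")
    m <- as.matrix(df)
    if (!is.numeric(m))
      stop("parse error: non-numeric cell in ", p)
    if (is.null(nodes)) {
      nodes <- colnames(m)
    } else {
      if (!setequal(colnames(m), nodes))
        stop("format error: inconsistent node headers in subject ",
             man$subject[r])
      m <- m[, nodes, drop = FALSE]
    }
    mats[[r]] <- m
  }
  n_tp <- unique(vapply(mats, nrow, integer(1)))
  if (length(n_tp) != 1)
    stop("format error: subjects have different numbers of time points")
  data <- array(NA_real_, dim = c(nrow(man), length(nodes), n_tp),
                dimnames = list(man$subject, nodes, NULL))
  for (r in seq_len(nrow(man))) data[r, , ] <- t(mats[[r]])
  structure(list(data = data, TR_s = man$TR_s[1], subject_ids = man$subject,
                 lags = NULL, cfg = NULL),
            class = "bold_panel")
}

#' Write/read a flat key-value configuration file
#'
#' @param config named list of scalar values.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  keys <- names(config)
  vals <- vapply(config, function(v)
    if (is.numeric(v)) paste(.fmt(v), collapse = ",")
    else paste(as.character(v), collapse = ","), character(1))
  writeLines(paste0(keys, " = ", vals), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("format error: no such config: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("format error: malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- strsplit(val, ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}
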