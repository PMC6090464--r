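# Plain-text I/O for connectivity matrices and sweep tables.

#' Construct a ConnectivityMatrix
#'
#' Validates a dense square weight matrix: entries must lie in \[-1, 1\]
#' (tolerance 1e-9, tiny overshoot is clamped), asymmetry beyond 1e-9 is
#' rejected (smaller asymmetry is averaged away), and a nonzero diagonal is
#' zeroed with a warning since self-correlations carry no information here.
#'
#' @param weights square numeric matrix of signed correlation weights.
#' @param subjectId single label for the subject.
#' @return a validated [ConnectivityMatrix-class].
#' @examples
#' w <- matrix(c(0, .5, .2, .5, 0, -.3, .2, -.3, 0), 3, 3)
#' ConnectivityMatrix(w, "demo")
#' @export
ConnectivityMatrix <- function(weights, subjectId = "subject") {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("'weights' must be a numeric matrix")
  if (nrow(weights) != ncol(weights))
    stop(sprintf("matrix is not square: %d rows by %d columns",
                 nrow(weights), ncol(weights)))
  if (nrow(weights) < 2)
    stop("a connectivity matrix needs at least 2 regions")
  if (any(!is.finite(weights)))
    stop("matrix contains non-finite entries")
  over <- abs(weights) - 1
  if (any(over > 1e-9))
    stop(sprintf("%d entries fall outside [-1, 1] (worst overshoot %.3g)",
                 sum(over > 1e-9), max(over)))
  weights[] <- pmin(pmax(weights, -1), 1)
  asym <- max(abs(weights - t(weights)))
  if (asym > 1e-9)
    stop(sprintf("matrix is asymmetric (max |w_ij - w_ji| = %.3g)", asym))
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) {
    warning("nonzero diagonal entries set to 0 (self-connections are excluded)")
    diag(weights) <- 0
  }
  dimnames(weights) <- NULL
  new("ConnectivityMatrix", subjectId = as.character(subjectId)[1],
      weights = weights)
}

#' Read a connectivity matrix from a dense text file
#'
#' Accepts whitespace- or comma-delimited square numeric matrices, with or
#' without a header row of region labels. The delimiter is auto-detected
#' from the first line unless a hint is given; a header is detected by a
#' non-numeric first line.
#'
#' @param path file to read.
#' @param delimiter optional delimiter hint ("," or "" for whitespace).
#' @param subjectId optional label; defaults to the file name stem.
#' @return a validated [ConnectivityMatrix-class].
#' @export
readConnectivityMatrix <- function(path, delimiter = NULL, subjectId = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (!is.null(delimiter)) delimiter
         else if (grepl(",", first, fixed = TRUE)) "," else ""
  toks <- strsplit(trimws(first),
                   if (identical(sep, ",")) "," else "[[:space:]]+")[[1]]
  toks <- trimws(toks)
  hasHeader <- any(is.na(suppressWarnings(as.numeric(toks[toks != ""]))))
  df <- utils::read.table(path, header = FALSE, sep = sep,
                          skip = as.integer(hasHeader),
                          strip.white = TRUE, colClasses = "numeric")
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    stop(sprintf("non-square matrix in '%s': %d rows by %d columns",
                 basename(path), nrow(m), ncol(m)))
  if (is.null(subjectId))
    subjectId <- sub("\\.[^.]*$", "", basename(path))
  ConnectivityMatrix(m, subjectId = subjectId)
}

#' Write a connectivity matrix as dense delimited text
#'
#' Writes at full double precision (17 significant digits) so that a
#' read-back reproduces the matrix entrywise to 1e-12 or better.
#'
#' @param matrix a [ConnectivityMatrix-class].
#' @param path destination file.
#' @return the path, invisibly.
#' @export
writeConnectivityMatrix <- function(matrix, path) {
  stopifnot(is(matrix, "ConnectivityMatrix"))
  w <- matrix@weights
  txt <- apply(w, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop(sprintf("cannot write '%s': %s",
                                                   path, conditionMessage(e))))
  on.exit(close(con))
  writeLines(txt, con)
  invisible(path)
}

sweepTableColumns <- c("subject_id", "n", "p", "w_t", "m", "lcc_fraction",
                       "clustering", "delta_clustering",
                       "ks_boundary_power", "ks_truncated_power_law")

#' Write a sweep-result table as CSV
#'
#' One delimited row per (subject, n, p) cell with a fixed header in a
#' stable column order: subject_id, n, p, w_t, m, lcc_fraction, clustering,
#' delta_clustering, ks_boundary_power, ks_truncated_power_law.
#' Accepts a data frame, a list of identically named records, or a
#' [SweepResult-class] (whose ensemble rows are appended with subject_id
#' `"__ensemble__"`).
#'
#' @param rows the records to serialize.
#' @param path destination CSV file.
#' @return the path, invisibly.
#' @export
writeSweepTable <- function(rows, path) {
  if (is(rows, "SweepResult")) {
    ens <- rows@ensembleTable
    if (nrow(ens)) ens <- cbind(subject_id = "__ensemble__", ens)
    rows <- rbind(rows@subjectTable,
                  ens[, names(rows@subjectTable), drop = FALSE])
  }
  if (is.list(rows) && !is.data.frame(rows)) {
    if (length(rows) == 0) {
      rows <- as.data.frame(setNames(rep(list(numeric(0)),
                                         length(sweepTableColumns)),
                                     sweepTableColumns))
    } else {
      nms <- lapply(rows, function(r) sort(names(r)))
      if (!all(vapply(nms, identical, logical(1), nms[[1]])))
        stop("schema error: records carry differing fields")
      rows <- do.call(rbind, lapply(rows, function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
    }
  }
  if (!is.data.frame(rows)) stop("'rows' must be records or a data frame")
  required <- sweepTableColumns[1:7]
  missing <- setdiff(required, names(rows))
  if (length(missing))
    stop(sprintf("schema error: missing fields %s",
                 paste(missing, collapse = ", ")))
  unknown <- setdiff(names(rows), sweepTableColumns)
  if (length(unknown))
    stop(sprintf("schema error: unknown fields %s",
                 paste(unknown, collapse = ", ")))
  for (col in setdiff(sweepTableColumns, names(rows)))
    rows[[col]] <- rep(NA_real_, nrow(rows))
  rows <- rows[, sweepTableColumns]
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
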