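#' Read a tab-delimited expression table
#'
#' Reads a features-by-samples expression matrix in the tab-delimited
#' series-matrix layout: first row sample identifiers, first column feature
#' identifiers, numeric body.  Quoted identifiers are unquoted.  Gzipped
#' files are read transparently.  Class labels are attached either from a
#' two-column sample-to-label file (see [readSampleLabels()]) or from a
#' label vector.
#'
#' @param path path to a plain or gzipped TSV file.
#' @param labels per-sample class labels (\code{"case"}/\code{"control"}),
#'   either a named character vector or the path of a two-column TSV
#'   (sample_id, label).
#' @param naAction passed to [ExpressionMatrix()].
#' @return an [ExpressionMatrix-class].
#' @export
readExpressionTable <- function(path, labels, naAction = "drop") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("expression table needs a header and a body")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- unquote_ids(fields[[1]])
  # header may or may not carry a stub for the feature-id column
  body_width <- length(fields[[2]])
  sample_ids <- if (length(header) == body_width) header[-1] else header
  nsamp <- length(sample_ids)
  widths <- lengths(fields[-1])
  if (any(widths != body_width))
    stop("ragged rows: row(s) ",
         paste(which(widths != body_width) + 1L, collapse = ", "),
         " have a different number of fields than the first data row")
  if (body_width != nsamp + 1L)
    stop("header declares ", nsamp, " samples but rows have ",
         body_width - 1L, " value fields")
  feature_ids <- unquote_ids(vapply(fields[-1], `[[`, "", 1L))
  if (anyDuplicated(feature_ids))
    stop("duplicate feature identifiers: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  cells <- unlist(lapply(fields[-1], `[`, -1L), use.names = FALSE)
  vals <- suppressWarnings(as.numeric(cells))
  na_in <- cells %in% c("NA", "", "NaN", "null")
  bad <- which(is.na(vals) & !na_in)
  if (length(bad)) {
    b <- bad[1]
    stop(sprintf("non-numeric value '%s' at row %d, column %d",
                 cells[b], (b - 1L) %/% nsamp + 1L, (b - 1L) %% nsamp + 1L))
  }
  m <- matrix(vals, nrow = length(feature_ids), ncol = nsamp, byrow = TRUE,
              dimnames = list(feature_ids, sample_ids))
  if (is.character(labels) && length(labels) == 1 && file.exists(labels))
    labels <- readSampleLabels(labels)
  ExpressionMatrix(m, labels, naAction = naAction)
}

unquote_ids <- function(x) gsub('^"|"$', "", trimws(x))

#' Read a two-column sample-label table
#'
#' @param path TSV with columns sample_id and label (header optional; a
#'   header row is detected when its second field is not a valid label).
#' @return named character vector of labels.
#' @export
readSampleLabels <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(tab) < 2) stop("label file must have two columns")
  if (!tab[1, 2] %in% c("case", "control")) tab <- tab[-1, , drop = FALSE]
  stats::setNames(unquote_ids(tab[[2]]), unquote_ids(tab[[1]]))
}

#' Write an expression table
#'
#' Writes the matrix in the same layout [readExpressionTable()] consumes,
#' so that a write/read round trip preserves values, ordering, and (via the
#' companion label file) class labels exactly.
#'
#' @param m an [ExpressionMatrix-class].
#' @param path output TSV path (".gz" suffix writes gzipped).
#' @param labelPath optional path for the two-column label file.
#' @return \code{path}, invisibly.
#' @export
writeExpressionTable <- function(m, path, labelPath = NULL) {
  x <- exprsValues(m)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(x)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rownames(x)[i],
            formatC(x[i, ], format = "g", digits = 17)), collapse = "\t"),
    character(1))
  writeLines(body, con)
  if (!is.null(labelPath)) {
    lab <- classLabels(m)
    utils::write.table(data.frame(sample_id = names(lab), label = lab),
                       labelPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Undo a log2 transform
#'
#' Replaces every expression value x by 2^x, reconverting log2-scale
#' profiles to their raw scale before normalization (needed for platforms
#' distributed on the log scale).  Identifiers and labels are unchanged.
#'
#' @param m an [ExpressionMatrix-class].
#' @return an [ExpressionMatrix-class] on the raw scale.
#' @export
unlog2 <- function(m) {
  x <- exprsValues(m)
  out <- 2^x
  if (any(!is.finite(out)))
    stop("unlog2 overflow: values above ", .Machine$double.max.exp - 1,
         " cannot be exponentiated")
  SummarizedExperiment::assay(m, "exprs") <- out
  methods::validObject(m)
  m
}

#' Standardize each sample profile
#'
#' Centers and scales every sample (column) across features so that for
#' each sample j the feature-wise mean is 0 and the feature-wise mean
#' square is 1: (1/N) sum_i x_ij = 0 and (1/N) sum_i x_ij^2 = 1.  The
#' scaling uses the population (1/N) standard deviation — the sample
#' (1/(N-1)) variant would break the unit mean-square identity.  The
#' operation is idempotent.
#'
#' @param m an [ExpressionMatrix-class].
#' @return the standardized [ExpressionMatrix-class].
#' @export
normalizeSamples <- function(m) {
  x <- exprsValues(m)
  mu <- colMeans(x)
  x <- sweep(x, 2L, mu, "-")
  s <- sqrt(colMeans(x^2))
  zero <- s == 0 | !is.finite(s)
  if (any(zero))
    stop("zero variance (constant profile) in sample(s): ",
         paste(colnames(x)[zero], collapse = ", "))
  x <- sweep(x, 2L, s, "/")
  SummarizedExperiment::assay(m, "exprs") <- x
  m
}
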