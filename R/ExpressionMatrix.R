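#' Construct a two-class expression matrix
#'
#' Builds an [ExpressionMatrix-class] from a numeric features-by-samples
#' matrix and per-sample class labels.  Rows containing missing values are
#' dropped with a message (keeping the gram matrix well defined); feature
#' and sample identifiers must be unique.
#'
#' @param values numeric matrix, features in rows, samples in columns, with
#'   dimnames giving feature and sample identifiers.
#' @param labels character vector of per-sample classes, \code{"case"} or
#'   \code{"control"}, either in column order or named by sample identifier.
#' @param naAction how to handle features with missing values:
#'   \code{"drop"} (default) removes them, \code{"error"} aborts.
#' @return an \code{ExpressionMatrix}.
#' @examples
#' x <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- ExpressionMatrix(x, c("case", "case", "control", "control"))
#' nFeatures(em)
#' @export
ExpressionMatrix <- function(values, labels, naAction = c("drop", "error")) {
  naAction <- match.arg(naAction)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry feature and sample identifiers as dimnames")
  if (!is.null(names(labels))) {
    missing <- setdiff(colnames(values), names(labels))
    if (length(missing))
      stop("no class label for sample(s): ", paste(missing, collapse = ", "))
    labels <- labels[colnames(values)]
  }
  if (length(labels) != ncol(values))
    stop("need one class label per sample")
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("case", "control"))
  if (length(bad))
    stop("labels must be 'case' or 'control', got: ",
         paste(bad, collapse = ", "))
  if (anyNA(values)) {
    if (naAction == "error") stop("'values' contains missing entries")
    drop <- apply(values, 1L, anyNA)
    message("dropping ", sum(drop), " feature(s) with missing values")
    values <- values[!drop, , drop = FALSE]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(condition = labels,
                                   row.names = colnames(values)))
  methods::new("ExpressionMatrix", se)
}

#' @rdname ExpressionMatrix-class
#' @export
setMethod("classLabels", "ExpressionMatrix", function(x)
  stats::setNames(as.character(SummarizedExperiment::colData(x)$condition),
                  colnames(x)))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("nFeatures", "ExpressionMatrix", function(x) nrow(x))

#' Expression values of an ExpressionMatrix
#'
#' Convenience accessor for the \code{"exprs"} assay.
#'
#' @param x an [ExpressionMatrix-class].
#' @return numeric matrix, features x samples.
#' @export
exprsValues <- function(x) SummarizedExperiment::assay(x, "exprs")

setMethod("show", "ExpressionMatrix", function(object) {
  lab <- classLabels(object)
  cat("ExpressionMatrix:", nrow(object), "features x", ncol(object),
      "samples (", sum(lab == "case"), "case /", sum(lab == "control"),
      "control )\n")
  methods::callNextMethod()
})

setMethod("show", "PCADecomposition", function(object) {
  cat("PCADecomposition with", length(object@eigenvalues),
      "components over", nrow(object@scores), "features and",
      nrow(object@loadings), "samples\n")
  ev <- utils::head(object@eigenvalues, 5)
  cat("  leading eigenvalues:", paste(signif(ev, 4), collapse = ", "),
      if (length(object@eigenvalues) > 5) "..." else "", "\n")
})

setMethod("show", "PCSelection", function(object) {
  cat("PCSelection: |Omega| =", length(object@omega), "of",
      length(object@pvalues), "components at alpha =", object@alpha, "\n")
  if (length(object@omega))
    cat("  Omega:", paste(object@omega, collapse = ", "), "\n")
})

setMethod("show", "FeatureOutlierResult", function(object) {
  cat("FeatureOutlierResult:", sum(object@selected), "of",
      length(object@selected), "features selected (adjusted p <",
      object@threshold, ", df =", object@nOmega, ")\n")
})

setMethod("show", "DiscriminationResult", function(object) {
  cat("DiscriminationResult (L =", object@L, ")\n")
  print(object@confusion)
  cat("Fisher p =", format(object@pValue, digits = 3),
      ", odds ratio =", format(object@oddsRatio, digits = 3), "\n")
})

setMethod("show", "QValueResult", function(object) {
  cat("QValueResult:", sum(object@significant), "of",
      length(object@qvalues), "features with q <", object@threshold,
      "(pi0 =", signif(object@pi0, 3), ")\n")
})

setMethod("show", "TargetMap", function(object) {
  cat("TargetMap:", length(object@familyToGenes), "families,",
      length(unique(unlist(object@familyToGenes))), "distinct targets,",
      length(object@mirnaToFamily), "mature-name mappings",
      if (length(object@species)) paste0("(taxon ", object@species, ")"),
      "\n")
})

# accessor methods for the result classes

#' @rdname PCADecomposition-class
#' @export
setMethod("pcScores", "PCADecomposition", function(x) x@scores)

#' @rdname PCADecomposition-class
#' @export
setMethod("pcLoadings", "PCADecomposition", function(x) x@loadings)

#' @rdname PCADecomposition-class
#' @export
setMethod("eigenValues", "PCADecomposition", function(x) x@eigenvalues)

#' @rdname PCADecomposition-class
#' @export
setMethod("scoreSd", "PCADecomposition", function(x) x@scoreSd)

#' @rdname PCSelection-class
#' @export
setMethod("omega", "PCSelection", function(x) x@omega)

#' @rdname FeatureOutlierResult-class
#' @export
setMethod("rawP", "FeatureOutlierResult", function(x) x@rawP)

#' @rdname FeatureOutlierResult-class
#' @export
setMethod("adjustedP", "FeatureOutlierResult", function(x) x@adjustedP)

#' @rdname FeatureOutlierResult-class
#' @export
setMethod("selectedFeatures", "FeatureOutlierResult", function(x)
  names(x@selected)[x@selected])

#' @rdname DiscriminationResult-class
#' @export
setMethod("confusionMatrix", "DiscriminationResult", function(x) x@confusion)

#' @rdname DiscriminationResult-class
#' @export
setMethod("oddsRatio", "DiscriminationResult", function(x) x@oddsRatio)

#' @rdname QValueResult-class
#' @export
setMethod("qValues", "QValueResult", function(x) x@qvalues)

#' @rdname QValueResult-class
#' @export
setMethod("pi0", "QValueResult", function(x) x@pi0)
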