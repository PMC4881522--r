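#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Two-class expression matrix
#'
#' An \code{ExpressionMatrix} holds a features-by-samples expression matrix
#' (mRNA probes or miRNAs) together with a two-class sample annotation
#' (\code{"case"} = tumor, \code{"control"} = normal tissue).  It extends
#' \link[SummarizedExperiment]{SummarizedExperiment}: the expression values
#' live in the \code{"exprs"} assay and the class labels in the
#' \code{condition} column of \code{colData}.
#'
#' Rows are features and columns are samples throughout the package, matching
#' the series-matrix layout of public expression repositories.
#'
#' @slot .. inherited from \code{SummarizedExperiment}.
#' @seealso [ExpressionMatrix()] for construction,
#'   [normalizeSamples()] for the per-sample standardization that the
#'   principal-component embedding expects.
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    x <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(x)) msg <- c(msg, "'exprs' must be numeric")
    if (anyNA(x)) msg <- c(msg, "'exprs' contains missing values")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "feature identifiers must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers must be present and unique")
  if (!"condition" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'condition' column")
  else {
    cond <- SummarizedExperiment::colData(object)$condition
    if (!all(cond %in% c("case", "control")))
      msg <- c(msg, "condition labels must be 'case' or 'control'")
  }
  if (length(msg)) msg else TRUE
})

#' Principal-component decomposition of a feature embedding
#'
#' Result of [pcaDecompose()].  Unlike standard PCA, which embeds samples,
#' the decomposition here embeds the features: the PC score vector
#' \eqn{u_k} for component \eqn{k} is a unit-norm eigenvector of the gram
#' matrix \eqn{XX^T} (features by features, never materialized), and the PC
#' loading of sample \eqn{j} on component \eqn{k} is \eqn{v_{kj} = (X^T
#' u_k)_j}, an eigenvector of \eqn{X^T X} scaled by the singular value.
#'
#' @slot scores numeric matrix, features x components; column \eqn{k} is
#'   \eqn{u_k}, unit Euclidean norm.
#' @slot loadings numeric matrix, samples x components; column \eqn{k} is
#'   \eqn{v_k = X^T u_k}.
#' @slot eigenvalues nonnegative, strictly ordered descending; eigenvalues of
#'   \eqn{XX^T} (squared singular values of \eqn{X}).
#' @slot scoreSd per-component standard deviation of the scores across
#'   features, used to standardize scores in the chi-squared outlier
#'   statistic.
#' @export
setClass("PCADecomposition",
  representation(scores = "matrix", loadings = "matrix",
                 eigenvalues = "numeric", scoreSd = "numeric"))

setValidity("PCADecomposition", function(object) {
  msg <- character()
  k <- ncol(object@scores)
  if (ncol(object@loadings) != k || length(object@eigenvalues) != k ||
      length(object@scoreSd) != k)
    msg <- c(msg, "component counts of slots disagree")
  if (k > 0) {
    if (any(diff(object@eigenvalues) > 1e-8 * object@eigenvalues[1]))
      msg <- c(msg, "eigenvalues must be in descending order")
    if (any(object@eigenvalues < 0)) msg <- c(msg, "eigenvalues must be >= 0")
    nrm <- sqrt(colSums(object@scores^2))
    if (any(abs(nrm - 1) > 1e-8))
      msg <- c(msg, "score vectors must have unit norm")
    if (any(object@scoreSd <= 0)) msg <- c(msg, "scoreSd must be positive")
    if (k > min(dim(object@scores)[1], dim(object@loadings)[1]))
      msg <- c(msg, "more components than min(n_features, n_samples)")
  }
  if (length(msg)) msg else TRUE
})

#' Discriminative principal components
#'
#' The set \eqn{\Omega} of components whose loadings differ between cases
#' and controls (two-sample t test on the loadings, unadjusted p below
#' \code{alpha}).  \eqn{\Omega} may be empty; downstream operations that
#' need at least one component raise an error in that case.
#'
#' @slot omega integer component indices in \eqn{\Omega}.
#' @slot pvalues per-component t-test p-value on the loadings.
#' @slot alpha the per-component threshold (default 0.05).
#' @export
setClass("PCSelection",
  representation(omega = "integer", pvalues = "numeric", alpha = "numeric"))

setValidity("PCSelection", function(object) {
  msg <- character()
  expect <- unname(which(object@pvalues < object@alpha))
  if (!identical(unname(sort(object@omega)), as.integer(expect)))
    msg <- c(msg, "omega must equal {k : pvalues[k] < alpha}")
  if (length(object@alpha) != 1 || object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be a single value in (0,1)")
  if (length(msg)) msg else TRUE
})

#' Per-feature outlier test result
#'
#' Chi-squared upper-tail probabilities of the summed squared standardized
#' PC scores over \eqn{\Omega}, with Benjamini-Hochberg adjustment and the
#' selection flag at the adjusted threshold (default 0.01).
#'
#' @slot statistic per-feature value of
#'   \eqn{T_i = \sum_{k \in \Omega} (u_{ki}/\sigma_k)^2}.
#' @slot rawP upper-tail chi-squared probability with \eqn{|\Omega|} degrees
#'   of freedom at \eqn{T_i}.
#' @slot adjustedP Benjamini-Hochberg step-up adjusted probabilities.
#' @slot selected logical flag, \code{adjustedP < threshold}.
#' @slot threshold adjusted-p cutoff.
#' @slot nOmega number of components in \eqn{\Omega} (degrees of freedom).
#' @export
setClass("FeatureOutlierResult",
  representation(statistic = "numeric", rawP = "numeric",
                 adjustedP = "numeric", selected = "logical",
                 threshold = "numeric", nOmega = "integer"))

setValidity("FeatureOutlierResult", function(object) {
  msg <- character()
  n <- length(object@rawP)
  if (length(object@adjustedP) != n || length(object@selected) != n ||
      length(object@statistic) != n)
    msg <- c(msg, "per-feature slots differ in length")
  if (any(object@rawP < 0 | object@rawP > 1, na.rm = TRUE) ||
      any(object@adjustedP < 0 | object@adjustedP > 1, na.rm = TRUE))
    msg <- c(msg, "probabilities must lie in [0,1]")
  if (any(object@adjustedP + 1e-12 < object@rawP))
    msg <- c(msg, "adjusted p must be >= raw p")
  if (!identical(unname(object@selected),
                 unname(object@adjustedP < object@threshold)))
    msg <- c(msg, "selected flag must equal adjustedP < threshold")
  if (length(msg)) msg else TRUE
})

#' Conserved miRNA target map
#'
#' Mapping from miRNA families to their conserved target gene symbols, as
#' distributed in conserved-family target tables, plus an optional mature
#' miRNA name to family map.  All lookup keys are normalized with
#' [normalizeMirnaName()] (species prefix stripped, case folded, arm suffix
#' kept), so lookups are case-insensitive.
#'
#' @slot familyToGenes named list; each element the character set of target
#'   gene symbols of one family (nonempty).
#' @slot mirnaToFamily named character; mature miRNA key to family key.
#' @slot species the taxon identifier the table was filtered to.
#' @export
setClass("TargetMap",
  representation(familyToGenes = "list", mirnaToFamily = "character",
                 species = "character"))

setValidity("TargetMap", function(object) {
  msg <- character()
  if (length(object@familyToGenes)) {
    if (is.null(names(object@familyToGenes)))
      msg <- c(msg, "familyToGenes must be named")
    if (any(lengths(object@familyToGenes) == 0))
      msg <- c(msg, "every mapped gene set must be nonempty")
  }
  if (length(msg)) msg else TRUE
})

#' Leave-one-out discrimination result
#'
#' Confusion matrix of leave-one-out cross-validated linear discriminant
#' analysis on the first \code{L} recomputed PC loadings, with Fisher's
#' exact test p-value and conditional-MLE odds ratio.  Rows are predicted
#' classes, columns are true classes; the odds ratio may be \code{Inf} when
#' an off-diagonal cell is zero.
#'
#' @slot L number of leading PC loadings used.
#' @slot confusion 2x2 integer matrix, rows predicted, columns true.
#' @slot pValue two-sided Fisher exact p-value.
#' @slot oddsRatio conditional maximum-likelihood odds ratio.
#' @export
setClass("DiscriminationResult",
  representation(L = "integer", confusion = "matrix",
                 pValue = "numeric", oddsRatio = "numeric"))

setValidity("DiscriminationResult", function(object) {
  msg <- character()
  if (!all(dim(object@confusion) == c(2, 2)))
    msg <- c(msg, "confusion must be 2x2")
  if (any(object@confusion < 0) ||
      any(object@confusion != round(object@confusion)))
    msg <- c(msg, "confusion entries must be nonnegative integers")
  if (!is.na(object@pValue) &&
      (object@pValue <= 0 || object@pValue > 1))
    msg <- c(msg, "pValue must lie in (0,1]")
  if (!is.na(object@oddsRatio) && object@oddsRatio < 0)
    msg <- c(msg, "oddsRatio must be >= 0 (possibly Inf)")
  if (length(msg)) msg else TRUE
})

#' Storey q-value result
#'
#' @slot qvalues per-feature q-values in [0,1], order-isotonic with the
#'   input p-values.
#' @slot pi0 estimated proportion of null features in (0,1].
#' @slot threshold significance cutoff (default 0.01).
#' @slot significant logical flag, \code{qvalues < threshold}.
#' @export
setClass("QValueResult",
  representation(qvalues = "numeric", pi0 = "numeric",
                 threshold = "numeric", significant = "logical"))

setValidity("QValueResult", function(object) {
  msg <- character()
  if (any(object@qvalues < 0 | object@qvalues > 1))
    msg <- c(msg, "q-values must lie in [0,1]")
  if (object@pi0 <= 0 || object@pi0 > 1)
    msg <- c(msg, "pi0 must lie in (0,1]")
  if (!identical(unname(object@significant),
                 unname(object@qvalues < object@threshold)))
    msg <- c(msg, "significant flag must equal qvalues < threshold")
  if (length(msg)) msg else TRUE
})

#' Synthetic-data configuration
#'
#' Study conditions for [generateSynthetic()]: paired mRNA/miRNA
#' case-control matrices with Gaussian noise, planted class-shifted outlier
#' features, and a planted reciprocal miRNA-to-target structure embedded in
#' a conserved target map with decoy targets.  The mRNA and miRNA cohorts
#' may have different sample counts (unmatched cohorts).
#'
#' @slot nMrna,nMirna feature counts of the two matrices.
#' @slot nCase,nControl sample counts of the mRNA matrix.
#' @slot nCaseMirna,nControlMirna sample counts of the miRNA matrix.
#' @slot nOutlierMrna,nOutlierMirna planted outlier feature counts.
#' @slot effect class shift of planted features, in pre-normalization units.
#' @slot noiseSd Gaussian noise standard deviation.
#' @slot targetsPerMirna target out-degree per miRNA family.
#' @slot reciprocalFraction fraction of a planted miRNA's targets drawn from
#'   planted mRNAs of the opposite regulation direction (the true pairs).
#' @slot seed RNG seed; a fixed seed gives byte-identical output.
#' @export
setClass("SyntheticConfig",
  representation(nMrna = "integer", nMirna = "integer",
                 nCase = "integer", nControl = "integer",
                 nCaseMirna = "integer", nControlMirna = "integer",
                 nOutlierMrna = "integer", nOutlierMirna = "integer",
                 effect = "numeric", noiseSd = "numeric",
                 targetsPerMirna = "integer",
                 reciprocalFraction = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nOutlierMrna > object@nMrna ||
      object@nOutlierMirna > object@nMirna)
    msg <- c(msg, "planted counts must not exceed feature counts")
  if (object@effect < 0) msg <- c(msg, "effect must be >= 0")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be > 0")
  if (object@reciprocalFraction < 0 || object@reciprocalFraction > 1)
    msg <- c(msg, "reciprocalFraction must lie in [0,1]")
  if (object@reciprocalFraction > 0 && object@targetsPerMirna > 0 &&
      (object@nOutlierMrna == 0 || object@nOutlierMirna == 0))
    msg <- c(msg,
      "reciprocal pairs requested but no planted features to form them")
  if (min(object@nCase, object@nControl, object@nCaseMirna,
          object@nControlMirna) < 2)
    msg <- c(msg, "each class needs at least 2 samples")
  if (length(msg)) msg else TRUE
})
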