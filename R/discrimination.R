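#' Recompute PC loadings on a restricted feature set
#'
#' Restricts the matrix to the given features, re-standardizes each sample
#' over that restricted set, and re-runs the feature-side decomposition;
#' the returned loadings are the per-sample embedding used for
#' discrimination, with components ordered by eigenvalue.
#'
#' @param m an [ExpressionMatrix-class] (any scale; columns are
#'   re-standardized internally over the restricted set).
#' @param selected character vector of >= 2 feature identifiers.
#' @return numeric matrix, samples x components, with the eigenvalues as
#'   attribute \code{"eigenvalues"}.
#' @export
recomputeLoadings <- function(m, selected) {
  if (length(selected) < 2)
    stop("need at least 2 selected features to recompute loadings")
  missing <- setdiff(selected, rownames(m))
  if (length(missing))
    stop("selected features absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  sub <- normalizeSamples(m[selected, ])
  d <- pcaDecompose(sub)
  structure(pcLoadings(d), eigenvalues = eigenValues(d))
}

#' Leave-one-out cross-validated linear discriminant analysis
#'
#' Classifies every sample with a linear discriminant (pooled within-class
#' covariance, equal class priors 1/2, 1/2) fitted on the first \code{L}
#' embedding coordinates of all remaining samples, and tallies the 2x2
#' confusion matrix (rows predicted, columns true; class order "case",
#' "control").  The embedding itself is computed once on all samples —
#' only the classifier is refit per fold, mirroring the validation design
#' this statistic reproduces; the resulting mild information leakage
#' through the shared embedding is a documented property, not a bug.
#' Internally this is \code{MASS::lda(..., CV = TRUE, prior = c(1/2,
#' 1/2))}.
#'
#' @param embedding samples x components matrix from
#'   [recomputeLoadings()] (or any per-sample embedding).
#' @param labels per-sample classes, \code{"case"}/\code{"control"}, in
#'   embedding row order.
#' @param L number of leading coordinates to use.
#' @return 2x2 integer confusion matrix.
#' @export
ldaLoocv <- function(embedding, labels, L) {
  embedding <- as.matrix(embedding)
  if (L < 1 || L > ncol(embedding))
    stop("L must lie in 1..", ncol(embedding))
  labels <- factor(as.character(labels), levels = c("case", "control"))
  if (any(table(labels) < 2))
    stop("both classes need at least 2 samples")
  emb <- embedding[, seq_len(L), drop = FALSE]
  fit <- tryCatch(
    MASS::lda(emb, grouping = labels, prior = c(0.5, 0.5), CV = TRUE),
    error = function(e)
      stop("LDA failed (", conditionMessage(e),
           "); the pooled covariance may be singular - try a smaller L",
           call. = FALSE))
  conf <- table(Predicted = fit$class, True = labels)
  matrix(as.integer(conf), 2, 2, dimnames = dimnames(conf))
}

#' Fisher's exact test on a confusion matrix
#'
#' Two-sided exact test on a 2x2 table: the p-value sums the
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table
#' (minimum-likelihood rule), and the odds ratio is the conditional
#' maximum-likelihood estimate under the noncentral hypergeometric model
#' (infinite when an off-diagonal cell is zero with nonzero diagonal, zero
#' in the symmetric case).  This is the convention of
#' \code{stats::fisher.test}, which performs the computation.
#'
#' @param confusion 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @return list with elements \code{p.value} and \code{odds.ratio}.
#' @examples
#' fisherExactTest(matrix(c(28, 2, 2, 28), 2))  # OR ~ 154.7
#' @export
fisherExactTest <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == c(2, 2)))
    stop("confusion must be a 2x2 matrix")
  if (any(confusion < 0) || any(confusion != round(confusion)))
    stop("confusion entries must be nonnegative integers")
  if (any(rowSums(confusion) == 0) || any(colSums(confusion) == 0))
    stop("both margins must be positive")
  f <- stats::fisher.test(confusion)
  list(p.value = f$p.value, odds.ratio = unname(f$estimate))
}

#' Discriminate patients from controls on selected features
#'
#' Convenience wrapper: [recomputeLoadings()] on the selected features,
#' [ldaLoocv()] with the first \code{L} loadings, and [fisherExactTest()]
#' on the resulting confusion matrix.
#'
#' @param m an [ExpressionMatrix-class].
#' @param selected selected feature identifiers.
#' @param L number of leading PC loadings for the discriminant; when
#'   \code{NULL}, L is scanned over \code{1..Lmax} and the value
#'   maximizing leave-one-out accuracy is kept.
#' @param Lmax upper bound of the scan (default 10, capped at the
#'   embedding dimension).
#' @return a [DiscriminationResult-class].
#' @export
discriminate <- function(m, selected, L = NULL, Lmax = 10) {
  emb <- recomputeLoadings(m, selected)
  labels <- classLabels(m)
  if (is.null(L)) {
    cand <- seq_len(min(Lmax, ncol(emb)))
    acc <- vapply(cand, function(l) {
      conf <- tryCatch(ldaLoocv(emb, labels, l),
                       error = function(e) NULL)
      if (is.null(conf)) -Inf else sum(diag(conf)) / sum(conf)
    }, numeric(1))
    L <- cand[which.max(acc)]
  }
  conf <- ldaLoocv(emb, labels, L)
  ft <- fisherExactTest(conf)
  methods::new("DiscriminationResult", L = as.integer(L), confusion = conf,
               pValue = ft$p.value, oddsRatio = ft$odds.ratio)
}
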