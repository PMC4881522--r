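#' Feature-side principal-component decomposition
#'
#' Embeds the features (genes or miRNAs) rather than the samples: the PC
#' score vectors \eqn{u_k} are unit-norm eigenvectors of the gram matrix
#' \eqn{XX^T} and the PC loadings \eqn{v_k = X^T u_k} are the corresponding
#' per-sample coordinates.  The decomposition is computed through a thin
#' SVD of \eqn{X} (features x samples), never by materializing the
#' features-by-features gram matrix, so it scales to tens of thousands of
#' probes.  Components with eigenvalue below \code{1e-10} times the leading
#' eigenvalue are dropped.  Each score vector's sign is fixed so that its
#' largest-magnitude entry is positive, making the output deterministic;
#' all downstream statistics are even in \eqn{u_k}, so the convention
#' carries no meaning.
#'
#' @param m an [ExpressionMatrix-class], standardized with
#'   [normalizeSamples()] (column means over features must be 0).
#' @return a [PCADecomposition-class].
#' @examples
#' em <- ExpressionMatrix(
#'   matrix(rnorm(200), 50, 4,
#'          dimnames = list(paste0("g", 1:50), paste0("s", 1:4))),
#'   rep(c("case", "control"), each = 2))
#' d <- pcaDecompose(normalizeSamples(em))
#' eigenValues(d)
#' @export
pcaDecompose <- function(m) {
  x <- exprsValues(m)
  if (ncol(x) < 2) stop("need at least 2 samples to decompose")
  if (max(abs(colMeans(x))) > 1e-6)
    warning("sample profiles are not centered; the embedding assumes ",
            "normalizeSamples() has been applied")
  sv <- svd(x)
  ev <- sv$d^2
  keep <- which(ev >= 1e-10 * ev[1] & sv$d > 0)
  scores <- sv$u[, keep, drop = FALSE]
  loadings <- sweep(sv$v[, keep, drop = FALSE], 2L, sv$d[keep], "*")
  # deterministic sign: largest-|score| entry positive
  for (k in seq_along(keep)) {
    i <- which.max(abs(scores[, k]))
    if (scores[i, k] < 0) {
      scores[, k] <- -scores[, k]
      loadings[, k] <- -loadings[, k]
    }
  }
  cn <- paste0("PC", seq_along(keep))
  dimnames(scores) <- list(rownames(x), cn)
  dimnames(loadings) <- list(colnames(x), cn)
  methods::new("PCADecomposition", scores = scores, loadings = loadings,
               eigenvalues = ev[keep],
               scoreSd = apply(scores, 2L, stats::sd))
}

#' Select discriminative components by a t test on loadings
#'
#' For every retained component, compares the PC loadings of case samples
#' against control samples with a two-sample unequal-variance (Welch)
#' t test; the set \eqn{\Omega} collects the components with unadjusted
#' p below \code{alpha}.  No multiplicity correction is applied at this
#' stage: \eqn{\Omega} feeds the chi-squared outlier statistic, whose own
#' feature-level probabilities are BH-corrected downstream.
#'
#' @param d a [PCADecomposition-class].
#' @param labels per-sample class labels, \code{"case"}/\code{"control"},
#'   in the loading row order (both classes need >= 2 samples).
#' @param alpha per-component threshold, default 0.05.
#' @param var.equal use the pooled-variance t test instead of Welch.
#' @return a [PCSelection-class]; \eqn{\Omega} may be empty.
#' @export
selectPCs <- function(d, labels, alpha = 0.05, var.equal = FALSE) {
  v <- pcLoadings(d)
  labels <- as.character(labels)
  if (length(labels) != nrow(v))
    stop("need one label per sample")
  case <- labels == "case"
  if (sum(case) < 2 || sum(!case) < 2)
    stop("both classes need at least 2 samples")
  p <- vapply(seq_len(ncol(v)), function(k)
    stats::t.test(v[case, k], v[!case, k], var.equal = var.equal)$p.value,
    numeric(1))
  names(p) <- colnames(v)
  methods::new("PCSelection", omega = which(p < alpha), pvalues = p,
               alpha = alpha)
}

#' Chi-squared outlier probability per feature
#'
#' The outlier statistic of feature i sums its squared standardized scores
#' over the discriminative components,
#' \eqn{T_i = \sum_{k \in \Omega} (u_{ki}/\sigma_k)^2}, where
#' \eqn{\sigma_k} is the standard deviation of the k-th scores across
#' features.  Assuming Gaussian PC scores, \eqn{T_i} is chi-squared with
#' \eqn{|\Omega|} degrees of freedom under the null, and
#' \eqn{P_i = P[\chi^2_{|\Omega|} > T_i]} is the upper-tail probability.
#'
#' @param d a [PCADecomposition-class].
#' @param s a [PCSelection-class] with nonempty \eqn{\Omega}.
#' @return named vector of raw upper-tail probabilities, one per feature.
#' @export
chi2OutlierPvalues <- function(d, s) {
  k <- omega(s)
  if (length(k) == 0)
    stop("no discriminative components: Omega is empty")
  u <- pcScores(d)[, k, drop = FALSE]
  z <- sweep(u, 2L, scoreSd(d)[k], "/")
  stat <- rowSums(z^2)
  stats::pchisq(stat, df = length(k), lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Literal step-up definition: sort the m p-values ascending, scale the
#' r-th by m/r, enforce monotonicity by a cumulative minimum from the
#' largest down, cap at 1, and restore the input order.
#'
#' @param p vector of p-values in [0,1].
#' @return adjusted values in the input order.
#' @export
bhAdjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0,1] with no missing values")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- pmin(rev(cummin(rev(scaled))), 1)
  out <- numeric(m)
  out[o] <- adj
  names(out) <- names(p)
  out
}

#' PCA-based unsupervised feature extraction
#'
#' Composition of the selection pipeline: decompose the standardized
#' matrix, pick the components whose loadings separate cases from controls
#' ([selectPCs()]), convert each feature's standardized scores over
#' \eqn{\Omega} to a chi-squared upper-tail probability
#' ([chi2OutlierPvalues()]), BH-adjust, and flag features with adjusted
#' probability below \code{threshold}.  The class labels enter only through
#' the component selection — the embedding itself is unsupervised — which
#' is why the number of selected features scales with the number of
#' features rather than the number of samples.
#'
#' @param m a normalized [ExpressionMatrix-class].
#' @param alphaPC component-selection threshold (default 0.05).
#' @param threshold adjusted-probability cutoff for outlier features
#'   (default 0.01).
#' @param var.equal passed to [selectPCs()].
#' @return a [FeatureOutlierResult-class].
#' @export
selectFeatures <- function(m, alphaPC = 0.05, threshold = 0.01,
                           var.equal = FALSE) {
  d <- pcaDecompose(m)
  s <- selectPCs(d, classLabels(m), alpha = alphaPC, var.equal = var.equal)
  raw <- chi2OutlierPvalues(d, s)
  k <- omega(s)
  u <- pcScores(d)[, k, drop = FALSE]
  stat <- rowSums(sweep(u, 2L, scoreSd(d)[k], "/")^2)
  adj <- bhAdjust(raw)
  methods::new("FeatureOutlierResult",
               statistic = stat, rawP = raw, adjustedP = adj,
               selected = adj < threshold, threshold = threshold,
               nOmega = length(k))
}

#' Write feature and component reports
#'
#' @param res a [FeatureOutlierResult-class].
#' @param path output TSV (feature_id, statistic, raw_p, adjusted_p,
#'   selected).
#' @return \code{path}, invisibly.
#' @export
writeFeatureReport <- function(res, path) {
  utils::write.table(
    data.frame(feature_id = names(res@rawP), statistic = res@statistic,
               raw_p = res@rawP, adjusted_p = res@adjustedP,
               selected = res@selected),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureReport
#' @param d,s the decomposition and component selection of the same run.
#' @export
writeComponentReport <- function(d, s, path) {
  utils::write.table(
    data.frame(k = seq_along(eigenValues(d)), eigenvalue = eigenValues(d),
               t_p = s@pvalues, in_omega = seq_along(eigenValues(d)) %in%
                 omega(s)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
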