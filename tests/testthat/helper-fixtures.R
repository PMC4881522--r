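# fixtures are built in code; all randomness is seeded at the call site

rand_em <- function(n_feat, n_case, n_ctrl, seed = 1, sd = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n_feat * (n_case + n_ctrl), sd = sd), n_feat,
              dimnames = list(sprintf("f%04d", seq_len(n_feat)),
                              sprintf("s%03d", seq_len(n_case + n_ctrl))))
  ExpressionMatrix(x, rep(c("case", "control"), c(n_case, n_ctrl)))
}

# fabricate a valid PCADecomposition from arbitrary score/loading matrices
fake_decomp <- function(scores, loadings) {
  scores <- sweep(scores, 2L, sqrt(colSums(scores^2)), "/")
  k <- ncol(scores)
  new("PCADecomposition", scores = scores, loadings = loadings,
      eigenvalues = rev(seq_len(k)) + 0, scoreSd = apply(scores, 2, sd))
}

pair_key <- function(d) paste(d$mirna_id, d$gene_id)

jaccard <- function(a, b) {
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}
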