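# Independent brute-force oracles, kept deliberately naive and separate from
# the implementation paths they check.

# dense eigendecomposition of the gram matrix XX^T (features x features)
dense_gram_oracle <- function(x) {
  e <- eigen(x %*% t(x), symmetric = TRUE)
  keep <- e$values >= 1e-10 * e$values[1]
  list(values = e$values[keep], vectors = e$vectors[, keep, drop = FALSE])
}

# literal BH step-up: find largest r with p_(r) <= q*r/m for each q on a
# grid is awkward; instead compute adjusted values from the definition
# applied literally, one rank at a time
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (r in seq_len(m)) {
    adj[o[r]] <- min(1, min(p[o[r:m]] * m / (r:m)))
  }
  adj
}

# two-sided Fisher p by full enumeration of tables with the observed margins
fisher_p_oracle <- function(tab) {
  a <- tab[1, 1]
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2]); r1 <- sum(tab[1, ])
  support <- max(0, r1 - c2):min(r1, c1)
  pr <- dhyper(support, c1, c2, r1)
  obs <- dhyper(a, c1, c2, r1)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# conditional-MLE odds ratio by direct maximization of the noncentral
# hypergeometric likelihood on log(psi)
fisher_or_oracle <- function(tab) {
  a <- tab[1, 1]
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2]); r1 <- sum(tab[1, ])
  support <- max(0, r1 - c2):min(r1, c1)
  loglik <- function(logpsi) {
    w <- dhyper(support, c1, c2, r1, log = TRUE) + support * logpsi
    w[support == a] - log(sum(exp(w - max(w)))) - max(w)
  }
  opt <- optimize(loglik, c(-25, 25), maximum = TRUE, tol = 1e-10)
  exp(opt$maximum)
}

# explicit leave-one-out refit of an equal-prior pooled-covariance linear
# discriminant
lda_loocv_oracle <- function(emb, labels) {
  labels <- factor(labels, levels = c("case", "control"))
  pred <- character(length(labels))
  for (i in seq_along(labels)) {
    tr <- emb[-i, , drop = FALSE]
    gl <- labels[-i]
    m1 <- colMeans(tr[gl == "case", , drop = FALSE])
    m0 <- colMeans(tr[gl == "control", , drop = FALSE])
    n1 <- sum(gl == "case"); n0 <- sum(gl == "control")
    s1 <- stats::cov(tr[gl == "case", , drop = FALSE])
    s0 <- stats::cov(tr[gl == "control", , drop = FALSE])
    sp <- ((n1 - 1) * s1 + (n0 - 1) * s0) / (n1 + n0 - 2)
    x <- emb[i, ]
    score <- function(mk) sum(x * solve(sp, mk)) - 0.5 * sum(mk * solve(sp, mk))
    pred[i] <- if (score(m1) >= score(m0)) "case" else "control"
  }
  tab <- table(Predicted = factor(pred, levels = levels(labels)),
               True = labels)
  matrix(as.integer(tab), 2, 2, dimnames = dimnames(tab))
}
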