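# Independent oracles used to validate the package's computations.
# These are written from the textbook definitions and deliberately share no
# code path with the implementation.

# Welch two-sample t from the textbook formula, scalar arithmetic only.
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  ma <- sum(a) / na; mb <- sum(b) / nb
  va <- sum((a - ma)^2) / (na - 1)
  vb <- sum((b - mb)^2) / (nb - 1)
  t <- (ma - mb) / sqrt(va / na + vb / nb)
  df <- (va / na + vb / nb)^2 /
    ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# Upper-tail hypergeometric probability P[X >= a] by exhaustive summation of
# the pmf written with log-binomial coefficients.
oracle_fisher_tail <- function(a, b, c, d) {
  N <- a + b + c + d   # population
  K <- a + c           # successes in population
  n <- a + b           # draws
  ks <- a:min(K, n)
  if (!length(ks) || a > min(K, n)) return(0)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# Per-cell least squares through the explicit normal equations, one cell at
# a time (assumes full-rank Xc).
oracle_project <- function(X, Xc_query, Xc_ref) {
  out <- matrix(0, nrow(Xc_ref), ncol(X))
  G <- solve(t(Xc_query) %*% Xc_query)
  for (j in seq_len(ncol(X))) {
    beta <- G %*% (t(Xc_query) %*% X[, j])
    out[, j] <- Xc_ref %*% beta
  }
  out
}

# Naive LISI: explicit per-cell loop, plain bisection on the Gaussian
# precision until the weight entropy hits log(perplexity), then the inverse
# Simpson index of label proportions.
oracle_lisi <- function(embedding, labels, perplexity, tol = 1e-5,
                        max_iter = 50) {
  labels <- as.factor(labels)
  n <- nrow(embedding)
  k <- floor(3 * perplexity)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(embedding) - embedding[i, ])^2)
    ord <- order(d2)
    ord <- ord[ord != i][1:k]
    di <- d2[ord]
    if (all(di == 0)) {
      w <- rep(1 / k, k)
    } else {
      lo <- -Inf; hi <- Inf; beta <- 1
      for (it in 1:max_iter) {
        u <- exp(-beta * di)
        su <- sum(u)
        H <- if (su == 0) 0 else log(su) + beta * sum(di * u) / su
        if (abs(H - log(perplexity)) < tol) break
        if (H > log(perplexity)) {
          lo <- beta
          beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
        } else {
          hi <- beta
          beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
        }
      }
      u <- exp(-beta * di)
      w <- u / sum(u)
    }
    q <- tapply(w, labels[ord], sum)
    q[is.na(q)] <- 0
    scores[i] <- 1 / sum(q^2)
  }
  scores
}

# Small random expression matrix with dimnames, for unit tests.
random_expr <- function(p, n, batch_id = "b", seed = 1) {
  set.seed(seed)
  m <- matrix(abs(rnorm(p * n)), p, n,
              dimnames = list(sprintf("g%d", 1:p), sprintf("c%d", 1:n)))
  expression_matrix(m, batch_id = batch_id)
}

# Majority planted type of each cluster in an assignment.
cluster_majority_type <- function(assign, truth) {
  vapply(seq_len(assign$K), function(k) {
    tt <- truth$cell_type_of[names(assign$labels)[assign$labels == k]]
    names(which.max(table(tt)))
  }, character(1))
}
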