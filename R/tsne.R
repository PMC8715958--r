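# Compact exact t-SNE (no approximation tree; adequate for the few hundred
# feature vectors produced by the cross-validation harness).
#
# Pairwise Gaussian affinities with per-point precision found by bisection
# to match the target perplexity, symmetrised; the 2-D map minimises the
# Kullback-Leibler divergence to the Student-t neighbour distribution by
# momentum gradient descent with early exaggeration.

.tsne_affinities <- function(x, perplexity) {
  n <- nrow(x)
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  diag(d2) <- Inf
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- 0; hi <- Inf
    di <- d2[i, ]
    for (iter in 1:60) {
      p <- exp(-di * beta)
      s <- sum(p)
      if (s <= 0) { beta <- beta / 2; hi <- beta * 2; next }
      p <- p / s
      h <- -sum(p[p > 0] * log(p[p > 0]))  # Shannon entropy = log perplexity
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- (beta + lo) / 2 }
    }
    P[i, ] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

.tsne <- function(x, seed = 1L, perplexity = 30, n_iter = 400,
                  eta = 100, exaggeration = 4, exag_iter = 100) {
  n <- nrow(x)
  perplexity <- min(perplexity, max(2, floor((n - 1) / 3)))
  P <- .tsne_affinities(x, perplexity)
  with_seed(seed, {
    y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    inc <- matrix(0, n, 2)
    for (it in seq_len(n_iter)) {
      Pi <- if (it <= exag_iter) P * exaggeration else P
      sq <- rowSums(y^2)
      num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      W <- (Pi - Q) * num
      grad <- 4 * (diag(rowSums(W)) - W) %*% y
      momentum <- if (it <= 250) 0.5 else 0.8
      inc <- momentum * inc - eta * grad
      y <- y + inc
      y <- scale(y, center = TRUE, scale = FALSE)
    }
    y
  })
}
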