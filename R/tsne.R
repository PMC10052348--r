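# Exact (O(n^2)) t-SNE from a precomputed distance matrix. Used only for
# 2D reporting layouts of screening hits; clustering never depends on it.

# Per-point conditional probabilities at a target perplexity via binary
# search on the Gaussian precision.
tsne_input_probs <- function(d2, perplexity, tol = 1e-5, max_iter = 50L) {
  n <- nrow(d2)
  target <- log(perplexity)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- d2[i, -i]
    for (it in seq_len(max_iter)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { h <- 0; pr <- rep(0, length(di)) }
      else {
        pr <- w / sw
        h <- -sum(ifelse(pr > 0, pr * log(pr), 0))
      }
      if (abs(h - target) < tol) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    p[i, -i] <- pr
  }
  p <- (p + t(p)) / (2 * n)
  pmax(p, 1e-12)
}

#' 2D t-SNE layout of screening hits
#'
#' Stochastic neighbor embedding of fingerprint Jaccard distances into two
#' dimensions, reproducible under a fixed seed. Intended for reporting and
#' plotting only; cluster assignments are computed in fingerprint space.
#'
#' @param fingerprints 0/1 matrix (rows = compounds), or a precomputed
#'   distance matrix via `distances`.
#' @param distances optional distance matrix overriding `fingerprints`.
#' @param perplexity neighborhood size parameter; requires at least
#'   `3 * perplexity` points.
#' @param n_iter gradient-descent iterations.
#' @param seed layout seed.
#' @return numeric matrix (n x 2) of coordinates.
#' @export
embed_2d <- function(fingerprints = NULL, distances = NULL, perplexity = 30,
                     n_iter = 400L, seed = 12345L) {
  if (is.null(distances)) {
    stopifnot(is.matrix(fingerprints))
    distances <- 1 - tanimoto_matrix(fingerprints, fingerprints)
  }
  n <- nrow(distances)
  if (n < 3 * perplexity) {
    stop("need at least 3 * perplexity = ", ceiling(3 * perplexity),
         " points, got ", n)
  }
  p <- tsne_input_probs(distances^2, perplexity)
  with_seed(seed, {
    y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    gain <- matrix(1, n, 2)
    inc <- matrix(0, n, 2)
    eta <- 200
    for (it in seq_len(n_iter)) {
      exagg <- if (it <= 100L) 12 else 1
      mom <- if (it <= 250L) 0.5 else 0.8
      sum_y <- rowSums(y^2)
      num <- 1 / (1 + outer(sum_y, sum_y, "+") - 2 * tcrossprod(y))
      diag(num) <- 0
      q <- pmax(num / sum(num), 1e-12)
      l <- (exagg * p - q) * num
      grad <- 4 * (diag(rowSums(l)) - l) %*% y
      gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
      gain[gain < 0.01] <- 0.01
      inc <- mom * inc - eta * gain * grad
      y <- y + inc
      y <- sweep(y, 2, colMeans(y))
    }
    colnames(y) <- c("tsne1", "tsne2")
    y
  })
}
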