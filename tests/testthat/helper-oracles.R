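# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the implementation they check.

brute_gip <- function(A, axis, lambda_prime = 1) {
  A <- as.matrix(A)
  profiles <- if (axis == "microbe") lapply(seq_len(ncol(A)), function(j) A[, j])
              else lapply(seq_len(nrow(A)), function(i) A[i, ])
  lambda <- lambda_prime / mean(vapply(profiles, function(p) sum(p^2), 0))
  n <- length(profiles)
  K <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      K[i, j] <- exp(-lambda * sum((profiles[[i]] - profiles[[j]])^2))
  K
}

brute_propagate <- function(G, H, W) {
  n <- length(G$degrees)
  out <- matrix(0, n, ncol(W))
  for (i in seq_len(n))
    for (q in seq_len(ncol(W)))
      for (j in seq_len(n))
        for (p in seq_len(ncol(H)))
          out[i, q] <- out[i, q] +
            G$adjacency[i, j] / sqrt(G$degrees[i] * G$degrees[j]) *
            H[j, p] * W[p, q]
  tanh(out)
}

brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos)
    for (n in neg)
      wins <- wins + (p > n) + 0.5 * (p == n)
  wins / (length(pos) * length(neg))
}

brute_bce <- function(scores, labels, eps = 1e-7) {
  p <- pmin(pmax(as.numeric(scores), eps), 1 - eps)
  y <- as.numeric(labels)
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

# a small config that trains in milliseconds, for contract tests where the
# quality of the fit is irrelevant
cheap_config <- function(epochs = 5, ...) {
  mdagcan_config(k = 6, epochs = epochs, lr = 5e-3,
                 dp_node = 0.1, dp_reg = 0.1, seed = 1, ...)
}

random_association <- function(nd, nm, seed, density = 0.3) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(nd * nm, 1, density), nd, nm)
    if (any(m == 1) && any(m == 0)) break
  }
  association_matrix(m)
}

# numerical gradient of the full encoder-decoder-loss for one parameter set
numeric_gradients <- function(G, A, params, cfg, h = 1e-5) {
  loss_fn <- function(p) {
    fwd <- mdagcan:::forward_pass(G, p, cfg, training = FALSE)
    focal_loss(fwd$scores, A, cfg$alpha, cfg$gamma)
  }
  out <- params
  for (nm in names(params)) {
    g <- params[[nm]] * 0
    for (i in seq_along(params[[nm]])) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
      g[i] <- (loss_fn(pp) - loss_fn(pm)) / (2 * h)
    }
    out[[nm]] <- g
  }
  out
}
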