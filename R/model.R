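#' Model and fusion hyperparameters
#'
#' Collects every tunable of the pipeline with validated ranges.  The
#' defaults are the grid-search optima of the method: `mu = 0.5` (weight of
#' GIP vs functional similarity in the fusion), `beta = 8` (penalty scaling
#' the similarity blocks of the heterogeneous adjacency), `k = 64`
#' (embedding width), `lr = 5e-5` (Adam learning rate), focal-loss weights
#' `alpha = 0.1` and `gamma = 2`, node dropout `dp_node = 0.5`, regular
#' dropout `dp_reg = 0.7`, and `epochs = 500` training iterations, with a
#' 2-layer graph-convolution stack refined by a single graph-attention
#' layer.
#'
#' @param mu fusion weight on GIP similarity, in \[0, 1\].
#' @param beta similarity-block penalty, > 0.
#' @param k embedding dimension, >= 1.
#' @param lr Adam learning rate, > 0.
#' @param alpha focal-loss class weight, in (0, 1\].
#' @param gamma focal-loss focusing exponent, >= 0.
#' @param dp_node node (whole-row) dropout rate, in \[0, 1).
#' @param dp_reg elementwise dropout rate, in \[0, 1).
#' @param epochs number of Adam steps, >= 1.
#' @param n_gcn_layers number of graph convolutional layers, >= 1.
#' @param n_gat_layers number of graph attention layers, >= 0.
#' @param lambda_prime original GIP bandwidth, > 0.
#' @param threshold classification threshold for the confusion-matrix
#'   metrics, in (0, 1).
#' @param seed integer RNG seed controlling initialization and dropout.
#' @return object of class `mdagcan_config` (a validated named list).
#' @export
mdagcan_config <- function(mu = 0.5, beta = 8, k = 64, lr = 5e-5,
                           alpha = 0.1, gamma = 2,
                           dp_node = 0.5, dp_reg = 0.7, epochs = 500,
                           n_gcn_layers = 2, n_gat_layers = 1,
                           lambda_prime = 1, threshold = 0.5, seed = 1L) {
  cfg <- list(mu = mu, beta = beta, k = as.integer(k), lr = lr,
              alpha = alpha, gamma = gamma,
              dp_node = dp_node, dp_reg = dp_reg,
              epochs = as.integer(epochs),
              n_gcn_layers = as.integer(n_gcn_layers),
              n_gat_layers = as.integer(n_gat_layers),
              lambda_prime = lambda_prime,
              threshold = threshold, seed = as.integer(seed))
  validate_mdagcan_config(cfg)
  structure(cfg, class = "mdagcan_config")
}

validate_mdagcan_config <- function(cfg) {
  chk <- function(ok, key, msg)
    if (!isTRUE(ok)) stop(sprintf("config key '%s' %s", key, msg), call. = FALSE)
  num1 <- function(key) {
    v <- cfg[[key]]
    chk(is.numeric(v) && length(v) == 1L && is.finite(v), key,
        "must be a finite number")
    v
  }
  chk(num1("mu") >= 0 && cfg$mu <= 1, "mu", "must lie in [0, 1]")
  chk(num1("beta") > 0, "beta", "must be > 0")
  chk(num1("k") >= 1, "k", "must be >= 1")
  chk(num1("lr") > 0, "lr", "must be > 0")
  chk(num1("alpha") > 0 && cfg$alpha <= 1, "alpha", "must lie in (0, 1]")
  chk(num1("gamma") >= 0, "gamma", "must be >= 0")
  chk(num1("dp_node") >= 0 && cfg$dp_node < 1, "dp_node", "must lie in [0, 1)")
  chk(num1("dp_reg") >= 0 && cfg$dp_reg < 1, "dp_reg", "must lie in [0, 1)")
  chk(num1("epochs") >= 1, "epochs", "must be >= 1")
  chk(num1("n_gcn_layers") >= 1, "n_gcn_layers", "must be >= 1")
  chk(num1("n_gat_layers") >= 0, "n_gat_layers", "must be >= 0")
  chk(num1("lambda_prime") > 0, "lambda_prime", "must be > 0")
  chk(num1("threshold") > 0 && cfg$threshold < 1, "threshold",
      "must lie in (0, 1)")
  num1("seed")
  invisible(cfg)
}

#' @export
print.mdagcan_config <- function(x, ...) {
  cat("mdagcan_config:\n")
  for (k in names(x)) cat(sprintf("  %-13s %s\n", k, format(x[[k]])))
  invisible(x)
}

# ---- parameter initialization -------------------------------------------

xavier <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# Trainable weights as a flat named list of arrays; the RNG state at call
# time determines the draw (callers seed it).
init_params <- function(n_nodes, config) {
  k <- config$k
  p <- list()
  dims_in <- c(n_nodes, rep(k, config$n_gcn_layers - 1L))
  for (l in seq_len(config$n_gcn_layers))
    p[[paste0("gcn_W", l)]] <- xavier(dims_in[l], k)
  for (l in seq_len_safe(config$n_gat_layers)) {
    p[[paste0("gat_W", l)]] <- xavier(k, k)
    p[[paste0("gat_a", l)]] <- as.numeric(xavier(2 * k, 1))
  }
  p$decoder_W <- xavier(k, k)
  p
}

seq_len_safe <- function(n) if (n < 1L) integer(0) else seq_len(n)

# ---- forward pass --------------------------------------------------------

# Dropout masks as multiplicative matrices (inverted dropout scaling).
dropout_mask <- function(nr, nc, dp_node, dp_reg) {
  m <- matrix(1, nr, nc)
  if (dp_node > 0) {
    keep <- stats::runif(nr) >= dp_node
    m <- m * (keep / (1 - dp_node))
  }
  if (dp_reg > 0) {
    keep <- matrix(stats::runif(nr * nc) >= dp_reg, nr, nc)
    m <- m * (keep / (1 - dp_reg))
  }
  m
}

#' Graph attention coefficients
#'
#' Scores every edge of the heterogeneous graph (plus self-loops) with
#' `e_ij = relu(a' [W h_i || W h_j])` and normalizes each node's scores
#' over its neighborhood with a softmax.  Rows sum to 1; entries outside
#' the neighborhood are exactly 0.
#'
#' @param H node feature matrix (`nd + nm` rows).
#' @param G a `hetero_graph` defining neighborhoods (`G_HN > 0` plus self).
#' @param W_gat shared projection matrix (`ncol(H) x k'`).
#' @param a_vec attention vector of length `2 k'`.
#' @return list with `att` (row-stochastic attention matrix), `e`
#'   (pre-softmax scores), and internals used by backpropagation.
#' @export
gat_coefficients <- function(H, G, W_gat, a_vec) {
  H <- as.matrix(H)
  n <- nrow(H)
  kp <- ncol(W_gat)
  if (length(a_vec) != 2 * kp) stop("attention vector length must be 2 * ncol(W_gat)")
  nb <- G$adjacency > 0
  diag(nb) <- TRUE
  HW <- H %*% W_gat
  u <- as.numeric(HW %*% a_vec[seq_len(kp)])
  v <- as.numeric(HW %*% a_vec[kp + seq_len(kp)])
  raw <- outer(u, rep(1, n)) + outer(rep(1, n), v)
  e <- pmax(raw, 0)
  esc <- ifelse(nb, e, -Inf)
  mx <- apply(esc, 1, max)           # neighborhoods are non-empty (self-loop)
  ex <- exp(esc - mx)
  ex[!nb] <- 0
  att <- ex / rowSums(ex)
  list(att = att, e = ifelse(nb, e, 0), raw = raw, nb = nb, HW = HW)
}

#' Attention-weighted neighbor aggregation
#'
#' @param H node feature matrix.
#' @param att row-stochastic attention matrix from [gat_coefficients()].
#' @return `att %*% H`: each node's new representation is the
#'   attention-weighted average of its neighbors' representations.
#' @export
gat_aggregate <- function(H, att) {
  if (ncol(att) != nrow(H)) stop("attention and feature dimensions disagree")
  att %*% as.matrix(H)
}

#' Bilinear decoder
#'
#' Reconstructs the association score matrix
#' `sigmoid(Z_d W' Z_m')` from the disease and microbe embedding blocks.
#'
#' @param Z_d disease embeddings (`nd x k`).
#' @param Z_m microbe embeddings (`nm x k`).
#' @param W_prime trainable `k x k` matrix.
#' @return `nd x nm` score matrix with entries strictly in (0, 1).
#' @export
bilinear_decode <- function(Z_d, Z_m, W_prime) {
  Z_d <- as.matrix(Z_d); Z_m <- as.matrix(Z_m); W_prime <- as.matrix(W_prime)
  if (ncol(Z_d) != nrow(W_prime) || ncol(Z_m) != ncol(W_prime))
    stop("decoder dimensions do not match embeddings")
  plogis(Z_d %*% W_prime %*% t(Z_m))
}

# Full encoder-decoder forward pass.  training = TRUE draws dropout masks
# from the current RNG stream and caches everything backward_pass needs.
forward_pass <- function(G, params, config, training = FALSE) {
  Ahat <- hetnet_norm_adjacency(G)
  n <- G$nd + G$nm
  H <- G$h0
  gcn_cache <- vector("list", config$n_gcn_layers)
  for (l in seq_len(config$n_gcn_layers)) {
    mask <- if (training)
      dropout_mask(n, ncol(H), config$dp_node, config$dp_reg)
    else NULL
    Hdrop <- if (is.null(mask)) H else H * mask
    W <- params[[paste0("gcn_W", l)]]
    AH <- Ahat %*% Hdrop
    Hout <- tanh(AH %*% W)
    gcn_cache[[l]] <- list(mask = mask, AH = AH, Hout = Hout)
    H <- Hout
  }
  gat_cache <- vector("list", config$n_gat_layers)
  for (l in seq_len_safe(config$n_gat_layers)) {
    W <- params[[paste0("gat_W", l)]]
    a <- params[[paste0("gat_a", l)]]
    co <- gat_coefficients(H, G, W, a)
    Z <- gat_aggregate(H, co$att)
    gat_cache[[l]] <- c(co, list(Hin = H, Z = Z))
    H <- Z
  }
  Zd <- H[seq_len(G$nd), , drop = FALSE]
  Zm <- H[G$nd + seq_len(G$nm), , drop = FALSE]
  M <- Zd %*% params$decoder_W %*% t(Zm)
  scores <- plogis(M)
  dimnames(scores) <- list(G$node_ids[seq_len(G$nd)],
                           G$node_ids[G$nd + seq_len(G$nm)])
  list(scores = scores, M = M, Zd = Zd, Zm = Zm,
       gcn_cache = gcn_cache, gat_cache = gat_cache, Ahat = Ahat)
}

# ---- focal loss ----------------------------------------------------------

FOCAL_EPS <- 1e-7

#' Focal loss on an association score matrix
#'
#' Sum over the sampled cells of the focal binary cross-entropy
#' `-alpha (1 - p)^gamma log p` on positives and
#' `-alpha p^gamma log(1 - p)` on negatives, with scores clamped to
#' `[1e-7, 1 - 1e-7]` before the logarithm.  With `gamma = 0`,
#' `alpha = 1` it reduces exactly to binary cross-entropy.
#'
#' @param scores score matrix in (0, 1).
#' @param A binary association matrix of matching shape (the labels).
#' @param alpha class weight applied to both branches.
#' @param gamma focusing exponent down-weighting easy samples.
#' @param samples optional logical matrix selecting the cells in
#'   `Omega+ \\/ Omega-`; by default every cell is used.
#' @return nonnegative scalar loss.
#' @export
focal_loss <- function(scores, A, alpha = 0.1, gamma = 2, samples = NULL) {
  p <- pmin(pmax(as.matrix(scores), FOCAL_EPS), 1 - FOCAL_EPS)
  A <- as.matrix(A)
  psi <- ifelse(A == 1,
                -alpha * (1 - p)^gamma * log(p),
                -alpha * p^gamma * log(1 - p))
  if (!is.null(samples)) psi <- psi[samples]
  sum(psi)
}

# d(loss)/d(logit M); the clamp zeroes the gradient where active.
focal_loss_grad_logit <- function(scores, A, alpha, gamma) {
  p_raw <- as.matrix(scores)
  p <- pmin(pmax(p_raw, FOCAL_EPS), 1 - FOCAL_EPS)
  A <- as.matrix(A)
  dpsi <- ifelse(A == 1,
                 alpha * gamma * (1 - p)^pmax(gamma - 1, 0) *
                   (if (gamma > 0) log(p) else 0) - alpha * (1 - p)^gamma / p,
                 -alpha * gamma * p^pmax(gamma - 1, 0) *
                   (if (gamma > 0) log(1 - p) else 0) + alpha * p^gamma / (1 - p))
  active <- (p_raw > FOCAL_EPS) & (p_raw < 1 - FOCAL_EPS)
  dpsi * p_raw * (1 - p_raw) * active
}

# ---- backward pass -------------------------------------------------------

backward_pass <- function(G, params, config, fwd, dM) {
  grads <- list()
  Zm <- fwd$Zm; Zd <- fwd$Zd
  Wp <- params$decoder_W
  grads$decoder_W <- crossprod(Zd, dM %*% Zm)
  dZd <- dM %*% Zm %*% t(Wp)
  dZm <- t(dM) %*% Zd %*% Wp
  dH <- rbind(dZd, dZm)
  for (l in rev(seq_len_safe(config$n_gat_layers))) {
    cc <- fwd$gat_cache[[l]]
    a <- params[[paste0("gat_a", l)]]
    kp <- length(a) / 2
    a1 <- a[seq_len(kp)]; a2 <- a[kp + seq_len(kp)]
    att <- cc$att; Hin <- cc$Hin
    datt <- dH %*% t(Hin)                  # dL/datt
    dHin <- crossprod(att, dH)             # aggregation path
    srow <- rowSums(att * datt)
    de <- att * (datt - srow)              # softmax backward (0 off-neighborhood)
    draw <- de * (cc$raw > 0 & cc$nb)      # relu backward
    du <- rowSums(draw)
    dv <- colSums(draw)
    dHW <- outer(du, a1) + outer(dv, a2)
    grads[[paste0("gat_a", l)]] <- c(as.numeric(crossprod(cc$HW, du)),
                                     as.numeric(crossprod(cc$HW, dv)))
    grads[[paste0("gat_W", l)]] <- crossprod(Hin, dHW)
    dHin <- dHin + dHW %*% t(params[[paste0("gat_W", l)]])
    dH <- dHin
  }
  for (l in rev(seq_len(config$n_gcn_layers))) {
    cc <- fwd$gcn_cache[[l]]
    W <- params[[paste0("gcn_W", l)]]
    dP <- dH * (1 - cc$Hout^2)
    grads[[paste0("gcn_W", l)]] <- crossprod(cc$AH, dP)
    dHdrop <- fwd$Ahat %*% (dP %*% t(W))   # Ahat is symmetric
    dH <- if (is.null(cc$mask)) dHdrop else dHdrop * cc$mask
  }
  grads
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# ---- training loop -------------------------------------------------------

# Trains the encoder-decoder on a heterogeneous graph built from a
# (possibly masked) association matrix.  Deterministic for a fixed seed:
# the seed drives Xavier initialization and the per-epoch dropout masks.
train_model <- function(G, A, config) {
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  n <- G$nd + G$nm
  params <- init_params(n, config)
  opt <- adam_init(params)
  Am <- as_plain_matrix(as.matrix(A))
  loss_trace <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    fwd <- forward_pass(G, params, config, training = TRUE)
    loss <- focal_loss(fwd$scores, Am, config$alpha, config$gamma)
    if (!is.finite(loss))
      stop(sprintf("non-finite training loss at epoch %d", ep))
    loss_trace[ep] <- loss
    dM <- focal_loss_grad_logit(fwd$scores, Am, config$alpha, config$gamma)
    grads <- backward_pass(G, params, config, fwd, dM)
    upd <- adam_step(params, grads, opt, config$lr)
    params <- upd$params
    opt <- upd$opt
  }
  fwd <- forward_pass(G, params, config, training = FALSE)
  list(params = params, loss_trace = loss_trace, scores = fwd$scores)
}

# Inference-only forward pass (dropout disabled); deterministic.
predict_scores <- function(params, G, config) {
  forward_pass(G, params, config, training = FALSE)$scores
}
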