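#' Degree-normalize a similarity block
#'
#' Symmetric degree normalization `S* = Ds^{-1/2} S Ds^{-1/2}` with
#' `Ds = diag(rowSums(S))`, which bounds the spectral radius of the block
#' by 1 before it enters the heterogeneous adjacency.  A divide-by-max
#' alternative is available via `method = "max"`.
#'
#' @param S a `similarity_matrix` (or symmetric nonnegative matrix) with
#'   strictly positive row sums.
#' @param method `"degree"` (default) or `"max"`.
#' @return normalized `similarity_matrix` (same kind attribute).
#' @export
normalize_block <- function(S, method = c("degree", "max")) {
  method <- match.arg(method)
  kind <- attr(S, "kind") %||% "integrated"
  ids <- rownames(S)
  M <- as_plain_matrix(as.matrix(S))
  if (any(M < 0)) stop("similarity block must be nonnegative")
  if (method == "degree") {
    d <- rowSums(M)
    if (any(d <= 0)) stop("zero row sum: cannot degree-normalize")
    inv <- 1 / sqrt(d)
    out <- M * outer(inv, inv)
  } else {
    mx <- max(M)
    if (mx <= 0) stop("all-zero similarity block")
    out <- M / mx
  }
  out <- (out + t(out)) / 2
  similarity_matrix(out, entity_ids = ids, kind = kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble the heterogeneous disease-microbe graph
#'
#' Builds the `(nd + nm) x (nd + nm)` block adjacency
#' `G_HN = [[beta * DS*, A], [A', beta * MS*]]` (diseases first, then
#' microbes), its degree vector, and the fixed initial feature matrix
#' `H0 = [[0, A], [A', 0]]`.
#'
#' @param DS_star normalized integrated disease similarity (`nd x nd`).
#' @param MS_star normalized integrated microbe similarity (`nm x nm`).
#' @param A the `nd x nm` [association_matrix()].
#' @param beta penalty factor scaling the similarity blocks (default 8).
#' @return object of class `hetero_graph` with elements `adjacency`,
#'   `degrees`, `h0`, `node_ids`, `nd`, `nm`.
#' @export
build_hetnet <- function(DS_star, MS_star, A, beta = 8) {
  if (beta <= 0) stop("beta must be positive")
  nd <- nrow(A); nm <- ncol(A)
  if (nrow(DS_star) != nd) stop("DS* dimension does not match diseases of A")
  if (nrow(MS_star) != nm) stop("MS* dimension does not match microbes of A")
  Am <- as_plain_matrix(as.matrix(A))
  DSm <- as_plain_matrix(as.matrix(DS_star))
  MSm <- as_plain_matrix(as.matrix(MS_star))
  G <- rbind(cbind(beta * DSm, Am),
             cbind(t(Am), beta * MSm))
  H0 <- rbind(cbind(matrix(0, nd, nd), Am),
              cbind(t(Am), matrix(0, nm, nm)))
  node_ids <- c(rownames(A), colnames(A))
  dimnames(G) <- list(node_ids, node_ids)
  dimnames(H0) <- list(node_ids, node_ids)
  deg <- rowSums(G)
  if (any(deg <= 0))
    stop("zero-degree node in heterogeneous graph; similarity diagonals should prevent this")
  structure(list(adjacency = G, degrees = deg, h0 = H0,
                 node_ids = node_ids, nd = nd, nm = nm),
            class = "hetero_graph")
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat(sprintf("hetero_graph: %d diseases + %d microbes = %d nodes\n",
              x$nd, x$nm, x$nd + x$nm))
  invisible(x)
}

# D^{-1/2} G D^{-1/2}, cached on first use
hetnet_norm_adjacency <- function(G) {
  inv <- 1 / sqrt(G$degrees)
  G$adjacency * outer(inv, inv)
}

#' One symmetric-normalized graph convolution step
#'
#' Computes `tanh(D^{-1/2} G_HN D^{-1/2} H W)` -- the propagation rule of a
#' graph convolutional layer under symmetric degree normalization.
#'
#' @param G a `hetero_graph`.
#' @param H feature matrix with `nd + nm` rows.
#' @param W weight matrix with `ncol(H)` rows.
#' @return matrix of the same row count, entries in (-1, 1).
#' @export
sym_norm_propagate <- function(G, H, W) {
  H <- as.matrix(H); W <- as.matrix(W)
  if (nrow(H) != G$nd + G$nm) stop("H row count does not match graph")
  if (ncol(H) != nrow(W)) stop("W inner dimension does not match H")
  tanh(hetnet_norm_adjacency(G) %*% H %*% W)
}
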