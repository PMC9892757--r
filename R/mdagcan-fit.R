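#' Build the heterogeneous graph for a (possibly masked) association matrix
#'
#' Runs the full similarity pipeline: GIP kernels on rows and columns of
#' `A`, conditional fusion with the functional similarities (pure GIP where
#' functional evidence is absent), symmetric degree normalization of each
#' fused block, and block assembly of the heterogeneous adjacency with the
#' `beta` penalty.
#'
#' @param A an [association_matrix()].
#' @param config an [mdagcan_config()].
#' @param disease_functional,microbe_functional optional `similarity_matrix`
#'   objects (kind `"functional"`) over the diseases / microbes of `A`;
#'   `NULL` means no functional evidence, i.e. pure GIP similarity.
#' @return a `hetero_graph`.
#' @export
mdagcan_graph <- function(A, config = mdagcan_config(),
                          disease_functional = NULL,
                          microbe_functional = NULL) {
  KD <- gip_similarity(A, "disease", config$lambda_prime)
  KM <- gip_similarity(A, "microbe", config$lambda_prime)
  DS <- if (is.null(disease_functional)) KD
        else integrate_similarity(KD, disease_functional, config$mu)
  MS <- if (is.null(microbe_functional)) KM
        else integrate_similarity(KM, microbe_functional, config$mu)
  build_hetnet(normalize_block(DS), normalize_block(MS), A, config$beta)
}

#' Fit the graph convolutional attention model
#'
#' The single entry point of the package: builds the heterogeneous graph
#' from the association matrix (and optional functional similarities),
#' trains the GCN + GAT encoder and bilinear decoder by minimising the
#' focal loss with Adam, and returns the fitted model with the
#' reconstructed disease-by-microbe score matrix.
#'
#' @param A an [association_matrix()] (or a binary labelled matrix).
#' @param config an [mdagcan_config()].
#' @param disease_functional,microbe_functional optional functional
#'   `similarity_matrix` objects; see [mdagcan_graph()].
#' @return an object of class `mdagcan` with components `scores` (the
#'   fitted score matrix, entries in (0, 1)), `A`, `graph`, `params`
#'   (trained weights), `loss_trace`, and `config`.
#' @examples
#' sim <- generate_associations(synthetic_spec(nd = 8, nm = 12, seed = 3))
#' fit <- mdagcan(sim$A, mdagcan_config(k = 8, epochs = 25, seed = 3))
#' fit
#' head(rank_candidates(fit, rownames(sim$A)[1], top_k = 3))
#' @export
mdagcan <- function(A, config = mdagcan_config(),
                    disease_functional = NULL,
                    microbe_functional = NULL) {
  if (!is_association_matrix(A)) A <- association_matrix(A)
  validate_mdagcan_config(config)
  G <- mdagcan_graph(A, config, disease_functional, microbe_functional)
  tr <- train_model(G, A, config)
  structure(list(scores = tr$scores, A = A, graph = G,
                 params = tr$params, loss_trace = tr$loss_trace,
                 config = config,
                 call = match.call()),
            class = "mdagcan")
}

#' @export
print.mdagcan <- function(x, ...) {
  cat("Graph convolutional attention model for microbe-disease association\n")
  cat(sprintf("  %d diseases x %d microbes, %d known associations\n",
              nrow(x$A), ncol(x$A), sum(x$A)))
  cat(sprintf("  k = %d, %d GCN + %d GAT layer(s), %d epochs\n",
              x$config$k, x$config$n_gcn_layers, x$config$n_gat_layers,
              x$config$epochs))
  cat(sprintf("  focal loss: %.5f (epoch 1) -> %.5f (final)\n",
              x$loss_trace[1], x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' @export
summary.mdagcan <- function(object, ...) {
  sc <- object$scores
  pos <- sc[object$A == 1]
  neg <- sc[object$A == 0]
  out <- list(
    dims = dim(object$A),
    n_pos = length(pos),
    train_auc = if (length(pos) && length(neg)) auc(c(pos, neg),
      c(rep(1, length(pos)), rep(0, length(neg)))) else NA_real_,
    mean_pos = mean(pos), mean_neg = mean(neg),
    final_loss = object$loss_trace[length(object$loss_trace)],
    config = object$config)
  class(out) <- "summary.mdagcan"
  out
}

#' @export
print.summary.mdagcan <- function(x, ...) {
  cat(sprintf("mdagcan fit: %d diseases x %d microbes, %d positives\n",
              x$dims[1], x$dims[2], x$n_pos))
  cat(sprintf("  training-set AUC        %.4f\n", x$train_auc))
  cat(sprintf("  mean score, positives   %.4f\n", x$mean_pos))
  cat(sprintf("  mean score, negatives   %.4f\n", x$mean_neg))
  cat(sprintf("  final focal loss        %.5f\n", x$final_loss))
  invisible(x)
}

#' @export
coef.mdagcan <- function(object, ...) object$params

#' Predict association scores from a fitted model
#'
#' Runs the deterministic (dropout-free) forward pass.  With the default
#' `newgraph = NULL` this reproduces the fitted score matrix.
#'
#' @param object a fitted `mdagcan` model.
#' @param newgraph optional `hetero_graph` of compatible dimensions to
#'   score instead of the training graph.
#' @param ... unused.
#' @return disease-by-microbe score matrix with entries in (0, 1).
#' @export
predict.mdagcan <- function(object, newgraph = NULL, ...) {
  G <- if (is.null(newgraph)) object$graph else newgraph
  predict_scores(object$params, G, object$config)
}

#' @export
fitted.mdagcan <- function(object, ...) object$scores

#' @export
residuals.mdagcan <- function(object, ...) {
  as_plain_matrix(as.matrix(object$A)) - object$scores
}

#' Simulate association matrices from a fitted model
#'
#' Draws binary matrices with independent Bernoulli cells at the fitted
#' association probabilities.
#'
#' @param object a fitted `mdagcan` model.
#' @param nsim number of matrices.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of [association_matrix()] draws.
#' @export
simulate.mdagcan <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$scores
  lapply(seq_len(nsim), function(i) {
    association_matrix(matrix(stats::rbinom(length(p), 1, p), nrow(p), ncol(p)),
                       rownames(p), colnames(p))
  })
}

#' Plot a fitted model
#'
#' Left panel: focal-loss trace over training epochs.  Right panel: fitted
#' score distributions for known-positive and unknown cells.
#'
#' @param x a fitted `mdagcan` model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mdagcan <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$loss_trace, type = "l", xlab = "epoch",
                 ylab = "focal loss", main = "training loss", ...)
  pos <- x$scores[x$A == 1]
  neg <- x$scores[x$A == 0]
  dp <- stats::density(pos)
  dn <- stats::density(neg)
  graphics::plot(dn, col = "grey40", main = "fitted scores",
                 xlab = "score", ylim = range(dp$y, dn$y))
  graphics::lines(dp, col = "firebrick")
  graphics::legend("topright", legend = c("positives", "unknowns"),
                   col = c("firebrick", "grey40"), lty = 1, bty = "n")
  invisible(x)
}

#' Save / load a fitted model
#'
#' The full model state (trained weights, configuration incl. seed, score
#' matrix and training graph) is stored as a single RDS archive.
#'
#' @param object a fitted `mdagcan` model.
#' @param path file path.
#' @return `path` (save) or the restored `mdagcan` object (load).
#' @export
save_mdagcan <- function(object, path) {
  stopifnot(inherits(object, "mdagcan"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_mdagcan
#' @export
load_mdagcan <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "mdagcan")) stop("not a saved mdagcan model")
  obj
}
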