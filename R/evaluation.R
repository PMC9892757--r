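#' Rank-based AUC
#'
#' Area under the ROC curve computed from midranks (the Mann-Whitney
#' statistic): the probability that a random positive outscores a random
#' negative, counting ties as half.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector of the same length, both classes present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Confusion-matrix metrics at a fixed threshold
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector.
#' @param threshold scores `>= threshold` are called positive (default 0.5).
#' @return named vector with `f1`, `accuracy`, `sensitivity`,
#'   `specificity`; F1 is 0 when there are no positive predictions.
#' @export
threshold_metrics <- function(scores, labels, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  labels <- as.numeric(labels)
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  c(f1 = f1, accuracy = (tp + tn) / length(labels),
    sensitivity = sens, specificity = spec)
}

#' Zero a set of cells in an association matrix
#'
#' Used by every cross-validation protocol to mask held-out positives
#' before similarities and the model are recomputed from the training
#' matrix alone.
#'
#' @param A an [association_matrix()].
#' @param cells two-column matrix of (row, col) indices.
#' @return the masked [association_matrix()].
#' @export
mask_cells <- function(A, cells) {
  out <- as_plain_matrix(as.matrix(A))
  out[cells] <- 0
  association_matrix(out, rownames(A), colnames(A))
}

# Fit on a masked matrix and return the dense score matrix.  Functional
# similarities are independent of A, so they are reused unchanged; GIP
# similarities and the heterogeneous graph are rebuilt from the masked
# matrix in every call (no test-label leakage).
fit_masked_scores <- function(A_train, config, disease_functional = NULL,
                              microbe_functional = NULL) {
  fit <- mdagcan(A_train, config, disease_functional, microbe_functional)
  fit$scores
}

eval_result <- function(protocol, per_fold, threshold, extra = list()) {
  per_fold <- as.data.frame(per_fold)
  metr <- setdiff(names(per_fold), "fold")
  structure(c(list(protocol = protocol, per_fold = per_fold,
                   mean = vapply(per_fold[metr], mean, 0),
                   sd = vapply(per_fold[metr], stats::sd, 0),
                   threshold = threshold),
              extra),
            class = "mdagcan_eval")
}

#' @export
print.mdagcan_eval <- function(x, ...) {
  cat(sprintf("%s evaluation (%d fold(s), threshold %.2f)\n",
              x$protocol, nrow(x$per_fold), x$threshold))
  for (m in names(x$mean))
    cat(sprintf("  %-12s %.4f +/- %.4f\n", m, x$mean[[m]],
                if (is.na(x$sd[[m]])) 0 else x$sd[[m]]))
  invisible(x)
}

#' Leave-one-out cross-validation over known associations
#'
#' Each known association is masked in turn; GIP similarities, the fused
#' similarity, the heterogeneous graph and the model are all recomputed
#' from the masked matrix, and the held-out pair's score is ranked against
#' the scores of every unknown (0) pair of the original matrix.  A single
#' pooled AUC over all rounds is reported.
#'
#' @param A an [association_matrix()] with at least 2 positives.
#' @param config an [mdagcan_config()].
#' @param disease_functional,microbe_functional optional functional
#'   similarities (see [mdagcan_graph()]).
#' @return an `mdagcan_eval` with the pooled `auc`, per-round win
#'   fractions, and the held-out cells.
#' @export
loocv <- function(A, config = mdagcan_config(),
                  disease_functional = NULL, microbe_functional = NULL) {
  if (!is_association_matrix(A)) A <- association_matrix(A)
  pos <- which(as.matrix(A) == 1, arr.ind = TRUE)
  if (nrow(pos) < 2) stop("LOOCV needs at least 2 known associations")
  neg_mask <- as.matrix(A) == 0
  per_round <- numeric(nrow(pos))
  for (r in seq_len(nrow(pos))) {
    cell <- pos[r, , drop = FALSE]
    A_train <- mask_cells(A, cell)
    sc <- fit_masked_scores(A_train, config,
                            disease_functional, microbe_functional)
    per_round[r] <- auc(c(sc[cell], sc[neg_mask]),
                        c(1, rep(0, sum(neg_mask))))
  }
  eval_result("loocv",
              data.frame(fold = seq_len(nrow(pos)), auc = per_round),
              config$threshold,
              extra = list(pooled_auc = mean(per_round), held_out = pos))
}

#' k-fold cross-validation over known associations
#'
#' Known positives are partitioned into `k` seeded folds of near-equal
#' size.  For each fold, its positives are masked during training and then
#' scored against every unknown (0) pair of the original matrix; AUC and
#' threshold metrics are reported per fold with mean and sd.
#'
#' @inheritParams loocv
#' @param k number of folds (default 5).
#' @param seed seed for the fold partition (defaults to `config$seed`).
#' @return an `mdagcan_eval`; the `folds` element maps each fold to its
#'   held-out cells for auditing.
#' @export
kfold_cv <- function(A, config = mdagcan_config(), k = 5, seed = config$seed,
                     disease_functional = NULL, microbe_functional = NULL) {
  if (!is_association_matrix(A)) A <- association_matrix(A)
  pos <- which(as.matrix(A) == 1, arr.ind = TRUE)
  if (nrow(pos) < k) stop("fewer positives than folds")
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  assign_fold <- sample(rep(seq_len(k), length.out = nrow(pos)))
  neg_mask <- as.matrix(A) == 0
  rows <- vector("list", k)
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    test_cells <- pos[assign_fold == f, , drop = FALSE]
    folds[[f]] <- test_cells
    A_train <- mask_cells(A, test_cells)
    sc <- fit_masked_scores(A_train, config,
                            disease_functional, microbe_functional)
    scores <- c(sc[test_cells], sc[neg_mask])
    labels <- c(rep(1, nrow(test_cells)), rep(0, sum(neg_mask)))
    rows[[f]] <- c(fold = f, auc = auc(scores, labels),
                   threshold_metrics(scores, labels, config$threshold))
  }
  eval_result("kfold", do.call(rbind, rows), config$threshold,
              extra = list(k = k, folds = folds, seed = seed))
}

# Shared engine for the cold-start row/column holdout tests.
holdout_test <- function(A, config, fraction, n_repeats, seed, margin,
                         disease_functional, microbe_functional,
                         protocol) {
  if (!is_association_matrix(A)) A <- association_matrix(A)
  n_units <- if (margin == 1) nrow(A) else ncol(A)
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  n_hold <- max(1L, round(fraction * n_units))
  if (n_hold >= n_units) stop("holdout would remove every unit")
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  rows <- vector("list", n_repeats)
  held <- vector("list", n_repeats)
  for (rep_i in seq_len(n_repeats)) {
    repeat {   # resample if the held-out block has a single class
      units <- sort(sample(n_units, n_hold))
      block <- if (margin == 1) as.matrix(A)[units, , drop = FALSE]
               else as.matrix(A)[, units, drop = FALSE]
      if (sum(block) > 0 && sum(block) < length(block)) break
    }
    cells <- if (margin == 1)
      cbind(rep(units, each = ncol(A)), rep(seq_len(ncol(A)), length(units)))
    else
      cbind(rep(seq_len(nrow(A)), length(units)), rep(units, each = nrow(A)))
    A_train <- mask_cells(A, cells)
    sc <- fit_masked_scores(A_train, config,
                            disease_functional, microbe_functional)
    scores <- sc[cells]
    labels <- as.matrix(A)[cells]
    held[[rep_i]] <- units
    rows[[rep_i]] <- c(fold = rep_i, auc = auc(scores, labels),
                       threshold_metrics(scores, labels, config$threshold))
  }
  eval_result(protocol, do.call(rbind, rows), config$threshold,
              extra = list(fraction = fraction, held_out_units = held,
                           seed = seed))
}

#' Disease cold-start (horizontal) test
#'
#' A seeded fraction of disease rows is fully removed from training (all
#' their associations zeroed); the model is refit and every cell of the
#' held-out rows is scored against its true label.  Repeated over seeded
#' resamples with mean and sd reported, this measures generalization to
#' diseases with no known associations.
#'
#' @inheritParams loocv
#' @param fraction fraction of disease rows to hold out (default 0.2).
#' @param n_repeats number of seeded resamples (default 5).
#' @param seed resampling seed (defaults to `config$seed`).
#' @return an `mdagcan_eval`.
#' @export
horizontal_test <- function(A, config = mdagcan_config(), fraction = 0.2,
                            n_repeats = 5, seed = config$seed,
                            disease_functional = NULL,
                            microbe_functional = NULL) {
  holdout_test(A, config, fraction, n_repeats, seed, margin = 1,
               disease_functional, microbe_functional, "horizontal")
}

#' Microbe cold-start (vertical) test
#'
#' Column-wise analogue of [horizontal_test()]: a seeded fraction of
#' microbe columns is fully removed from training and scored after
#' refitting.  Implemented by transposing the matrix (and swapping the
#' functional similarities), so it mirrors the horizontal test exactly
#' under transposition.
#'
#' @inheritParams horizontal_test
#' @param fraction fraction of microbe columns to hold out (default 0.2).
#' @return an `mdagcan_eval`.
#' @export
vertical_test <- function(A, config = mdagcan_config(), fraction = 0.2,
                          n_repeats = 5, seed = config$seed,
                          disease_functional = NULL,
                          microbe_functional = NULL) {
  if (!is_association_matrix(A)) A <- association_matrix(A)
  At <- association_matrix(t(as.matrix(A)), colnames(A), rownames(A))
  out <- holdout_test(At, config, fraction, n_repeats, seed, margin = 1,
                      microbe_functional, disease_functional, "vertical")
  out
}

#' Permute association labels (null control)
#'
#' Randomly reassigns the known associations to uniformly drawn cells,
#' preserving their count; the resulting matrix carries no signal, so any
#' protocol run on it calibrates the null AUC (about 0.5).
#'
#' @param A an [association_matrix()].
#' @param seed RNG seed.
#' @return a shuffled [association_matrix()].
#' @export
shuffle_associations <- function(A, seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  v <- as.numeric(as.matrix(A))
  association_matrix(matrix(sample(v), nrow(A), ncol(A)),
                     rownames(A), colnames(A))
}

#' Rank candidate microbes for a query disease
#'
#' Known associations of the query disease are excluded; the remaining
#' microbes are sorted by score (descending, ties broken by input microbe
#' order) and the top `top_k` returned.
#'
#' @param object a fitted `mdagcan` model, or a score matrix (then `A`
#'   must be supplied).
#' @param disease_id the query disease label.
#' @param top_k number of candidates to return (default 20).
#' @param A the [association_matrix()] defining known pairs (taken from
#'   the fit when `object` is an `mdagcan`).
#' @return data frame with columns `rank`, `microbe_id`, `score`.
#' @export
rank_candidates <- function(object, disease_id, top_k = 20, A = NULL) {
  if (inherits(object, "mdagcan")) {
    scores <- object$scores
    A <- object$A
  } else {
    scores <- as.matrix(object)
    if (is.null(A)) stop("supply A when ranking from a bare score matrix")
  }
  if (!disease_id %in% rownames(scores))
    stop(sprintf("unknown disease id '%s'", disease_id))
  known <- as.matrix(A)[disease_id, ] == 1
  cand <- which(!known)
  if (top_k > length(cand))
    stop("top_k exceeds the number of unknown pairs for this disease")
  s <- scores[disease_id, cand]
  ord <- order(-s)            # stable: ties keep input microbe order
  sel <- cand[ord][seq_len(top_k)]
  data.frame(rank = seq_len(top_k),
             microbe_id = colnames(scores)[sel],
             score = scores[disease_id, sel],
             row.names = NULL)
}

#' Youden-J optimal classification threshold
#'
#' Returns the score threshold maximizing sensitivity + specificity - 1,
#' an alternative to the fixed default threshold for the confusion-matrix
#' metrics.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector, both classes present.
#' @return threshold in (0, 1).
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (!any(labels == 1) || !any(labels == 0)) stop("needs both classes")
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    sens + spec - 1
  }, 0)
  best <- cand[which.max(j)]
  # keep strictly inside (0, 1) for downstream threshold checks
  min(max(best, 1e-6), 1 - 1e-6)
}
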