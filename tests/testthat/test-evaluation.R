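test_that("rank-based AUC matches hand values and the all-pairs oracle", {
  expect_equal(auc(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(c(0.6, 0.6), c(1, 0)), 0.5)             # tie convention
  expect_equal(auc(c(0.8, 0.2, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(auc(c(0.1, 0.2), c(1, 1)), "both classes")
  set.seed(17)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    s <- round(runif(n), 2)                  # rounding forces ties
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0 || sum(y) == n) next
    expect_equal(auc(s, y), brute_auc(s, y), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(23)
  s <- runif(60)
  y <- rbinom(60, 1, 0.5)
  expect_equal(auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("threshold metrics follow the confusion matrix", {
  expect_equal(unname(threshold_metrics(c(0.9, 0.8, 0.1, 0.2),
                                        c(1, 1, 0, 0), 0.5)),
               c(1, 1, 1, 1))
  m <- threshold_metrics(c(0.4, 0.3, 0.2, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(unname(m[c("sensitivity", "specificity")]), c(0, 1))
  expect_equal(unname(m["f1"]), 0)           # no positive predictions
  m2 <- threshold_metrics(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(unname(m2), c(0.5, 0.5, 0.5, 0.5))
  expect_error(threshold_metrics(0.5, 1, 1.2), "threshold")
})

test_that("LOOCV runs one round per positive and is reproducible", {
  A <- association_matrix(matrix(c(1, 0, 0, 1), 2, byrow = TRUE))
  cfg <- cheap_config()
  r1 <- loocv(A, cfg)
  expect_equal(nrow(r1$per_fold), 2)
  r2 <- loocv(A, cfg)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_error(loocv(association_matrix(matrix(c(1, 0, 0, 0), 2)), cfg),
               "at least 2")
})

test_that("k-fold partitions cover each positive exactly once", {
  A <- random_association(8, 10, seed = 31)
  cfg <- cheap_config()
  res <- kfold_cv(A, cfg, k = 5, seed = 3)
  sizes <- vapply(res$folds, nrow, 0L)
  expect_lte(max(sizes) - min(sizes), 1)           # near-equal folds
  all_cells <- do.call(rbind, res$folds)
  key <- paste(all_cells[, 1], all_cells[, 2])
  expect_false(any(duplicated(key)))               # disjoint
  pos <- which(as.matrix(A) == 1, arr.ind = TRUE)
  expect_setequal(key, paste(pos[, 1], pos[, 2]))  # coverage
  expect_error(kfold_cv(A, cfg, k = sum(A) + 1), "fewer positives")
})

test_that("no cross-validation round sees held-out labels", {
  sim <- generate_associations(synthetic_spec(nd = 10, nm = 14,
                                              density = 0.15, seed = 8))
  A <- sim$A
  cfg <- cheap_config()
  res <- kfold_cv(A, cfg, k = 4, seed = 8)
  K_full_d <- as.matrix(gip_similarity(A, "disease"))
  K_full_m <- as.matrix(gip_similarity(A, "microbe"))
  for (f in seq_along(res$folds)) {
    cells <- res$folds[[f]]
    A_train <- mask_cells(A, cells)
    # held-out positives are zero in the training matrix (not in Omega+)
    expect_true(all(as.matrix(A_train)[cells] == 0))
    # masking a positive alters the row and column profiles involved,
    # so the recomputed GIP similarities must differ there
    K_tr_d <- as.matrix(gip_similarity(A_train, "disease"))
    K_tr_m <- as.matrix(gip_similarity(A_train, "microbe"))
    for (d in unique(cells[, 1]))
      expect_gt(max(abs(K_tr_d[d, ] - K_full_d[d, ])), 0)
    for (m in unique(cells[, 2]))
      expect_gt(max(abs(K_tr_m[m, ] - K_full_m[m, ])), 0)
  }
})

test_that("planted structure is recovered far above the shuffled null", {
  spec <- synthetic_spec(nd = 15, nm = 25, density = 0.12, seed = 4)
  sim <- generate_associations(spec)
  cfg <- mdagcan_config(k = 16, epochs = 150, lr = 5e-3, beta = 2,
                        dp_node = 0.1, dp_reg = 0.1, gamma = 5, seed = 4)
  real <- loocv(sim$A, cfg)
  null <- loocv(shuffle_associations(sim$A, seed = 44), cfg)
  expect_gt(real$pooled_auc, null$pooled_auc)
})

test_that("shuffled labels give chance-level k-fold AUC", {
  spec <- synthetic_spec(nd = 12, nm = 20, density = 0.15, seed = 9)
  sim <- generate_associations(spec)
  cfg <- mdagcan_config(k = 8, epochs = 40, lr = 5e-3,
                        dp_node = 0.1, dp_reg = 0.1, seed = 9)
  aucs <- vapply(1:10, function(i) {
    As <- shuffle_associations(sim$A, seed = 900 + i)
    kfold_cv(As, cfg, k = 3, seed = i)$mean[["auc"]]
  }, 0)
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("cold-start tests mask whole units and mirror under transpose", {
  sim <- generate_associations(synthetic_spec(nd = 10, nm = 14,
                                              density = 0.15, seed = 12))
  A <- sim$A
  cfg <- cheap_config()
  h <- horizontal_test(A, cfg, fraction = 0.2, n_repeats = 2, seed = 5)
  expect_equal(nrow(h$per_fold), 2)
  expect_true(all(h$per_fold$auc >= 0 & h$per_fold$auc <= 1))
  # held-out rows contribute zero training positives
  units <- h$held_out_units[[1]]
  cells <- cbind(rep(units, each = ncol(A)),
                 rep(seq_len(ncol(A)), length(units)))
  expect_true(all(as.matrix(mask_cells(A, cells))[units, ] == 0))
  # vertical on A is horizontal on t(A) with roles swapped
  At <- association_matrix(t(as.matrix(A)), colnames(A), rownames(A))
  v <- vertical_test(A, cfg, fraction = 0.2, n_repeats = 2, seed = 5)
  ht <- horizontal_test(At, cfg, fraction = 0.2, n_repeats = 2, seed = 5)
  expect_equal(v$per_fold, ht$per_fold)
  expect_error(horizontal_test(A, cfg, fraction = 0), "fraction")
})

test_that("candidate ranking excludes known pairs and breaks ties stably", {
  scores <- matrix(c(0.9, 0.7, 0.7, 0.2), 1,
                   dimnames = list("d1", paste0("m", 1:4)))
  A <- association_matrix(matrix(c(1, 0, 0, 0), 1), "d1", paste0("m", 1:4))
  r <- rank_candidates(scores, "d1", top_k = 2, A = A)
  expect_equal(r$microbe_id, c("m2", "m3"))       # m1 known; tie kept stable
  expect_equal(r$rank, 1:2)
  expect_equal(rank_candidates(scores, "d1", top_k = 1, A = A)$microbe_id,
               "m2")
  expect_error(rank_candidates(scores, "d9", top_k = 1, A = A),
               "unknown disease")
  expect_error(rank_candidates(scores, "d1", top_k = 4, A = A), "top_k")
  # scores non-increasing
  A0 <- association_matrix(matrix(0, 1, 4), "d1", paste0("m", 1:4))
  r4 <- rank_candidates(scores, "d1", top_k = 4, A = A0)
  expect_true(all(diff(r4$score) <= 0))
})

test_that("Youden-J threshold maximizes sensitivity + specificity", {
  s <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  y <- c(1, 1, 1, 0, 0, 0)
  t0 <- youden_threshold(s, y)
  m <- threshold_metrics(s, y, t0)
  expect_equal(unname(m["sensitivity"] + m["specificity"]), 2)
  expect_error(youden_threshold(c(0.1, 0.2), c(1, 1)), "both classes")
})
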