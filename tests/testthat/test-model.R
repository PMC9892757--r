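make_toy_graph <- function(seed = 11, nd = 3, nm = 4) {
  A <- random_association(nd, nm, seed = seed)
  cfg <- mdagcan_config(k = 3, dp_node = 0, dp_reg = 0, seed = 7)
  list(A = A, cfg = cfg, G = mdagcan_graph(A, cfg))
}

test_that("config validation enforces the legal parameter ranges", {
  expect_s3_class(mdagcan_config(), "mdagcan_config")
  expect_error(mdagcan_config(mu = 1.5), "mu")
  expect_error(mdagcan_config(alpha = 0), "alpha")
  expect_error(mdagcan_config(dp_reg = 1), "dp_reg")
  expect_error(mdagcan_config(epochs = 0), "epochs")
  expect_error(mdagcan_config(beta = -1), "beta")
})

test_that("a single GCN layer reduces to one propagation step", {
  tg <- make_toy_graph()
  cfg <- mdagcan_config(k = 3, n_gcn_layers = 1, n_gat_layers = 0,
                        dp_node = 0, dp_reg = 0, seed = 7)
  set.seed(7)
  params <- mdagcan:::init_params(7, cfg)
  fwd <- mdagcan:::forward_pass(tg$G, params, cfg, training = FALSE)
  H1 <- sym_norm_propagate(tg$G, tg$G$h0, params$gcn_W1)
  expect_equal(unname(fwd$gcn_cache[[1]]$Hout), unname(H1), tolerance = 1e-14)
})

test_that("stacked GCN layers iterate the propagation rule", {
  tg <- make_toy_graph()
  cfg <- tg$cfg
  set.seed(7)
  params <- mdagcan:::init_params(7, cfg)
  fwd <- mdagcan:::forward_pass(tg$G, params, cfg, training = FALSE)
  H1 <- sym_norm_propagate(tg$G, tg$G$h0, params$gcn_W1)
  H2 <- sym_norm_propagate(tg$G, H1, params$gcn_W2)
  expect_equal(unname(fwd$gcn_cache[[2]]$Hout), unname(H2), tolerance = 1e-14)
})

test_that("inference is deterministic and dropout only acts in training", {
  tg <- make_toy_graph()
  set.seed(7)
  params <- mdagcan:::init_params(7, tg$cfg)
  f1 <- mdagcan:::forward_pass(tg$G, params, tg$cfg, training = FALSE)
  f2 <- mdagcan:::forward_pass(tg$G, params, tg$cfg, training = FALSE)
  expect_identical(f1$scores, f2$scores)
  expect_true(all(f1$scores > 0 & f1$scores < 1))
})

test_that("attention coefficients normalize over the neighborhood", {
  tg <- make_toy_graph()
  set.seed(3)
  H <- matrix(rnorm(7 * 3), 7)
  W <- matrix(rnorm(9), 3)
  a <- rnorm(6)
  co <- gat_coefficients(H, tg$G, W, a)
  expect_lt(max(abs(rowSums(co$att) - 1)), 1e-12)
  expect_true(all(co$att[!co$nb] == 0))
  # equal scores spread attention uniformly over the neighborhood
  nb4 <- co$nb[1, ]
  co0 <- gat_coefficients(H * 0, tg$G, W, a)   # all e equal (zero)
  expect_equal(unname(co0$att[1, nb4]),
               rep(1 / sum(nb4), sum(nb4)))
})

test_that("attention scoring matches the one-dimensional hand example", {
  # h_i = 1, h_j = 2, W = 1, a = (1, 1): e_ij = relu(1*1 + 1*2) = 3
  G1 <- list(adjacency = matrix(c(0, 1, 1, 0), 2), degrees = c(1, 1),
             h0 = diag(2), node_ids = c("d1", "m1"), nd = 1, nm = 1)
  class(G1) <- "hetero_graph"
  co <- gat_coefficients(matrix(c(1, 2), 2, 1), G1,
                         matrix(1, 1, 1), c(1, 1))
  expect_equal(co$e[1, 2], 3)
  # a node whose only neighbor is itself attends to itself fully
  Giso <- list(adjacency = diag(2), degrees = c(1, 1), h0 = diag(2),
               node_ids = c("a", "b"), nd = 1, nm = 1)
  class(Giso) <- "hetero_graph"
  co_iso <- gat_coefficients(matrix(c(1, 2), 2, 1), Giso,
                             matrix(1, 1, 1), c(1, 1))
  expect_equal(unname(diag(co_iso$att)), c(1, 1))
})

test_that("attention aggregation is an exact weighted average", {
  set.seed(8)
  H <- matrix(rnorm(5 * 3), 5)
  att <- matrix(runif(25), 5)
  att <- att / rowSums(att)
  Z <- gat_aggregate(H, att)
  brute <- matrix(0, 5, 3)
  for (i in 1:5)
    for (j in 1:5)
      brute[i, ] <- brute[i, ] + att[i, j] * H[j, ]
  expect_lt(max(abs(Z - brute)), 1e-12)
  expect_equal(gat_aggregate(H, diag(5)), H)     # identity attention
  # uniform attention over two identical neighbors returns that vector
  H2 <- rbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(gat_aggregate(H2, matrix(0.5, 2, 2))[1, ]), c(1, 2, 3))
})

test_that("bilinear decoder reproduces hand-computed scores", {
  expect_equal(bilinear_decode(matrix(c(1, 0), 1), matrix(c(0, 1), 1),
                               diag(2))[1, 1], 0.5)
  expect_equal(bilinear_decode(matrix(c(1, 0), 1), matrix(c(0, 1), 1),
                               matrix(c(0, 0, 1, 0), 2))[1, 1],
               plogis(1))
  expect_equal(plogis(1), 0.731059, tolerance = 1e-5)
  expect_true(all(bilinear_decode(matrix(rnorm(6), 2), matrix(rnorm(9), 3),
                                  matrix(0, 3, 3)) == 0.5))
  expect_error(bilinear_decode(matrix(1, 1, 2), matrix(1, 1, 2),
                               matrix(1, 3, 3)), "dimensions")
})

test_that("focal loss matches hand values and reduces to cross-entropy", {
  # single positive at score 0.5: 0.1 * 0.25 * ln 2
  expect_equal(focal_loss(matrix(0.5), matrix(1), alpha = 0.1, gamma = 2),
               0.1 * 0.25 * log(2))
  expect_equal(focal_loss(matrix(0.5), matrix(1), alpha = 0.1, gamma = 2),
               0.0173287, tolerance = 1e-5)
  set.seed(4)
  p <- matrix(runif(12), 3)
  y <- matrix(rbinom(12, 1, 0.5), 3)
  expect_lt(abs(focal_loss(p, y, alpha = 1, gamma = 0) - brute_bce(p, y)),
            1e-12)
  # perfect scores drive the loss to zero
  expect_lt(focal_loss(ifelse(y == 1, 1 - 1e-9, 1e-9), y, 0.1, 2), 1e-10)
  # extreme scores are clamped, not -Inf
  expect_true(is.finite(focal_loss(matrix(c(0, 1), 1), matrix(c(1, 0), 1),
                                   0.1, 2)))
})

test_that("backpropagated gradients match finite differences on a 3x4 toy", {
  tg <- make_toy_graph(seed = 11, nd = 3, nm = 4)
  set.seed(7)
  params <- mdagcan:::init_params(7, tg$cfg)
  fwd <- mdagcan:::forward_pass(tg$G, params, tg$cfg, training = FALSE)
  dM <- mdagcan:::focal_loss_grad_logit(fwd$scores, tg$A,
                                        tg$cfg$alpha, tg$cfg$gamma)
  grads <- mdagcan:::backward_pass(tg$G, params, tg$cfg, fwd, dM)
  num <- numeric_gradients(tg$G, tg$A, params, tg$cfg)
  for (nm in names(params)) {
    rel <- max(abs(num[[nm]] - grads[[nm]])) /
      max(max(abs(num[[nm]])), 1e-8)
    expect_lt(rel, 1e-4)
  }
})

test_that("training is seed-reproducible and takes real optimizer steps", {
  A <- random_association(5, 8, seed = 2)
  cfg <- cheap_config()
  f1 <- mdagcan(A, cfg)
  f2 <- mdagcan(A, cfg)
  expect_identical(f1$scores, f2$scores)          # bitwise reproducibility
  cfg1 <- cheap_config(epochs = 1)
  f3 <- mdagcan(A, cfg1)
  set.seed(cfg1$seed)
  init <- mdagcan:::init_params(13, cfg1)
  expect_false(identical(f3$params$decoder_W, init$decoder_W))
  expect_identical(dim(f3$params$decoder_W), dim(init$decoder_W))
  expect_length(f3$loss_trace, 1)
})

test_that("training reduces the focal loss on planted-structure data", {
  sim <- generate_associations(synthetic_spec(nd = 12, nm = 18, seed = 5))
  fit <- mdagcan(sim$A, mdagcan_config(k = 8, epochs = 60, lr = 5e-3,
                                       dp_node = 0.1, dp_reg = 0.1, seed = 5))
  expect_lt(fit$loss_trace[length(fit$loss_trace)], fit$loss_trace[1])
})

test_that("prediction is deterministic with scores strictly inside (0,1)", {
  A <- random_association(4, 5, seed = 6)
  fit <- mdagcan(A, cheap_config())
  expect_identical(predict(fit), predict(fit))
  expect_identical(predict(fit), fit$scores)
  expect_true(all(fit$scores > 0 & fit$scores < 1))
  # zero decoder gives the indifferent score 0.5 everywhere
  fit0 <- fit
  fit0$params$decoder_W[] <- 0
  expect_true(all(predict(fit0) == 0.5))
})

test_that("model methods expose the usual fitted-model interface", {
  A <- random_association(4, 5, seed = 6)
  fit <- mdagcan(A, cheap_config())
  expect_named(coef(fit), c("gcn_W1", "gcn_W2", "gat_W1", "gat_a1",
                            "decoder_W"))
  expect_equal(dim(residuals(fit)), dim(A))
  expect_equal(unname(as.matrix(A) - fitted(fit)),
               unname(residuals(fit)))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "association_matrix")
  s <- summary(fit)
  expect_s3_class(s, "summary.mdagcan")
  expect_true(s$train_auc >= 0 && s$train_auc <= 1)
})

test_that("a fitted model survives a save/load round trip", {
  A <- random_association(4, 5, seed = 6)
  fit <- mdagcan(A, cheap_config())
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_mdagcan(fit, tmp)
  back <- load_mdagcan(tmp)
  expect_identical(back$scores, fit$scores)
  expect_identical(back$params, fit$params)
  expect_identical(predict(back), predict(fit))
})
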