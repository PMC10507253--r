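test_that("score_head is a 2-way softmax with closed-form limits", {
  expect_equal(unname(score_head(c(1, 2, 3),
                                 list(W = matrix(0, 2, 3), b = c(0, 0)))),
               matrix(0.5, 1, 2), tolerance = 1e-12)
  # logits (0, ln 3) -> (0.25, 0.75): encode via bias only
  p <- score_head(0, list(W = matrix(0, 2, 1), b = c(0, log(3))))
  expect_equal(unname(p), matrix(c(0.25, 0.75), 1), tolerance = 1e-12)
  set.seed(61)
  par <- list(W = matrix(rnorm(10), 2, 5), b = rnorm(2))
  P <- score_head(matrix(rnorm(40), 8, 5), par)
  expect_equal(unname(rowSums(P)), rep(1, 8), tolerance = 1e-9)
  expect_error(score_head(c(1, NA), list(W = matrix(0, 2, 2), b = c(0, 0))),
               "non-finite")
})

test_that("ce_loss equals the per-sample loop oracle and is monotone", {
  expect_equal(ce_loss(c(0, 1), 1), 0, tolerance = 1e-9)
  expect_equal(ce_loss(c(0.5, 0.5), 1), log(2), tolerance = 1e-12)
  set.seed(62)
  for (rep in 1:3) {
    n <- sample(3:10, 1)
    p1 <- runif(n, 0.01, 0.99)
    P <- cbind(1 - p1, p1)
    y <- rbinom(n, 1, 0.5)
    oracle <- 0
    for (i in seq_len(n)) {
      oracle <- oracle - (y[i] * log(P[i, 2]) + (1 - y[i]) * log(P[i, 1]))
    }
    expect_equal(ce_loss(P, y), unname(oracle), tolerance = 1e-10)
  }
  # loss decreases monotonically as p1 approaches the label
  ps <- seq(0.1, 0.9, 0.1)
  losses <- vapply(ps, function(p) ce_loss(c(1 - p, p), 1), numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_error(ce_loss(c(0.5, 0.5), 2), "labels")
})

test_that("fuse_scores is affine in lambda with exact boundaries", {
  expect_equal(fuse_scores(0.8, 0.4, 1), 0.8)
  expect_equal(fuse_scores(0.8, 0.4, 0), 0.4)
  expect_equal(fuse_scores(0.8, 0.4, 0.5), 0.6)
  # affine interpolation across a sweep, and matrix input uses p1
  st <- matrix(c(0.3, 0.7), 1); sa <- matrix(c(0.9, 0.1), 1)
  for (lam in c(0, 0.25, 0.5, 1)) {
    expect_equal(fuse_scores(st, sa, lam), lam * 0.7 + (1 - lam) * 0.1)
  }
  expect_error(fuse_scores(0.5, 0.5, 1.2), "lambda")
})

test_that("train_model fits, scores and reproduces itself at fixed seed", {
  ds <- tiny_dataset(seed = 3L)
  folds <- make_folds(ds$O, seed = 1L)
  cfg <- tiny_config(seed = 5L)
  m1 <- train_model(ds, folds, fold = 1L, config = cfg)
  # optimisation sanity: final epoch loss below the first
  expect_lt(tail(m1$head_log$loss, 1), m1$head_log$loss[1])
  sc <- m1$scores
  expect_true(all(c("drug", "side_effect", "score", "label",
                    "fold") %in% names(sc)))
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  expect_equal(sort(unique(sc$label)), c(0, 1))
  # determinism: identical score vectors for an identical seed
  m2 <- train_model(ds, folds, fold = 1L, config = cfg)
  expect_identical(m1$scores$score, m2$scores$score)
  # no test positive leaks into the training association matrix
  f <- folds$folds[[1]]
  expect_equal(max(m1$O_train[f$test_pos]), 0)
  expect_equal(sum(unclass(ds$O)) - sum(m1$O_train), nrow(f$test_pos))
})

test_that("ablation switches select the corresponding branch scores", {
  ds <- tiny_dataset(seed = 6L)
  folds <- make_folds(ds$O, seed = 2L)
  m_att <- train_model(ds, folds, 1L, tiny_config(use_tga = FALSE))
  expect_true(all(is.na(m_att$scores$score_topo)))
  expect_identical(m_att$scores$score, m_att$scores$score_att)   # lambda 0
  m_topo <- train_model(ds, folds, 1L, tiny_config(use_scpa = FALSE))
  expect_true(all(is.na(m_topo$scores$score_att)))
  expect_identical(m_topo$scores$score, m_topo$scores$score_topo) # lambda 1
  expect_error(train_config(use_tga = FALSE, use_scpa = FALSE),
               "at least one branch")
  # full model fuses with the configured lambda
  m_full <- train_model(ds, folds, 1L, tiny_config(lambda = 0.25))
  expect_equal(m_full$scores$score,
               0.25 * m_full$scores$score_topo +
                 0.75 * m_full$scores$score_att, tolerance = 1e-12)
})

test_that("topology head gradients agree with central differences", {
  set.seed(63)
  n_r <- 5L; n_s <- 6L; n_f <- 8L; B <- 4L
  H_chem <- matrix(rnorm((n_r + n_s) * n_f), n_r + n_s, n_f)
  H_dise <- matrix(rnorm((n_r + n_s) * n_f), n_r + n_s, n_f)
  pairs <- cbind(sample(n_r, B, TRUE), sample(n_s, B, TRUE))
  y <- c(1, 0, 1, 0); Y <- cbind(1 - y, y)
  cfg <- list(use_rla = TRUE)
  ac <- attention_params(n_f); ad <- attention_params(n_f)
  tc <- topo_conv_params(c(3L, 5L))
  params <- list(att_cW = ac$W, att_cb = ac$b, att_dW = ad$W,
                 att_db = ad$b, t1_W = tc$W1, t1_b = tc$b1, t2_W = tc$W2,
                 t2_b = tc$b2)
  probe <- adrgraph:::topo_conv_forward(array(0, c(1L, 2L, n_f, 1L)), tc)
  params$tf_W <- adrgraph:::glorot(c(2L, prod(dim(probe$out)[1:3])))
  params$tf_b <- numeric(2L)
  lossf <- function(params) {
    fw <- adrgraph:::topo_head_forward(params, cfg, H_chem, H_dise, pairs,
                                       n_r)
    ce_loss(fw$p, y) / B
  }
  fw <- adrgraph:::topo_head_forward(params, cfg, H_chem, H_dise, pairs,
                                     n_r)
  g <- adrgraph:::topo_head_backward(fw, params, cfg, (fw$p - Y) / B)
  numgrad_check(lossf, params, g, n_probe = 3L)
})
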