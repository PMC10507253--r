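test_that("gcn_layer computes relu(A H W) and validates shapes", {
  H <- matrix(c(1, 2, 3, 4), 2)
  expect_equal(gcn_layer(diag(2), H, diag(2)), H, ignore_attr = TRUE)
  # ReLU kills an all-negative product
  expect_equal(gcn_layer(diag(2), -H, diag(2)), 0 * H, ignore_attr = TRUE)
  A <- matrix(0.5, 2, 2)
  expect_equal(gcn_layer(A, matrix(c(1, 3), 2, 1), matrix(2)),
               matrix(4, 2, 1), ignore_attr = TRUE)
  expect_error(gcn_layer(diag(2), matrix(1, 3, 1), matrix(1)),
               "incompatible")
})

test_that("encode/decode chain equals manual layer composition", {
  ds <- tiny_dataset(seed = 8L, n_drugs = 3L, n_side_effects = 2L)
  g <- build_hetero_graph(ds$M_chem, ds$S, ds$O, "chem")
  set.seed(31)
  par <- generator_params(g$n_nodes, encoder_dims = c(4L, 3L),
                          decoder_dims = c(4L, g$n_nodes))
  A_hat <- laplace_normalize(g)
  H_en <- encode(g, par, A_hat)
  manual <- gcn_layer(A_hat, gcn_layer(A_hat, g$attributes, par$W_en[[1]]),
                      par$W_en[[2]])
  expect_equal(H_en, manual, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(dim(H_en), c(5L, 3L))
  H_hat <- decode(H_en, par, A_hat)
  manual2 <- gcn_layer(A_hat, gcn_layer(A_hat, H_en, par$W_de[[1]]),
                       par$W_de[[2]])
  expect_equal(H_hat, manual2, ignore_attr = TRUE)
  expect_equal(dim(H_hat), c(5L, 5L))
  # zero weights give a zero embedding
  par0 <- par
  par0$W_en <- lapply(par$W_en, function(w) w * 0)
  expect_equal(max(abs(encode(g, par0, A_hat))), 0)
  expect_error(generator_params(5L, decoder_dims = c(4L, 4L)), "node count")
})

test_that("discriminator outputs probability pairs and matches a manual MLP", {
  set.seed(32)
  par <- discriminator_params(4L, hidden_dims = c(3L, 3L))
  X <- matrix(rnorm(20), 5, 4)
  p <- discriminate(X, par)
  expect_equal(unname(rowSums(p)), rep(1, 5), tolerance = 1e-9)
  expect_true(all(p > 0 & p < 1))
  # zero parameters -> (0.5, 0.5)
  par0 <- list(W = lapply(par$W, function(w) w * 0),
               b = lapply(par$b, function(b) b * 0))
  expect_equal(unname(discriminate(rnorm(4), par0)),
               matrix(0.5, 1, 2), tolerance = 1e-12)
  # manual two-layer forward on a 3-vector
  par3 <- list(W = list(matrix(c(1, -1, 0, 1, 0.5, 0), 2, 3),
                        matrix(c(1, 0, -1, 1), 2, 2)),
               b = list(c(0.1, -0.2), c(0, 0.3)))
  h <- pmax(par3$W[[1]] %*% c(1, 2, 3) + par3$b[[1]], 0)
  logit <- par3$W[[2]] %*% h + par3$b[[2]]
  expect_equal(unname(discriminate(c(1, 2, 3), par3))[1, ],
               as.vector(exp(logit) / sum(exp(logit))), tolerance = 1e-12)
  expect_error(discriminate(c(1, NA, 3), par3), "non-finite")
})

test_that("adversarial training reduces reconstruction error deterministically", {
  ds <- tiny_dataset(seed = 4L)
  g <- build_hetero_graph(ds$M_chem, ds$S, ds$O, "chem")
  t1 <- adversarial_train(g, n_f = 8L, encoder_dims = c(16L, 8L),
                          decoder_dims = c(16L, g$n_nodes),
                          disc_dims = c(16L, 8L), epochs = 60L, seed = 2L)
  expect_lt(tail(t1$log$recon, 1), t1$log$recon[1])
  expect_true(all(is.finite(t1$H_en)))
  expect_equal(dim(t1$H_en), c(g$n_nodes, 8L))
  t2 <- adversarial_train(g, n_f = 8L, encoder_dims = c(16L, 8L),
                          decoder_dims = c(16L, g$n_nodes),
                          disc_dims = c(16L, 8L), epochs = 60L, seed = 2L)
  expect_identical(t1$H_en, t2$H_en)
  t3 <- adversarial_train(g, n_f = 8L, encoder_dims = c(16L, 8L),
                          decoder_dims = c(16L, g$n_nodes),
                          disc_dims = c(16L, 8L), epochs = 60L, seed = 3L)
  expect_false(identical(t1$H_en, t3$H_en))
})

test_that("a discriminator cannot beat chance when fake equals real", {
  # frozen generator emitting the truth: balanced batches are
  # indistinguishable, so accuracy collapses to 0.5 by construction
  set.seed(33)
  H <- matrix(runif(50), 10, 5)
  par <- discriminator_params(5L, c(4L, 4L))
  p_true <- discriminate(H, par)[, 1L]
  p_fake <- discriminate(H, par)[, 1L]   # identical inputs
  acc <- mean(c(p_true > 0.5, p_fake <= 0.5))
  expect_equal(acc, 0.5, tolerance = 1e-12)
})

test_that("generator and discriminator gradients match central differences", {
  set.seed(34)
  n_v <- 8L
  A <- matrix(runif(n_v^2), n_v); A <- (A + t(A)) / 2; diag(A) <- 1
  A_hat <- laplace_normalize(A)
  H <- A
  gen <- generator_params(n_v, c(5L, 3L), c(4L, n_v))
  disc <- discriminator_params(n_v, c(5L, 4L))
  idx <- 1:4
  lossG <- function(gen) {
    fw <- adrgraph:::gen_forward(A_hat, H, gen)
    ff <- adrgraph:::disc_forward(fw$H_hat[idx, , drop = FALSE], disc)
    mean(log(pmax(ff$p[, 2L], 1e-12))) + mean((fw$H_hat - H)^2)
  }
  fw <- adrgraph:::gen_forward(A_hat, H, gen)
  ff <- adrgraph:::disc_forward(fw$H_hat[idx, , drop = FALSE], disc)
  dlog <- cbind(-ff$p[, 1L], ff$p[, 1L]) / length(idx)
  gd <- adrgraph:::disc_backward(ff, disc, dlog)
  dHhat <- matrix(0, n_v, n_v)
  dHhat[idx, ] <- gd$dX
  dHhat <- dHhat + 2 * (fw$H_hat - H) / length(H)
  gg <- adrgraph:::gen_backward(A_hat, gen, fw, dHhat)
  eps <- 1e-6
  for (part in c("W_en", "W_de")) {
    for (l in seq_along(gen[[part]])) {
      for (i in sample(length(gen[[part]][[l]]), 3)) {
        gp <- gen; gp[[part]][[l]][i] <- gp[[part]][[l]][i] + eps
        gm <- gen; gm[[part]][[l]][i] <- gm[[part]][[l]][i] - eps
        expect_equal(gg[[part]][[l]][i],
                     (lossG(gp) - lossG(gm)) / (2 * eps), tolerance = 1e-4)
      }
    }
  }
})
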