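make_pair_fixture <- function() {
  M_chem <- similarity_matrix(matrix(c(1, .5, .5, 1), 2), "chem")
  M_dise <- similarity_matrix(matrix(c(1, .2, .2, 1), 2), "dise")
  S <- similarity_matrix(diag(3), "side_effect")
  O <- association_matrix(matrix(c(1, 0, 0, 1, 1, 0), 2, 3))
  list(M_chem = M_chem, M_dise = M_dise, S = S, O = O)
}

test_that("build_pair_attr lays out rows and channels as specified", {
  fx <- make_pair_fixture()
  pa <- build_pair_attr(fx$M_chem, fx$M_dise, fx$S, fx$O, i = 2L, j = 2L)
  expect_equal(dim(pa$X_chem), c(2L, 5L))
  expect_equal(dim(pa$X_att), c(2L, 2L, 5L))
  # row 1 channel 1: [M_chem_i || O_i] with O row 2 = (0, 1, 0)
  expect_equal(unname(pa$X_chem[1, ]), c(.5, 1, 0, 1, 0))
  # row 2: [t(O)_j || S_j] with O column 2 = (0, 1), S row 2 = (0, 1, 0)
  expect_equal(unname(pa$X_chem[2, ]), c(0, 1, 0, 1, 0))
  expect_equal(unname(pa$X_dise[1, ]), c(.2, 1, 0, 1, 0))
  # channels ordered (chem, dise); x2 shared
  expect_equal(pa$X_att[1, , ], unname(pa$X_chem))
  expect_equal(pa$X_att[2, , ], unname(pa$X_dise))
  # the known positive O_22 appears at x1 position N_r + j and x2 position i
  expect_equal(unname(pa$X_chem[1, 2 + 2]), 1)
  expect_equal(unname(pa$X_chem[2, 2]), 1)
  expect_error(build_pair_attr(fx$M_chem, fx$M_dise, fx$S, fx$O, 3L, 1L),
               "drug index")
  # all-zero O zeroes the association stretches
  O0 <- association_matrix(matrix(0, 2, 3))
  pa0 <- build_pair_attr(fx$M_chem, fx$M_dise, fx$S, O0, 1L, 1L)
  expect_equal(unname(pa0$X_chem[1, 3:5]), c(0, 0, 0))
  expect_equal(unname(pa0$X_chem[2, 1:2]), c(0, 0))
})

test_that("batched pair tensors agree with the single-pair builder", {
  ds <- tiny_dataset(seed = 12L, n_drugs = 6L, n_side_effects = 9L)
  is <- c(1L, 4L, 6L); js <- c(2L, 9L, 5L)
  Xb <- adrgraph:::build_pair_attr_batch(ds$M_chem, ds$M_dise, ds$S, ds$O,
                                         is, js)
  expect_equal(dim(Xb), c(2L, 2L, 15L, 3L))
  for (k in seq_along(is)) {
    pa <- build_pair_attr(ds$M_chem, ds$M_dise, ds$S, ds$O, is[k], js[k])
    expect_equal(Xb[, , , k], pa$X_att)
  }
})

test_that("latent path: pooling, conv, bilinear restore", {
  # unit single-tap filter: the worked 1x1x4 example
  par <- list(W_L = array(1, c(1L, 1L, 1L, 1L)), b_L = 0, latent_pool = 2L)
  x <- array(c(0, 2, 4, 6), c(1L, 1L, 4L))
  out <- scc_latent_path(x, par)
  expect_equal(as.vector(out), c(1, 2, 4, 5))
  # constants are fixed points with a unit filter and zero bias
  cst <- array(5, c(1L, 2L, 8L))
  expect_equal(as.vector(scc_latent_path(cst, par)), rep(5, 16))
  # zero input, zero bias -> zero output with any filter
  par2 <- scc_params(latent_pool = 4L)
  z <- scc_latent_path(array(0, c(2L, 2L, 12L)), par2)
  expect_equal(max(abs(z)), 0)
  expect_error(scc_latent_path(array(1, c(2L, 2L, 3L)), par2), "pooling")
})

test_that("calibration gates the convolved map through a sigmoid", {
  set.seed(51)
  par <- scc_params(latent_pool = 2L)
  X <- array(rnorm(2 * 2 * 8), c(2L, 2L, 8L))
  # X + X' = 0 everywhere -> neutral gate 0.5
  Xp <- -X
  Y <- scc_calibrate(X, Xp, par)
  cv <- adrgraph:::conv2d_forward(adrgraph:::as_nchw(X), par$W_cal,
                                  par$b_cal, "same")$out
  Ycal_manual <- cv * 0.5
  fz <- adrgraph:::conv2d_forward(Ycal_manual, par$W_fus, par$b_fus,
                                  "same")$out
  pooled <- adrgraph:::avgpool2d_forward(adrgraph:::sigmoid(fz), 2L, 2L)$out
  expect_equal(Y, array(pooled, dim(pooled)[1:3]), tolerance = 1e-10)
  # saturated negative gate kills the map before the fusion conv
  Xbig <- array(-40, c(2L, 2L, 8L))
  Yb <- scc_calibrate(X, Xbig - X, par)   # X + X' = -40 -> gate ~ 0
  fz0 <- adrgraph:::conv2d_forward(array(0, c(2L, 2L, 8L, 1L)), par$W_fus,
                                   par$b_fus, "same")$out
  p0 <- adrgraph:::avgpool2d_forward(adrgraph:::sigmoid(fz0), 2L, 2L)$out
  expect_equal(Yb, array(p0, dim(p0)[1:3]), tolerance = 1e-6)
  expect_error(scc_calibrate(X, array(0, c(1L, 2L, 9L)), par), "differ")
})

test_that("original path is unpadded with the stated filter counts", {
  par <- scc_params()
  expect_equal(dim(par$W_o1)[1], 16L)
  expect_equal(dim(par$W_o2)[1], 32L)
  X <- array(rnorm(2 * 2 * 5), c(2L, 2L, 5L))
  Y <- scc_original_path(X, par)
  expect_equal(dim(Y), c(32L, 1L, 3L))   # width 5 -> 4 -> 3
  expect_equal(max(abs(scc_original_path(X * 0, par))), 0)
})

test_that("scc_encode composes the three paths with channel concatenation", {
  set.seed(52)
  par <- scc_params(latent_pool = 3L)
  X <- array(rnorm(2 * 2 * 12), c(2L, 2L, 12L))
  Z <- scc_encode(X, par)
  Xp <- scc_latent_path(X, par)
  Ya <- scc_calibrate(X, Xp, par)
  Yo <- scc_original_path(X, par)
  w <- min(dim(Ya)[3], dim(Yo)[3])
  crop <- function(m) {
    off <- (dim(m)[3] - w) %/% 2
    m[, , off + seq_len(w), drop = FALSE]
  }
  expect_equal(dim(Z)[1], dim(Ya)[1] + dim(Yo)[1])
  expect_equal(Z[seq_len(dim(Ya)[1]), , , drop = FALSE], crop(Ya),
               tolerance = 1e-12)
  expect_equal(Z[dim(Ya)[1] + seq_len(dim(Yo)[1]), , , drop = FALSE],
               crop(Yo), tolerance = 1e-12)
  # determinism and the ablation routing
  expect_identical(Z, scc_encode(X, par))
  expect_equal(scc_encode(X, par, use_calibration = FALSE), Yo)
})

test_that("scc gradients agree with central differences", {
  set.seed(53)
  n_w <- 9L; B <- 2L
  Xb <- array(rnorm(2 * 2 * n_w * B), c(2L, 2L, n_w, B))
  y <- c(1, 0); Y <- cbind(1 - y, y)
  sccp <- scc_params(latent_pool = 3L)
  params <- list()
  for (nm in setdiff(names(sccp), "latent_pool")) params[[nm]] <- sccp[[nm]]
  probe <- adrgraph:::scc_forward(Xb[, , , 1, drop = FALSE], sccp, TRUE)
  params$af_W <- adrgraph:::glorot(c(2L, prod(dim(probe$out)[1:3])))
  params$af_b <- numeric(2L)
  cfg <- list(use_calibration = TRUE)
  lossf <- function(params) {
    fa <- adrgraph:::scc_head_forward(params, sccp, cfg, Xb)
    ce_loss(fa$p, y) / B
  }
  fa <- adrgraph:::scc_head_forward(params, sccp, cfg, Xb)
  g <- adrgraph:::scc_head_backward(fa, params, sccp, cfg, (fa$p - Y) / B)
  numgrad_check(lossf, params, g, n_probe = 3L)
})
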