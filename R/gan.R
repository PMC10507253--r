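# Enhanced topological representation learning: per graph view, a GCN
# autoencoder generator reconstructs the node attribute matrix while an MLP
# discriminator tries to tell original rows from reconstructed ones.

#' Single graph-convolution layer
#'
#' Computes `relu(A_hat %*% H %*% W)` where `A_hat` is the
#' Laplace-normalised adjacency.
#'
#' @param A_hat normalised adjacency (`n x n`).
#' @param H node feature matrix (`n x d_in`).
#' @param W weight matrix (`d_in x d_out`).
#' @return `n x d_out` feature matrix.
#' @export
gcn_layer <- function(A_hat, H, W) {
  if (ncol(A_hat) != nrow(H) || ncol(H) != nrow(W)) {
    stop_input("gcn_layer: incompatible shapes (%dx%d, %dx%d, %dx%d)",
               nrow(A_hat), ncol(A_hat), nrow(H), ncol(H), nrow(W), ncol(W))
  }
  relu(A_hat %*% H %*% W)
}

#' Generator (GCN autoencoder) parameters
#'
#' Encoder maps `N_v -> encoder_dims[...]` (last entry is the embedding
#' width `N_f`); the decoder maps `N_f -> decoder_dims[...]` whose last
#' entry must be `N_v` so the attribute matrix can be reconstructed.
#' Layers carry no bias, matching the graph-convolution formulation.
#'
#' @param n_v number of nodes.
#' @param encoder_dims,decoder_dims integer vectors of layer widths.
#' @return list with `W_en` and `W_de` weight lists.
#' @export
generator_params <- function(n_v, encoder_dims = c(64L, 32L),
                             decoder_dims = c(64L, n_v)) {
  if (decoder_dims[length(decoder_dims)] != n_v) {
    stop_input("last decoder dimension must equal the node count %d", n_v)
  }
  dims_en <- c(n_v, encoder_dims)
  dims_de <- c(encoder_dims[length(encoder_dims)], decoder_dims)
  W_en <- lapply(seq_along(encoder_dims), function(l) {
    glorot(c(dims_en[l], dims_en[l + 1L]))
  })
  W_de <- lapply(seq_along(decoder_dims), function(l) {
    glorot(c(dims_de[l], dims_de[l + 1L]))
  })
  list(W_en = W_en, W_de = W_de, n_v = n_v,
       n_f = encoder_dims[length(encoder_dims)])
}

#' Discriminator (MLP) parameters
#'
#' ReLU hidden layers followed by a 2-way softmax head giving
#' `(p_true, p_false)`.
#'
#' @param n_in input dimension (a node attribute row, length `N_v`).
#' @param hidden_dims widths of the hidden layers.
#' @return list of weight matrices `W` and bias vectors `b`.
#' @export
discriminator_params <- function(n_in, hidden_dims = c(64L, 32L)) {
  dims <- c(n_in, hidden_dims, 2L)
  W <- lapply(seq_len(length(dims) - 1L), function(l) {
    glorot(c(dims[l + 1L], dims[l]))
  })
  b <- lapply(seq_len(length(dims) - 1L), function(l) numeric(dims[l + 1L]))
  list(W = W, b = b)
}

#' Encode a heterogeneous graph into node embeddings
#'
#' Chains the encoder's graph-convolution layers over the normalised
#' adjacency; the output `H_en` is the `N_v x N_f` topological embedding.
#'
#' @param graph an `adr_hetero_graph`.
#' @param params from [generator_params()].
#' @param A_hat optional precomputed normalised adjacency.
#' @return `N_v x N_f` matrix.
#' @export
encode <- function(graph, params, A_hat = NULL) {
  A_hat <- A_hat %||% laplace_normalize(graph)
  H <- graph$attributes
  for (W in params$W_en) H <- gcn_layer(A_hat, H, W)
  H
}

#' Decode node embeddings back to the attribute space
#'
#' @param H_en `N_v x N_f` embedding matrix.
#' @param params from [generator_params()].
#' @param A_hat normalised adjacency used by every decoder layer.
#' @return reconstructed `N_v x N_v` attribute matrix `H_hat`.
#' @export
decode <- function(H_en, params, A_hat) {
  H <- H_en
  for (W in params$W_de) H <- gcn_layer(A_hat, H, W)
  H
}

#' Discriminator forward pass
#'
#' @param sample one attribute/reconstruction row, or a matrix of rows.
#' @param params from [discriminator_params()].
#' @return matrix of probability pairs `(p_true, p_false)`, rows sum to 1.
#' @export
discriminate <- function(sample, params) {
  X <- if (is.matrix(sample)) sample else matrix(sample, nrow = 1L)
  check_finite(X, "discriminator input")
  L <- length(params$W)
  for (l in seq_len(L - 1L)) {
    X <- relu(X %*% t(params$W[[l]]) +
                matrix(params$b[[l]], nrow(X), length(params$b[[l]]),
                       byrow = TRUE))
  }
  logits <- X %*% t(params$W[[L]]) +
    matrix(params$b[[L]], nrow(X), 2L, byrow = TRUE)
  p <- softmax_rows(logits)
  colnames(p) <- c("p_true", "p_false")
  p
}

# --- internal: forward/backward passes used during adversarial training ---

disc_forward <- function(X, par) {
  L <- length(par$W)
  acts <- vector("list", L)
  A <- X
  for (l in seq_len(L - 1L)) {
    pre <- A %*% t(par$W[[l]]) +
      matrix(par$b[[l]], nrow(A), length(par$b[[l]]), byrow = TRUE)
    acts[[l]] <- list(input = A, pre = pre)
    A <- relu(pre)
  }
  logits <- A %*% t(par$W[[L]]) + matrix(par$b[[L]], nrow(A), 2L, byrow = TRUE)
  acts[[L]] <- list(input = A, pre = logits)
  list(p = softmax_rows(logits), acts = acts)
}

# dlogits: n x 2 gradient at the logits; returns grads and gradient wrt input
disc_backward <- function(fw, par, dlogits) {
  L <- length(par$W)
  gW <- vector("list", L); gb <- vector("list", L)
  d <- dlogits
  for (l in rev(seq_len(L))) {
    gW[[l]] <- t(d) %*% fw$acts[[l]]$input
    gb[[l]] <- colSums(d)
    d <- d %*% par$W[[l]]
    if (l > 1L) d <- relu_bwd_cpp(d, fw$acts[[l - 1L]]$pre)
  }
  list(W = gW, b = gb, dX = d)
}

gen_forward <- function(A_hat, H, par) {
  pres <- list(); ins <- list()
  X <- H
  k <- 0L
  for (W in c(par$W_en, par$W_de)) {
    k <- k + 1L
    ins[[k]] <- X
    pre <- A_hat %*% X %*% W
    pres[[k]] <- pre
    X <- relu(pre)
    if (k == length(par$W_en)) H_en <- X
  }
  list(H_en = H_en, H_hat = X, pres = pres, ins = ins)
}

# backward of the full generator chain given dL/dH_hat
gen_backward <- function(A_hat, par, fw, dHhat) {
  Ws <- c(par$W_en, par$W_de)
  K <- length(Ws)
  gs <- vector("list", K)
  d <- dHhat
  for (k in rev(seq_len(K))) {
    d <- relu_bwd_cpp(d, fw$pres[[k]])
    AX <- A_hat %*% fw$ins[[k]]
    gs[[k]] <- t(AX) %*% d
    if (k > 1L) d <- t(A_hat) %*% d %*% t(Ws[[k]])
  }
  ne <- length(par$W_en)
  list(W_en = gs[seq_len(ne)], W_de = gs[ne + seq_len(K - ne)])
}

#' Adversarial training of the topological branch for one graph view
#'
#' Alternates one discriminator step (binary cross-entropy on balanced
#' original/reconstructed node rows) with one generator step (adversarial
#' term plus `gamma` times the mean-squared reconstruction error), both
#' optimised with Adam. Deterministic for a fixed seed.
#'
#' @param graph an `adr_hetero_graph`.
#' @param n_f embedding width (last encoder dimension).
#' @param encoder_dims,decoder_dims,disc_dims layer widths; decoder output
#'   is forced to `N_v`.
#' @param epochs,lr,gamma,batch_nodes training schedule.
#' @param seed integer seed for initialisation and batch order.
#' @return list of class `adr_topology`: `H_en`, `H_hat`, `generator`,
#'   `discriminator`, `log` (per-epoch losses, reconstruction error and
#'   discriminator accuracy), `view`.
#' @export
adversarial_train <- function(graph, n_f = 32L,
                              encoder_dims = c(64L, n_f),
                              decoder_dims = c(64L, graph$n_nodes),
                              disc_dims = c(64L, 32L),
                              epochs = 200L, lr = 1e-3, gamma = 1.0,
                              batch_nodes = 64L, seed = 1L) {
  A_hat <- laplace_normalize(graph)
  H <- unclass(graph$attributes)
  n_v <- graph$n_nodes
  batch_nodes <- min(batch_nodes, n_v)

  with_seed(derive_seed(seed, paste0("gan_init_", graph$view)), {
    gen <- generator_params(n_v, encoder_dims, decoder_dims)
    disc <- discriminator_params(n_v, disc_dims)
  })

  flat_gen <- function(p) c(stats::setNames(p$W_en, paste0("en", seq_along(p$W_en))),
                            stats::setNames(p$W_de, paste0("de", seq_along(p$W_de))))
  gen_vec <- flat_gen(gen)
  disc_vec <- c(stats::setNames(disc$W, paste0("W", seq_along(disc$W))),
                stats::setNames(disc$b, paste0("b", seq_along(disc$b))))
  opt_g <- adam_init(gen_vec, lr = lr)
  opt_d <- adam_init(disc_vec, lr = lr)

  unflat_gen <- function(v) {
    ne <- length(gen$W_en)
    list(W_en = unname(v[seq_len(ne)]),
         W_de = unname(v[ne + seq_len(length(gen$W_de))]),
         n_v = n_v, n_f = gen$n_f)
  }
  unflat_disc <- function(v) {
    L <- length(disc$W)
    list(W = unname(v[seq_len(L)]), b = unname(v[L + seq_len(L)]))
  }

  log <- data.frame(epoch = integer(), d_loss = numeric(),
                    g_loss = numeric(), recon = numeric(),
                    d_acc = numeric())
  rng_seed <- derive_seed(seed, paste0("gan_batches_", graph$view))

  with_seed(rng_seed, {
    for (ep in seq_len(epochs)) {
      gen <- unflat_gen(gen_vec)
      disc <- unflat_disc(disc_vec)
      fw <- gen_forward(A_hat, H, gen)
      idx <- sample.int(n_v, batch_nodes)
      Xtrue <- H[idx, , drop = FALSE]
      Xfake <- fw$H_hat[idx, , drop = FALSE]

      # -- discriminator step: CE on balanced true/false rows
      Xd <- rbind(Xtrue, Xfake)
      y <- cbind(c(rep(1, batch_nodes), rep(0, batch_nodes)),
                 c(rep(0, batch_nodes), rep(1, batch_nodes)))
      fd <- disc_forward(Xd, disc)
      p <- pmin(pmax(fd$p, 1e-12), 1 - 1e-12)
      d_loss <- -mean(rowSums(y * log(p)))
      d_acc <- mean((fd$p[, 1L] > 0.5) == (y[, 1L] == 1))
      gd <- disc_backward(fd, disc, (fd$p - y) / nrow(Xd))
      disc_vec <- adam_step(opt_d, disc_vec,
                            c(stats::setNames(gd$W, paste0("W", seq_along(gd$W))),
                              stats::setNames(gd$b, paste0("b", seq_along(gd$b)))))

      # -- generator step: log(1 - D(fake)) + gamma * MSE(H_hat, H)
      disc <- unflat_disc(disc_vec)
      ff <- disc_forward(Xfake, disc)
      pf <- pmin(pmax(ff$p, 1e-12), 1 - 1e-12)
      # non-saturating form of the adversarial objective: minimise
      # -log D(fake) instead of log(1 - D(fake)); identical fixed point,
      # non-vanishing gradient when the discriminator is ahead
      adv_loss <- -mean(log(pf[, 1L]))
      # d(-mean log p_true) / d logits = (p - e1) / n = (p1 - 1, p2) / n
      dlog <- cbind(pf[, 1L] - 1, pf[, 2L]) / nrow(Xfake)
      gdisc <- disc_backward(ff, disc, dlog)
      dHhat <- matrix(0, n_v, n_v)
      dHhat[idx, ] <- gdisc$dX
      # per-node squared reconstruction error, averaged over nodes: keeps
      # the reconstruction gradient commensurate with the adversarial one
      # on graphs of any size
      recon <- mean(rowSums((fw$H_hat - H)^2))
      dHhat <- dHhat + gamma * 2 * (fw$H_hat - H) / n_v
      gg <- gen_backward(A_hat, gen, fw, dHhat)
      gen_vec <- adam_step(opt_g, gen_vec, flat_gen(gg))

      g_loss <- adv_loss + gamma * recon
      log[nrow(log) + 1L, ] <- list(ep, d_loss, g_loss, recon, d_acc)
      if (!all(is.finite(c(d_loss, g_loss)))) {
        stop_input("adversarial training diverged at epoch %d", ep)
      }
    }
  })

  gen <- unflat_gen(gen_vec)
  fw <- gen_forward(A_hat, H, gen)
  structure(list(H_en = fw$H_en, H_hat = fw$H_hat, generator = gen,
                 discriminator = unflat_disc(disc_vec), log = log,
                 view = graph$view, A_hat = A_hat),
            class = "adr_topology")
}
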