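# Branch scoring heads, cross-entropy losses, joint training of the two
# branches, and lambda-weighted score fusion.

#' Softmax scoring head
#'
#' @param z flattened branch feature vector, or a matrix of them (rows).
#' @param params list with `W` (`2 x d`) and `b` (length 2).
#' @return matrix of probability pairs `(p0, p1)`; `p1` is the
#'   association probability.
#' @export
score_head <- function(z, params) {
  Z <- if (is.matrix(z)) z else matrix(z, nrow = 1L)
  check_finite(Z, "score head input")
  p <- softmax_rows(Z %*% t(params$W) +
                      matrix(params$b, nrow(Z), 2L, byrow = TRUE))
  colnames(p) <- c("p0", "p1")
  p
}

#' Cross-entropy loss of a batch of probability pairs
#'
#' Standard binary cross-entropy on the association probability `p1`,
#' summed over the batch, with epsilon clamping.
#'
#' @param prob_pairs matrix with columns `(p0, p1)` (or a single pair).
#' @param labels 0/1 vector.
#' @param eps clamping constant.
#' @return nonnegative scalar.
#' @export
ce_loss <- function(prob_pairs, labels, eps = 1e-12) {
  P <- if (is.matrix(prob_pairs)) prob_pairs else matrix(prob_pairs, nrow = 1L)
  if (!all(labels %in% c(0, 1))) stop_input("labels must be 0 or 1")
  if (length(labels) != nrow(P)) stop_input("labels/probabilities mismatch")
  p1 <- pmin(pmax(P[, 2L], eps), 1 - eps)
  -sum(labels * log(p1) + (1 - labels) * log(1 - p1))
}

#' Weighted fusion of the two branch scores
#'
#' `score = lambda * score_topo + (1 - lambda) * score_att`, applied to
#' the association-probability components.
#'
#' @param score_topo,score_att association probabilities (scalars or
#'   vectors), or 2-column probability-pair matrices whose `p1` column is
#'   used.
#' @param lambda fusion weight in \[0, 1\].
#' @return fused score(s).
#' @export
fuse_scores <- function(score_topo, score_att, lambda = 0.5) {
  if (length(lambda) != 1L || lambda < 0 || lambda > 1) {
    stop_input("lambda must lie in [0, 1]")
  }
  p <- function(x) if (is.matrix(x) && ncol(x) == 2L) x[, 2L] else x
  lambda * p(score_topo) + (1 - lambda) * p(score_att)
}

#' Training configuration
#'
#' Defaults follow the architecture at fixture scale: 2 x 2 kernels
#' everywhere, 16/32 filters in the two convolution stages of both
#' branches, a 1-filter latent and 32-filter fusion convolution in the
#' self-calibrated module, and an embedding width of 32. Adam with
#' learning rate 1e-3 throughout; 200 adversarial epochs and 100 head
#' epochs.
#'
#' @param n_f topological embedding width `N_f`.
#' @param encoder_dims,decoder_hidden,disc_dims generator/discriminator
#'   layer widths (decoder output is always `N_v`).
#' @param gan_epochs,gan_lr,gamma,gan_batch_nodes adversarial schedule;
#'   `gamma` weights the reconstruction term of the generator loss.
#' @param head_epochs,head_lr,batch_size branch-head schedule.
#' @param topo_filters,ori_filters,fusion_filters,latent_filters,
#'   latent_pool convolution widths (see [scc_params()]).
#' @param lambda fusion weight of the topology branch.
#' @param use_tga,use_rla,use_scpa,use_calibration ablation switches:
#'   disabling TGA drops the topology branch (lambda forced to 0),
#'   disabling SCPA drops the attribute branch (lambda forced to 1),
#'   disabling RLA replaces attention fusion by the residual sum, and
#'   disabling calibration routes `X_att` through the original path only.
#' @param seed master seed; all training streams derive from it.
#' @return a list of class `adr_train_config`.
#' @export
train_config <- function(n_f = 32L, encoder_dims = c(64L, n_f),
                         decoder_hidden = 64L, disc_dims = c(64L, 32L),
                         gan_epochs = 200L, gan_lr = 1e-3, gamma = 1.0,
                         gan_batch_nodes = 64L,
                         head_epochs = 100L, head_lr = 1e-3,
                         batch_size = 256L,
                         topo_filters = c(16L, 32L),
                         ori_filters = c(16L, 32L),
                         fusion_filters = 32L, latent_filters = 1L,
                         latent_pool = 4L, lambda = 0.5,
                         use_tga = TRUE, use_rla = TRUE, use_scpa = TRUE,
                         use_calibration = TRUE, seed = 1L) {
  if (!use_tga && !use_scpa) stop_input("at least one branch must be enabled")
  structure(as.list(environment()), class = "adr_train_config")
}

# lean internal head on column-oriented features (z: d x B)
head_softmax_cols <- function(z, W, b) {
  l <- W %*% z + as.vector(b)
  m <- pmax(l[1L, ], l[2L, ])
  e1 <- exp(l[1L, ] - m); e2 <- exp(l[2L, ] - m)
  s <- e1 + e2
  cbind(e1 / s, e2 / s)
}

flatten_cols <- function(x) {
  # [C,H,W,B] -> (C*H*W) x B without copying through t()
  d <- dim(x)
  dim(x) <- c(prod(d[1:3]), d[4])
  x
}

standardize_embedding <- function(H) {
  m <- colMeans(H)
  s <- apply(H, 2L, stats::sd)
  s[s < 1e-8] <- 1
  scale(H, center = m, scale = s)
}

effective_lambda <- function(config) {
  if (!config$use_tga) 0 else if (!config$use_scpa) 1 else config$lambda
}

# assemble the [1,2,n_f,B] topology input for a batch of pairs
topo_batch_input <- function(fused_rows, B) {
  n_f <- ncol(fused_rows)
  X <- array(0, dim = c(1L, 2L, n_f, B))
  X[1L, 1L, , ] <- t(fused_rows[seq_len(B), , drop = FALSE])
  X[1L, 2L, , ] <- t(fused_rows[B + seq_len(B), , drop = FALSE])
  X
}

#' Train the full association model on one cross-validation fold
#'
#' Stage one pre-trains, per graph view, the adversarially enhanced
#' topological embeddings ([adversarial_train()]); test-fold association
#' edges are zeroed beforehand so no held-out signal leaks into the
#' graphs or the pair attributes. Stage two jointly trains the two branch
#' scoring heads (attention fusion + convolution stack; self-calibrated
#' convolution stack) on balanced positive/negative batches by minimising
#' the sum of the two cross-entropy losses with Adam. Deterministic given
#' `config$seed`.
#'
#' @param dataset list with `M_chem`, `M_dise`, `S`, `O` (see
#'   [generate_dataset()] / [read_dataset()]).
#' @param folds an `adr_fold_split` from [make_folds()].
#' @param fold fold index to hold out.
#' @param config an [train_config()] object.
#' @return object of class `adr_model` containing trained parameters,
#'   the per-pair score table for the fold's test set (`drug`,
#'   `side_effect`, `score`, `label`, `fold` columns), embeddings, and
#'   training logs.
#' @export
train_model <- function(dataset, folds, fold = 1L,
                        config = train_config()) {
  stopifnot(inherits(folds, "adr_fold_split"))
  f <- folds$folds[[fold]]
  O <- unclass(dataset$O)
  n_r <- nrow(O); n_s <- ncol(O)

  # CV hygiene: zero held-out positives in the training association matrix
  O_train <- O
  O_train[f$test_pos] <- 0

  seed <- config$seed
  topo <- NULL
  if (config$use_tga) {
    g_chem <- build_hetero_graph(dataset$M_chem, dataset$S,
                                 O_train, "chem")
    g_dise <- build_hetero_graph(dataset$M_dise, dataset$S,
                                 O_train, "dise")
    n_v <- g_chem$n_nodes
    topo <- lapply(list(chem = g_chem, dise = g_dise), function(g) {
      adversarial_train(g, n_f = config$n_f,
                        encoder_dims = config$encoder_dims,
                        decoder_dims = c(config$decoder_hidden, n_v),
                        disc_dims = config$disc_dims,
                        epochs = config$gan_epochs, lr = config$gan_lr,
                        gamma = config$gamma,
                        batch_nodes = config$gan_batch_nodes, seed = seed)
    })
  }

  train_pairs <- rbind(f$train_pos, f$train_neg)
  y <- c(rep(1, nrow(f$train_pos)), rep(0, nrow(f$train_neg)))

  model <- with_seed(derive_seed(seed, "heads"), {
    train_heads(dataset, O_train, topo, train_pairs, y, config)
  })
  model$fold <- fold
  model$folds_seed <- folds$seed
  model$O_train <- O_train

  test_pairs <- rbind(f$test_pos, f$test_neg)
  test_y <- c(rep(1, nrow(f$test_pos)), rep(0, nrow(f$test_neg)))
  sc <- score_pairs(model, test_pairs[, 1L], test_pairs[, 2L])
  model$scores <- data.frame(
    drug = rownames(O)[test_pairs[, 1L]] %||% test_pairs[, 1L],
    side_effect = colnames(O)[test_pairs[, 2L]] %||% test_pairs[, 2L],
    drug_idx = test_pairs[, 1L], se_idx = test_pairs[, 2L],
    score = sc$score, score_topo = sc$score_topo,
    score_att = sc$score_att, label = test_y, fold = fold,
    stringsAsFactors = FALSE
  )
  model
}

# stage-two training of both scoring branches (internal)
train_heads <- function(dataset, O_train, topo, pairs, y, config) {
  n_r <- nrow(O_train); n_s <- ncol(O_train)
  n <- nrow(pairs)
  use_tga <- config$use_tga; use_scpa <- config$use_scpa

  params <- list()
  sccp <- NULL
  H_chem <- H_dise <- NULL
  if (use_tga) {
    # per-feature standardisation of the embeddings: removes the dominant
    # shared direction produced by dense similarity graphs and keeps the
    # conv head in a well-scaled regime (dead ReLU columns pass through
    # as zeros)
    H_chem <- standardize_embedding(topo$chem$H_en)
    H_dise <- standardize_embedding(topo$dise$H_en)
    if (config$use_rla) {
      ac <- attention_params(config$n_f)
      ad <- attention_params(config$n_f)
      params$att_cW <- ac$W; params$att_cb <- ac$b
      params$att_dW <- ad$W; params$att_db <- ad$b
    }
    tc <- topo_conv_params(config$topo_filters)
    params$t1_W <- tc$W1; params$t1_b <- tc$b1
    params$t2_W <- tc$W2; params$t2_b <- tc$b2
    # probe the flattened width
    probe <- topo_conv_forward(array(0, c(1L, 2L, config$n_f, 1L)), tc)
    dt <- prod(dim(probe$out)[1:3])
    params$tf_W <- glorot(c(2L, dt)); params$tf_b <- numeric(2L)
  }
  if (use_scpa) {
    sccp <- scc_params(channels = 2L,
                       latent_filters = config$latent_filters,
                       fusion_filters = config$fusion_filters,
                       ori_filters = config$ori_filters,
                       latent_pool = config$latent_pool)
    for (nm in setdiff(names(sccp), "latent_pool")) params[[nm]] <- sccp[[nm]]
    probe <- scc_forward(array(0, c(2L, 2L, n_r + n_s, 1L)), sccp,
                         config$use_calibration)
    da <- prod(dim(probe$out)[1:3])
    params$af_W <- glorot(c(2L, da)); params$af_b <- numeric(2L)
  }

  # precompute the full pair-attribute tensor for the training pairs
  X_att_all <- if (use_scpa) {
    build_pair_attr_batch(dataset$M_chem, dataset$M_dise, dataset$S,
                          O_train, pairs[, 1L], pairs[, 2L])
  } else NULL

  opt <- adam_init(params, lr = config$head_lr)
  log <- data.frame(epoch = integer(), loss = numeric(),
                    loss_topo = numeric(), loss_att = numeric())

  for (ep in seq_len(config$head_epochs)) {
    ord <- sample.int(n)
    tot <- tot_t <- tot_a <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      bidx <- ord[start:min(start + config$batch_size - 1L, n)]
      B <- length(bidx)
      yb <- y[bidx]
      Y <- cbind(1 - yb, yb, deparse.level = 0)
      grads <- list()

      if (use_tga) {
        fw <- topo_head_forward(params, config, H_chem, H_dise,
                                pairs[bidx, , drop = FALSE], n_r)
        loss_t <- ce_loss(fw$p, yb)
        dlog <- (fw$p - Y) / B
        grads <- c(grads, topo_head_backward(fw, params, config, dlog))
        tot_t <- tot_t + loss_t
      }
      if (use_scpa) {
        Xb <- X_att_all[, , , bidx, drop = FALSE]
        fa <- scc_head_forward(params, sccp, config, Xb)
        loss_a <- ce_loss(fa$p, yb)
        dlog <- (fa$p - Y) / B
        grads <- c(grads, scc_head_backward(fa, params, sccp, config, dlog))
        tot_a <- tot_a + loss_a
      }
      params <- adam_step(opt, params, grads)
    }
    tot <- tot_t + tot_a
    log[nrow(log) + 1L, ] <- list(ep, tot, tot_t, tot_a)
    if (!is.finite(tot)) stop_input("head training diverged at epoch %d", ep)
  }

  structure(list(params = params, scc = sccp, config = config,
                 H_chem = H_chem, H_dise = H_dise, topo = topo,
                 dataset = dataset, head_log = log,
                 n_drugs = n_r, n_side_effects = n_s),
            class = "adr_model")
}

topo_head_forward <- function(params, config, H_chem, H_dise, pairs, n_r) {
  B <- nrow(pairs)
  rows <- c(pairs[, 1L], n_r + pairs[, 2L])
  Hc <- H_chem[rows, , drop = FALSE]
  Hd <- H_dise[rows, , drop = FALSE]
  if (config$use_rla) {
    fc <- attention_forward(Hc, list(W = params$att_cW, b = params$att_cb))
    fd <- attention_forward(Hd, list(W = params$att_dW, b = params$att_db))
    fused <- (fc$alpha * Hc + Hc) + (fd$alpha * Hd + Hd)
  } else {
    fc <- fd <- NULL
    fused <- Hc + Hd
  }
  X <- topo_batch_input(fused, B)
  conv <- topo_conv_forward(X, list(W1 = params$t1_W, b1 = params$t1_b,
                                    W2 = params$t2_W, b2 = params$t2_b))
  z <- flatten_cols(conv$out)
  p <- head_softmax_cols(z, params$tf_W, params$tf_b)
  list(p = p, z = z, conv = conv, fc = fc, fd = fd, Hc = Hc, Hd = Hd,
       B = B, X = X)
}

topo_head_backward <- function(fw, params, config, dlog) {
  dlt <- t(dlog)
  g <- list(tf_W = tcrossprod(dlt, fw$z), tf_b = colSums(dlog))
  dmaps <- crossprod(params$tf_W, dlt)
  dim(dmaps) <- dim(fw$conv$out)
  cb <- topo_conv_backward(fw$conv, list(W1 = params$t1_W, W2 = params$t2_W),
                           dmaps, need_dx = config$use_rla)
  g$t1_W <- cb$W1; g$t1_b <- cb$b1; g$t2_W <- cb$W2; g$t2_b <- cb$b2
  if (config$use_rla) {
    B <- fw$B
    dX <- cb$dX  # [1,2,n_f,B]
    drows <- rbind(t(dX[1L, 1L, , , drop = TRUE]),
                   t(dX[1L, 2L, , , drop = TRUE]))
    if (B == 1L) {
      drows <- rbind(matrix(dX[1L, 1L, , 1L], 1L),
                     matrix(dX[1L, 2L, , 1L], 1L))
    }
    # d fused / d alpha = H; residual terms carry no parameter gradient
    ga <- attention_backward(fw$fc, drows * fw$Hc)
    gb <- attention_backward(fw$fd, drows * fw$Hd)
    g$att_cW <- ga$W; g$att_cb <- ga$b
    g$att_dW <- gb$W; g$att_db <- gb$b
  }
  g
}

scc_head_forward <- function(params, sccp, config, Xb) {
  par <- sccp
  for (nm in setdiff(names(sccp), "latent_pool")) par[[nm]] <- params[[nm]]
  fw <- scc_forward(Xb, par, config$use_calibration)
  z <- flatten_cols(fw$out)
  p <- head_softmax_cols(z, params$af_W, params$af_b)
  list(p = p, z = z, fw = fw, par = par)
}

scc_head_backward <- function(fa, params, sccp, config, dlog) {
  dlt <- t(dlog)
  g <- list(af_W = tcrossprod(dlt, fa$z), af_b = colSums(dlog))
  dmaps <- crossprod(params$af_W, dlt)
  dim(dmaps) <- dim(fa$fw$out)
  gs <- scc_backward(fa$fw, fa$par, dmaps)
  c(g, gs)
}

#' Score drug/side-effect pairs with a trained model
#'
#' @param model an `adr_model` from [train_model()].
#' @param is,js parallel vectors of drug and side-effect indices.
#' @param chunk scoring batch size.
#' @return data frame with `score_topo`, `score_att` and the fused
#'   `score` (effective lambda respects the ablation switches).
#' @export
score_pairs <- function(model, is, js, chunk = 512L) {
  config <- model$config
  n <- length(is)
  lam <- effective_lambda(config)
  p_topo <- p_att <- rep(NA_real_, n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    if (config$use_tga) {
      fw <- topo_head_forward(model$params, config, model$H_chem,
                              model$H_dise,
                              cbind(is[idx], js[idx]), model$n_drugs)
      p_topo[idx] <- fw$p[, 2L]
    }
    if (config$use_scpa) {
      Xb <- build_pair_attr_batch(model$dataset$M_chem,
                                  model$dataset$M_dise, model$dataset$S,
                                  model$O_train %||% model$dataset$O,
                                  is[idx], js[idx])
      fa <- scc_head_forward(model$params, model$scc, config, Xb)
      p_att[idx] <- fa$p[, 2L]
    }
  }
  score <- fuse_scores(ifelse(is.na(p_topo), 0, p_topo),
                       ifelse(is.na(p_att), 0, p_att), lam)
  data.frame(score_topo = p_topo, score_att = p_att, score = score)
}

#' @export
print.adr_model <- function(x, ...) {
  cat(sprintf(
    "<adr_model: %d drugs x %d side effects; branches: %s%s; lambda = %.2f>\n",
    x$n_drugs, x$n_side_effects,
    if (x$config$use_tga) "topology " else "",
    if (x$config$use_scpa) "attribute" else "",
    effective_lambda(x$config)))
  invisible(x)
}
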