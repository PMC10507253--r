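# Representation-level attention over the two per-view embeddings and the
# convolutional topology branch that scores a drug/side-effect pair.

#' Attention parameters for one graph view
#'
#' One weight matrix and bias shared by all nodes of the view (feature- or
#' representation-level attention): the score vector of a node is
#' `LeakyReLU(W %*% h + b)`, softmax-normalised over features.
#'
#' @param n_f embedding width.
#' @return list with `W` (`n_f x n_f`) and `b` (length `n_f`).
#' @export
attention_params <- function(n_f) {
  list(W = glorot(c(n_f, n_f)), b = numeric(n_f))
}

#' Normalised per-feature attention weights
#'
#' @param H_row a node embedding row (or a matrix of rows).
#' @param params from [attention_params()].
#' @param slope LeakyReLU negative slope.
#' @return matrix of attention weights, one row per node, rows sum to 1.
#' @export
attention_scores <- function(H_row, params, slope = 0.01) {
  H <- if (is.matrix(H_row)) H_row else matrix(H_row, nrow = 1L)
  check_finite(H, "attention input")
  pre <- H %*% t(params$W) +
    matrix(params$b, nrow(H), length(params$b), byrow = TRUE)
  softmax_rows(leaky_relu(pre, slope))
}

# internal batched forward keeping the pre-activations for backprop
attention_forward <- function(H, params, slope = 0.01) {
  pre <- H %*% t(params$W) +
    matrix(params$b, nrow(H), length(params$b), byrow = TRUE)
  s <- leaky_relu(pre, slope)
  alpha <- softmax_rows(s)
  list(alpha = alpha, pre = pre, H = H, slope = slope)
}

attention_backward <- function(fw, dalpha) {
  ds <- fw$alpha * (dalpha - rowSums(dalpha * fw$alpha))
  dpre <- ds * dleaky_relu(fw$pre, fw$slope)
  list(W = t(dpre) %*% fw$H, b = colSums(dpre))
}

#' Fuse the two per-view topological embeddings
#'
#' Per node `i`, the fused embedding is
#' `h_i = (a_i * H_i_chem + H_i_chem) + (b_i * H_i_dise + H_i_dise)`
#' where `a_i`, `b_i` are the per-view attention weights and `*` the
#' elementwise product; the bare terms are the residual connections.
#' With `use_rla = FALSE` (ablation) the attention terms are dropped and
#' the fusion reduces to `H_chem + H_dise`.
#'
#' @param H_chem,H_dise `N_v x N_f` embedding matrices.
#' @param params_chem,params_dise per-view [attention_params()].
#' @param use_rla logical; disable to ablate representation-level attention.
#' @param slope LeakyReLU negative slope.
#' @return fused `N_v x N_f` matrix.
#' @export
fuse_views <- function(H_chem, H_dise, params_chem = NULL,
                       params_dise = NULL, use_rla = TRUE, slope = 0.01) {
  if (!all(dim(H_chem) == dim(H_dise))) {
    stop_input("view embeddings must share their shape")
  }
  if (!use_rla || is.null(params_chem)) {
    return(H_chem + H_dise)
  }
  a <- attention_scores(H_chem, params_chem, slope)
  b <- attention_scores(H_dise, params_dise, slope)
  (a * H_chem + H_chem) + (b * H_dise + H_dise)
}

#' Per-pair topological embedding
#'
#' Stacks the fused embedding row of drug `i` on top of the row of side
#' effect `j` (stored at row `n_drugs + j`).
#'
#' @param H_en fused embedding (`(N_r+N_s) x N_f`).
#' @param i drug index (1-based).
#' @param j side-effect index (1-based).
#' @param n_drugs number of drug rows `N_r`.
#' @return `2 x N_f` matrix `X_topo`.
#' @export
pair_topo_embedding <- function(H_en, i, j, n_drugs) {
  n_s <- nrow(H_en) - n_drugs
  if (i < 1L || i > n_drugs) stop_input("drug index %d out of range", i)
  if (j < 1L || j > n_s) stop_input("side-effect index %d out of range", j)
  rbind(H_en[i, ], H_en[n_drugs + j, ])
}

#' Convolution parameters of the topology branch
#'
#' Two convolution-pooling stages with 2 x 2 kernels; the second stage
#' convolves height-1 maps with 1 x 2 kernels, and average pooling always
#' halves the width.
#'
#' @param filters filter counts of the two stages.
#' @return list with `W1`, `b1`, `W2`, `b2`.
#' @export
topo_conv_params <- function(filters = c(16L, 32L)) {
  list(W1 = glorot(c(filters[1L], 1L, 2L, 2L)), b1 = numeric(filters[1L]),
       W2 = glorot(c(filters[2L], filters[1L], 1L, 2L)),
       b2 = numeric(filters[2L]))
}

# internal batched forward through conv-pool-conv-pool
topo_conv_forward <- function(X, par) {
  c1 <- conv2d_forward(X, par$W1, par$b1, "valid")
  r1 <- relu(c1$out)
  p1 <- avgpool2d_forward(r1, min(dim(r1)[2], 2L), 2L)
  c2 <- conv2d_forward(p1$out, par$W2, par$b2, "valid")
  r2 <- relu(c2$out)
  p2 <- avgpool2d_forward(r2, min(dim(r2)[2], 2L), 2L)
  list(out = p2$out, c1 = c1, r1pre = c1$out, p1 = p1, c2 = c2,
       r2pre = c2$out, p2 = p2)
}

topo_conv_backward <- function(fw, par, dout, need_dx = TRUE) {
  d <- avgpool2d_backward(fw$p2, dout)
  d <- relu_bwd_cpp(d, fw$r2pre)
  b2 <- conv2d_backward(fw$c2, par$W2, d)
  d <- avgpool2d_backward(fw$p1, b2$dx)
  d <- relu_bwd_cpp(d, fw$r1pre)
  b1 <- conv2d_backward(fw$c1, par$W1, d, need_dx = need_dx)
  list(dX = b1$dx, W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db)
}

#' Topology-branch convolutional encoding of a pair embedding
#'
#' Applies the two convolution-pooling stages to `X_topo` and returns the
#' pooled feature map `Z_topo` (channels x height x width).
#'
#' @param X_topo `2 x N_f` pair embedding from [pair_topo_embedding()].
#' @param params from [topo_conv_params()].
#' @return 3-d array `Z_topo`.
#' @export
topo_conv <- function(X_topo, params) {
  check_finite(X_topo, "X_topo")
  X <- aperm(array(X_topo, dim = c(2L, ncol(X_topo), 1L, 1L)),
             c(3L, 1L, 2L, 4L))
  out <- topo_conv_forward(X, params)$out
  array(out, dim = dim(out)[1:3])
}
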