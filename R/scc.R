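# Pairwise attribute branch: per drug/side-effect pair, the similarity and
# association rows of both graph views form a two-channel tensor that a
# self-calibrated convolutional module encodes. A downsampled latent path
# (larger receptive field) gates the original-resolution path through a
# sigmoid calibration weight; an unpadded original path preserves edge
# information; their maps are concatenated channel-wise.

#' Per-pair attribute embedding
#'
#' For drug `i` and side effect `j`, row 1 of each channel concatenates
#' drug `i`'s similarities to all drugs with its association row
#' (`[M_i || O_i]`), and row 2 concatenates side effect `j`'s association
#' column with its similarity row (`[t(O)_j || S_j]`). Channel 1 uses the
#' chemical drug similarity, channel 2 the disease-based one.
#'
#' @param M_chem,M_dise drug-drug similarity matrices.
#' @param S side-effect similarity matrix.
#' @param O binary association matrix.
#' @param i,j drug and side-effect indices (1-based).
#' @return list with `X_chem`, `X_dise` (`2 x (N_r+N_s)` matrices) and
#'   `X_att` (array `2 x 2 x (N_r+N_s)`, channel first).
#' @export
build_pair_attr <- function(M_chem, M_dise, S, O, i, j) {
  n_r <- nrow(O); n_s <- ncol(O)
  if (i < 1L || i > n_r) stop_input("drug index %d out of range", i)
  if (j < 1L || j > n_s) stop_input("side-effect index %d out of range", j)
  x1_chem <- c(unclass(M_chem)[i, ], unclass(O)[i, ])
  x1_dise <- c(unclass(M_dise)[i, ], unclass(O)[i, ])
  x2 <- c(unclass(O)[, j], unclass(S)[j, ])
  X_chem <- rbind(x1_chem, x2, deparse.level = 0)
  X_dise <- rbind(x1_dise, x2, deparse.level = 0)
  X_att <- array(0, dim = c(2L, 2L, n_r + n_s))
  X_att[1L, , ] <- X_chem
  X_att[2L, , ] <- X_dise
  list(X_chem = X_chem, X_dise = X_dise, X_att = X_att)
}

# batched builder: returns [2, 2, N_r+N_s, B]
build_pair_attr_batch <- function(M_chem, M_dise, S, O, is, js) {
  n_r <- nrow(O); n_s <- ncol(O)
  Mc <- unclass(M_chem); Md <- unclass(M_dise)
  Ss <- unclass(S); Oo <- unclass(O)
  B <- length(is)
  x1c <- cbind(Mc[is, , drop = FALSE], Oo[is, , drop = FALSE])
  x1d <- cbind(Md[is, , drop = FALSE], Oo[is, , drop = FALSE])
  x2 <- cbind(t(Oo)[js, , drop = FALSE], Ss[js, , drop = FALSE])
  X <- array(0, dim = c(2L, 2L, n_r + n_s, B))
  X[1L, 1L, , ] <- t(x1c)
  X[1L, 2L, , ] <- t(x2)
  X[2L, 1L, , ] <- t(x1d)
  X[2L, 2L, , ] <- t(x2)
  X
}

#' Self-calibrated convolution parameters
#'
#' @param channels input channels of `X_att` (2: chem and dise views).
#' @param latent_filters filters of the latent-space convolution.
#' @param fusion_filters filters of the calibrated fusion convolution.
#' @param ori_filters filter counts of the two unpadded original-path
#'   convolutions.
#' @param latent_pool average-pooling factor along the width (the
#'   latent-space downscale).
#' @return parameter list; kernels are 2 x 2 except where a height-1 map
#'   forces 1 x 2.
#' @export
scc_params <- function(channels = 2L, latent_filters = 1L,
                       fusion_filters = 32L, ori_filters = c(16L, 32L),
                       latent_pool = 4L) {
  list(W_L = glorot(c(latent_filters, channels, 2L, 2L)),
       b_L = numeric(latent_filters),
       W_cal = glorot(c(channels, channels, 2L, 2L)),
       b_cal = numeric(channels),
       W_fus = glorot(c(fusion_filters, channels, 2L, 2L)),
       b_fus = numeric(fusion_filters),
       W_o1 = glorot(c(ori_filters[1L], channels, 2L, 2L)),
       b_o1 = numeric(ori_filters[1L]),
       W_o2 = glorot(c(ori_filters[2L], ori_filters[1L], 1L, 2L)),
       b_o2 = numeric(ori_filters[2L]),
       latent_pool = as.integer(latent_pool))
}

latent_forward <- function(X, par) {
  d <- dim(X)
  if (par$latent_pool > d[3]) {
    stop_input("latent pooling factor %d exceeds width %d",
               par$latent_pool, d[3])
  }
  ap <- avgpool2d_forward(X, 1L, par$latent_pool)
  cv <- conv2d_forward(ap$out, par$W_L, par$b_L, "same")
  rl <- relu(cv$out)
  bi <- bilinear_resize_forward(rl, d[2], d[3])
  list(out = bi$out, ap = ap, cv = cv, rlpre = cv$out, bi = bi)
}

latent_backward <- function(fw, par, dout) {
  d <- bilinear_resize_backward(fw$bi, dout)
  d <- relu_bwd_cpp(d, fw$rlpre)
  cb <- conv2d_backward(fw$cv, par$W_L, d, need_dx = FALSE)
  list(W_L = cb$dW, b_L = cb$db)
}

#' Latent (small feature space) path of the self-calibrated module
#'
#' Average-pools `X_att` along the width, convolves with ReLU, and maps
#' the result back to the original spatial shape by bilinear
#' interpolation (align-corners-false convention).
#'
#' @param X_att array `channels x height x width` (single pair) .
#' @param params from [scc_params()].
#' @return array with the latent filters as channels and `X_att`'s
#'   spatial shape.
#' @export
scc_latent_path <- function(X_att, params) {
  check_finite(X_att, "X_att")
  X <- as_nchw(X_att)
  out <- latent_forward(X, params)$out
  array(out, dim = dim(out)[1:3])
}

broadcast_channels <- function(Xp, channels) {
  d <- dim(Xp)
  if (d[1] == channels) return(Xp)
  if (d[1] != 1L) stop_input("cannot broadcast %d channels to %d", d[1],
                             channels)
  y <- array(0, dim = c(channels, d[2], d[3], d[4]))
  for (ch in seq_len(channels)) y[ch, , , ] <- Xp[1L, , , ]
  y
}

calibrate_forward <- function(X, Xp, par) {
  d <- dim(X)
  Xpb <- broadcast_channels(Xp, d[1])
  gate <- sigmoid(X + Xpb)
  cv <- conv2d_forward(X, par$W_cal, par$b_cal, "same")
  Ycal <- cv$out * gate
  fz <- conv2d_forward(Ycal, par$W_fus, par$b_fus, "same")
  Yatt_pre <- sigmoid(fz$out)
  pl <- avgpool2d_forward(Yatt_pre, min(d[2], 2L), 2L)
  list(out = pl$out, gate = gate, cv = cv, fz = fz, Yatt_pre = Yatt_pre,
       pl = pl, latent_channels = dim(Xp)[1])
}

calibrate_backward <- function(fw, par, dout) {
  d <- avgpool2d_backward(fw$pl, dout)
  d <- sigmoid_bwd_cpp(d, fw$Yatt_pre)
  fb <- conv2d_backward(fw$fz, par$W_fus, d)
  dYcal <- fb$dx
  dC <- dYcal * fw$gate
  cb <- conv2d_backward(fw$cv, par$W_cal, dC, need_dx = FALSE)
  dgate <- dYcal * fw$cv$out
  dsum <- sigmoid_bwd_cpp(dgate, fw$gate)
  # collapse the channel broadcast back onto the latent path
  dXp <- if (fw$latent_channels == dim(dsum)[1]) dsum else {
    y <- array(0, dim = c(1L, dim(dsum)[2], dim(dsum)[3], dim(dsum)[4]))
    for (c in seq_len(dim(dsum)[1])) y[1L, , , ] <- y[1L, , , ] + dsum[c, , , ]
    y
  }
  list(W_cal = cb$dW, b_cal = cb$db, W_fus = fb$dW, b_fus = fb$db,
       dXp = dXp)
}

#' Calibration of the original-space features by the latent path
#'
#' Forms the calibration weight
#' `Y_cal = (W_cal * X_att + b_cal) (x) sigmoid(X_att (+) X'_att)` and
#' fuses it through a convolution-pooling layer:
#' `Y_att = pool(sigmoid(W_fus * Y_cal + b_fus))`.
#'
#' @param X_att array `channels x height x width`.
#' @param X_att_prime output of [scc_latent_path()] (broadcast over
#'   channels if it has a single one).
#' @param params from [scc_params()].
#' @return calibrated feature map `Y_att`.
#' @export
scc_calibrate <- function(X_att, X_att_prime, params) {
  X <- as_nchw(X_att); Xp <- as_nchw(X_att_prime)
  if (!all(dim(X)[2:3] == dim(Xp)[2:3])) {
    stop_input("X_att and X'_att spatial shapes differ")
  }
  out <- calibrate_forward(X, Xp, params)$out
  array(out, dim = dim(out)[1:3])
}

original_forward <- function(X, par) {
  c1 <- conv2d_forward(X, par$W_o1, par$b_o1, "valid")
  r1 <- relu(c1$out)
  c2 <- conv2d_forward(r1, par$W_o2, par$b_o2, "valid")
  r2 <- relu(c2$out)
  list(out = r2, c1 = c1, c2 = c2)
}

original_backward <- function(fw, par, dout) {
  d <- relu_bwd_cpp(dout, fw$c2$out)
  b2 <- conv2d_backward(fw$c2, par$W_o2, d)
  d <- relu_bwd_cpp(b2$dx, fw$c1$out)
  b1 <- conv2d_backward(fw$c1, par$W_o1, d, need_dx = FALSE)
  list(W_o1 = b1$dW, b_o1 = b1$db, W_o2 = b2$dW, b_o2 = b2$db)
}

#' Original-space path of the self-calibrated module
#'
#' Two unpadded (valid) convolutions with ReLU; no padding is applied so
#' the pair tensor's edge information is preserved.
#'
#' @inheritParams scc_latent_path
#' @return feature map `Y_ori`.
#' @export
scc_original_path <- function(X_att, params) {
  X <- as_nchw(X_att)
  out <- original_forward(X, params)$out
  array(out, dim = dim(out)[1:3])
}

center_crop_width <- function(x, w_out) {
  w <- dim(x)[3]
  if (w == w_out) return(x)
  off <- (w - w_out) %/% 2L
  x[, , off + seq_len(w_out), , drop = FALSE]
}

scc_forward <- function(X, par, use_calibration = TRUE) {
  ori <- original_forward(X, par)
  if (!use_calibration) {
    return(list(out = ori$out, ori = ori, use_calibration = FALSE))
  }
  lat <- latent_forward(X, par)
  cal <- calibrate_forward(X, lat$out, par)
  wa <- dim(cal$out)[3]; wo <- dim(ori$out)[3]
  w <- min(wa, wo)
  Ya <- center_crop_width(cal$out, w)
  Yo <- center_crop_width(ori$out, w)
  out <- array(0, dim = c(dim(Ya)[1] + dim(Yo)[1], dim(Ya)[2], w,
                          dim(Ya)[4]))
  out[seq_len(dim(Ya)[1]), , , ] <- Ya
  out[dim(Ya)[1] + seq_len(dim(Yo)[1]), , , ] <- Yo
  list(out = out, ori = ori, lat = lat, cal = cal, w = w,
       ca = dim(Ya)[1], use_calibration = TRUE)
}

scc_backward <- function(fw, par, dout) {
  pad_width <- function(dx, w_full) {
    w <- dim(dx)[3]
    if (w == w_full) return(dx)
    off <- (w_full - w) %/% 2L
    full <- array(0, dim = c(dim(dx)[1], dim(dx)[2], w_full, dim(dx)[4]))
    full[, , off + seq_len(w), ] <- dx
    full
  }
  if (!fw$use_calibration) {
    g <- original_backward(fw$ori, par, dout)
    return(g)
  }
  ca <- fw$ca
  dYa <- dout[seq_len(ca), , , , drop = FALSE]
  dYo <- dout[ca + seq_len(dim(dout)[1] - ca), , , , drop = FALSE]
  g_ori <- original_backward(fw$ori, par,
                             pad_width(dYo, dim(fw$ori$out)[3]))
  g_cal <- calibrate_backward(fw$cal, par,
                              pad_width(dYa, dim(fw$cal$out)[3]))
  g_lat <- latent_backward(fw$lat, par, g_cal$dXp)
  c(g_ori, g_cal[c("W_cal", "b_cal", "W_fus", "b_fus")], g_lat)
}

#' Self-calibrated encoding of a pair attribute tensor
#'
#' Composes the latent, calibration and original paths and concatenates
#' `Y_att` and `Y_ori` along the channel axis (the wider map is
#' center-cropped to the narrower one). With `use_calibration = FALSE`
#' (ablation) only the original path is used.
#'
#' @inheritParams scc_latent_path
#' @param use_calibration logical ablation switch.
#' @return feature map `Z_att` (channels x height x width).
#' @export
scc_encode <- function(X_att, params, use_calibration = TRUE) {
  X <- as_nchw(X_att)
  out <- scc_forward(X, params, use_calibration)$out
  array(out, dim = dim(out)[1:3])
}
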