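# Minimal dense-tensor layer primitives with hand-written backward passes.
# Tensor convention throughout: array [channels, height, width, batch].
# Convolutions are computed as <= kh*kw shifted matrix products, which keeps
# everything in BLAS at the small kernel sizes (2 x 2) used here.

as_nchw <- function(x) {
  # promote [H,W] or [C,H,W] to [C,H,W,B]; no copy when already 4-d
  d <- dim(x)
  if (length(d) == 4L) return(x)
  d <- d %||% c(1L, length(x))
  if (length(d) == 2L) d <- c(1L, d)
  if (length(d) == 3L) d <- c(d, 1L)
  dim(x) <- d
  if (!is.double(x)) storage.mode(x) <- "double"
  x
}

conv2d_forward <- function(x, W, b = NULL, padding = c("valid", "same")) {
  padding <- match.arg(padding)
  x <- as_nchw(x)
  dx <- dim(x)
  dw <- dim(W); kh <- dw[3]; kw <- dw[4]
  if (dw[2] != dx[1]) stop_input("conv: %d input channels, filter expects %d",
                                 dx[1], dw[2])
  if (padding == "valid" && (dx[2] < kh || dx[3] < kw)) {
    stop_input("conv: input %dx%d smaller than kernel %dx%d", dx[2], dx[3],
               kh, kw)
  }
  same <- padding == "same"
  col <- im2col_cpp(x, kh, kw, same)
  ho <- if (same) dx[2] else dx[2] - kh + 1L
  wo <- if (same) dx[3] else dx[3] - kw + 1L
  y <- matrix(W, dw[1], dw[2] * kh * kw) %*% col
  if (!is.null(b)) y <- y + as.vector(b)
  dim(y) <- c(dw[1], ho, wo, dx[4])
  list(out = y, col = col, padding = padding, in_dim = dx)
}

conv2d_backward <- function(cache, W, dy, need_dx = TRUE) {
  dw <- dim(W); kh <- dw[3]; kw <- dw[4]
  dym <- dy; dim(dym) <- c(dw[1], length(dy) / dw[1])
  dW <- array(tcrossprod(dym, cache$col), dw)
  db <- rowSums(dym)
  dx <- NULL
  if (need_dx) {
    dcol <- crossprod(matrix(W, dw[1], dw[2] * kh * kw), dym)
    dx <- col2im_cpp(dcol, cache$in_dim, kh, kw, cache$padding == "same")
  }
  list(dx = dx, dW = dW, db = db)
}

# Non-overlapping pooling in floor mode (trailing remainder dropped).
avgpool2d_forward <- function(x, ph, pw) {
  x <- as_nchw(x)
  d <- dim(x); ho <- d[2] %/% ph; wo <- d[3] %/% pw
  if (ho < 1L || wo < 1L) stop_input("pool window %dx%d exceeds input %dx%d",
                                     ph, pw, d[2], d[3])
  list(out = avgpool_fwd_cpp(x, ph, pw), in_dim = d, ph = ph, pw = pw)
}

avgpool2d_backward <- function(cache, dy) {
  avgpool_bwd_cpp(dy, cache$in_dim, cache$ph, cache$pw)
}

# Interpolation matrix for 1-D linear resize, align-corners = FALSE with
# edge clamping (the convention matched by the bilinear examples).
resize_matrix <- function(n_in, n_out) {
  R <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    pos <- (i - 0.5) * n_in / n_out - 0.5
    pos <- min(max(pos, 0), n_in - 1)
    lo <- floor(pos); frac <- pos - lo
    hi <- min(lo + 1, n_in - 1)
    R[i, lo + 1] <- R[i, lo + 1] + (1 - frac)
    R[i, hi + 1] <- R[i, hi + 1] + frac
  }
  R
}

apply_axis <- function(x, R, axis) {
  # multiply resize matrix R along axis 2 (height) or 3 (width)
  d <- dim(x)
  perm <- if (axis == 2L) c(2L, 1L, 3L, 4L) else c(3L, 1L, 2L, 4L)
  xp <- aperm(x, perm)
  dp <- dim(xp)
  dim(xp) <- c(dp[1], prod(dp[-1]))
  y <- R %*% xp
  dim(y) <- c(nrow(R), dp[-1])
  aperm(y, order(perm))
}

bilinear_resize_forward <- function(x, h_out, w_out) {
  x <- as_nchw(x)
  d <- dim(x)
  Rh <- resize_matrix(d[2], h_out)
  Rw <- resize_matrix(d[3], w_out)
  y <- apply_axis(apply_axis(x, Rh, 2L), Rw, 3L)
  list(out = y, Rh = Rh, Rw = Rw)
}

bilinear_resize_backward <- function(cache, dy) {
  apply_axis(apply_axis(dy, t(cache$Rw), 3L), t(cache$Rh), 2L)
}

relu <- function(x) relu_cpp(x)
leaky_relu <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)
dleaky_relu <- function(x, slope = 0.01) ifelse(x > 0, 1, slope)
sigmoid <- function(x) sigmoid_cpp(x)

# row-wise softmax of a matrix of logits
softmax_rows <- function(z) {
  z <- as.matrix(z)
  e <- exp(z - apply(z, 1L, max))
  e / rowSums(e)
}
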