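# Shared fixtures: everything is generated in code, nothing on disk.

tiny_dataset <- function(seed = 3L, n_drugs = 20L, n_side_effects = 30L) {
  generate_dataset(synthetic_config(n_drugs = n_drugs,
                                    n_side_effects = n_side_effects,
                                    n_blocks = 2L, seed = seed))
}

tiny_config <- function(seed = 5L, ...) {
  defaults <- list(n_f = 8L, encoder_dims = c(16L, 8L),
                   decoder_hidden = 16L, disc_dims = c(16L, 8L),
                   gan_epochs = 30L, head_epochs = 8L, batch_size = 64L,
                   seed = seed)
  do.call(train_config, utils::modifyList(defaults, list(...)))
}

# independent literal-loop Laplace normalisation oracle
laplace_oracle <- function(A) {
  n <- nrow(A)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- sum(A[i, ])
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- A[i, j] / (sqrt(d[i]) * sqrt(d[j]))
    }
  }
  out
}

# literal sliding-window valid 2-d convolution oracle over [C,H,W] arrays
conv_oracle <- function(x, W, b = NULL) {
  cin <- dim(x)[1]; h <- dim(x)[2]; w <- dim(x)[3]
  cout <- dim(W)[1]; kh <- dim(W)[3]; kw <- dim(W)[4]
  ho <- h - kh + 1L; wo <- w - kw + 1L
  out <- array(0, c(cout, ho, wo))
  for (co in seq_len(cout)) {
    for (i in seq_len(ho)) {
      for (j in seq_len(wo)) {
        acc <- if (is.null(b)) 0 else b[co]
        for (ci in seq_len(cin)) {
          for (di in seq_len(kh)) {
            for (dj in seq_len(kw)) {
              acc <- acc + W[co, ci, di, dj] * x[ci, i + di - 1L, j + dj - 1L]
            }
          }
        }
        out[co, i, j] <- acc
      }
    }
  }
  out
}

# O(n^2) pairwise-concordance AUC oracle with half-credit ties
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (n in neg) {
      tot <- tot + (p > n) + 0.5 * (p == n)
    }
  }
  tot / (length(pos) * length(neg))
}

# central-difference gradient check for a named parameter list
numgrad_check <- function(lossf, params, grads, n_probe = 3L, eps = 1e-6,
                          tol = 1e-5) {
  for (nm in names(grads)) {
    if (is.null(grads[[nm]])) next
    idx <- sample(length(params[[nm]]), min(n_probe, length(params[[nm]])))
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (lossf(pp) - lossf(pm)) / (2 * eps)
      expect_equal(as.numeric(grads[[nm]][i]), as.numeric(num), tolerance = tol,
                   label = sprintf("analytic grad %s[%d]", nm, i))
    }
  }
}
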