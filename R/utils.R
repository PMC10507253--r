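#' @keywords internal
#' @useDynLib adrgraph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Deterministic sub-seed derivation: one user-facing seed fans out into
# independent streams (one per matrix / per training stage) so adding a new
# consumer never perturbs earlier draws. Kept below 2^31 - 1.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% 2147483629
  }
  as.integer((as.numeric(seed) %% 2147483629 * 7919 + h) %% 2147483629 + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

# Glorot-style uniform initialisation used for every weight matrix/filter.
glorot <- function(dims) {
  fan <- if (length(dims) == 2L) sum(dims) else prod(dims[-1L]) + dims[1L]
  limit <- sqrt(6 / fan)
  array(stats::runif(prod(dims), -limit, limit), dim = dims)
}

#' Adam optimiser state
#'
#' Creates and applies Adam updates for a named list of parameter arrays.
#' Used by every training loop in the package.
#'
#' @param params named list of numeric arrays.
#' @param lr learning rate.
#' @param beta1,beta2 moment decay rates.
#' @param eps numerical stabiliser.
#' @return an environment holding optimiser state with an `update(grads)`
#'   function returning the updated parameter list.
#' @keywords internal
adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  st$v <- st$m
  st$t <- 0L
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st
}

adam_step <- function(st, params, grads) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  corr1 <- 1 - b1^st$t
  corr2 <- 1 - b2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    mhat <- st$m[[nm]] / corr1
    vhat <- st$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - st$lr * mhat / (sqrt(vhat) + st$eps)
  }
  params
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_input("non-finite values in %s", what)
  invisible(x)
}
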