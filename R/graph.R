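#' Similarity matrix constructor
#'
#' Validates and tags a square similarity matrix. Entries must lie in
#' \[0, 1\], the matrix must be symmetric, and the diagonal must equal 1.
#'
#' @param values square numeric matrix.
#' @param kind one of `"chem"`, `"dise"`, `"side_effect"`.
#' @param entity_ids optional character vector of row/column identifiers;
#'   defaults to existing dimnames or `e1..en`.
#' @return the matrix with class `adr_similarity` and attributes `kind`.
#' @export
similarity_matrix <- function(values, kind = c("chem", "dise", "side_effect"),
                              entity_ids = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    stop_input("similarity matrix must be square")
  }
  if (any(values < -1e-12) || any(values > 1 + 1e-12)) {
    stop_input("similarity values must lie in [0, 1]")
  }
  if (max(abs(values - t(values))) > 1e-8) {
    stop_input("similarity matrix must be symmetric")
  }
  if (max(abs(diag(values) - 1)) > 1e-8) {
    stop_input("similarity diagonal must equal 1")
  }
  ids <- entity_ids %||% rownames(values) %||%
    paste0("e", seq_len(nrow(values)))
  dimnames(values) <- list(ids, ids)
  structure(values, class = c("adr_similarity", class(values)),
            kind = kind)
}

#' Association matrix constructor
#'
#' Validates a binary drug (rows) by side-effect (columns) matrix.
#'
#' @param values binary numeric matrix.
#' @return the matrix with class `adr_association`.
#' @export
association_matrix <- function(values) {
  if (!is.matrix(values)) stop_input("association matrix must be a matrix")
  if (!all(values %in% c(0, 1))) {
    stop_input("association matrix entries must be 0 or 1")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("drug", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("se", seq_len(ncol(values)))
  }
  structure(values, class = c("adr_association", class(values)))
}

#' Cosine similarity from binary feature profiles
#'
#' Computes pairwise cosine similarity between entity rows of a binary (or
#' nonnegative) feature matrix, e.g. drug chemical-substructure
#' fingerprints. The diagonal is forced to 1; pairs involving an all-zero
#' row get off-diagonal similarity 0 by convention.
#'
#' @param profiles numeric matrix, rows = entities, columns = features.
#' @param kind passed to [similarity_matrix()].
#' @return an `adr_similarity` matrix.
#' @export
#' @examples
#' p <- rbind(a = c(1, 1, 0), b = c(1, 0, 1))
#' cosine_similarity(p)["a", "b"] # 0.5
cosine_similarity <- function(profiles, kind = "chem") {
  if (!is.matrix(profiles) || nrow(profiles) == 0L || ncol(profiles) == 0L) {
    stop_input("profiles must be a non-empty matrix")
  }
  if (any(profiles < 0)) stop_input("profiles must be nonnegative")
  if (all(profiles == 0)) stop_input("profiles must contain a nonzero row")
  nrm <- sqrt(rowSums(profiles^2))
  sim <- tcrossprod(profiles)
  denom <- outer(nrm, nrm)
  sim <- ifelse(denom > 0, sim / denom, 0)
  sim[sim > 1] <- 1  # guard rounding
  sim <- (sim + t(sim)) / 2
  diag(sim) <- 1
  rownames(sim) <- colnames(sim) <- rownames(profiles)
  similarity_matrix(sim, kind = kind)
}

#' Jaccard index between two sets
#'
#' Default measure for set-based similarity; both-empty pairs return 0.
#'
#' @param a,b vectors interpreted as sets.
#' @return scalar in \[0, 1\].
#' @export
jaccard_index <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Set-membership similarity
#'
#' Pairwise similarity between entities described by association sets
#' (e.g. the diseases treated by each drug, or the drugs causing each side
#' effect): entities sharing more members are more similar. The measure is
#' pluggable; the default is the Jaccard index.
#'
#' @param memberships list of vectors, one set per entity (possibly empty).
#' @param kind passed to [similarity_matrix()].
#' @param measure function(a, b) returning a similarity in \[0, 1\].
#' @return an `adr_similarity` matrix with unit diagonal.
#' @export
#' @examples
#' set_similarity(list(d1 = c("a", "b", "c"), d2 = c("b", "c", "d")))[1, 2]
set_similarity <- function(memberships, kind = "dise",
                           measure = jaccard_index) {
  if (!is.list(memberships)) stop_input("memberships must be a list of sets")
  n <- length(memberships)
  sim <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        v <- measure(memberships[[i]], memberships[[j]])
        sim[i, j] <- v
        sim[j, i] <- v
      }
    }
  }
  ids <- names(memberships) %||% paste0("e", seq_len(n))
  rownames(sim) <- colnames(sim) <- ids
  similarity_matrix(sim, kind = kind)
}

#' Build a drug/side-effect heterogeneous graph
#'
#' Assembles the block adjacency matrix
#' `A = [[M, O], [t(O), S]]` over `N_r` drug and `N_s` side-effect nodes.
#' `A` doubles as the node attribute matrix `H`: row i concatenates node
#' i's within-type similarities and cross-type associations. Self-loops
#' are supplied by the unit similarity diagonal, so every node has
#' positive degree whenever its similarity row is nonzero.
#'
#' @param M drug-drug similarity (`N_r x N_r`).
#' @param S side-effect similarity (`N_s x N_s`).
#' @param O binary association matrix (`N_r x N_s`).
#' @param view `"chem"` or `"dise"`, recorded on the result.
#' @return an object of class `adr_hetero_graph`: list with `adjacency`,
#'   `attributes` (identical), `view`, `n_drugs`, `n_side_effects`,
#'   `n_nodes`.
#' @export
build_hetero_graph <- function(M, S, O, view = c("chem", "dise")) {
  view <- match.arg(view)
  n_r <- nrow(M); n_s <- nrow(S)
  if (ncol(M) != n_r || ncol(S) != n_s) stop_input("M and S must be square")
  if (nrow(O) != n_r || ncol(O) != n_s) {
    stop_input("O must be %d x %d, got %d x %d", n_r, n_s, nrow(O), ncol(O))
  }
  A <- rbind(cbind(unclass(M), unclass(O)),
             cbind(t(unclass(O)), unclass(S)))
  ids <- c(rownames(M) %||% paste0("drug", seq_len(n_r)),
           rownames(S) %||% paste0("se", seq_len(n_s)))
  dimnames(A) <- list(ids, ids)
  structure(
    list(adjacency = A, attributes = A, view = view,
         n_drugs = n_r, n_side_effects = n_s, n_nodes = n_r + n_s),
    class = "adr_hetero_graph"
  )
}

#' @export
print.adr_hetero_graph <- function(x, ...) {
  cat(sprintf("<adr_hetero_graph view=%s: %d drugs + %d side effects = %d nodes>\n",
              x$view, x$n_drugs, x$n_side_effects, x$n_nodes))
  invisible(x)
}

#' Symmetric Laplace normalisation of an adjacency matrix
#'
#' Computes `D^(-1/2) A D^(-1/2)` with `D_ii = sum_j A_ij`, the standard
#' rescaling that keeps graph convolution numerically stable. Accepts an
#' `adr_hetero_graph` or a plain nonnegative matrix.
#'
#' @param graph an `adr_hetero_graph` or a square nonnegative matrix.
#' @return the normalised adjacency matrix.
#' @export
laplace_normalize <- function(graph) {
  A <- if (inherits(graph, "adr_hetero_graph")) graph$adjacency else graph
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop_input("adjacency must be square")
  if (any(A < 0)) stop_input("adjacency must be nonnegative")
  d <- rowSums(A)
  bad <- which(d <= 0)
  if (length(bad) > 0L) {
    stop_input("zero-degree node(s) at index: %s",
               paste(bad, collapse = ", "))
  }
  dinv <- 1 / sqrt(d)
  At <- A * tcrossprod(dinv)  # dinv_i * A_ij * dinv_j
  dimnames(At) <- dimnames(A)
  At
}
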