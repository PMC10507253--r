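# Five-fold cross-validation protocol and ranking metrics.

#' Create a cross-validation fold split
#'
#' Positives are shuffled and partitioned into `n_folds` subsets of equal
#' size (within one). Per fold, the held-out subset is the positive test
#' set; training negatives are sampled (without replacement, balanced:
#' one per training positive) from the unobserved pairs, and every
#' remaining negative is a test negative, reproducing the heavy test-time
#' class imbalance.
#'
#' @param O binary association matrix.
#' @param seed RNG seed; the split is reproducible.
#' @param n_folds number of folds.
#' @return object of class `adr_fold_split`: list of `folds`, each with
#'   integer index-pair matrices `train_pos`, `test_pos`, `train_neg`,
#'   `test_neg`.
#' @export
make_folds <- function(O, seed = 1L, n_folds = 5L) {
  O <- unclass(O)
  pos <- which(O == 1, arr.ind = TRUE)
  neg <- which(O == 0, arr.ind = TRUE)
  dimnames(pos) <- dimnames(neg) <- NULL
  if (nrow(pos) < n_folds) {
    stop_input("need at least %d positives for %d folds", n_folds, n_folds)
  }
  folds <- with_seed(derive_seed(seed, "folds"), {
    assignment <- rep(seq_len(n_folds), length.out = nrow(pos))
    assignment <- assignment[sample.int(nrow(pos))]
    lapply(seq_len(n_folds), function(k) {
      test_pos <- pos[assignment == k, , drop = FALSE]
      train_pos <- pos[assignment != k, , drop = FALSE]
      ni <- sample.int(nrow(neg), min(nrow(train_pos), nrow(neg)))
      list(train_pos = train_pos, test_pos = test_pos,
           train_neg = neg[ni, , drop = FALSE],
           test_neg = neg[-ni, , drop = FALSE])
    })
  })
  structure(list(folds = folds, n_folds = n_folds, seed = seed,
                 n_drugs = nrow(O), n_side_effects = ncol(O)),
            class = "adr_fold_split")
}

#' AUC and AUPR of a score vector
#'
#' AUC is rank-based (Mann-Whitney; ties get half credit). AUPR is the
#' step integration of the precision-recall curve (average precision):
#' walking down the score-sorted list, each positive contributes the
#' precision at its position.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 vector.
#' @return named vector `c(auc, aupr)`.
#' @export
auc_aupr <- function(scores, labels) {
  if (length(scores) != length(labels)) stop_input("length mismatch")
  if (!all(labels %in% c(0, 1))) stop_input("labels must be 0 or 1")
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0L || nn == 0L) {
    stop_input("need at least one positive and one negative")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
  ord <- order(-scores, seq_along(scores))
  yo <- labels[ord]
  tp <- cumsum(yo)
  prec <- tp / seq_along(yo)
  aupr <- sum(prec[yo == 1]) / np
  c(auc = auc, aupr = aupr)
}

#' Recall within the top-k ranked candidates
#'
#' For each drug, its test-pair candidate side effects are ranked by
#' score (stable ties: score, then side-effect index); recall at `k` is
#' the fraction of that drug's test positives ranked in the top `k`. The
#' default aggregation averages per-drug recall over drugs with at least
#' one test positive; `mode = "pooled"` instead ranks all test pairs
#' jointly.
#'
#' @param scores_df data frame with `drug_idx`, `se_idx`, `score`,
#'   `label` (as produced by [train_model()]).
#' @param k_values vector of positive cutoffs.
#' @param mode `"per_drug"` or `"pooled"`.
#' @return named numeric vector of recall values, nondecreasing in `k`.
#' @export
recall_at_k <- function(scores_df, k_values = seq(30L, 240L, by = 30L),
                        mode = c("per_drug", "pooled")) {
  mode <- match.arg(mode)
  if (any(k_values <= 0)) stop_input("k must be positive")
  k_values <- as.integer(k_values)
  if (mode == "pooled") {
    ord <- order(-scores_df$score, scores_df$se_idx)
    yo <- scores_df$label[ord]
    np <- sum(yo)
    out <- vapply(k_values, function(k) sum(yo[seq_len(min(k, length(yo)))]) /
                    np, numeric(1))
  } else {
    per_drug <- lapply(split(scores_df, scores_df$drug_idx), function(d) {
      if (sum(d$label) == 0L) return(NULL)
      ord <- order(-d$score, d$se_idx)
      yo <- d$label[ord]
      vapply(k_values, function(k) {
        sum(yo[seq_len(min(k, length(yo)))]) / sum(yo)
      }, numeric(1))
    })
    per_drug <- per_drug[!vapply(per_drug, is.null, logical(1))]
    if (length(per_drug) == 0L) stop_input("no drug has a test positive")
    out <- colMeans(do.call(rbind, per_drug))
  }
  stats::setNames(out, paste0("recall@", k_values))
}

#' Per-drug AUC and AUPR table
#'
#' Drugs lacking a test positive or a test negative are skipped with a
#' message.
#'
#' @param scores_df as in [recall_at_k()].
#' @return data frame keyed by `drug_idx` with `auc`, `aupr`, `n_pos`,
#'   `n_neg`.
#' @export
per_drug_metrics <- function(scores_df) {
  rows <- lapply(split(scores_df, scores_df$drug_idx), function(d) {
    np <- sum(d$label == 1); nn <- sum(d$label == 0)
    if (np == 0L || nn == 0L) {
      message(sprintf("skipping drug %s: %d positives / %d negatives",
                      d$drug_idx[1L], np, nn))
      return(NULL)
    }
    m <- auc_aupr(d$score, d$label)
    data.frame(drug_idx = d$drug_idx[1L], auc = m[["auc"]],
               aupr = m[["aupr"]], n_pos = np, n_neg = nn)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Cross-validated evaluation of the full pipeline
#'
#' Chains [make_folds()], [train_model()] and the metrics over the
#' requested folds.
#'
#' @param dataset as in [train_model()].
#' @param config an [train_config()].
#' @param n_folds number of folds in the split.
#' @param folds_to_run which folds to actually train (defaults to all).
#' @param seed split seed.
#' @param k_values recall cutoffs.
#' @return list of class `adr_cv_report` with per-fold metrics, their
#'   averages, the recall curve of the pooled per-fold tables, and all
#'   score tables.
#' @export
cross_validate <- function(dataset, config = train_config(),
                           n_folds = 5L, folds_to_run = seq_len(n_folds),
                           seed = 1L,
                           k_values = seq(30L, 240L, by = 30L)) {
  folds <- make_folds(dataset$O, seed = seed, n_folds = n_folds)
  per_fold <- lapply(folds_to_run, function(k) {
    m <- train_model(dataset, folds, fold = k, config = config)
    met <- auc_aupr(m$scores$score, m$scores$label)
    list(fold = k, auc = met[["auc"]], aupr = met[["aupr"]],
         scores = m$scores)
  })
  scores_all <- do.call(rbind, lapply(per_fold, `[[`, "scores"))
  structure(list(
    fold_metrics = data.frame(
      fold = vapply(per_fold, `[[`, numeric(1), "fold"),
      auc = vapply(per_fold, `[[`, numeric(1), "auc"),
      aupr = vapply(per_fold, `[[`, numeric(1), "aupr")),
    mean_auc = mean(vapply(per_fold, `[[`, numeric(1), "auc")),
    mean_aupr = mean(vapply(per_fold, `[[`, numeric(1), "aupr")),
    recall = recall_at_k(scores_all, k_values),
    scores = scores_all, seed = seed
  ), class = "adr_cv_report")
}

#' @export
print.adr_cv_report <- function(x, ...) {
  cat("Cross-validation report\n")
  print(x$fold_metrics, row.names = FALSE)
  cat(sprintf("mean AUC  = %.4f\nmean AUPR = %.4f\n", x$mean_auc,
              x$mean_aupr))
  print(round(x$recall, 4))
  invisible(x)
}
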