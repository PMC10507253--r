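#' Read / write delimited numeric matrices
#'
#' Matrices travel as tab-delimited text with a header row of entity IDs
#' and an index column of row IDs, the format shared by every pipeline
#' stage and the CLI.
#'
#' @param path file path.
#' @return `read_matrix_tsv`: a numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  df <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  as.matrix(df)
}

#' @rdname read_matrix_tsv
#' @param x numeric matrix (dimnames written as header/index).
#' @export
write_matrix_tsv <- function(x, path) {
  x <- unclass(x)
  attr(x, "kind") <- NULL
  df <- as.data.frame(x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Write a dataset to a directory
#'
#' Emits `M_chem.tsv`, `M_dise.tsv`, `S.tsv`, `O.tsv` and a sidecar
#' `config.json` recording dimensions (and, for synthetic data, the
#' generator settings and block labels).
#'
#' @param dataset list as returned by [generate_dataset()] (only the four
#'   matrices are required).
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(dataset$M_chem, file.path(dir, "M_chem.tsv"))
  write_matrix_tsv(dataset$M_dise, file.path(dir, "M_dise.tsv"))
  write_matrix_tsv(dataset$S, file.path(dir, "S.tsv"))
  write_matrix_tsv(dataset$O, file.path(dir, "O.tsv"))
  meta <- list(n_drugs = nrow(dataset$O), n_side_effects = ncol(dataset$O))
  if (!is.null(dataset$config)) meta$config <- unclass(dataset$config)
  if (!is.null(dataset$drug_blocks)) meta$drug_blocks <- dataset$drug_blocks
  if (!is.null(dataset$se_blocks)) meta$se_blocks <- dataset$se_blocks
  jsonlite::write_json(meta, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset directory
#'
#' Inverse of [write_dataset()]; validates matrices on the way in.
#'
#' @param dir directory containing the four `.tsv` files and
#'   `config.json`.
#' @return list with `M_chem`, `M_dise`, `S`, `O` and any recorded
#'   metadata.
#' @export
read_dataset <- function(dir) {
  meta_path <- file.path(dir, "config.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  out <- list(
    M_chem = similarity_matrix(read_matrix_tsv(file.path(dir, "M_chem.tsv")),
                               kind = "chem"),
    M_dise = similarity_matrix(read_matrix_tsv(file.path(dir, "M_dise.tsv")),
                               kind = "dise"),
    S = similarity_matrix(read_matrix_tsv(file.path(dir, "S.tsv")),
                          kind = "side_effect"),
    O = association_matrix(read_matrix_tsv(file.path(dir, "O.tsv")))
  )
  n_r <- meta$n_drugs %||% nrow(out$O)
  n_s <- meta$n_side_effects %||% ncol(out$O)
  if (nrow(out$O) != n_r || ncol(out$O) != n_s) {
    stop_input("config.json dimensions disagree with O.tsv")
  }
  c(out, meta[setdiff(names(meta), c("n_drugs", "n_side_effects"))],
    list(n_drugs = n_r, n_side_effects = n_s))
}
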