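#' Synthetic dataset configuration
#'
#' Parameters of the planted-block generator used to exercise the whole
#' pipeline without any external download. Drugs and side effects are
#' partitioned into `n_blocks` communities; a drug associates with a side
#' effect of its own block with probability `p_in` and otherwise with
#' probability `p_out`. Each block owns disjoint chemical-substructure and
#' disease signature features whose noisy per-drug memberships generate
#' the similarity matrices.
#'
#' @param n_drugs,n_side_effects entity counts.
#' @param n_blocks number of planted communities.
#' @param p_in,p_out within/cross-block association probabilities
#'   (`p_in > p_out`).
#' @param n_substructures size of the binary fingerprint universe.
#' @param n_diseases size of the disease universe.
#' @param noise_flip probability of flipping a feature bit / membership.
#' @param seed integer RNG seed; every matrix draws from its own stream
#'   derived from it.
#' @return a list of class `adr_synth_config`.
#' @export
synthetic_config <- function(n_drugs = 60L, n_side_effects = 120L,
                             n_blocks = 3L, p_in = 0.5, p_out = 0.02,
                             n_substructures = 64L, n_diseases = 90L,
                             noise_flip = 0.05, seed = 1L) {
  cfg <- list(n_drugs = as.integer(n_drugs),
              n_side_effects = as.integer(n_side_effects),
              n_blocks = as.integer(n_blocks),
              p_in = p_in, p_out = p_out,
              n_substructures = as.integer(n_substructures),
              n_diseases = as.integer(n_diseases),
              noise_flip = noise_flip, seed = as.integer(seed))
  probs <- c(p_in = p_in, p_out = p_out, noise_flip = noise_flip)
  if (any(probs < 0) || any(probs > 1)) {
    stop_input("probabilities must lie in [0, 1]")
  }
  if (!(p_in > p_out)) stop_input("p_in must exceed p_out")
  if (cfg$n_blocks < 1L) stop_input("n_blocks must be positive")
  if (cfg$n_drugs < cfg$n_blocks || cfg$n_side_effects < cfg$n_blocks ||
      cfg$n_substructures < cfg$n_blocks || cfg$n_diseases < cfg$n_blocks) {
    stop_input("entity and feature counts must be >= n_blocks")
  }
  structure(cfg, class = "adr_synth_config")
}

# noisy block-signature binary membership matrix: entity x features,
# signature bits on (flip off with prob noise), background bits off
# (flip on with prob noise)
noisy_signature <- function(blocks, n_feat, n_blocks, noise) {
  owner <- sort(rep(seq_len(n_blocks), length.out = n_feat))
  base <- outer(blocks, owner, `==`) * 1
  flips <- matrix(stats::rbinom(length(base), 1L, noise),
                  nrow = nrow(base))
  abs(base - flips)
}

#' Generate a synthetic drug/side-effect dataset with planted structure
#'
#' Produces all four input matrices of the prediction pipeline plus the
#' ground-truth block labels. Associations follow a bipartite planted
#' block model; `M_chem` is the cosine similarity of noisy block-signature
#' fingerprints, `M_dise` the Jaccard similarity of noisy block disease
#' sets, and `S` the Jaccard similarity of each side effect's associated
#' drug set (as for the real data, side effects sharing drugs are
#' similar). Output is deterministic given `cfg$seed`.
#'
#' @param cfg an [synthetic_config()] object.
#' @return list with `M_chem`, `M_dise`, `S` (class `adr_similarity`),
#'   `O` (class `adr_association`), `drug_blocks`, `se_blocks`, and the
#'   `config`.
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  if (!inherits(cfg, "adr_synth_config")) {
    stop_input("cfg must come from synthetic_config()")
  }
  nb <- cfg$n_blocks
  drug_blocks <- sort(rep(seq_len(nb), length.out = cfg$n_drugs))
  se_blocks <- sort(rep(seq_len(nb), length.out = cfg$n_side_effects))

  O <- with_seed(derive_seed(cfg$seed, "associations"), {
    same <- outer(drug_blocks, se_blocks, `==`)
    p <- ifelse(same, cfg$p_in, cfg$p_out)
    matrix(stats::rbinom(length(p), 1L, p), nrow = cfg$n_drugs)
  })
  rownames(O) <- paste0("drug", seq_len(cfg$n_drugs))
  colnames(O) <- paste0("se", seq_len(cfg$n_side_effects))

  fp <- with_seed(derive_seed(cfg$seed, "fingerprints"),
                  noisy_signature(drug_blocks, cfg$n_substructures, nb,
                                  cfg$noise_flip))
  # a drug with an all-zero fingerprint breaks the cosine convention only
  # off-diagonal; ensure at least one bit so degrees stay positive
  zero <- rowSums(fp) == 0
  if (any(zero)) fp[zero, 1L] <- 1
  rownames(fp) <- rownames(O)
  M_chem <- cosine_similarity(fp, kind = "chem")

  dis <- with_seed(derive_seed(cfg$seed, "diseases"),
                   noisy_signature(drug_blocks, cfg$n_diseases, nb,
                                   cfg$noise_flip))
  disease_sets <- apply(dis, 1L, function(r) which(r == 1), simplify = FALSE)
  names(disease_sets) <- rownames(O)
  M_dise <- set_similarity(disease_sets, kind = "dise")

  drug_sets <- apply(O, 2L, function(col) which(col == 1), simplify = FALSE)
  names(drug_sets) <- colnames(O)
  S <- set_similarity(drug_sets, kind = "side_effect")

  list(M_chem = M_chem, M_dise = M_dise, S = S,
       O = association_matrix(O),
       drug_blocks = drug_blocks, se_blocks = se_blocks, config = cfg)
}
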