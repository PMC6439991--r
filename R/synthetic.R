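#' Configuration for the synthetic network generator
#'
#' The generator emulates the structure the predictor relies on: two sparse
#' interaction layers (drug-protein and disease-protein) with independent
#' Bernoulli entries, and a drug-disease treatment layer in which the
#' probability of a treat edge grows with the number of proteins the drug
#' and the disease share. A pair with no shared protein is a treat edge
#' with probability `base_treat_rate`; each shared protein adds
#' `overlap_boost` to the log-odds. With `overlap_boost = 0` the treatment
#' layer is pure noise.
#'
#' Protein popularity is heterogeneous: protein `p` carries a log-normal
#' weight `w_p` (log-sd `protein_popularity_sd`, normalised to mean 1)
#' and every drug or disease interacts with it at rate
#' `density * w_p` (capped at 1), so the layer-wide density stays on
#' target while interactions concentrate on hub proteins. Curated
#' interactomes share this trait — a minority of targets accounts for
#' most interactions — and it is what gives the commuting matrices
#' genuine low-rank structure for the SVD step to find; with homogeneous
#' layers (`protein_popularity_sd = 0`) the commuting matrices have a
#' nearly flat spectrum and a rank-`r` truncation retains little of the
#' planted signal.
#'
#' Defaults give a network of 200 drugs, 150 proteins and 80 diseases —
#' hundreds of nodes so a full cross-validation run stays fast. Layer
#' densities default to 0.05, an order of magnitude above the real
#' curated layers (about 0.003): with only 150 proteins the expected
#' shared-protein count per pair is `n_proteins * density^2`, so toy-scale
#' densities must be inflated for protein overlaps — the carrier of the
#' planted signal — to occur at all (0.05 gives ~0.4 expected shared
#' proteins, i.e. roughly a third of pairs can be reached through a
#' protein). The default noise floor `base_treat_rate = 0.005` keeps
#' protein-mediated edges the dominant origin of treatment associations,
#' which is the mechanism the predictor assumes.
#'
#' @param n_drugs,n_proteins,n_diseases universe sizes (>= 1).
#' @param density_dp,density_sp Bernoulli densities of the drug-protein and
#'   disease-protein layers, in \[0, 1\].
#' @param base_treat_rate treat-edge probability for a pair sharing no
#'   protein, in \[0, 1\].
#' @param overlap_boost additive log-odds per shared protein (>= 0).
#' @param protein_popularity_sd log-sd of the per-protein popularity
#'   weights (>= 0; 0 gives homogeneous Erdos-Renyi layers).
#' @param seed integer seed; generation is a pure function of the config.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_drugs = 200L, n_proteins = 150L,
                             n_diseases = 80L,
                             density_dp = 0.05, density_sp = 0.05,
                             base_treat_rate = 0.002, overlap_boost = 2,
                             protein_popularity_sd = 1,
                             seed = 1L) {
  stopifnot(n_drugs >= 1, n_proteins >= 1, n_diseases >= 1,
            density_dp >= 0, density_dp <= 1,
            density_sp >= 0, density_sp <= 1,
            base_treat_rate >= 0, base_treat_rate <= 1,
            overlap_boost >= 0, protein_popularity_sd >= 0)
  structure(list(n_drugs = as.integer(n_drugs),
                 n_proteins = as.integer(n_proteins),
                 n_diseases = as.integer(n_diseases),
                 density_dp = density_dp, density_sp = density_sp,
                 base_treat_rate = base_treat_rate,
                 overlap_boost = overlap_boost,
                 protein_popularity_sd = protein_popularity_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic heterogeneous network with planted signal
#'
#' Samples the three interaction layers under a [synthetic_config()]:
#' independent Bernoulli drug-protein and disease-protein entries at the
#' target layer densities (modulated per protein by the popularity
#' weights), then for every drug-disease pair a treat edge with
#' probability `plogis(qlogis(base_treat_rate) + overlap_boost * k)` where
#' `k` is the number of proteins bound by the drug and associated with the
#' disease. The sampled treat edges are both the `A_ds` layer and the
#' ground-truth positive set.
#'
#' @param config a `synthetic_config`.
#' @return a list with `network` (an aligned `hetero_network`), `positives`
#'   (integer matrix of ground-truth treat pairs, columns drug/disease) and
#'   `config`.
#' @examples
#' sim <- generate_network(synthetic_config(30, 20, 15, seed = 42))
#' network_summary(sim$network)
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ids <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))
  drugs <- ids("d", config$n_drugs)
  proteins <- ids("p", config$n_proteins)
  diseases <- ids("s", config$n_diseases)
  with_seed(config$seed, {
    w <- exp(stats::rnorm(config$n_proteins, 0, config$protein_popularity_sd))
    w <- w / mean(w)  # layer-level density stays on target
    dp <- matrix(stats::rbinom(config$n_drugs * config$n_proteins, 1L,
                               rep(pmin(1, config$density_dp * w),
                                   each = config$n_drugs)),
                 config$n_drugs, config$n_proteins,
                 dimnames = list(drugs, proteins))
    sp <- matrix(stats::rbinom(config$n_diseases * config$n_proteins, 1L,
                               rep(pmin(1, config$density_sp * w),
                                   each = config$n_diseases)),
                 config$n_diseases, config$n_proteins,
                 dimnames = list(diseases, proteins))
    overlap <- dp %*% t(sp)
    base_logit <- stats::qlogis(config$base_treat_rate)
    p_treat <- stats::plogis(base_logit + config$overlap_boost * overlap)
    if (config$base_treat_rate == 0) p_treat[] <- 0
    if (sum(p_treat) < 1)
      warning("expected number of treat edges is below 1 under this config")
    ds <- matrix(stats::rbinom(length(p_treat), 1L, as.vector(p_treat)),
                 nrow(p_treat), ncol(p_treat),
                 dimnames = dimnames(p_treat))
    network <- build_network(interaction_matrix(dp, "Drug", "Protein"),
                             interaction_matrix(sp, "Disease", "Protein"),
                             interaction_matrix(ds, "Drug", "Disease"))
    positives <- Matrix::which(network$A_ds$values != 0, arr.ind = TRUE)
    positives <- as_pair_matrix(positives[order(positives[, 1L], positives[, 2L]),
                                          , drop = FALSE])
    list(network = network, positives = positives, config = config)
  })
}

# Evaluate expr under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# Deterministic sub-seed derivation, kept inside 32-bit integer range.
derive_seed <- function(master, ...) {
  parts <- c(as.numeric(master), as.numeric(c(...)))
  h <- 0
  for (p in parts) h <- (h * 1009 + (p %% 1e6) + 7) %% 2147483629
  as.integer(h)
}
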