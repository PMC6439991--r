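# Shared fixtures and independent brute-force oracles.

# Write an edge list to a temp TSV and return its path.
write_edges_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# Network from three in-memory edge lists given as "a\tb" strings.
network_from_edges <- function(dp, sp, ds) {
  build_network(
    read_edge_list(write_edges_tsv(dp), "Drug", "Protein"),
    read_edge_list(write_edges_tsv(sp), "Disease", "Protein"),
    read_edge_list(write_edges_tsv(ds), "Drug", "Disease"))
}

# The worked toy example: drug d3 binds proteins p3 and p5, both proteins
# cause disease s2, so two Drug->Protein->Disease instances reach (d3, s2).
toy_network <- function() {
  network_from_edges(
    dp = c("d1\tp1", "d2\tp2", "d3\tp3", "d3\tp5"),
    sp = c("s1\tp1", "s2\tp3", "s2\tp5"),
    ds = c("d1\ts1"))
}

# Uniformly random small network over fixed-size registries (some rows or
# columns may stay empty; registries are forced complete via a dummy
# all-zero dense constructor so indices are comparable across layers).
random_small_network <- function(n_drugs, n_proteins, n_diseases,
                                 p = 0.25, seed = 1) {
  set.seed(seed)
  ids <- function(prefix, n) sprintf("%s%02d", prefix, seq_len(n))
  rand_layer <- function(nr, nc, rids, cids, rt, ct) {
    m <- matrix(rbinom(nr * nc, 1, p), nr, nc, dimnames = list(rids, cids))
    interaction_matrix(m, rt, ct)
  }
  d <- ids("d", n_drugs); pr <- ids("p", n_proteins); s <- ids("s", n_diseases)
  build_network(rand_layer(n_drugs, n_proteins, d, pr, "Drug", "Protein"),
                rand_layer(n_diseases, n_proteins, s, pr, "Disease", "Protein"),
                rand_layer(n_drugs, n_diseases, d, s, "Drug", "Disease"))
}

# Minimal single-edge layers for alignment tests.
a_sp_stub <- function() read_edge_list(write_edges_tsv("s1\tp1"), "Disease", "Protein")
a_ds_stub <- function() read_edge_list(write_edges_tsv("d1\ts1"), "Drug", "Disease")

# Brute-force reliable negatives: double loop with explicit set intersection.
oracle_reliable_negatives <- function(network) {
  dp <- as.matrix(network$A_dp$values)
  sp <- as.matrix(network$A_sp$values)
  ds <- as.matrix(network$A_ds$values)
  out <- NULL
  for (d in seq_len(nrow(ds))) {
    drug_prot <- which(dp[d, ] != 0)
    for (s in seq_len(ncol(ds))) {
      dis_prot <- which(sp[s, ] != 0)
      if (ds[d, s] == 0 && length(intersect(drug_prot, dis_prot)) == 0L)
        out <- rbind(out, c(d, s))
    }
  }
  out
}

# Brute-force AUC: fraction of concordant positive-negative pairs, ties 1/2.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Exhaustive F1-threshold scan over a fine grid spanning all cut positions.
oracle_best_f1 <- function(scores, labels) {
  cuts <- sort(unique(c(scores - 1e-9, scores + 1e-9,
                        min(scores) - 1, max(scores) + 1)))
  f1 <- function(t) {
    tp <- sum(scores > t & labels == 1)
    fp <- sum(scores > t & labels == 0)
    fn <- sum(scores <= t & labels == 1)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  max(vapply(cuts, f1, numeric(1)))
}

pair_keys <- function(pairs) paste(pairs[, 1L], pairs[, 2L], sep = ":")

# Deterministic half-sample of 1..n used to hide known positives.
with_seed_idx <- function(n, seed) {
  set.seed(seed)
  sample.int(n, floor(n / 2))
}
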