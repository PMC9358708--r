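# small builders shared across tests

make_counts <- function(values, taxa = NULL, samples = NULL) {
  m <- if (is.matrix(values)) values else
    matrix(values, nrow = if (!is.null(taxa)) length(taxa)
                          else length(values) / 2)   # vectors: 2 samples
  if (is.null(taxa)) taxa <- paste0("OTU_", seq_len(nrow(m)))
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(m)))
  dimnames(m) <- list(taxa, samples)
  otu_table(m, unit = "counts")
}

# labeled patristic-style matrix from a named lower-triangle spec
make_dist <- function(labels, ...) {
  vals <- list(...)
  d <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (nm in names(vals)) {
    pair <- strsplit(nm, "_")[[1]]
    d[pair[1], pair[2]] <- d[pair[2], pair[1]] <- vals[[nm]]
  }
  d
}

# random tree with positive branch lengths; its patristic matrix is additive
random_additive_matrix <- function(n_tips, seed) {
  set.seed(seed)
  tree <- ape::rtree(n_tips, br = function(k) stats::runif(k, 0.1, 2))
  patristic_distances(tree)
}

# tiny deterministic metacommunity for pipeline-level tests
tiny_sim <- function(seed = 7, n_taxa = 60, n_samples = 8, depth = 2000) {
  simulate_metacommunity(synthetic_scenario(
    n_taxa = n_taxa, n_samples = n_samples, depth = depth,
    s = 0, lambda = 0, theta = 50, seed = seed))
}
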