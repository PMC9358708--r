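#' Simulate a pure-birth phylogeny
#'
#' Yule (pure-birth) tree with exponential waiting times, rescaled so the
#' root-to-tip height is exactly 1. Tips are labeled `t1..tn`.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return An ultrametric `phylo` of unit height.
#' @export
simulate_tree <- function(n_taxa, seed = NULL) {
  if (n_taxa < 2) stop("need at least 2 taxa", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  depths <- ape::node.depth.edgelength(tree)
  h <- max(depths[seq_len(n_taxa)])
  tree$edge.length <- tree$edge.length / h
  tree$tip.label <- paste0("t", seq_len(n_taxa))
  tree
}

#' Simulate Brownian niche traits on a tree
#'
#' Brownian motion from a root value of 0: along every branch the trait
#' accrues independent Normal(0, sigma2 * branch length) increments, so tip
#' variance equals sigma2 times tip depth and two tips share covariance
#' sigma2 times their shared path length.
#'
#' @param tree a `phylo` with branch lengths.
#' @param sigma2 Brownian rate (>= 0; 0 gives identical traits).
#' @param seed optional integer seed.
#' @return Named numeric vector of tip traits.
#' @export
simulate_traits <- function(tree, sigma2, seed = NULL) {
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (sigma2 == 0) {
    return(stats::setNames(rep(0, length(tree$tip.label)), tree$tip.label))
  }
  tr <- ape::rTraitCont(tree, model = "BM", sigma = sqrt(sigma2),
                        root.value = 0)
  tr[tree$tip.label]
}

#' Define a synthetic metacommunity scenario
#'
#' Parameters of the generative model behind [simulate_metacommunity()].
#' The defaults mirror a rarefied 44-sample survey design (depth 24,251
#' reads/sample) with a 1,000-taxon regional pool; the calibration studies
#' use smaller explicit scenarios.
#'
#' @param n_taxa regional pool size.
#' @param n_samples number of local communities.
#' @param depth reads per sample (rarefied depth).
#' @param s selection strength (0 = neutral).
#' @param omega niche breadth (trait units).
#' @param sigma2 Brownian rate of the niche trait on the tree.
#' @param lambda dispersal decay (0 = free dispersal; larger = more
#'   dispersal-limited); acts through an exp(-lambda * distance) kernel over
#'   sample coordinates.
#' @param theta drift concentration (smaller = stronger drift), used both
#'   for the locally drifted source pools and the Dirichlet-multinomial
#'   read sampling.
#' @param env per-sample environmental values (default equally spaced on
#'   \[0, 1\]).
#' @param coords n_samples x 2 matrix of spatial coordinates (default
#'   uniform on the unit square, independent of `env`).
#' @param seed master seed; output is bit-reproducible given the scenario.
#' @return A list with class `synthetic_scenario` including the derived
#'   regime `label` (neutral / selection / dispersal_limited / mixed).
#' @export
synthetic_scenario <- function(n_taxa = 1000L, n_samples = 44L,
                               depth = 24251L, s = 0, omega = 0.1,
                               sigma2 = 1, lambda = 0, theta = 20,
                               env = NULL, coords = NULL, seed = 1L) {
  if (n_taxa < 2 || n_samples < 2 || depth < 1) {
    stop("n_taxa, n_samples >= 2 and depth >= 1 required", call. = FALSE)
  }
  if (s < 0 || omega <= 0 || sigma2 < 0 || lambda < 0 || theta <= 0) {
    stop("invalid parameter range (need s, lambda >= 0; omega, theta > 0; ",
         "sigma2 >= 0)", call. = FALSE)
  }
  if (is.null(env)) env <- seq(0, 1, length.out = n_samples)
  if (length(env) != n_samples) stop("env length must equal n_samples",
                                     call. = FALSE)
  if (!is.null(coords) &&
      (!is.matrix(coords) || nrow(coords) != n_samples || ncol(coords) != 2)) {
    stop("coords must be an n_samples x 2 matrix", call. = FALSE)
  }
  label <- if (s == 0 && lambda == 0) "neutral"
           else if (s > 0 && lambda == 0) "selection"
           else if (s == 0 && lambda > 0) "dispersal_limited"
           else "mixed"
  structure(list(n_taxa = as.integer(n_taxa),
                 n_samples = as.integer(n_samples),
                 depth = as.integer(depth), s = s, omega = omega,
                 sigma2 = sigma2, lambda = lambda, theta = theta,
                 env = env, coords = coords, seed = as.integer(seed),
                 label = label),
            class = "synthetic_scenario")
}

# Dirichlet draw by gamma normalization; degenerate all-zero draws fall back
# to the mean direction
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) <= 0) return(alpha / sum(alpha))
  g / sum(g)
}

#' Simulate a metacommunity with known assembly regime
#'
#' Generative model (one draw per scenario seed):
#' 1. A unit-height pure-birth phylogeny and Brownian niche optima `mu`
#'    ([simulate_tree()], [simulate_traits()]).
#' 2. Lognormal(0, 1) metacommunity abundances `m`.
#' 3. Locally drifted source pools: per sample,
#'    `pi_j ~ Dirichlet(theta * m / sum(m))` — independent local histories.
#' 4. Dispersal mixing: pools are blended by the spatial kernel
#'    `K(j, k) = exp(-lambda * ||x_j - x_k||)`; `lambda = 0` homogenizes all
#'    pools (free dispersal), large `lambda` keeps them local.
#' 5. Selection filter: taxon i's expected share in sample j is proportional
#'    to `pool_j(i) * exp(-s * (mu_i - E_j)^2 / (2 * omega^2))`.
#' 6. Drift + sampling: counts are Dirichlet-multinomial with concentration
#'    `theta * share` and column total exactly `depth`.
#'
#' @param scenario a [synthetic_scenario()].
#' @return A list: `otu` (count [otu_table()], taxa x samples), `metadata`
#'   (data frame: sample_id, X, Y, ENV), `tree` (`phylo`), and `truth`
#'   (niche optima `mu`, deterministic `expected` composition, metacommunity
#'   shares, regime `label`, the scenario).
#' @export
simulate_metacommunity <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  sc <- scenario
  set.seed(sc$seed)
  tree <- simulate_tree(sc$n_taxa)
  mu <- simulate_traits(tree, sc$sigma2)
  m <- stats::rlnorm(sc$n_taxa, 0, 1)
  m <- m / sum(m)
  names(m) <- tree$tip.label
  coords <- sc$coords
  if (is.null(coords)) {
    coords <- cbind(stats::runif(sc$n_samples), stats::runif(sc$n_samples))
  }
  E <- sc$env
  # locally drifted source pools, then dispersal mixing; the pool stage is
  # deliberately milder (10 theta) than the read-sampling stage so that theta
  # remains the single drift knob without collapsing per-sample occupancy
  pools <- vapply(seq_len(sc$n_samples),
                  function(j) rdirichlet1(10 * sc$theta * m),
                  numeric(sc$n_taxa))
  K <- exp(-sc$lambda * as.matrix(stats::dist(coords)))
  K <- sweep(K, 1, rowSums(K), "/")
  mixed <- pools %*% t(K)                       # column j = blended pool of j
  # selection filter on the blended pools; log-space with per-sample shift so
  # the best-matched taxon never underflows (normalization absorbs the shift)
  logf <- -sc$s * outer(mu, E, function(a, b) (a - b)^2) / (2 * sc$omega^2)
  filt <- exp(sweep(logf, 2, apply(logf, 2, max), "-"))
  shares <- mixed * filt
  cs <- colSums(shares)
  if (any(cs <= 0)) stop("selection filter removed every taxon in a sample",
                         call. = FALSE)
  shares <- sweep(shares, 2, cs, "/")
  # deterministic expectation (no pool drift) for the ground truth
  exp_shares <- matrix(m, sc$n_taxa, sc$n_samples) * filt
  exp_shares <- sweep(exp_shares, 2, colSums(exp_shares), "/")
  counts <- vapply(seq_len(sc$n_samples), function(j) {
    p <- rdirichlet1(sc$theta * shares[, j])
    as.integer(stats::rmultinom(1, sc$depth, p))
  }, integer(sc$n_taxa))
  sample_ids <- sprintf("S%02d", seq_len(sc$n_samples))
  dimnames(counts) <- list(tree$tip.label, sample_ids)
  dimnames(exp_shares) <- dimnames(counts)
  metadata <- data.frame(sample_id = sample_ids,
                         X = coords[, 1], Y = coords[, 2], ENV = E)
  rownames(metadata) <- sample_ids
  list(otu = otu_table(counts, unit = "counts"),
       metadata = metadata, tree = tree,
       truth = list(mu = mu, metacommunity = m, expected = exp_shares,
                    label = sc$label, scenario = sc))
}

#' Write a simulated metacommunity to disk
#'
#' Emits the same formats the readers consume: OTU table and metadata as
#' TSV, tree as newick, scenario parameters as a YAML-style provenance
#' snippet.
#'
#' @param sim a [simulate_metacommunity()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_metacommunity <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_otu_table(sim$otu, file.path(dir, "otu_table.tsv"))
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  sc <- sim$truth$scenario
  keep <- c("n_taxa", "n_samples", "depth", "s", "omega", "sigma2",
            "lambda", "theta", "seed", "label")
  writeLines(paste0(keep, ": ", vapply(sc[keep], format, character(1))),
             file.path(dir, "scenario.yml"))
  invisible(dir)
}
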