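#' Pairwise Bray-Curtis dissimilarity between samples
#'
#' Computed on relative abundances:
#' \eqn{BC(x,y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}. Counts are
#' converted to proportions per sample first, so the result is invariant to
#' rescaling any sample's counts. Delegates to [vegan::vegdist()].
#'
#' @param table an [otu_table()].
#' @return Labeled symmetric samples x samples matrix in \[0, 1\] with
#'   attribute `metric = "bray_curtis"`.
#' @export
bray_curtis_matrix <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  p <- unclass(to_relative_abundance(table))
  m <- as.matrix(vegan::vegdist(t(p), method = "bray"))
  m <- m[colnames(p), colnames(p)]
  attr(m, "metric") <- "bray_curtis"
  m
}

# per-sample weights over present taxa: relative abundance within the present
# set when weighted, else 1/richness; zero for absent taxa
mntd_weights <- function(p, weighted) {
  W <- matrix(0, nrow(p), ncol(p), dimnames = dimnames(p))
  for (s in seq_len(ncol(p))) {
    pres <- p[, s] > 0
    if (!any(pres)) {
      stop("sample with no present taxa: ", colnames(p)[s], call. = FALSE)
    }
    W[pres, s] <- if (weighted) p[pres, s] / sum(p[pres, s])
                  else 1 / sum(pres)
  }
  W
}

# core betaMNTD given weights, presence list and a 1-based taxon permutation
bmntd_from_weights <- function(D, W, present0, perm1) {
  M <- nearest_taxon_mins(D, present0, perm1 - 1L)
  A <- crossprod(W, M)
  0.5 * (A + t(A))
}

#' Pairwise beta mean nearest taxon distance (betaMNTD)
#'
#' For samples k and m,
#' \deqn{\beta MNTD = 0.5 \left[ \sum_{i \in k} w_i \min_{j \in m} d(i,j)
#'   + \sum_{j \in m} w_j \min_{i \in k} d(j,i) \right]}
#' where sums run over taxa present (abundance > 0), `d` is patristic
#' distance, and the weights `w` are relative abundances within the present
#' set (`weighted = TRUE`, default) or `1/richness` (`weighted = FALSE`).
#' A taxon shared by both samples contributes 0 through `d(i,i) = 0`.
#'
#' @param table an [otu_table()]; every taxon must appear in `patristic`.
#' @param patristic labeled patristic distance matrix covering the taxa
#'   (see [patristic_distances()]).
#' @param weighted abundance-weight the taxa (default `TRUE`).
#' @return Labeled symmetric samples x samples matrix (zero diagonal) with
#'   attributes `metric = "beta_mntd"` and `weighted`.
#' @export
beta_mntd_matrix <- function(table, patristic, weighted = TRUE) {
  stopifnot(inherits(table, "otu_table"))
  check_dist(patristic, what = "patristic matrix")
  missing_taxa <- setdiff(rownames(table), rownames(patristic))
  if (length(missing_taxa)) {
    stop("taxa missing from patristic matrix: ",
         paste(utils::head(missing_taxa, 5), collapse = ", "), call. = FALSE)
  }
  p <- unclass(to_relative_abundance(table))
  D <- patristic[rownames(p), rownames(p)]
  W <- mntd_weights(p, weighted)
  present0 <- lapply(seq_len(ncol(p)), function(s) which(p[, s] > 0) - 1L)
  m <- bmntd_from_weights(D, W, present0, seq_len(nrow(p)))
  dimnames(m) <- list(colnames(p), colnames(p))
  diag(m) <- 0
  attr(m, "metric") <- "beta_mntd"
  attr(m, "weighted") <- weighted
  m
}
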