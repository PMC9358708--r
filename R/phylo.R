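# shared validation for labeled distance matrices
check_dist <- function(d, allow_negative = FALSE, what = "distance matrix") {
  if (!is.matrix(d) || !is.numeric(d)) stop(what, " must be a numeric matrix",
                                            call. = FALSE)
  if (nrow(d) != ncol(d)) stop(what, " must be square", call. = FALSE)
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d))) {
    stop(what, " must have identical row and column labels", call. = FALSE)
  }
  if (anyDuplicated(rownames(d))) stop(what, " has duplicate labels",
                                       call. = FALSE)
  if (any(abs(d - t(d)) > 1e-12)) stop(what, " is not symmetric",
                                       call. = FALSE)
  if (any(abs(diag(d)) > 0)) stop(what, " diagonal must be zero",
                                  call. = FALSE)
  if (!allow_negative && any(d < 0)) stop(what, " has negative entries",
                                          call. = FALSE)
  invisible(d)
}

# lower-triangle vector of a labeled square matrix, pair order fixed
lower_vec <- function(d) d[lower.tri(d)]

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the standard Q criterion
#' \eqn{Q(i,j) = (n-2) d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)}. At every step
#' the minimal-Q pair is joined; on exact ties the lexicographically smallest
#' label pair wins (internal nodes carry the smallest tip label of their
#' subtree), so the result does not depend on input label order. Branch
#' lengths come from the standard two-point formulas; a negative estimate is
#' clamped to 0 and the deficit moved to the sister branch, preserving the
#' two branches' sum.
#'
#' On an additive distance matrix the tree is recovered exactly:
#' `patristic_distances(nj_tree(D))` equals `D`.
#'
#' @param d labeled symmetric distance matrix, zero diagonal, `n >= 2` taxa.
#' @return An unrooted `phylo` tree (for `n = 2`, a single cherry whose two
#'   pendant branches sum to `d`).
#' @export
nj_tree <- function(d) {
  check_dist(d, what = "NJ input")
  n <- nrow(d)
  if (n < 2) stop("need at least 2 taxa", call. = FALSE)
  labels <- rownames(d)
  if (n == 2) {
    txt <- sprintf("(%s:0,%s:%.12g);", labels[1], labels[2], d[1, 2])
    return(ape::read.tree(text = txt))
  }
  # active nodes: newick fragment + tie-break key (smallest tip label inside)
  frag <- labels
  key <- labels
  D <- d
  while (nrow(D) > 2) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-12 * max(1, abs(qmin))
    cand <- which(Q - qmin <= tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break: smallest sorted label pair
    pair_key <- apply(cand, 1, function(ij) {
      k <- sort(c(key[ij[1]], key[ij[2]]))
      paste(k, collapse = "\r")
    })
    pick <- cand[order(pair_key)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_frag <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], li, frag[j], lj)
    new_key <- min(key[i], key[j])
    dn <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dn[keep]),
                c(dn[keep], 0))
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], new_key)
    D <- D2
    frag <- c(frag[keep], new_frag)
    key <- c(key[keep], new_key)
  }
  txt <- sprintf("(%s:0,%s:%.12g);", frag[1], frag[2], max(D[1, 2], 0))
  ape::read.tree(text = txt)
}

#' Patristic (cophenetic) distances between tree tips
#'
#' Sum of branch lengths along the unique path between every pair of tips,
#' via [ape::cophenetic.phylo()].
#'
#' @param tree a `phylo` object with branch lengths.
#' @return Labeled symmetric matrix of patristic distances, zero diagonal.
#' @export
patristic_distances <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object",
                                     call. = FALSE)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree has missing branch lengths", call. = FALSE)
  }
  d <- ape::cophenetic.phylo(tree)
  d[rownames(d), rownames(d)]
}

#' Read a labeled square distance matrix from TSV
#'
#' @param path TSV with labels in the first row and first column.
#' @param allow_negative permit negative off-diagonal entries (e.g. for a
#'   betaNTI matrix).
#' @return Labeled symmetric numeric matrix.
#' @export
read_dist_tsv <- function(path, allow_negative = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          row.names = 1, comment.char = "")
  m <- as.matrix(df)
  check_dist(m, allow_negative = allow_negative)
}

#' Write a distance matrix as square and/or long TSV
#'
#' @param d labeled square matrix.
#' @param path output path for the square form.
#' @param long_path optional output path for the long form
#'   (`sample_i`, `sample_j`, `value`; unordered pairs once).
#' @return `path`, invisibly.
#' @export
write_dist_tsv <- function(d, path, long_path = NULL) {
  df <- data.frame(id = rownames(d), as.data.frame(d), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(long_path)) {
    idx <- which(lower.tri(d), arr.ind = TRUE)
    long <- data.frame(sample_i = rownames(d)[idx[, 2]],
                       sample_j = rownames(d)[idx[, 1]],
                       value = d[idx])
    utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
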