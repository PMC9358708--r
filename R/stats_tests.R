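#' Environmental divergence matrix for one variable
#'
#' Pairwise absolute differences of a metadata variable. Samples with a
#' missing value are excluded and reported in the `excluded` attribute.
#'
#' @param metadata a data frame from [read_metadata()] (or any data frame
#'   with a `sample_id` column and numeric variables).
#' @param variable variable name.
#' @return Labeled symmetric matrix of |v_i - v_j|. If the variable is
#'   constant the attribute `constant` is `TRUE` (a Mantel test on it is
#'   undefined).
#' @export
env_distance <- function(metadata, variable) {
  if (!variable %in% colnames(metadata)) {
    stop("unknown variable: ", variable, call. = FALSE)
  }
  v <- metadata[[variable]]
  ids <- metadata$sample_id
  keep <- !is.na(v)
  if (sum(keep) < 2) stop("fewer than 2 non-missing samples for ", variable,
                          call. = FALSE)
  d <- abs(outer(v[keep], v[keep], "-"))
  dimnames(d) <- list(ids[keep], ids[keep])
  attr(d, "excluded") <- ids[!keep]
  attr(d, "constant") <- all(d == 0)
  d
}

#' Mantel permutation test between two distance matrices
#'
#' The statistic is the Pearson (default) or Spearman correlation over the
#' n(n-1)/2 unordered off-diagonal pairs. The null is generated by
#' simultaneously permuting the rows and columns of `d2`; the one-sided
#' "greater" p-value uses the add-one correction
#' \eqn{p = (\#\{r_{perm} \ge r_{obs}\} + 1)/(n_{perm} + 1)}, so it can never
#' be 0. When `n! <= exhaustive_cap` all label permutations are enumerated
#' and the p-value is exact (the identity permutation included).
#'
#' @param d1,d2 labeled square distance matrices over the same samples
#'   (negative entries allowed, e.g. a betaNTI matrix).
#' @param n_perm permutations (default 999).
#' @param seed RNG seed for the sampled mode.
#' @param method `"pearson"` or `"spearman"`.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param exhaustive_cap enumerate all permutations when `n!` is at most
#'   this (default 720 = 6!); set 0 to force sampling.
#' @return A list with class `mantel_result`: `r`, `p`, `n_perm`, `method`,
#'   `alternative`, `exhaustive`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999L, seed = 1L,
                        method = c("pearson", "spearman"),
                        alternative = c("greater", "two.sided"),
                        exhaustive_cap = 720) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  check_dist(d1, allow_negative = TRUE, what = "d1")
  check_dist(d2, allow_negative = TRUE, what = "d2")
  if (!setequal(rownames(d1), rownames(d2))) {
    stop("d1 and d2 must cover the same samples", call. = FALSE)
  }
  d2 <- d2[rownames(d1), rownames(d1)]
  n <- nrow(d1)
  if (n < 4) stop("need at least 4 samples", call. = FALSE)
  v1 <- lower_vec(d1)
  if (stats::sd(v1) == 0 || stats::sd(lower_vec(d2)) == 0) {
    stop("zero-variance distance vector: correlation undefined",
         call. = FALSE)
  }
  if (method == "spearman") v1 <- rank(v1)
  stat <- function(m2) {
    v2 <- lower_vec(m2)
    if (method == "spearman") v2 <- rank(v2)
    stats::cor(v1, v2)
  }
  r_obs <- stat(d2)
  score <- function(r_perm) {
    if (alternative == "greater") r_perm >= r_obs - 1e-12
    else abs(r_perm) >= abs(r_obs) - 1e-12
  }
  exhaustive <- factorial(n) <= exhaustive_cap && exhaustive_cap > 0
  if (exhaustive) {
    perms <- permutations_all(n)
    hits <- sum(apply(perms, 1, function(pp) score(stat(d2[pp, pp]))))
    p <- hits / nrow(perms)
    n_used <- nrow(perms)
  } else {
    set.seed(as.integer(seed))
    hits <- 0L
    for (b in seq_len(n_perm)) {
      pp <- sample.int(n)
      if (score(stat(d2[pp, pp]))) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(r = r_obs, p = p, n_perm = n_used, method = method,
                 alternative = alternative, exhaustive = exhaustive),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f, p = %.4g (%s, %s, %s)\n", x$r, x$p,
              x$method, x$alternative,
              if (x$exhaustive) "exhaustive" else paste0(x$n_perm, " perms")))
  invisible(x)
}

#' Spearman correlations of category summaries vs environment
#'
#' Correlates each per-sample response (richness and summed relative
#' abundance per abundance category) with each environmental variable.
#' Spearman rho uses average ranks for ties; the two-sided p-value comes from
#' the t approximation ([stats::cor.test()] with `exact = FALSE`). Cells with
#' fewer than `min_pairs` complete pairs are left missing. An optional
#' Benjamini-Hochberg adjusted column is appended across the whole panel.
#'
#' @param summary a [category_summary()] result.
#' @param metadata a metadata data frame with `sample_id`.
#' @param variables variable names to use (default: all numeric columns
#'   except coordinates-free `sample_id`).
#' @param min_pairs minimum complete pairs per cell (default 3).
#' @param adjust append a BH-adjusted p column (default `TRUE`).
#' @return Long data frame: response, category, variable, rho, p, n
#'   (and p_adj).
#' @export
spearman_correlations <- function(summary, metadata, variables = NULL,
                                  min_pairs = 3, adjust = TRUE) {
  stopifnot(inherits(summary, "category_summary"))
  per <- summary$per_sample
  if (is.null(variables)) {
    variables <- setdiff(colnames(metadata)[vapply(metadata, is.numeric,
                                                   logical(1))],
                         "sample_id")
  }
  common <- intersect(unique(per$sample_id), metadata$sample_id)
  if (length(common) == 0) stop("no overlapping samples", call. = FALSE)
  md <- metadata[match(common, metadata$sample_id), , drop = FALSE]
  rows <- list()
  for (resp in c("richness", "abundance")) {
    for (cc in unique(per$category)) {
      y <- per[[resp]][match(paste(common, cc),
                             paste(per$sample_id, per$category))]
      for (v in variables) {
        x <- md[[v]]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) >= min_pairs && stats::sd(x[ok]) > 0 &&
            stats::sd(y[ok]) > 0) {
          ct <- suppressWarnings(
            stats::cor.test(x[ok], y[ok], method = "spearman",
                            exact = FALSE))
          rho <- unname(ct$estimate); pv <- ct$p.value
        } else {
          rho <- NA_real_; pv <- NA_real_
        }
        rows[[length(rows) + 1L]] <- data.frame(
          response = resp, category = cc, variable = v,
          rho = rho, p = pv, n = sum(ok), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Mann-Whitney rank-sum test
#'
#' U statistic with average ranks for ties. Exact mode enumerates every
#' assignment of the pooled values into groups of the observed sizes
#' (default when `n_a + n_b <= 12`); otherwise the two-sided p-value uses
#' the normal approximation with tie correction and continuity correction.
#'
#' @param a,b numeric vectors (each non-empty).
#' @param exact force exact enumeration on/off; default `NULL` chooses exact
#'   when the pooled size is at most 12.
#' @return A list with class `rank_sum_result`: `statistic` (U for group a),
#'   `p`, `exact`.
#' @export
rank_sum_test <- function(a, b, exact = NULL) {
  if (length(a) == 0 || length(b) == 0) stop("empty group", call. = FALSE)
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  rk <- rank(pooled)
  u_of <- function(ida) sum(rk[ida]) - na * (na + 1) / 2
  U <- u_of(seq_len(na))
  mu <- na * nb / 2
  if (is.null(exact)) exact <- n <= 12
  if (exact) {
    combs <- utils::combn(n, na)
    us <- apply(combs, 2, u_of)
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
  } else {
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-max(z, 0))
    }
  }
  structure(list(statistic = U, p = min(p, 1), exact = exact),
            class = "rank_sum_result")
}
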