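# independent RNG substream per analysis, derived from the master seed, so
# adding one analysis never perturbs another's draws
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(as.numeric(seed)) * 1009 + h * 7919) %% 2147483629)
}

# all permutations of 1..n as a matrix (n! rows); used by exhaustive modes
permutations_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_all(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- seq_len(nrow(sub)) + r
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

#' Configuration for the assembly null models
#'
#' @param n_null number of null replicates (default 999, the conventional
#'   permutation count).
#' @param seed master seed; betaNTI and RC-Bray derive independent
#'   substreams from it.
#' @param bnti_threshold |betaNTI| beyond which selection is inferred
#'   (default 2).
#' @param rc_threshold |RC| beyond which dispersal processes are inferred
#'   (default 0.95).
#' @param exhaustive enumerate all tip permutations instead of sampling when
#'   `n_taxa!` does not exceed `exhaustive_cap`.
#' @param exhaustive_cap largest factorial enumerated (default 40320 = 8!).
#' @param sign_convention `"framework"` (default): betaNTI > +threshold is
#'   heterogeneous (variable) selection, betaNTI < -threshold homogeneous
#'   selection. `"literal"` swaps the two labels.
#' @return A list with class `null_model_config`.
#' @export
null_model_config <- function(n_null = 999L, seed = 1L, bnti_threshold = 2,
                              rc_threshold = 0.95, exhaustive = FALSE,
                              exhaustive_cap = 40320L,
                              sign_convention = c("framework", "literal")) {
  if (n_null < 1) stop("n_null must be >= 1", call. = FALSE)
  if (bnti_threshold <= 0 || rc_threshold <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  structure(list(n_null = as.integer(n_null), seed = as.integer(seed),
                 bnti_threshold = bnti_threshold,
                 rc_threshold = rc_threshold,
                 exhaustive = isTRUE(exhaustive),
                 exhaustive_cap = exhaustive_cap,
                 sign_convention = match.arg(sign_convention)),
            class = "null_model_config")
}

#' Beta nearest taxon index (betaNTI) from tip-shuffle null models
#'
#' The observed betaMNTD of every sample pair is standardized against a null
#' distribution obtained by randomly permuting taxon labels on the patristic
#' matrix (equivalent to shuffling tips across the phylogeny):
#' \deqn{\beta NTI = (\beta MNTD_{obs} - \bar{\beta MNTD}_{null}) / SD_{null}}
#' One shuffle per null replicate is shared across all pairs. With
#' `cfg$exhaustive` and a small taxon set, all permutations are enumerated
#' instead (deterministic, seed-independent). Pairs whose null distribution
#' has zero spread are flagged degenerate and carry `NA` betaNTI.
#'
#' @param table an [otu_table()].
#' @param patristic labeled patristic distance matrix covering the taxa.
#' @param cfg a [null_model_config()].
#' @param weighted abundance-weight betaMNTD (default `TRUE`).
#' @return A `bnti_result`: matrices `obs`, `null_mean`, `null_sd`, `bnti`,
#'   logical `degenerate`, plus `n_null` and `exhaustive`.
#' @export
bnti_matrix <- function(table, patristic, cfg = null_model_config(),
                        weighted = TRUE) {
  stopifnot(inherits(table, "otu_table"),
            inherits(cfg, "null_model_config"))
  check_dist(patristic, what = "patristic matrix")
  missing_taxa <- setdiff(rownames(table), rownames(patristic))
  if (length(missing_taxa)) {
    stop("taxa missing from patristic matrix: ",
         paste(utils::head(missing_taxa, 5), collapse = ", "), call. = FALSE)
  }
  p <- unclass(to_relative_abundance(table))
  nt <- nrow(p)
  D <- patristic[rownames(p), rownames(p)]
  W <- mntd_weights(p, weighted)
  present0 <- lapply(seq_len(ncol(p)), function(s) which(p[, s] > 0) - 1L)
  obs <- bmntd_from_weights(D, W, present0, seq_len(nt))
  dimnames(obs) <- list(colnames(p), colnames(p))
  diag(obs) <- 0

  use_exhaustive <- cfg$exhaustive && factorial(nt) <= cfg$exhaustive_cap
  if (use_exhaustive) {
    perms <- permutations_all(nt)
  } else {
    set.seed(derive_seed(cfg$seed, "bnti"))
    perms <- t(replicate(cfg$n_null, sample.int(nt)))
  }
  n_rep <- nrow(perms)
  acc <- matrix(0, ncol(p), ncol(p))
  acc2 <- matrix(0, ncol(p), ncol(p))
  for (r in seq_len(n_rep)) {
    bm <- bmntd_from_weights(D, W, present0, perms[r, ])
    acc <- acc + bm
    acc2 <- acc2 + bm * bm
  }
  null_mean <- acc / n_rep
  if (use_exhaustive) {
    # full enumeration: the null is the complete population
    null_var <- acc2 / n_rep - null_mean^2
  } else {
    null_var <- (acc2 - n_rep * null_mean^2) / (n_rep - 1)
  }
  null_sd <- sqrt(pmax(null_var, 0))
  degenerate <- null_sd < 1e-10
  bnti <- (obs - null_mean) / null_sd
  bnti[degenerate] <- NA_real_
  diag(bnti) <- 0
  diag(degenerate) <- FALSE
  dimnames(null_mean) <- dimnames(null_sd) <- dimnames(bnti) <-
    dimnames(degenerate) <- dimnames(obs)
  structure(list(obs = obs, null_mean = null_mean, null_sd = null_sd,
                 bnti = bnti, degenerate = degenerate,
                 n_null = n_rep, exhaustive = use_exhaustive,
                 weighted = weighted),
            class = "bnti_result")
}

#' Assemble one Raup-Crick null community
#'
#' Draws `richness` taxa from the regional pool with probability proportional
#' to `occ_prob`, seeds each with one read so null richness equals observed
#' richness, then allocates the remaining `total - richness` reads
#' multinomially with probability proportional to `abund_prob` over the drawn
#' taxa.
#'
#' @param richness number of taxa to draw.
#' @param total reads to allocate (>= `richness`).
#' @param occ_prob per-taxon draw weights (occupancy; any non-negative
#'   weights summing > 0).
#' @param abund_prob per-taxon read-allocation weights (regional relative
#'   abundance).
#' @return Integer count vector over the pool (length = `length(occ_prob)`).
#' @export
assemble_null_community <- function(richness, total, occ_prob, abund_prob) {
  n_pool <- length(occ_prob)
  if (richness > n_pool) {
    stop("sample richness (", richness, ") exceeds pool size (", n_pool, ")",
         call. = FALSE)
  }
  if (total < richness) stop("total reads below richness", call. = FALSE)
  drawn <- sample.int(n_pool, richness, prob = occ_prob)
  counts <- integer(n_pool)
  counts[drawn] <- 1L
  extra <- total - richness
  if (extra > 0) {
    w <- abund_prob[drawn]
    if (sum(w) <= 0) w <- rep(1, richness)
    counts[drawn] <- counts[drawn] +
      as.integer(stats::rmultinom(1, extra, w))
  }
  counts
}

#' Raup-Crick metric on Bray-Curtis dissimilarity (RC-Bray)
#'
#' For every sample pair, `cfg$n_null` null community pairs are assembled
#' (each null sample keeps its observed richness and read total; taxa drawn
#' with probability proportional to occupancy, reads allocated proportional
#' to regional relative abundance) and their Bray-Curtis dissimilarity forms
#' the null distribution. The exceedance probability
#' \eqn{P = (\#\{null < obs\} + 0.5\,\#\{null = obs\}) / n_{null}} is rescaled
#' to \eqn{RC = 2 (P - 0.5) \in [-1, 1]}.
#'
#' @param table an [otu_table()]; proportions are converted to integer read
#'   counts via `depth`.
#' @param cfg a [null_model_config()].
#' @param depth reads per sample used to scale a proportions table
#'   (ignored for counts).
#' @param pool optional explicit null pool: a list with numeric vectors
#'   `occupancy` and `abundance` named by taxon (defaults are estimated from
#'   `table`). Useful for calibration against a known generative null.
#' @param occupancy_weighting draw taxa proportional to occupancy
#'   (`FALSE` = uniform over the pool).
#' @param abundance_weighting allocate reads proportional to regional
#'   relative abundance (`FALSE` = uniform over drawn taxa).
#' @return An `rc_result`: matrices `obs` (Bray-Curtis), `p` (exceedance
#'   probability) and `rc`, plus `n_null`.
#' @export
rc_bray_matrix <- function(table, cfg = null_model_config(), depth = NULL,
                           pool = NULL, occupancy_weighting = TRUE,
                           abundance_weighting = TRUE) {
  stopifnot(inherits(table, "otu_table"),
            inherits(cfg, "null_model_config"))
  if (otu_unit(table) == "proportions") {
    if (is.null(depth)) {
      stop("a proportions table needs `depth` to recover read counts",
           call. = FALSE)
    }
    x <- round(unclass(table) * depth)
  } else {
    x <- unclass(table)
  }
  ns <- ncol(x)
  if (ns < 2) stop("need at least 2 samples", call. = FALSE)
  if (is.null(pool)) {
    occ <- rowSums(x > 0)
    reg <- rowSums(x) / sum(x)
  } else {
    occ <- pool$occupancy[rownames(x)]
    reg <- pool$abundance[rownames(x)]
    if (anyNA(occ) || anyNA(reg)) {
      stop("pool must cover every taxon in the table", call. = FALSE)
    }
  }
  occ_w <- if (occupancy_weighting) occ else as.numeric(occ > 0)
  reg_w <- if (abundance_weighting) reg else as.numeric(reg > 0)
  S <- colSums(x > 0)
  N <- colSums(x)
  obs <- bray_curtis_matrix(as_otu(x, "counts"))
  set.seed(derive_seed(cfg$seed, "rcbray"))
  # independent null draws per sample pair (pairs in fixed column order)
  nulls_for <- function(k) {
    vapply(seq_len(cfg$n_null), function(r) {
      assemble_null_community(S[k], N[k], occ_w, reg_w)
    }, integer(nrow(x)))
  }
  p <- matrix(0.5, ns, ns)
  for (i in seq_len(ns - 1)) {
    for (j in seq(i + 1, ns)) {
      bc <- colSums(abs(nulls_for(i) / N[i] - nulls_for(j) / N[j])) / 2
      o <- obs[i, j]
      p[i, j] <- p[j, i] <-
        (sum(bc < o - 1e-12) + 0.5 * sum(abs(bc - o) <= 1e-12)) / cfg$n_null
    }
  }
  rc <- 2 * (p - 0.5)
  diag(p) <- 0.5
  diag(rc) <- 0
  dimnames(p) <- dimnames(rc) <- dimnames(obs)
  structure(list(obs = obs, p = p, rc = rc, n_null = cfg$n_null),
            class = "rc_result")
}

#' Classify assembly processes per sample pair
#'
#' Selection is inferred where |betaNTI| exceeds `cfg$bnti_threshold` (the
#' sign separating heterogeneous from homogeneous selection according to
#' `cfg$sign_convention`). Otherwise RC-Bray decides:
#' `RC > cfg$rc_threshold` is dispersal limitation,
#' `RC < -cfg$rc_threshold` homogenizing dispersal, anything in between
#' undominated. Boundary values fall to the less extreme class. Pairs with a
#' degenerate betaNTI null are `undefined` and excluded from the fraction
#' denominators.
#'
#' @param bnti a `bnti_result` from [bnti_matrix()].
#' @param rc an `rc_result` from [rc_bray_matrix()] over the same samples.
#' @param cfg a [null_model_config()].
#' @return An `assembly_classification`: `pairs` (long data frame with the
#'   observed statistics and process per unordered pair), `fractions` (the
#'   five process fractions over defined pairs), `deterministic` and
#'   `stochastic` shares, `n_defined`, `n_degenerate`.
#' @export
classify_assembly <- function(bnti, rc, cfg = null_model_config()) {
  stopifnot(inherits(bnti, "bnti_result"), inherits(rc, "rc_result"))
  if (!identical(rownames(bnti$bnti), rownames(rc$rc))) {
    stop("betaNTI and RC results cover different sample sets", call. = FALSE)
  }
  labs <- rownames(bnti$bnti)
  idx <- which(lower.tri(bnti$bnti), arr.ind = TRUE)
  b <- bnti$bnti[idx]
  r <- rc$rc[idx]
  deg <- bnti$degenerate[idx]
  pos_label <- if (cfg$sign_convention == "framework")
    "heterogeneous_selection" else "homogeneous_selection"
  neg_label <- if (cfg$sign_convention == "framework")
    "homogeneous_selection" else "heterogeneous_selection"
  process <- rep("undominated", length(b))
  process[!deg & b > cfg$bnti_threshold] <- pos_label
  process[!deg & b < -cfg$bnti_threshold] <- neg_label
  stochastic_pair <- !deg & abs(b) <= cfg$bnti_threshold
  process[stochastic_pair & r > cfg$rc_threshold] <- "dispersal_limitation"
  process[stochastic_pair & r < -cfg$rc_threshold] <- "homogenizing_dispersal"
  process[deg] <- "undefined"
  levels5 <- c("heterogeneous_selection", "homogeneous_selection",
               "homogenizing_dispersal", "dispersal_limitation",
               "undominated")
  defined <- process != "undefined"
  fractions <- if (any(defined)) {
    table(factor(process[defined], levels = levels5)) / sum(defined)
  } else {
    stats::setNames(rep(NA_real_, 5), levels5)
  }
  fractions <- stats::setNames(as.numeric(fractions), levels5)
  deterministic <- sum(fractions[c("heterogeneous_selection",
                                   "homogeneous_selection")])
  pairs <- data.frame(
    sample_i = labs[idx[, 2]], sample_j = labs[idx[, 1]],
    bmntd_obs = bnti$obs[idx], null_mean = bnti$null_mean[idx],
    null_sd = bnti$null_sd[idx], bnti = b,
    bc_obs = rc$obs[idx], rc = r, process = process,
    stringsAsFactors = FALSE)
  structure(list(pairs = pairs, fractions = fractions,
                 deterministic = deterministic,
                 stochastic = 1 - deterministic,
                 n_defined = sum(defined), n_degenerate = sum(deg)),
            class = "assembly_classification")
}

#' @export
print.assembly_classification <- function(x, ...) {
  cat("assembly process fractions (", x$n_defined, " pairs):\n", sep = "")
  print(round(x$fractions, 3))
  cat(sprintf("deterministic %.3f | stochastic %.3f | degenerate pairs %d\n",
              x$deterministic, x$stochastic, x$n_degenerate))
  invisible(x)
}
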