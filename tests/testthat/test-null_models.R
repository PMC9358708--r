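test_that("betaNTI standardizes the observed betaMNTD against tip shuffles", {
  set.seed(31)
  m <- matrix(rpois(40, 6), 8, 5,
              dimnames = list(paste0("t", 1:8), paste0("S", 1:5)))
  m[1, colSums(m) == 0] <- 1
  tab <- otu_table(m, "counts")
  D <- random_additive_matrix(8, seed = 3)
  dimnames(D) <- list(rownames(m), rownames(m))
  cfg <- null_model_config(n_null = 199, seed = 4)
  res <- bnti_matrix(tab, D, cfg)
  ok <- !res$degenerate & upper.tri(res$bnti)
  expect_equal(res$bnti[ok],
               (res$obs[ok] - res$null_mean[ok]) / res$null_sd[ok])
  expect_true(all(res$null_sd >= 0))
  # same seed, same answer
  res2 <- bnti_matrix(tab, D, cfg)
  expect_identical(res$bnti, res2$bnti)
})

test_that("a symmetric star phylogeny makes the betaNTI null degenerate", {
  tab <- make_counts(c(3L, 0L, 4L, 0L, 5L, 1L), taxa = c("t1", "t2", "t3"))
  star <- matrix(0.8, 3, 3,
                 dimnames = list(c("t1", "t2", "t3"), c("t1", "t2", "t3")))
  diag(star) <- 0
  res <- bnti_matrix(tab, star, null_model_config(n_null = 49, seed = 1))
  expect_true(res$degenerate["S1", "S2"])
  expect_true(is.na(res$bnti["S1", "S2"]))
})

test_that("exhaustive-mode betaNTI is deterministic and seed independent", {
  set.seed(6)
  m <- matrix(rpois(20, 5) + 1L, 4, 5,
              dimnames = list(paste0("t", 1:4), paste0("S", 1:5)))
  m[2, 2] <- 0L; m[3, 4] <- 0L
  tab <- otu_table(m, "counts")
  D <- random_additive_matrix(4, seed = 8)
  dimnames(D) <- list(rownames(m), rownames(m))
  a <- bnti_matrix(tab, D, null_model_config(seed = 1, exhaustive = TRUE))
  b <- bnti_matrix(tab, D, null_model_config(seed = 999, exhaustive = TRUE))
  expect_identical(a$bnti, b$bnti)
  expect_true(a$exhaustive)
  expect_equal(a$n_null, factorial(4))
})

test_that("sampled betaNTI converges to the exhaustive enumeration", {
  set.seed(12)
  m <- matrix(rpois(25, 8) + 1L, 5, 5,
              dimnames = list(paste0("t", 1:5), paste0("S", 1:5)))
  m[1, 1] <- 0L; m[4, 3] <- 0L
  tab <- otu_table(m, "counts")
  D <- random_additive_matrix(5, seed = 13)
  dimnames(D) <- list(rownames(m), rownames(m))
  ex <- bnti_matrix(tab, D, null_model_config(exhaustive = TRUE))
  sa <- bnti_matrix(tab, D, null_model_config(n_null = 10000, seed = 2))
  ok <- !ex$degenerate & upper.tri(ex$bnti)
  expect_lt(max(abs(ex$bnti[ok] - sa$bnti[ok])), 0.05)
})

test_that("RC-Bray returns its exact extremes on constructed cases", {
  set.seed(20)
  m <- matrix(rpois(40, 10) + 1L, 8, 5,
              dimnames = list(paste0("t", 1:8), paste0("S", 1:5)))
  tab <- otu_table(m, "counts")
  cfg <- null_model_config(n_null = 99, seed = 7)
  res <- rc_bray_matrix(tab, cfg)
  off <- upper.tri(res$rc)
  expect_true(all(res$rc[off] >= -1 & res$rc[off] <= 1))
  # all samples share one single taxon: obs BC = 0 and every null pair is
  # identical single-taxon communities -> all ties -> RC = 0
  one <- otu_table(matrix(c(10L, 0L, 12L, 0L), 2, 2,
                          dimnames = list(c("a", "b"), c("S1", "S2"))),
                   "counts")
  tie <- rc_bray_matrix(one, cfg)
  expect_equal(tie$obs["S1", "S2"], 0)
  expect_equal(tie$p["S1", "S2"], 0.5)
  expect_equal(tie$rc["S1", "S2"], 0)
  # two disjoint single-taxon samples in a two-taxon pool: obs BC = 1 beats
  # every null that draws the same taxon for both samples, ties the rest
  two <- otu_table(matrix(c(10L, 0L, 0L, 10L), 2, 2,
                          dimnames = list(c("a", "b"), c("S1", "S2"))),
                   "counts")
  ext <- rc_bray_matrix(two, cfg)
  expect_gte(ext$rc["S1", "S2"], 0)
  expect_true(all(abs(ext$rc) <= 1))
})

test_that("RC-Bray null communities preserve richness and totals", {
  set.seed(33)
  occ <- c(4, 2, 1, 3, 5); reg <- c(0.4, 0.1, 0.05, 0.15, 0.3)
  for (i in 1:20) {
    cm <- assemble_null_community(3, 50, occ, reg)
    expect_equal(sum(cm > 0), 3)
    expect_equal(sum(cm), 50)
  }
  expect_error(assemble_null_community(6, 50, occ, reg), "exceeds")
})

test_that("degenerate RC inputs error as contracted", {
  tab <- make_counts(matrix(c(1L, 2L), 1, 2), taxa = "t1")
  expect_error(rc_bray_matrix(otu_table(matrix(c(0.5, 0.5), 2, 1,
    dimnames = list(c("a", "b"), "S1")), "proportions"),
    null_model_config(n_null = 9)), "depth")
})

test_that("process classification honors thresholds, boundaries and signs", {
  mk_bnti <- function(vals) {
    b <- make_dist(c("A", "B", "C"), A_B = vals[1], A_C = vals[2],
                   B_C = vals[3])
    structure(list(obs = b, null_mean = b * 0, null_sd = b * 0 + 1,
                   bnti = b, degenerate = b != b, n_null = 999,
                   exhaustive = FALSE, weighted = TRUE),
              class = "bnti_result")
  }
  mk_rc <- function(vals) {
    r <- make_dist(c("A", "B", "C"), A_B = vals[1], A_C = vals[2],
                   B_C = vals[3])
    structure(list(obs = abs(r), p = (r + 1) / 2, rc = r, n_null = 999),
              class = "rc_result")
  }
  cfg <- null_model_config()
  # betaNTI decides first; otherwise RC splits the stochastic classes
  cl <- classify_assembly(mk_bnti(c(2.5, -2.5, 0.5)),
                          mk_rc(c(0, 0, 0.99)), cfg)
  pr <- setNames(cl$pairs$process,
                 paste(cl$pairs$sample_i, cl$pairs$sample_j))
  expect_equal(unname(pr["A B"]), "heterogeneous_selection")
  expect_equal(unname(pr["A C"]), "homogeneous_selection")
  expect_equal(unname(pr["B C"]), "dispersal_limitation")
  cl2 <- classify_assembly(mk_bnti(c(0.5, 0.5, 2)),
                           mk_rc(c(-0.99, 0.3, 0.95)), cfg)
  pr2 <- setNames(cl2$pairs$process,
                  paste(cl2$pairs$sample_i, cl2$pairs$sample_j))
  expect_equal(unname(pr2["A B"]), "homogenizing_dispersal")
  expect_equal(unname(pr2["A C"]), "undominated")
  # boundaries fall to the less extreme class: betaNTI = 2, RC = 0.95
  expect_equal(unname(pr2["B C"]), "undominated")
  # literal sign convention swaps the selection labels
  lit <- null_model_config(sign_convention = "literal")
  cl3 <- classify_assembly(mk_bnti(c(2.5, -2.5, 0.5)),
                           mk_rc(c(0, 0, 0)), lit)
  pr3 <- setNames(cl3$pairs$process,
                  paste(cl3$pairs$sample_i, cl3$pairs$sample_j))
  expect_equal(unname(pr3["A B"]), "homogeneous_selection")
  expect_equal(unname(pr3["A C"]), "heterogeneous_selection")
})

test_that("process fractions partition the defined pairs", {
  set.seed(41)
  sim <- tiny_sim(seed = 41)
  cfg <- null_model_config(n_null = 99, seed = 5)
  bn <- bnti_matrix(sim$otu, patristic_distances(sim$tree), cfg)
  rc <- rc_bray_matrix(sim$otu, cfg)
  cl <- classify_assembly(bn, rc, cfg)
  expect_equal(sum(cl$fractions), 1, tolerance = 1e-9)
  expect_equal(cl$deterministic + cl$stochastic, 1, tolerance = 1e-9)
  expect_equal(cl$n_defined + cl$n_degenerate, nrow(cl$pairs))
})
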