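md <- data.frame(sample_id = c("A", "B", "C"), pH = c(7, 9, 4),
                 flat = c(1, 1, 1), holey = c(1, NA, 3))

test_that("environmental divergence is the absolute difference", {
  d <- env_distance(md, "pH")
  expect_equal(d["A", "B"], 2)
  expect_equal(d["B", "C"], 5)
  expect_equal(d["A", "C"], 3)
  expect_true(attr(env_distance(md, "flat"), "constant"))
  dh <- env_distance(md, "holey")
  expect_equal(attr(dh, "excluded"), "B")
  expect_equal(dim(dh), c(2L, 2L))
  expect_error(env_distance(md, "nope"), "unknown variable")
})

test_that("Mantel r is exact on linearly related matrices", {
  D <- random_additive_matrix(5, seed = 2)
  res <- mantel_test(D, 2 * D, exhaustive_cap = 0, n_perm = 99, seed = 1)
  expect_equal(res$r, 1)
  expect_gte(res$p, 1 / 100)
})

test_that("sampled Mantel p matches exhaustive enumeration at n = 4", {
  set.seed(3)
  D1 <- random_additive_matrix(4, seed = 31)
  D2 <- random_additive_matrix(4, seed = 32)
  dimnames(D2) <- dimnames(D1)
  ex <- mantel_test(D1, D2, exhaustive_cap = 24)
  expect_true(ex$exhaustive)
  sa <- mantel_test(D1, D2, n_perm = 9999, seed = 5, exhaustive_cap = 0)
  expect_lt(abs(ex$p - sa$p), 0.02)
})

test_that("Mantel p is approximately uniform under independence", {
  set.seed(9)
  n <- 6
  hits <- 0; reps <- 200
  for (i in seq_len(reps)) {
    v1 <- runif(n * (n - 1) / 2); v2 <- runif(n * (n - 1) / 2)
    m1 <- matrix(0, n, n); m1[lower.tri(m1)] <- v1
    m1 <- m1 + t(m1)
    m2 <- matrix(0, n, n); m2[lower.tri(m2)] <- v2
    m2 <- m2 + t(m2)
    dimnames(m1) <- dimnames(m2) <- list(paste0("s", 1:n), paste0("s", 1:n))
    p <- mantel_test(m1, m2, n_perm = 199, seed = i,
                     exhaustive_cap = 0)$p
    if (p <= 0.05) hits <- hits + 1
  }
  expect_gt(hits / reps, 0.01)
  expect_lt(hits / reps, 0.10)
})

test_that("Mantel agrees with vegan and is relabeling invariant", {
  D1 <- random_additive_matrix(8, seed = 51)
  D2 <- random_additive_matrix(8, seed = 52)
  dimnames(D2) <- dimnames(D1)
  ours <- mantel_test(D1, D2, n_perm = 999, seed = 3, exhaustive_cap = 0)
  ref <- vegan::mantel(as.dist(D1), as.dist(D2), permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p - ref$signif), 0.05)
  # common relabeling of both matrices leaves r unchanged
  perm <- sample(8)
  ours2 <- mantel_test(D1[perm, perm], D2[perm, perm], n_perm = 99, seed = 3,
                       exhaustive_cap = 0)
  expect_equal(ours2$r, ours$r, tolerance = 1e-12)
  # degenerate input errors
  flat <- D1 * 0
  dimnames(flat) <- dimnames(D1)
  expect_error(mantel_test(D1, flat, exhaustive_cap = 0), "zero-variance")
})

test_that("Spearman panel reproduces the rank worked example and monotone limits", {
  per <- data.frame(sample_id = paste0("S", 1:5),
                    category = "abundant",
                    richness = c(2, 1, 4, 3, 5),
                    richness_share = NA, abundance = c(5, 4, 3, 2, 1))
  cs <- structure(list(per_sample = per, means = NULL),
                  class = "category_summary")
  md5 <- data.frame(sample_id = paste0("S", 1:5), VAR = 1:5)
  out <- spearman_correlations(cs, md5, variables = "VAR")
  # x = 1..5 vs y = (2,1,4,3,5): sum d^2 = 4, rho = 1 - 6*4/(5*24) = 0.8
  expect_equal(out$rho[out$response == "richness"], 0.8)
  expect_equal(out$rho[out$response == "abundance"], -1)
  # strictly monotone transform leaves rho unchanged
  md5b <- data.frame(sample_id = paste0("S", 1:5), VAR = exp(1:5))
  out2 <- spearman_correlations(cs, md5b, variables = "VAR")
  expect_equal(out2$rho, out$rho)
})

test_that("rank-sum exact enumeration matches hand counts", {
  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 4.5)   # U = n_a n_b / 2 under full ties
  expect_equal(same$p, 1)
  sep <- rank_sum_test(c(1, 2), c(10, 11))
  expect_equal(sep$statistic, 0)
  expect_equal(sep$p, 1 / 3)          # 2 of the C(4,2)=6 splits as extreme
  expect_error(rank_sum_test(numeric(0), 1), "empty")
})

test_that("normal approximation tracks the exact rank-sum p for (5,5) splits", {
  set.seed(17)
  pool <- round(rnorm(10), 2)
  splits <- combn(10, 5)
  for (j in seq_len(ncol(splits))) {
    a <- pool[splits[, j]]; b <- pool[-splits[, j]]
    pe <- rank_sum_test(a, b, exact = TRUE)$p
    pn <- rank_sum_test(a, b, exact = FALSE)$p
    expect_lt(abs(pe - pn), 0.05)
  }
})

test_that("rank-sum agrees with wilcox.test where both are defined", {
  set.seed(23)
  a <- rnorm(20); b <- rnorm(25, 0.5)
  ours <- rank_sum_test(a, b)
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
})
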