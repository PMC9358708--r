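test_that("regional classification honors the 0.1% / 0.01% boundaries", {
  # mean relative abundances planted directly via a proportions table
  p <- matrix(c(0.002, 0.00005, 0.0005, 0.001, 0.0001, 0.99635,
                0.002, 0.00005, 0.0005, 0.001, 0.0001, 0.99635), 6, 2,
              dimnames = list(c("abn", "rar", "mid", "edge_ab", "edge_ra",
                                "fill"), c("S1", "S2")))
  cls <- classify_regional(otu_table(p, "proportions"))
  expect_equal(unname(cls$labels["abn"]), "abundant")      # 0.2%
  expect_equal(unname(cls$labels["rar"]), "rare")          # 0.005%
  expect_equal(unname(cls$labels["mid"]), "intermediate")  # 0.05%
  expect_equal(unname(cls$labels["edge_ab"]), "abundant")  # exactly 0.1%: >=
  expect_equal(unname(cls$labels["edge_ra"]), "intermediate") # exactly 0.01%: <
})

test_that("regional means include zero entries across all samples", {
  # taxon at 0.2% in one of two samples: mean 0.1% -> abundant (boundary)
  p <- matrix(c(0.002, 0.998, 0, 1), 2, 2,
              dimnames = list(c("t", "fill"), c("S1", "S2")))
  cls <- classify_regional(otu_table(p, "proportions"))
  expect_equal(unname(cls$labels["t"]), "abundant")
})

test_that("local classification distinguishes absent from rare", {
  p <- matrix(c(0.001, 0.00009, 0, 0.99891), 4, 1,
              dimnames = list(c("ab", "ra", "gone", "fill"), "S1"))
  cls <- classify_local(otu_table(p, "proportions"))
  expect_equal(unname(cls$labels["ab", "S1"]), "abundant")
  expect_equal(unname(cls$labels["ra", "S1"]), "rare")
  expect_equal(unname(cls$labels["gone", "S1"]), "absent")
})

test_that("classification is invariant to counts-vs-proportions input", {
  set.seed(3)
  m <- matrix(rpois(200, 40) * rbinom(200, 1, 0.8), 20, 10,
              dimnames = list(paste0("t", 1:20), paste0("S", 1:10)))
  m[1, ] <- m[1, ] + 5000   # make one clearly abundant taxon
  tab <- otu_table(m, "counts")
  th <- abundance_thresholds(0.05, 0.005)
  reg_c <- classify_regional(tab, th)
  reg_p <- classify_regional(to_relative_abundance(tab), th)
  expect_identical(reg_c$labels, reg_p$labels)
  loc_c <- classify_local(tab, th)
  loc_p <- classify_local(to_relative_abundance(tab), th)
  expect_identical(loc_c$labels, loc_p$labels)
})

test_that("the regional partition is exhaustive, exclusive and monotone", {
  set.seed(8)
  m <- matrix(rpois(300, 10) * rbinom(300, 1, 0.6), 30, 10,
              dimnames = list(paste0("t", 1:30), paste0("S", 1:10)))
  m[m == 0][1] <- 1
  tab <- otu_table(m, "counts")
  th <- abundance_thresholds(0.04, 0.02)
  cls <- classify_regional(tab, th)
  expect_setequal(names(cls$labels), rownames(tab))
  expect_true(all(cls$labels %in% c("abundant", "intermediate", "rare")))
  # raising abundant_min shrinks (or keeps) the abundant set; lowering
  # rare_max shrinks the rare set
  stricter <- classify_regional(tab, abundance_thresholds(0.08, 0.01))
  expect_true(all(names(which(stricter$labels == "abundant")) %in%
                  names(which(cls$labels == "abundant"))))
  expect_true(all(names(which(stricter$labels == "rare")) %in%
                  names(which(cls$labels == "rare"))))
})

test_that("subcommunity subsets are disjoint row filters with samples intact", {
  set.seed(5)
  m <- matrix(rpois(120, 25), 12, 10,
              dimnames = list(paste0("t", 1:12), paste0("S", 1:10)))
  m[1:2, ] <- m[1:2, ] * 50
  m[11:12, ] <- pmin(m[11:12, ], 1)
  tab <- otu_table(m, "counts")
  th <- abundance_thresholds(0.1, 0.01)
  cls <- classify_regional(tab, th)
  ab <- subset_subcommunity(tab, cls, "abundant")
  ra <- subset_subcommunity(tab, cls, "rare")
  expect_identical(colnames(ab), colnames(tab))
  expect_length(intersect(rownames(ab), rownames(ra)), 0)
  expect_equal(sort(c(rownames(ab), rownames(ra),
                      names(which(cls$labels == "intermediate")))),
               sort(rownames(tab)))
  # counts are carried over un-renormalized
  expect_equal(unclass(ab), unclass(tab)[rownames(ab), ],
               ignore_attr = TRUE)
  all_ab <- classify_regional(tab, abundance_thresholds(0.9999, 0.99))
  expect_error(subset_subcommunity(tab, all_ab, "abundant"), "no taxa")
})

test_that("category summaries recover planted richness and abundance shares", {
  # sample with 10 present taxa, 2 abundant carrying 70% of 1000 reads
  counts <- c(rep(350L, 2), rep(50L, 4), rep(25L, 4), 0L)
  tab <- make_counts(matrix(counts, 11, 1), taxa = paste0("t", 1:11))
  th <- abundance_thresholds(abundant_min = 0.2, rare_max = 0.001)
  loc <- classify_local(tab, th)
  cs <- category_summary(tab, loc)
  ab_row <- subset(cs$per_sample, category == "abundant")
  expect_equal(ab_row$richness, 2)
  expect_equal(ab_row$richness_share, 0.2)
  expect_equal(ab_row$abundance, 0.7)
  # per-sample category richness sums to observed richness
  expect_equal(sum(cs$per_sample$richness), 10)
  expect_lte(sum(cs$per_sample$abundance), 1 + 1e-9)
})
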