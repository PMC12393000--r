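test_that("alpha diversity closed forms hold", {
  for (S in c(2, 4, 10)) {
    x <- rep(5, S)
    expect_equal(alpha_diversity(x, "shannon"), log(S))
    expect_equal(alpha_diversity(x, "simpson"), 1 - 1 / S)
    expect_equal(alpha_diversity(x, "richness"), S)
  }
  expect_equal(alpha_diversity(c(0, 7, 0), "shannon"), 0)
  expect_equal(alpha_diversity(c(0, 7, 0), "simpson"), 0)
  expect_equal(alpha_diversity(c(0, 7, 0), "richness"), 1)
  expect_equal(alpha_diversity(c(0.5, 0.25, 0.25), "shannon"), 1.5 * log(2))
  expect_error(alpha_diversity(c(0, 0), "shannon"), "all-zero")
})

test_that("alpha diversity agrees with vegan on random data", {
  skip_if_not_installed("vegan")
  set.seed(31)
  mat <- matrix(rpois(5 * 20, 10), 5, 20,
                dimnames = list(paste0("s", 1:5), paste0("f", 1:20)))
  tab <- alpha_diversity_table(mat)
  expect_equal(tab$shannon, unname(vegan::diversity(mat, "shannon")))
  expect_equal(tab$simpson, unname(vegan::diversity(mat, "simpson")))
})

test_that("Bray-Curtis matches its definition and vegan", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)
  expect_equal(bray_curtis(c(2, 1), c(1, 1)), 0.2)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(1, c(1, 2)), "length")

  skip_if_not_installed("vegan")
  set.seed(32)
  mat <- matrix(runif(6 * 15, 0, 50), 6, 15,
                dimnames = list(paste0("s", 1:6), paste0("f", 1:15)))
  d <- bray_curtis_matrix(mat)
  expect_equal(unclass(d)[lower.tri(d)],
               as.vector(vegan::vegdist(mat, "bray")), tolerance = 1e-12)
})

test_that("PCoA recovers geometry from Euclidean distances", {
  # two points at distance 4 -> one axis at +/- 2
  d2 <- dist_matrix(matrix(c(0, 4, 4, 0), 2,
                           dimnames = list(c("a", "b"), c("a", "b"))))
  expect_warning(res2 <- pcoa(d2, n_axes = 2), "positive axes")
  expect_equal(unname(sort(res2$coordinates[, 1])), c(-2, 2))
  expect_equal(res2$explained_fraction, 1)

  # random planar configuration: distances reconstructed within 1e-8
  set.seed(33)
  pts <- matrix(rnorm(8 * 2), 8, 2)
  dmat <- as.matrix(dist(pts))
  dimnames(dmat) <- list(paste0("s", 1:8), paste0("s", 1:8))
  res <- pcoa(dist_matrix(dmat), n_axes = 2)
  rec <- as.matrix(dist(res$coordinates))
  expect_lt(max(abs(rec - dmat)), 1e-8)

  # identical points: degenerate
  d0 <- dist_matrix(matrix(0, 3, 3, dimnames = list(letters[1:3],
                                                    letters[1:3])))
  expect_warning(res0 <- pcoa(d0), "identical")
  expect_identical(ncol(res0$coordinates), 0L)
})

test_that("PCoA agrees with classical cmdscale", {
  set.seed(34)
  pts <- matrix(rnorm(10 * 3), 10, 3)
  dmat <- as.matrix(dist(pts))
  dimnames(dmat) <- list(paste0("s", 1:10), paste0("s", 1:10))
  res <- pcoa(dist_matrix(dmat), n_axes = 3)
  ref <- cmdscale(as.dist(dmat), k = 3)
  for (ax in 1:3) {  # axes defined up to sign
    expect_true(isTRUE(all.equal(res$coordinates[, ax], unname(ref[, ax]),
                                 tolerance = 1e-6, check.attributes = FALSE)) ||
                isTRUE(all.equal(res$coordinates[, ax], -unname(ref[, ax]),
                                 tolerance = 1e-6, check.attributes = FALSE)))
  }
})

test_that("PERMANOVA partitions match the direct sums and vegan's adonis", {
  set.seed(35)
  mat <- matrix(runif(12 * 8, 0, 30), 12, 8,
                dimnames = list(paste0("s", 1:12), paste0("f", 1:8)))
  groups <- rep(c("A", "B", "C"), each = 4)
  d <- bray_curtis_matrix(mat)
  res <- permanova(d, groups, n_permutations = 99, seed = 1)

  # direct SS computation
  n <- 12; k <- 3
  d2 <- unclass(d)^2
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  ss_w <- sum(vapply(split(1:12, groups), function(idx) {
    sub <- d2[idx, idx]
    sum(sub[upper.tri(sub)]) / length(idx)
  }, 0))
  expect_equal(res$r_squared, (ss_tot - ss_w) / ss_tot, tolerance = 1e-12)
  expect_equal(res$pseudo_F,
               ((ss_tot - ss_w) / (k - 1)) / (ss_w / (n - k)),
               tolerance = 1e-12)

  skip_if_not_installed("vegan")
  ref <- vegan::adonis2(as.dist(unclass(d)) ~ g,
                        data = data.frame(g = groups), permutations = 99)
  expect_equal(res$pseudo_F, ref$F[1], tolerance = 1e-9)
  expect_equal(res$r_squared, ref$R2[1], tolerance = 1e-9)
})

test_that("PERMANOVA degenerate cases behave as specified", {
  mat <- matrix(c(0, 0, 1, 1, 0, 0, 1, 1), 4, 2,
                dimnames = list(paste0("s", 1:4), c("f1", "f2")))
  d <- bray_curtis_matrix(mat + 1)
  expect_error(permanova(d, c("a", "b", "c", "d"), 99, seed = 1), "residual")
  expect_error(permanova(d, rep("a", 4), 99, seed = 1), "two groups")
  expect_error(permanova(d, rep(c("a", "b"), 2), 99), "seed")

  # within-group distances 0, between > 0 -> R2 = 1
  mm <- matrix(c(1, 1, 5, 5, 2, 2, 9, 9), 4, 2,
               dimnames = list(paste0("s", 1:4), c("f1", "f2")))
  dd <- bray_curtis_matrix(mm)
  res <- permanova(dd, c("g1", "g1", "g2", "g2"), 99, seed = 2)
  expect_equal(res$r_squared, 1)
  expect_gte(res$p_value, 1 / 100)
})

test_that("PERMANOVA pseudo-F equals one-way ANOVA F on univariate data", {
  set.seed(36)
  y <- c(rnorm(6, 0), rnorm(6, 1), rnorm(6, 2))
  g <- rep(c("a", "b", "c"), each = 6)
  dmat <- as.matrix(dist(y))
  dimnames(dmat) <- list(paste0("s", 1:18), paste0("s", 1:18))
  res <- permanova(dist_matrix(dmat), g, n_permutations = 49, seed = 3)
  f_ref <- summary(aov(y ~ g))[[1]]$`F value`[1]
  expect_equal(res$pseudo_F, f_ref, tolerance = 1e-9)
})

test_that("pairwise PERMANOVA covers all pairs with FDR", {
  set.seed(37)
  mat <- matrix(runif(15 * 6, 0, 10), 15, 6,
                dimnames = list(paste0("s", 1:15), paste0("f", 1:6)))
  g <- rep(c("a", "b", "c"), each = 5)
  out <- pairwise_permanova(bray_curtis_matrix(mat), g, 49, seed = 4)
  expect_identical(nrow(out), 3L)
  expect_true(all(out$p_adjusted >= out$p_value))
})

test_that("Wilcoxon exact p-values come from full enumeration", {
  res <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(res$p_value, 1 / 3)
  expect_match(res$method, "exact")

  # symmetry: identical multisets give p = 1 (no ties across groups needed)
  res2 <- wilcoxon_rank_sum(c(1, 3, 5), c(2, 4, 6))
  expect_equal(wilcoxon_rank_sum(c(2, 4, 6), c(1, 3, 5))$p_value,
               res2$p_value)

  # cross-check against stats::wilcox.test exact p on tie-free draws
  set.seed(38)
  for (i in 1:20) {
    x <- sample(1:100, 6); y <- sample(101:200, 7) - 100.5
    ref <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, ref$p.value,
                 tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact test and handles ties", {
  set.seed(39)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15, 0.5)
    p_exact <- wilcoxon_rank_sum(x, y, mode = "exact")$p_value
    p_norm <- wilcoxon_rank_sum(x, y, mode = "normal")$p_value
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
  # tie-corrected variance matches stats::wilcox.test with correction
  x <- c(1, 2, 2, 3, 5, 5, 6, 8, 9, 10)
  y <- c(2, 3, 3, 4, 5, 7, 7, 8, 11, 12)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(wilcoxon_rank_sum(x, y, mode = "normal")$p_value, ref$p.value,
               tolerance = 1e-9)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "empty")
})

test_that("BH adjustment matches the hand step-up and p.adjust", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(40)
  p <- runif(50)
  expect_equal(bh_fdr(p), p.adjust(p, "BH"))
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("Fisher's method combines p-values via the chi-square tail", {
  expect_equal(fishers_method(c(1, 1, 1))$p_value, 1)
  res <- fishers_method(c(0.5, 0.5))
  expect_equal(res$statistic, -2 * (log(0.5) + log(0.5)))
  expect_equal(res$p_value, 0.5966, tolerance = 1e-4)
  expect_equal(fishers_method(0.123)$p_value, 0.123, tolerance = 1e-9)
  expect_warning(fishers_method(c(0, 0.5)), "clamped")
  # combining k identical p < 1 strengthens the evidence as k grows
  p3 <- fishers_method(rep(0.3, 3))$p_value
  p6 <- fishers_method(rep(0.3, 6))$p_value
  expect_lt(p6, p3)
})

test_that("Cohen's d uses the pooled n-2 denominator", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  x <- c(0.5, 1.5); y <- c(-0.5, 0.5)
  expect_equal(cohens_d(x, y), 1 / sqrt(0.5))  # pooled var = 0.5
  set.seed(41)
  a <- rnorm(5000, 0.7); b <- rnorm(5000, 0)
  expect_lt(abs(cohens_d(a, b) - 0.7), 0.05)
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
  expect_equal(cohens_d(c(2, 2, 2), c(2, 2, 2)), 0)
  expect_error(cohens_d(c(2, 2), c(3, 3)), "variance")
})

test_that("compare_groups flags planted feature shifts with directions", {
  set.seed(42)
  mat <- cbind(shifted = c(rnorm(10, 5), rnorm(10, 0)),
               flat = rnorm(20))
  rownames(mat) <- paste0("s", 1:20)
  g <- rep(c("case", "ctrl"), each = 10)
  out <- compare_groups(mat, g)
  row <- out[out$feature == "shifted", ]
  expect_lt(row$p_adjusted, 0.05)
  expect_identical(row$direction, 1)  # case > ctrl
  expect_gt(out$p_value[out$feature == "flat"], 0.05)
})
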