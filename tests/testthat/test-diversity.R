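test_that("alpha diversity matches hand-computed values", {
  tab <- otu_table(rbind(c(1, 1, 1, 1), c(4, 2, 2, 0)))
  d <- suppressWarnings(alpha_diversity(tab))
  expect_equal(d$richness, c(4L, 3L))
  expect_equal(d$shannon[1], log(4), tolerance = 1e-9)
  expect_equal(d$pielou[1], 1, tolerance = 1e-9)
  # [4,2,2]: H = 0.5 ln 2 + 0.5 ln 4, J = H / ln 3
  expect_equal(d$shannon[2], 0.5 * log(2) + 0.5 * log(4), tolerance = 1e-3)
  expect_equal(d$pielou[2], d$shannon[2] / log(3), tolerance = 1e-3)
})

test_that("Good's coverage counts singletons over reads", {
  # 100 reads with 5 singletons -> coverage 0.95
  m <- rbind(c(rep(1, 5), 45, 50), c(rep(2, 5), 45, 45))
  d <- suppressWarnings(alpha_diversity(otu_table(m)))
  expect_equal(d$goods_coverage[1], 0.95)
  expect_equal(d$goods_coverage[2], 1)
})

test_that("Shannon is maximal iff uniform; zero OTUs never change H", {
  x <- c(5, 9, 1, 7)
  h1 <- suppressWarnings(
    alpha_diversity(otu_table(matrix(x, 2, 4, byrow = TRUE))))$shannon[1]
  h2 <- suppressWarnings(
    alpha_diversity(otu_table(matrix(c(x, 0), 2, 5, byrow = TRUE))))$shannon[1]
  expect_equal(h1, h2, tolerance = 1e-12)
  expect_lt(h1, log(4))
})

test_that("Bray-Curtis agrees with the closed form and its bounds", {
  m <- rbind(c(1, 0), c(0, 1), c(2, 2), c(1, 3))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d[1, 2], 1)
  expect_equal(d[3, 4], 0.25)    # 2/8
  expect_equal(diag(d), setNames(rep(0, 4), rownames(d)))
  h <- hellinger(random_otu_table(6, 20, seed = 5))
  dh <- as.vector(bray_curtis(h))
  expect_true(all(dh >= 0 & dh <= 1))
})

test_that("NMDS recovers embeddable configurations with near-zero stress", {
  pts <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
  d <- dist(pts)
  fit <- nmds(d, k = 2, n_restarts = 5, seed = 1)
  expect_lt(fit$stress, 0.01)
  expect_equal(dim(fit$points), c(4L, 2L))
})

test_that("NMDS recovers the rank order of a line of equally spaced points", {
  d <- dist(matrix(1:5, ncol = 1))
  fit <- nmds(d, k = 2, n_restarts = 10, seed = 2)
  dv <- as.vector(d)
  recv <- as.vector(dist(fit$points))
  # monotone recovery: strictly smaller input distances stay smaller
  smaller <- outer(dv, dv, function(a, b) a < b - 1e-9)
  expect_true(all(outer(recv, recv, "<")[smaller]))
})

test_that("UPGMA merges by average linkage with non-decreasing heights", {
  d <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  d["A", "B"] <- d["B", "A"] <- 1
  d["A", "C"] <- d["C", "A"] <- 4
  d["B", "C"] <- d["C", "B"] <- 4
  hc <- upgma(as.dist(d))
  expect_equal(hc$height, c(1, 4))
  first <- hc$merge[1, ]
  expect_setequal(first, c(-1, -2))  # A and B merge first
  # ultrametric input is a fixed point
  cop <- as.matrix(stats::cophenetic(hc))
  expect_equal(cop[rownames(d), colnames(d)], d)
  # two clear blocks: root splits them
  m2 <- matrix(0.9, 6, 6)
  m2[1:3, 1:3] <- 0.1; m2[4:6, 4:6] <- 0.1
  diag(m2) <- 0
  hc2 <- upgma(as.dist(m2))
  expect_setequal(stats::cutree(hc2, 2)[1:3], 1)
  expect_setequal(stats::cutree(hc2, 2)[4:6], 2)
})

test_that("PERMANOVA pseudo-F matches the direct sums-of-squares formula", {
  set.seed(8)
  x <- matrix(rpois(8 * 10, 30), 8, 10)
  g <- rep(c("a", "b"), each = 4)
  d <- bray_curtis(x)
  res <- permanova(d, g, n_perm = 99, seed = 1)
  dm <- as.matrix(d)
  N <- 8; gsize <- 4
  sst <- sum(dm[upper.tri(dm)]^2) / N
  ssw <- sum(dm[1:4, 1:4][upper.tri(dm[1:4, 1:4])]^2) / gsize +
    sum(dm[5:8, 5:8][upper.tri(dm[5:8, 5:8])]^2) / gsize
  f_direct <- ((sst - ssw) / 1) / (ssw / (N - 2))
  expect_equal(res$statistic, f_direct, tolerance = 1e-9)
})

test_that("PERMANOVA detects complete separation and respects p bounds", {
  dm <- matrix(1, 6, 6)
  dm[1:3, 1:3] <- 0; dm[4:6, 4:6] <- 0
  diag(dm) <- 0
  res <- permanova(as.dist(dm), rep(c("a", "b"), each = 3),
                   n_perm = 999, seed = 2)
  expect_lte(res$p_value, 0.05)
  expect_gte(res$p_value, 1 / 1000)
  expect_error(permanova(as.dist(dm), c("a", rep("b", 5)), seed = 1),
               "at least 2")
})

test_that("geodesic distance uses haversine with a 6371 km radius", {
  meta <- data.frame(sample_id = c("p", "q", "r"),
                     lat = c(0, 0, 45), lon = c(0, 1, 60))
  d <- as.matrix(geodesic_distance(meta))
  expect_equal(d["p", "q"], 111.195, tolerance = 0.01)
  expect_equal(d["p", "p"], 0)
  expect_equal(d, t(d))
})

test_that("Mantel reports perfect correlation for a scaled matrix", {
  set.seed(3)
  d1 <- dist(matrix(rnorm(14), 7, 2))
  res <- mantel_test(d1, 3 * d1, n_perm = 999, seed = 1)
  expect_equal(res$statistic, 1, tolerance = 1e-12)
  expect_equal(res$p_value, 1 / 1000)
  expect_error(mantel_test(d1, dist(rep(0, 7)) + 0, n_perm = 99, seed = 1),
               "constant")
})

test_that("t-test wrapper matches the textbook pooled case and handles ties", {
  # means 1 vs 3, each n = 2, s^2 = 1: pooled t = -2, df = 2
  v <- c(1 - 1 / sqrt(2), 1 + 1 / sqrt(2), 3 - 1 / sqrt(2), 3 + 1 / sqrt(2))
  g <- c("a", "a", "b", "b")
  res <- group_ttest(v, g, var_equal = TRUE)
  expect_equal(res$statistic, -2, tolerance = 1e-9)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 2 * pt(-2, 2), tolerance = 1e-9)
  same <- group_ttest(c(1, 1, 1, 1), g)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("t-test has power against a large mean shift", {
  set.seed(11)
  rej <- sapply(1:50, function(i) {
    v <- c(rnorm(9, 0), rnorm(8, 5))
    group_ttest(v, rep(c("a", "b"), c(9, 8)))$p_value < 0.001
  })
  expect_gte(mean(rej), 0.99)
})
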