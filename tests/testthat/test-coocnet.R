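test_that("all four measures agree with brute-force oracles", {
  set.seed(21)
  for (rep in 1:20) {
    tab <- random_otu_table(sample(4:8, 1), sample(4:10, 1), lambda = 20)
    rel <- to_relative(tab)
    sc <- pairwise_measures(tab)
    for (r in sample(nrow(sc), min(20, nrow(sc)))) {
      x <- rel[, sc$otu_a[r]]
      y <- rel[, sc$otu_b[r]]
      expected <- unname(switch(sc$measure[r],
        pearson = brute_pearson(x, y),
        spearman = brute_spearman(x, y),
        bray_curtis = brute_bray(x, y),
        kullback_leibler = brute_kl(x, y)))
      tol <- if (sc$measure[r] %in% c("pearson", "spearman")) 1e-10 else 1e-9
      expect_equal(sc$raw[r], expected, tolerance = tol)
    }
  }
})

test_that("measures hit their closed-form extremes", {
  m <- rbind(c(10, 10, 40, 40), c(20, 20, 30, 30),
             c(30, 30, 20, 20), c(40, 40, 10, 10))
  tab <- otu_table(m, otu_ids = c("a", "a2", "b", "b2"))
  sc <- pairwise_measures(tab)
  g <- function(p, q, mm)
    sc$raw[sc$otu_a == p & sc$otu_b == q & sc$measure == mm]
  # identical profiles: a and a2
  expect_equal(g("a", "a2", "pearson"), 1, tolerance = 1e-12)
  expect_equal(g("a", "a2", "spearman"), 1, tolerance = 1e-12)
  expect_equal(g("a", "a2", "bray_curtis"), 0, tolerance = 1e-12)
  expect_equal(g("a", "a2", "kullback_leibler"), 0, tolerance = 1e-9)
  # perfectly anti-ranked profiles: a = 10,20,30,40 vs b = 40,30,20,10
  expect_equal(g("a", "b", "pearson"), -1, tolerance = 1e-12)
  expect_equal(g("a", "b", "spearman"), -1, tolerance = 1e-12)
})

test_that("preselection keeps unions, saturates, and bounds candidates", {
  tab <- random_otu_table(6, 12, seed = 4)
  sc <- pairwise_measures(tab)
  expect_warning(sel <- preselect_edges(sc, 250), "keeping all")
  # saturation: all 66 pairs become candidates
  expect_equal(length(unique(paste(sel$otu_a, sel$otu_b))), 66)
  sel2 <- preselect_edges(sc, 5)
  key2 <- unique(paste(sel2$otu_a, sel2$otu_b))
  expect_lte(length(key2), 4 * 2 * 5)
  # union semantics: a pair top-ranked by any single measure is a candidate
  pe <- sc[sc$measure == "pearson", ]
  best <- pe[which.max(pe$association), ]
  expect_true(paste(best$otu_a, best$otu_b) %in% key2)
})

test_that("ReBoot null and bootstrap are seeded and order-invariant", {
  tab <- random_otu_table(8, 6, seed = 6)
  n1 <- reboot_null(tab, c("OTU1", "OTU3"), "pearson", B = 50, seed = 9)
  n2 <- reboot_null(tab, c("OTU1", "OTU3"), "pearson", B = 50, seed = 9)
  expect_identical(n1, n2)
  # swapping the pair order gives the same stream
  n3 <- reboot_null(tab, c("OTU3", "OTU1"), "pearson", B = 50, seed = 9)
  expect_identical(n1, n3)
  expect_false(identical(n1, reboot_null(tab, c("OTU1", "OTU3"), "pearson",
                                         B = 50, seed = 10)))
  b1 <- bootstrap_scores(tab, c("OTU1", "OTU3"), "spearman", B = 50, seed = 9)
  expect_identical(b1, bootstrap_scores(tab, c("OTU1", "OTU3"), "spearman",
                                        B = 50, seed = 9))
})

test_that("a self-copied OTU beats its entire permutation null", {
  set.seed(31)
  base <- rpois(10, 40) + 1
  m <- cbind(base, base, matrix(rpois(10 * 4, 40) + 1, 10, 4))
  tab <- otu_table(m, otu_ids = paste0("o", 1:6))
  obs <- pairwise_measures(tab)
  o <- obs$association[obs$otu_a == "o1" & obs$otu_b == "o2" &
                         obs$measure == "pearson"]
  nl <- reboot_null(tab, c("o1", "o2"), "pearson", B = 100, seed = 3)
  expect_true(all(o > nl, na.rm = TRUE))
  # bootstrap of a duplicated pair is constant at the observed value
  bs <- bootstrap_scores(tab, c("o1", "o2"), "bray_curtis", B = 50, seed = 3)
  expect_true(all(abs(bs - 0) < 1e-12, na.rm = TRUE))
})

test_that("bootstrap distribution is centred near the observed score", {
  set.seed(41)
  ok <- 0
  for (i in 1:10) {
    tab <- random_otu_table(12, 4, lambda = 80)
    obs <- pairwise_measures(tab, "pearson")
    o <- obs$association[obs$otu_a == "OTU1" & obs$otu_b == "OTU2"]
    bs <- bootstrap_scores(tab, c("OTU1", "OTU2"), "pearson",
                           B = 100, seed = i)
    se <- sd(bs, na.rm = TRUE)
    if (abs(mean(bs, na.rm = TRUE) - o) < 2 * se) ok <- ok + 1
  }
  expect_gte(ok, 8)
})

test_that("edge p-values behave at the extremes and gate on stability", {
  nl <- rnorm(100)
  res <- edge_pvalue(50, nl, rnorm(100, 50, 0.5))
  expect_equal(res$p_value, 1 / 101)
  expect_true(res$stable)
  res2 <- edge_pvalue(mean(nl), nl, rnorm(100, mean(nl), 0.5))
  expect_equal(res2$p_value, 1)
  expect_false(res2$stable)   # null mean inside the bootstrap interval
  expect_true(is.na(edge_pvalue(1, rnorm(10))$p_value))
})

test_that("Simes merging follows the sorted-minimum formula", {
  expect_equal(simes_merge(c(0.01, 0.03, 0.04)), 0.03)
  expect_equal(simes_merge(rep(0.2, 4)), 0.2)
  expect_equal(simes_merge(0.07), 0.07)
  expect_equal(simes_merge(c(0.9, 0.95, NA)), min(2 * 0.9, 0.95))
})

test_that("BH correction reproduces the step-up computation", {
  bh <- bh_correct(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_equal(bh$q, rep(0.04, 4))
  expect_true(all(bh$keep))
  bh1 <- bh_correct(rep(1, 5))
  expect_equal(bh1$q, rep(1, 5))
  expect_false(any(bh1$keep))
})

test_that("build_network yields a simple annotated signed graph", {
  edges <- data.frame(otu_a = c("a", "a", "c"), otu_b = c("b", "c", "d"),
                      sign = c("+", "-", "+"), merged_p = c(1e-4, 1e-3, 1e-3),
                      q = c(0.01, 0.02, 0.02),
                      supporting_measures = "pearson",
                      stringsAsFactors = FALSE)
  tax <- toy_taxonomy(letters[1:4])
  net <- build_network(edges, tax, setNames(c(0.1, 0.2, 0.3, 0.4),
                                            letters[1:4]))
  expect_equal(igraph::vcount(net), 4)
  expect_equal(igraph::ecount(net), 3)
  expect_true(igraph::is_simple(net))
  expect_setequal(igraph::E(net)$sign, c("+", "-", "+"))
  expect_equal(sort(igraph::V(net)$mean_rel_abundance), c(0.1, 0.2, 0.3, 0.4))
  expect_warning(empty <- build_network(edges[0, ]), "no significant")
  expect_equal(igraph::vcount(empty), 0)
})

test_that("network inference is deterministic and order-invariant", {
  sim <- generate_community(synthetic_spec(
    n_core = 16, n_tail = 30, n_blocks = 3, block_size = 4,
    n_exclusion = 1, seed = 77))
  rar <- rarefy_table(sim$table, "min", seed = 1)
  prev <- filter_prevalence(filter_low_abundance(rar))
  nw1 <- infer_network(prev, sim$taxonomy, B = 40, top_n = 30, seed = 5)
  nw2 <- infer_network(prev, sim$taxonomy, B = 40, top_n = 30, seed = 5)
  expect_identical(nw1$edges, nw2$edges)
  # permute OTU columns: identical edge set
  perm <- sample(ncol(prev))
  prev_p <- otu_table(unclass(prev)[, perm])
  nw3 <- infer_network(prev_p, sim$taxonomy, B = 40, top_n = 30, seed = 5)
  key <- function(e) sort(paste(e$otu_a, e$otu_b, e$sign))
  expect_identical(key(nw1$edges), key(nw3$edges))
})

test_that("sign handling: planted exclusion pairs come out negative", {
  sim <- generate_community(synthetic_spec(
    n_core = 20, n_tail = 20, n_blocks = 2, block_size = 4,
    n_exclusion = 3, delta = 0, decay_rate = 0, seed = 13))
  rar <- rarefy_table(sim$table, "min", seed = 1)
  prev <- filter_prevalence(filter_low_abundance(rar))
  nw <- infer_network(prev, sim$taxonomy, top_n = 60, seed = 3)
  ek <- paste(sim$truth$exclusion_pairs$otu_a, sim$truth$exclusion_pairs$otu_b)
  kk <- paste(nw$edges$otu_a, nw$edges$otu_b)
  found <- nw$edges$sign[kk %in% ek]
  expect_gte(length(found), 1)
  expect_true(all(found == "-"))
})
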