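#' Per-sample alpha diversity
#'
#' Computes, for every sample: richness S (number of OTUs observed), Shannon
#' H in nats (vegan's `diversity`), Pielou evenness J = H / ln S (NA when
#' S = 1), and Good's coverage 1 - singletons / reads, the estimated
#' fraction of the community captured by the sequencing effort. Intended for
#' depth-equalized tables; a warning is raised when row sums differ.
#'
#' @param table an [otu_table].
#' @return data.frame with columns `sample_id`, `richness`, `shannon`,
#'   `pielou`, `goods_coverage`.
#' @export
alpha_diversity <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  m <- unclass_table(table)
  if (length(unique(rowSums(m))) > 1L)
    warning("unequal sample depths; rarefy before comparing alpha diversity")
  S <- rowSums(m > 0)
  H <- vegan::diversity(m, index = "shannon")
  J <- ifelse(S > 1, H / log(S), NA_real_)
  singletons <- rowSums(m == 1)
  coverage <- 1 - singletons / rowSums(m)
  data.frame(sample_id = rownames(m), richness = as.integer(S),
             shannon = as.numeric(H), pielou = as.numeric(J),
             goods_coverage = as.numeric(coverage),
             row.names = rownames(m))
}

#' Two-sample comparison of a per-sample index
#'
#' Welch's t-test by default (robust to unequal variances); set
#' `var_equal = TRUE` for the classical pooled-variance Student's t.
#' Two-sided. Degenerate input with zero variance in both groups and equal
#' means returns t = 0, p = 1.
#'
#' @param values numeric vector, one value per sample.
#' @param groups factor/character of the same length with exactly 2 levels,
#'   each with at least 2 members.
#' @param var_equal pool the variances (classical Student's t)?
#' @return list with `statistic`, `df`, `p_value`.
#' @export
group_ttest <- function(values, groups, var_equal = FALSE) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 samples")
  sp <- split(values, groups)
  if (stats::var(sp[[1]]) == 0 && stats::var(sp[[2]]) == 0 &&
      mean(sp[[1]]) == mean(sp[[2]])) {
    return(list(statistic = 0, df = length(values) - 2L, p_value = 1))
  }
  tt <- stats::t.test(values ~ groups, var.equal = var_equal)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Bray-Curtis distance matrix
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i), in [0, 1] for non-negative
#' profiles. Conventionally applied to Hellinger-transformed abundances
#' (see [hellinger]).
#'
#' @param mat samples x OTUs non-negative matrix.
#' @return a `dist` object.
#' @export
bray_curtis <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("Bray-Curtis needs non-negative input")
  if (any(rowSums(mat) == 0)) stop("all-zero row: Bray-Curtis undefined")
  vegan::vegdist(mat, method = "bray")
}

#' Non-metric multidimensional scaling
#'
#' Kruskal NMDS minimizing stress-1 on the supplied distance matrix, best of
#' `n_restarts` random starts (vegan's `metaMDS` engine on a pre-computed
#' distance). Stress is reported on the 0-1 scale.
#'
#' @param d a `dist` object.
#' @param k target dimensionality (default 2).
#' @param n_restarts number of random restarts.
#' @param seed integer seed.
#' @return list with `points` (n x k coordinates), `stress`, `converged`.
#' @export
nmds <- function(d, k = 2, n_restarts = 20, seed = 1L) {
  n <- attr(d, "Size")
  if (n < k + 1) stop("need at least k+1 points")
  set.seed(as.integer(seed))
  fit <- vegan::metaMDS(d, k = k, try = n_restarts, trymax = n_restarts,
                        trace = 0, wascores = FALSE)
  list(points = fit$points, stress = fit$stress,
       converged = isTRUE(fit$converged) || fit$stress < 1e-3,
       n_restarts = n_restarts)
}

#' UPGMA dendrogram
#'
#' Average-linkage agglomerative clustering of a distance matrix; merge
#' heights are non-decreasing. Use [ape::write.tree] with [ape::as.phylo] to
#' export Newick.
#'
#' @param d a `dist` object over at least 2 samples.
#' @return an `hclust` object.
#' @export
upgma <- function(d) {
  if (attr(d, "Size") < 2L) stop("need at least 2 points")
  stats::hclust(d, method = "average")
}

#' Write a dendrogram in Newick format
#'
#' @param hc an `hclust` tree (e.g. from [upgma]).
#' @param path output file.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' PERMANOVA on a distance matrix
#'
#' One-way permutational multivariate analysis of variance: the pseudo-F
#' statistic compares among-group to within-group dispersion of squared
#' distances, with significance from random label permutations (vegan's
#' `adonis2`). p-values use the add-one convention, so p >= 1/(n_perm+1).
#'
#' @param d a `dist` object.
#' @param groups group label per sample (>= 2 groups, each of size >= 2).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `statistic` (pseudo-F), `r2`, `n_permutations`,
#'   `p_value`, `seed`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 members")
  set.seed(as.integer(seed))
  df <- data.frame(group = groups)
  fit <- vegan::adonis2(d ~ group, data = df, permutations = n_perm)
  list(statistic = fit$F[1], r2 = fit$R2[1], n_permutations = n_perm,
       p_value = fit$`Pr(>F)`[1], seed = as.integer(seed))
}

#' Great-circle distances between samples (km)
#'
#' Haversine distance with Earth radius 6371 km, so 1 degree of latitude is
#' 111.195 km.
#'
#' @param meta data.frame with columns `sample_id`, `lat`, `lon`.
#' @return a `dist` object in kilometres.
#' @export
geodesic_distance <- function(meta) {
  if (any(!is.finite(meta$lat)) || any(!is.finite(meta$lon)))
    stop("missing coordinates")
  xy <- cbind(meta$lon, meta$lat)
  m <- geosphere::distm(xy, fun = function(a, b)
    geosphere::distHaversine(a, b, r = 6371000)) / 1000
  rownames(m) <- colnames(m) <- meta$sample_id
  stats::as.dist(m)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries, with a one-sided
#' permutation test (r_perm >= r_obs) by simultaneous row/column permutation
#' of one matrix — the directional test for distance decay of community
#' similarity. Add-one p convention.
#'
#' @param d1,d2 `dist` objects over the same samples in the same order.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `statistic` (Mantel r), `n_permutations`, `p_value`,
#'   `seed`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1L) {
  if (attr(d1, "Size") != attr(d2, "Size"))
    stop("distance matrices must match in size")
  if (stats::sd(as.vector(d1)) == 0 || stats::sd(as.vector(d2)) == 0)
    stop("constant distance matrix: Mantel r undefined")
  set.seed(as.integer(seed))
  fit <- vegan::mantel(d1, d2, method = "pearson", permutations = n_perm)
  list(statistic = fit$statistic, n_permutations = n_perm,
       p_value = fit$signif, seed = as.integer(seed))
}
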