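# Independent brute-force oracles. These deliberately use naive loops and
# direct textbook formulas, sharing no code with the package internals.

brute_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- den1 <- den2 <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    den1 <- den1 + (x[i] - mx)^2
    den2 <- den2 + (y[i] - my)^2
  }
  if (den1 == 0 || den2 == 0) return(NA_real_)
  num / sqrt(den1 * den2)
}

brute_spearman <- function(x, y) brute_pearson(rank(x), rank(y))

brute_bray <- function(x, y) {
  num <- den <- 0
  for (i in seq_along(x)) {
    num <- num + abs(x[i] - y[i])
    den <- den + x[i] + y[i]
  }
  if (den == 0) return(NA_real_)
  num / den
}

brute_kl <- function(x, y, eps = 1e-6) {
  p <- x + eps
  q <- y + eps
  p <- p / sum(p)
  q <- q / sum(q)
  d <- 0
  for (i in seq_along(p))
    d <- d + 0.5 * (p[i] * log(p[i] / q[i]) + q[i] * log(q[i] / p[i]))
  d
}

# unweighted shortest-path machinery on an adjacency matrix (BFS per source)
brute_sp <- function(adj, s) {
  n <- nrow(adj)
  dist <- rep(Inf, n)
  nsp <- rep(0, n)
  dist[s] <- 0
  nsp[s] <- 1
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in which(adj[v, ] == 1)) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1) nsp[w] <- nsp[w] + nsp[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, nsp = nsp)
}

# Brandes-semantics betweenness by direct triple enumeration
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  sp <- lapply(seq_len(n), function(s) brute_sp(adj, s))
  btw <- rep(0, n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    dst <- sp[[s]]$dist[t]
    if (is.infinite(dst)) next
    sigma <- sp[[s]]$nsp[t]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (sp[[s]]$dist[v] + sp[[t]]$dist[v] == dst)
        btw[v] <- btw[v] + sp[[s]]$nsp[v] * sp[[t]]$nsp[v] / sigma
    }
  }
  btw
}

# per-component closeness (n_c - 1) / sum of distances
brute_closeness <- function(adj) {
  n <- nrow(adj)
  d <- sapply(seq_len(n), function(s) brute_sp(adj, s)$dist)
  cls <- rep(NA_real_, n)
  for (v in seq_len(n)) {
    comp <- which(is.finite(d[, v]))
    if (length(comp) < 2) next
    cls[v] <- (length(comp) - 1) / sum(d[comp, v])
  }
  cls
}

# modularity by direct double sum over the adjacency matrix
brute_modularity <- function(adj, membership) {
  m2 <- sum(adj)            # 2m
  if (m2 == 0) return(0)
  deg <- rowSums(adj)
  q <- 0
  n <- nrow(adj)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (membership[i] == membership[j])
      q <- q + adj[i, j] - deg[i] * deg[j] / m2
  }
  q / m2
}

# all set partitions of 1..n (restricted growth strings); n <= 9 only
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, kmax) {
    i <- length(assign) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- assign
      return()
    }
    for (k in seq_len(kmax + 1)) rec(c(assign, k), max(kmax, k))
  }
  rec(integer(0), 0L)
  out
}

brute_best_modularity <- function(adj) {
  best <- -Inf
  for (p in all_partitions(nrow(adj)))
    best <- max(best, brute_modularity(adj, p))
  best
}

# random test fixtures -------------------------------------------------------

random_otu_table <- function(n_samples, n_otus, lambda = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rpois(n_samples * n_otus, lambda) + 1L, n_samples, n_otus)
  otu_table(m, paste0("S", seq_len(n_samples)),
            paste0("OTU", seq_len(n_otus)))
}

random_graph <- function(n, p_edge = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (runif(1) < p_edge) adj[i, j] <- adj[j, i] <- 1L
  rownames(adj) <- colnames(adj) <- paste0("v", seq_len(n))
  adj
}

graph_from_adj <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# minimal taxonomy for a set of OTU ids
toy_taxonomy <- function(otu_ids, phylum = "Proteobacteria") {
  data.frame(otu_id = otu_ids, phylum = phylum,
             class = "c", order = "o", family = "f",
             genus = paste0("Genus_", otu_ids),
             stringsAsFactors = FALSE)
}
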