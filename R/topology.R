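## Network topology: global metrics, fast-greedy modules, centralities,
## keystones and taxonomic co-presence structure. All metrics are computed
## on the unsigned skeleton; edge signs only enter the positive-edge count
## and the same-phylum co-presence fraction.

#' Global network metrics
#'
#' Node and edge counts, number of positive edges, and the clustering
#' coefficient. The default clustering coefficient is the average local one,
#' C_i = 2 T_i / (k_i (k_i - 1)) averaged over all nodes with C_i = 0 for
#' degree < 2; `type = "global"` gives instead the transitivity ratio
#' (3 x triangles / connected triples).
#'
#' @param net igraph network with an edge attribute `sign` (`"+"`/`"-"`);
#'   a missing attribute counts every edge as positive.
#' @param type `"local_average"` (default) or `"global"`.
#' @return list with `n_nodes`, `n_edges`, `n_positive`,
#'   `clustering_coefficient`.
#' @export
global_metrics <- function(net, type = c("local_average", "global")) {
  type <- match.arg(type)
  n <- igraph::vcount(net)
  m <- igraph::ecount(net)
  if (n == 0L) {
    warning("empty network")
    return(list(n_nodes = 0L, n_edges = 0L, n_positive = 0L,
                clustering_coefficient = 0))
  }
  sgn <- igraph::edge_attr(net, "sign")
  npos <- if (is.null(sgn)) m else sum(sgn == "+")
  cc <- if (type == "local_average") {
    if (m == 0L) 0 else
      mean(igraph::transitivity(net, type = "localundirected",
                                isolates = "zero"))
  } else {
    t <- igraph::transitivity(net, type = "global")
    if (is.nan(t)) 0 else t
  }
  list(n_nodes = n, n_edges = m, n_positive = as.integer(npos),
       clustering_coefficient = cc)
}

#' Modularity of a given partition
#'
#' Q = (1/2m) sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j) on the unsigned
#' skeleton; the single-community partition always gives Q = 0.
#'
#' @param net igraph network.
#' @param membership integer/character community label per node.
#' @return modularity Q.
#' @export
modularity_q <- function(net, membership) {
  m <- igraph::ecount(net)
  if (m == 0L) return(0)
  membership <- as.integer(as.factor(membership))
  el <- igraph::as_edgelist(net, names = FALSE)
  within <- membership[el[, 1]] == membership[el[, 2]]
  deg <- igraph::degree(net)
  dc <- tapply(deg, membership, sum)
  sum(within) / m - sum((dc / (2 * m))^2)
}

#' Fast-greedy module detection
#'
#' Clauset-Newman-Moore greedy modularity agglomeration: communities start
#' as singletons and the merge with the largest modularity gain is applied
#' until no gain remains. Disconnected networks are handled; module IDs are
#' global. The reported Q is recomputed in-package from the returned
#' partition by the modularity formula, so the two always agree.
#'
#' @param net igraph network.
#' @return list with `membership` (named integer vector), `n_modules`, `Q`.
#' @export
fast_greedy_modules <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0L) return(list(membership = integer(0), n_modules = 0L, Q = 0))
  if (igraph::ecount(net) == 0L) {
    mem <- stats::setNames(seq_len(n), igraph::V(net)$name)
    return(list(membership = mem, n_modules = n, Q = 0))
  }
  g <- igraph::simplify(igraph::as_undirected(net))
  cl <- igraph::cluster_fast_greedy(g, weights = NULL)
  mem <- igraph::membership(cl)
  mem <- stats::setNames(as.integer(mem), igraph::V(g)$name)
  list(membership = mem, n_modules = length(unique(mem)),
       Q = modularity_q(g, mem))
}

#' Betweenness and closeness centrality
#'
#' Betweenness follows Brandes' definition (unnormalized shortest-path pair
#' counts); closeness is computed within each connected component as
#' (n_c - 1) / sum of distances, so disconnected networks get per-component
#' values. Singleton components have undefined closeness (NA).
#'
#' @param net igraph network.
#' @return data.frame with `node`, `betweenness`, `closeness`.
#' @export
centralities <- function(net) {
  if (igraph::vcount(net) == 0L) stop("empty network")
  btw <- igraph::betweenness(net, directed = FALSE, normalized = FALSE)
  comp <- igraph::components(net)$membership
  dmat <- igraph::distances(net)
  cls <- rep(NA_real_, igraph::vcount(net))
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    if (length(idx) < 2L) next
    cls[idx] <- (length(idx) - 1) / rowSums(dmat[idx, idx, drop = FALSE])
  }
  data.frame(node = igraph::V(net)$name, betweenness = unname(btw),
             closeness = cls, stringsAsFactors = FALSE,
             row.names = igraph::V(net)$name)
}

#' Keystone taxa by betweenness/closeness rank-sum
#'
#' Nodes are ranked separately by betweenness and by closeness (largest
#' first); the keystone score is the sum of the two ranks, smaller meaning
#' more keystone. Ties break by higher betweenness, then lexicographic node
#' ID. Relative abundance plays no role, so rare taxa can surface as
#' keystones.
#'
#' @param net igraph network (taxonomy/abundance vertex attributes are
#'   echoed into the output when present).
#' @param cent output of [centralities]; computed when NULL.
#' @param top_k number of keystones to return.
#' @return data.frame of the `top_k` keystone nodes with ranks and any
#'   genus / mean abundance annotation.
#' @export
keystones <- function(net, cent = NULL, top_k = 3) {
  if (is.null(cent)) cent <- centralities(net)
  if (nrow(cent) < top_k) {
    warning("network smaller than top_k; returning all nodes")
    top_k <- nrow(cent)
  }
  rb <- rank(-cent$betweenness, ties.method = "average")
  rc <- rank(-ifelse(is.na(cent$closeness), -Inf, cent$closeness),
             ties.method = "average")
  score <- rb + rc
  o <- order(score, -cent$betweenness, cent$node)
  out <- cent[o[seq_len(top_k)], , drop = FALSE]
  out$rank_sum <- score[o[seq_len(top_k)]]
  for (attrib in c("genus", "phylum", "mean_rel_abundance")) {
    v <- igraph::vertex_attr(net, attrib)
    if (!is.null(v))
      out[[attrib]] <- v[match(out$node, igraph::V(net)$name)]
  }
  rownames(out) <- NULL
  out
}

#' Fraction of co-present OTU pairs from the same phylum
#'
#' Among positive (co-occurrence) edges only, the fraction whose two
#' endpoints share an identical, classified phylum label. Edges with an
#' unclassified phylum on either end are excluded from the denominator and
#' reported separately.
#'
#' @param net igraph network with `sign` edge attribute and `phylum` vertex
#'   attribute (or supply `taxonomy`).
#' @param taxonomy optional taxonomy data.frame used when the network lacks
#'   a `phylum` vertex attribute.
#' @return list with `fraction` (NA when no eligible positive edge),
#'   `n_same`, `n_positive_classified`, `n_excluded_unclassified`.
#' @export
same_phylum_fraction <- function(net, taxonomy = NULL) {
  phy <- igraph::vertex_attr(net, "phylum")
  if (is.null(phy)) {
    if (is.null(taxonomy)) stop("no phylum annotation available")
    phy <- taxonomy[match(igraph::V(net)$name, taxonomy$otu_id), "phylum"]
  }
  phy[is.na(phy)] <- "unclassified"
  el <- igraph::as_edgelist(net, names = FALSE)
  sgn <- igraph::edge_attr(net, "sign")
  if (is.null(sgn)) sgn <- rep("+", nrow(el))
  pos <- sgn == "+"
  if (!any(pos))
    return(list(fraction = NA_real_, n_same = 0L,
                n_positive_classified = 0L, n_excluded_unclassified = 0L))
  pa <- phy[el[pos, 1]]
  pb <- phy[el[pos, 2]]
  uncl <- pa == "unclassified" | pb == "unclassified"
  eligible <- !uncl
  if (!any(eligible))
    return(list(fraction = NA_real_, n_same = 0L,
                n_positive_classified = 0L,
                n_excluded_unclassified = sum(uncl)))
  same <- pa[eligible] == pb[eligible]
  list(fraction = mean(same), n_same = sum(same),
       n_positive_classified = sum(eligible),
       n_excluded_unclassified = sum(uncl))
}

#' Full topology report for a network
#'
#' Bundles global metrics, the fast-greedy module partition, per-node
#' centralities, the keystone list and the same-phylum co-presence fraction.
#'
#' @param net igraph network.
#' @param taxonomy optional taxonomy data.frame (for phylum co-presence when
#'   the network lacks vertex annotation).
#' @param top_k keystones to report.
#' @return list of class `topology_report`.
#' @export
topology_report <- function(net, taxonomy = NULL, top_k = 3) {
  gm <- global_metrics(net)
  if (gm$n_nodes == 0L) {
    rep <- list(n_nodes = 0L, n_edges = 0L, n_positive = 0L,
                clustering_coefficient = 0, Q = 0, n_modules = 0L,
                same_phylum = list(fraction = NA_real_),
                centralities = data.frame(), keystones = data.frame(),
                membership = integer(0))
    class(rep) <- "topology_report"
    return(rep)
  }
  mod <- fast_greedy_modules(net)
  cent <- centralities(net)
  ks <- keystones(net, cent, top_k = min(top_k, nrow(cent)))
  sp <- tryCatch(same_phylum_fraction(net, taxonomy),
                 error = function(e) list(fraction = NA_real_))
  rep <- c(gm, list(Q = mod$Q, n_modules = mod$n_modules,
                    membership = mod$membership,
                    same_phylum = sp, centralities = cent, keystones = ks))
  class(rep) <- "topology_report"
  rep
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf(
    "topology report: %d nodes, %d edges (%d positive), C = %.3f\n",
    x$n_nodes, x$n_edges, x$n_positive, x$clustering_coefficient))
  cat(sprintf("  %d modules, Q = %.3f; same-phylum co-presence = %s\n",
              x$n_modules, x$Q,
              ifelse(is.na(x$same_phylum$fraction), "NA",
                     sprintf("%.3f", x$same_phylum$fraction))))
  invisible(x)
}

#' Side-by-side comparison of two topology reports
#'
#' Tabulates the headline metrics of two networks and flags which is more
#' fragmented: a network is called more fragmented when it has both higher
#' modularity Q and more modules; discordant orderings are labelled
#' inconclusive.
#'
#' @param a,b `topology_report` objects.
#' @param labels length-2 character labels.
#' @return list with `table` (metric x network data.frame) and
#'   `more_fragmented` (`labels[1]`, `labels[2]`, `"equal"` or
#'   `"inconclusive"`).
#' @export
compare_networks <- function(a, b, labels = c("A", "B")) {
  row <- function(r) c(n_nodes = r$n_nodes, n_edges = r$n_edges,
                       n_positive = r$n_positive,
                       positive_frac = if (r$n_edges > 0)
                         r$n_positive / r$n_edges else NA_real_,
                       clustering = r$clustering_coefficient,
                       n_modules = r$n_modules, Q = r$Q,
                       edges_per_node = if (r$n_nodes > 0)
                         r$n_edges / r$n_nodes else NA_real_)
  tab <- data.frame(metric = names(row(a)), check.names = FALSE)
  tab[[labels[1]]] <- unname(row(a))
  tab[[labels[2]]] <- unname(row(b))
  frag <- if (a$Q > b$Q && a$n_modules > b$n_modules) labels[1]
    else if (b$Q > a$Q && b$n_modules > a$n_modules) labels[2]
    else if (a$Q == b$Q && a$n_modules == b$n_modules) "equal"
    else "inconclusive"
  list(table = tab, more_fragmented = frag)
}
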