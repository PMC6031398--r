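## Ensemble co-occurrence inference.
##
## Candidate OTU-OTU associations are scored by four measures (Pearson,
## Spearman, Bray-Curtis, Kullback-Leibler) on relative-abundance profiles;
## each measure's significance comes from a renormalized permutation null
## that preserves the compositional bias (permute the pair's counts across
## samples, then recompute every sample's relative abundances with the
## permuted pair in place), paired with a bootstrap stability filter.
## Measure p-values are merged by the Simes rule and the candidate set is
## FDR-controlled by Benjamini-Hochberg.

COOC_MEASURES <- c("pearson", "spearman", "bray_curtis", "kullback_leibler")
KL_PSEUDOCOUNT <- 1e-6

# deterministic per-pair seed so results do not depend on OTU column order
pair_seed <- function(seed, a, b) {
  ids <- sort(c(a, b))
  h <- 0
  for (ch in utf8ToInt(paste(ids, collapse = "\r"))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  h <- (h * 48271) %% 2147483647
  bitwXor(as.integer(seed %% 2147483647), as.integer(h))
}

# column-wise measures between paired profile matrices (samples x B)
.pearson_cols <- function(X, Y) {
  n <- nrow(X)
  Xc <- X - rep(colMeans(X), each = n)
  Yc <- Y - rep(colMeans(Y), each = n)
  den <- sqrt(colSums(Xc * Xc) * colSums(Yc * Yc))
  r <- colSums(Xc * Yc) / den
  r[!is.finite(r)] <- NA_real_
  r
}

.spearman_cols <- function(X, Y) {
  .pearson_cols(apply(X, 2, rank), apply(Y, 2, rank))
}

.bray_cols <- function(X, Y) {
  den <- colSums(X + Y)
  d <- colSums(abs(X - Y)) / den
  d[den == 0] <- NA_real_
  d
}

.kl_cols <- function(X, Y) {
  P <- X + KL_PSEUDOCOUNT
  Q <- Y + KL_PSEUDOCOUNT
  P <- P / rep(colSums(P), each = nrow(P))
  Q <- Q / rep(colSums(Q), each = nrow(Q))
  0.5 * (colSums(P * log(P / Q)) + colSums(Q * log(Q / P)))
}

# raw scores for all requested measures; X, Y are samples x B matrices of
# relative abundances. Returns measures x B matrix of RAW values.
.measure_cols <- function(X, Y, measures) {
  out <- matrix(NA_real_, length(measures), ncol(X),
                dimnames = list(measures, NULL))
  for (m in measures) {
    out[m, ] <- switch(m,
      pearson = .pearson_cols(X, Y),
      spearman = .spearman_cols(X, Y),
      bray_curtis = .bray_cols(X, Y),
      kullback_leibler = .kl_cols(X, Y))
  }
  out
}

# orientation: larger = stronger co-occurrence for every measure
.to_association <- function(raw, measures) {
  flip <- measures %in% c("bray_curtis", "kullback_leibler")
  raw * ifelse(flip, -1, 1)
}

is_dissimilarity <- function(measure) {
  measure %in% c("bray_curtis", "kullback_leibler")
}

#' Pairwise association measures between OTU profiles
#'
#' Computes the four ensemble measures for every unordered OTU pair on
#' per-sample relative abundances: Pearson and Spearman correlation,
#' Bray-Curtis dissimilarity, and symmetrized Kullback-Leibler divergence
#' (profiles renormalized to sum one after adding a 1e-6 pseudocount).
#' Each raw value is also reported on a common association scale oriented
#' so that larger means stronger co-occurrence (dissimilarities negated).
#'
#' @param table an [otu_table] (typically prevalence-filtered); converted to
#'   per-sample relative abundances internally.
#' @param measures subset of
#'   `c("pearson", "spearman", "bray_curtis", "kullback_leibler")`.
#' @return data.frame with columns `otu_a`, `otu_b` (lexicographically
#'   ordered within each pair), `measure`, `raw`, `association`. Pairs with
#'   an undefined measure (zero-variance profile) carry NA for that measure.
#' @export
pairwise_measures <- function(table, measures = COOC_MEASURES) {
  measures <- match.arg(measures, COOC_MEASURES, several.ok = TRUE)
  m <- unclass_table(as.matrix(table))
  if (nrow(m) < 4L) stop("need at least 4 samples")
  rel <- to_relative(m)
  p <- ncol(rel)
  ids <- colnames(rel)
  pair_idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  a <- pmin(ids[pair_idx[, 1]], ids[pair_idx[, 2]])
  b <- pmax(ids[pair_idx[, 1]], ids[pair_idx[, 2]])

  res <- list()
  for (mm in measures) {
    raw <- switch(mm,
      pearson = {
        r <- suppressWarnings(stats::cor(rel))
        r[pair_idx]
      },
      spearman = {
        r <- suppressWarnings(stats::cor(rel, method = "spearman"))
        r[pair_idx]
      },
      bray_curtis = {
        d <- as.matrix(vegan::vegdist(t(rel), method = "bray"))
        d[pair_idx]
      },
      kullback_leibler = {
        P <- rel + KL_PSEUDOCOUNT
        P <- P / rep(colSums(P), each = nrow(P))
        L <- log(P)
        s <- colSums(P * L)
        M <- crossprod(P, L)          # M[j,k] = sum_i P[i,j] log P[i,k]
        D <- 0.5 * (s - M + t(s - M))
        D[pair_idx]
      })
    res[[mm]] <- data.frame(otu_a = a, otu_b = b, measure = mm, raw = raw,
                            association = .to_association(raw, mm),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Preselect top- and bottom-ranking candidate edges
#'
#' For each measure, pairs are ranked by association; the `top_n` strongest
#' co-occurrence and `top_n` strongest mutual-exclusion pairs are kept, and
#' the candidate set is the union across measures. Ties at a cutoff are
#' broken lexicographically on the pair IDs, so selection is deterministic.
#'
#' @param scores output of [pairwise_measures].
#' @param top_n edges kept from each end of each measure's ranking.
#' @return data.frame `otu_a`, `otu_b`, `measure`, `list` ("top" or
#'   "bottom"): one row per (pair, measure) selection event. Unique pairs
#'   are the candidate set.
#' @export
preselect_edges <- function(scores, top_n = 250) {
  if (top_n < 1) stop("top_n must be >= 1")
  sel <- list()
  for (mm in unique(scores$measure)) {
    sc <- scores[scores$measure == mm & !is.na(scores$association), ]
    key <- paste(sc$otu_a, sc$otu_b, sep = "\r")
    if (nrow(sc) < 2 * top_n)
      warning("measure ", mm, ": only ", nrow(sc),
              " scored pairs for 2*", top_n, " slots; keeping all")
    o_top <- order(-sc$association, key)
    o_bot <- order(sc$association, key)
    top <- sc[o_top[seq_len(min(top_n, nrow(sc)))], c("otu_a", "otu_b")]
    bot <- sc[o_bot[seq_len(min(top_n, nrow(sc)))], c("otu_a", "otu_b")]
    top$measure <- mm; top$list <- "top"
    bot$measure <- mm; bot$list <- "bottom"
    sel[[mm]] <- rbind(top, bot)
  }
  out <- do.call(rbind, sel)
  rownames(out) <- NULL
  out
}

# resampling engine for one pair: returns list(null = measures x B raw,
# boot = measures x B raw). Null permutes the two count profiles across
# samples independently and renormalizes every sample's full composition;
# bootstrap resamples samples with replacement (>= 3 distinct samples per
# draw, redrawn up to 10 times).
.pair_resamples <- function(counts, a, b, B, seed, measures,
                            what = c("null", "boot")) {
  n <- nrow(counts)
  ids <- sort(c(a, b))   # all measures are symmetric: order-invariant stream
  a <- ids[1]; b <- ids[2]
  x <- counts[, a]
  y <- counts[, b]
  tot <- rowSums(counts)
  rest <- tot - x - y
  set.seed(pair_seed(seed, a, b))
  out <- list()
  if ("null" %in% what) {
    Xp <- matrix(0, n, B)
    Yp <- matrix(0, n, B)
    for (i in seq_len(B)) {
      Xp[, i] <- x[sample.int(n)]
      Yp[, i] <- y[sample.int(n)]
    }
    Tp <- rest + Xp + Yp
    bad <- Tp == 0
    Tp[bad] <- 1  # avoid 0/0; the affected relative abundance is 0 anyway
    out$null <- .measure_cols(Xp / Tp, Yp / Tp, measures)
  }
  if ("boot" %in% what) {
    xr <- x / tot
    yr <- y / tot
    Xb <- matrix(NA_real_, n, B)
    Yb <- matrix(NA_real_, n, B)
    for (i in seq_len(B)) {
      for (try in 1:10) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(idx)) >= 3L) break
        idx <- NULL
      }
      if (!is.null(idx)) {
        Xb[, i] <- xr[idx]
        Yb[, i] <- yr[idx]
      }
    }
    out$boot <- .measure_cols(Xb, Yb, measures)
  }
  out
}

#' Renormalized permutation null scores for one edge
#'
#' Each of the `B` iterations independently permutes the two OTUs' count
#' profiles across samples, then renormalizes every sample's composition
#' (relative abundances are recomputed with the permuted pair in place)
#' before scoring — this preserves the compositional bias under the null,
#' the key idea of the ReBoot procedure.
#'
#' @param table an [otu_table] (counts).
#' @param pair character vector of two OTU IDs.
#' @param measure one of the four ensemble measures.
#' @param B number of resamples (>= 20).
#' @param seed integer seed; scores are reproducible and independent of
#'   column order.
#' @return numeric vector of `B` null scores on the association scale
#'   (NA where a permuted profile was degenerate for the measure).
#' @export
reboot_null <- function(table, pair, measure = COOC_MEASURES, B = 100,
                        seed = 1L) {
  measure <- match.arg(measure)
  if (B < 20) stop("B must be >= 20")
  m <- unclass_table(as.matrix(table))
  r <- .pair_resamples(m, pair[1], pair[2], B, seed, measure, what = "null")
  .to_association(r$null[measure, ], measure)
}

#' Bootstrap scores for one edge
#'
#' Resamples samples with replacement `B` times and recomputes the measure
#' on each resample; used for the stability filter (an edge whose bootstrap
#' distribution overlaps the null mean is discarded as unstable).
#'
#' @inheritParams reboot_null
#' @return numeric vector of `B` bootstrap scores on the association scale.
#' @export
bootstrap_scores <- function(table, pair, measure = COOC_MEASURES, B = 100,
                             seed = 1L) {
  measure <- match.arg(measure)
  if (B < 20) stop("B must be >= 20")
  m <- unclass_table(as.matrix(table))
  r <- .pair_resamples(m, pair[1], pair[2], B, seed, measure, what = "boot")
  .to_association(r$boot[measure, ], measure)
}

#' Measure-specific empirical p-value and stability flag
#'
#' Two-tailed empirical p relative to the permutation null:
#' p = (1 + #\{|null - mean(null)| >= |obs - mean(null)|\}) / (1 + B_valid).
#' The edge-measure is flagged unstable (and later discarded) when the null
#' mean lies inside the central 95\% interval of the bootstrap distribution,
#' i.e. when resampling cannot separate the observed association from the
#' null.
#'
#' @param observed observed association value.
#' @param null_scores,bootstrap_scores vectors on the association scale
#'   (NAs allowed; at least 20 valid null scores required for a p-value).
#' @return list with `p_value` (NA when undeterminable) and `stable`
#'   (logical).
#' @export
edge_pvalue <- function(observed, null_scores, bootstrap_scores = NULL) {
  null_scores <- null_scores[!is.na(null_scores)]
  if (is.na(observed) || length(null_scores) < 20L)
    return(list(p_value = NA_real_, stable = FALSE))
  mu <- mean(null_scores)
  p <- (1 + sum(abs(null_scores - mu) >= abs(observed - mu) - 1e-12)) /
    (1 + length(null_scores))
  stable <- NA
  if (!is.null(bootstrap_scores)) {
    bs <- bootstrap_scores[!is.na(bootstrap_scores)]
    if (length(bs) >= 20L) {
      ci <- stats::quantile(bs, c(0.025, 0.975), names = FALSE)
      stable <- mu < ci[1] || mu > ci[2]
    } else {
      stable <- FALSE
    }
  }
  list(p_value = p, stable = stable)
}

#' Simes combination of per-measure p-values
#'
#' With m valid p-values sorted ascending, the merged p is
#' min over i of m * p_(i) / i, capped at 1.
#'
#' @param p_values numeric vector (NAs dropped).
#' @return merged p-value.
#' @export
simes_merge <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (length(p) == 0L) return(NA_real_)
  p <- sort(p)
  m <- length(p)
  min(1, min(m * p / seq_len(m)))
}

#' Benjamini-Hochberg FDR control over candidate edges
#'
#' Step-up q-values (`p.adjust(..., "BH")`); edges with q <= alpha are kept.
#'
#' @param merged_p vector of merged p-values.
#' @param alpha FDR level.
#' @return list with `q` (same order as input) and `keep` (logical).
#' @export
bh_correct <- function(merged_p, alpha = 0.05) {
  if (length(merged_p) == 0L) stop("empty p-value vector")
  q <- stats::p.adjust(merged_p, method = "BH")
  list(q = q, keep = !is.na(q) & q <= alpha)
}

#' Assemble the co-occurrence network from kept edges
#'
#' Builds a simple undirected signed graph: nodes are OTUs incident to at
#' least one kept edge, annotated with taxonomy and mean relative abundance;
#' each edge carries its consensus sign (`+` co-occurrence, `-` mutual
#' exclusion), merged p and q. Edges whose supporting measures disagree in
#' sign must be removed upstream ([infer_network] does this and logs them).
#'
#' @param edges data.frame with columns `otu_a`, `otu_b`, `sign`,
#'   `merged_p`, `q`, `supporting_measures`.
#' @param taxonomy taxonomy data.frame (see [read_taxonomy]); optional.
#' @param mean_abundance named numeric vector of mean relative abundances;
#'   optional.
#' @return an `igraph` object.
#' @export
build_network <- function(edges, taxonomy = NULL, mean_abundance = NULL) {
  if (nrow(edges) == 0L) {
    warning("no significant edges: returning an empty network")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  stopifnot(all(edges$otu_a != edges$otu_b))
  key <- paste(pmin(edges$otu_a, edges$otu_b),
               pmax(edges$otu_a, edges$otu_b))
  stopifnot(!anyDuplicated(key))
  nodes <- sort(unique(c(edges$otu_a, edges$otu_b)))
  vdf <- data.frame(name = nodes, stringsAsFactors = FALSE)
  if (!is.null(taxonomy)) {
    for (r in c("phylum", "class", "order", "family", "genus")) {
      v <- taxonomy[match(nodes, taxonomy$otu_id), r]
      v[is.na(v)] <- "unclassified"
      vdf[[r]] <- v
    }
  }
  if (!is.null(mean_abundance))
    vdf$mean_rel_abundance <- unname(mean_abundance[nodes])
  g <- igraph::graph_from_data_frame(
    edges[, c("otu_a", "otu_b", "sign", "merged_p", "q",
              "supporting_measures")],
    directed = FALSE, vertices = vdf)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = "first")
}

#' Infer a signed co-occurrence network from a filtered OTU table
#'
#' The full ensemble inference: (1) optionally restrict to OTUs with a
#' classified genus, or aggregate counts to genus level; (2) score all pairs
#' with the four measures; (3) keep each measure's `top_n` top- and
#' bottom-ranking pairs (union = candidate set); (4) for every candidate,
#' draw `B` renormalized permutation nulls and `B` bootstrap resamples and
#' compute measure-specific two-tailed empirical p-values with the
#' bootstrap stability filter; (5) merge stable p-values by the Simes rule;
#' (6) Benjamini-Hochberg FDR at `alpha`; (7) assemble the signed graph,
#' discarding sign-conflicting edges.
#'
#' Per-measure signs: correlations carry their own sign; a dissimilarity
#' scores co-presence (`+`) when it falls below its null median. An edge's
#' consensus sign comes from its supporting measures — those that both
#' preselected the pair and yielded a stable p — and edges whose supporting
#' measures disagree are discarded and counted in `n_sign_conflict`.
#'
#' @param table a prepared (rarefied, filtered) [otu_table].
#' @param taxonomy taxonomy data.frame (see [read_taxonomy]); required for
#'   genus handling unless `genus_mode = "none"`.
#' @param measures ensemble members to use.
#' @param B resamples per null/bootstrap (>= 20).
#' @param top_n per-measure preselection depth.
#' @param alpha BH FDR level.
#' @param seed integer master seed.
#' @param genus_mode `"restrict"` (default: drop OTUs with unclassified
#'   genus), `"aggregate"` (sum counts per genus) or `"none"`.
#' @param p_method `"pooled"` (default): studentized pooled permutation
#'   p-values — each edge's observed association is z-scored against its own
#'   renormalized null, the standardized null scores of all candidate edges
#'   are pooled per measure, and the two-tailed p is the empirical tail of
#'   |z| in that pool. This keeps the per-edge null calibration while giving
#'   p-value resolution ~1/(B x n_candidates), which the step-up FDR
#'   correction needs; `"edgewise"` uses the per-edge empirical p of
#'   [edge_pvalue], whose resolution is limited to 1/(B+1).
#' @return list with `network` (igraph), `edges` (kept edge table),
#'   `candidates` (all tested candidates with per-measure p-values, merged p
#'   and q), `n_sign_conflict`, `n_unstable`, and the call parameters.
#' @export
infer_network <- function(table, taxonomy = NULL,
                          measures = COOC_MEASURES, B = 100, top_n = 250,
                          alpha = 0.05, seed = 1L,
                          genus_mode = c("restrict", "aggregate", "none"),
                          p_method = c("pooled", "edgewise")) {
  genus_mode <- match.arg(genus_mode)
  p_method <- match.arg(p_method)
  measures <- match.arg(measures, COOC_MEASURES, several.ok = TRUE)
  m <- unclass_table(as.matrix(table))

  if (genus_mode != "none") {
    if (is.null(taxonomy)) stop("taxonomy required for genus_mode != 'none'")
    gen <- taxonomy[match(colnames(m), taxonomy$otu_id), "genus"]
    gen[is.na(gen)] <- "unclassified"
    if (genus_mode == "restrict") {
      keep <- gen != "unclassified"
      if (sum(keep) < 2L) stop("fewer than 2 genus-classified OTUs")
      m <- m[, keep, drop = FALSE]
    } else {
      keep <- gen != "unclassified"
      m <- m[, keep, drop = FALSE]
      gen <- gen[keep]
      agg <- t(rowsum(t(m), gen))
      tax2 <- taxonomy[match(colnames(agg),
                             taxonomy$genus[match(colnames(m),
                                                  taxonomy$otu_id)]), ]
      # aggregated taxonomy: lineage of the first OTU of each genus
      first <- !duplicated(gen)
      tax2 <- taxonomy[match(colnames(m)[first], taxonomy$otu_id), ]
      tax2$otu_id <- gen[first]
      tax2 <- tax2[match(colnames(agg), tax2$otu_id), ]
      taxonomy <- tax2
      m <- agg
    }
  }

  tab <- otu_table(m)
  rel <- to_relative(tab)
  scores <- pairwise_measures(tab, measures)
  sel <- preselect_edges(scores, top_n)
  cand_key <- unique(paste(sel$otu_a, sel$otu_b, sep = "\r"))
  cand <- do.call(rbind, strsplit(cand_key, "\r", fixed = TRUE))
  nc <- nrow(cand)

  obs_map <- stats::setNames(
    scores$association, paste(scores$otu_a, scores$otu_b, scores$measure,
                              sep = "\r"))
  sel_key <- paste(sel$otu_a, sel$otu_b, sep = "\r")
  sel_by <- split(sel$measure, sel_key)

  nm <- length(measures)
  obs_a <- mu_n <- sd_n <- z_obs <- p_edge <-
    matrix(NA_real_, nc, nm, dimnames = list(NULL, measures))
  stable_m <- matrix(FALSE, nc, nm, dimnames = list(NULL, measures))
  sign_m <- matrix(NA_character_, nc, nm, dimnames = list(NULL, measures))
  z_null <- array(NA_real_, c(nc, nm, B),
                  dimnames = list(NULL, measures, NULL))

  # pass 1: resampling per candidate; studentize each edge's null
  for (i in seq_len(nc)) {
    a <- cand[i, 1]; b <- cand[i, 2]
    rs <- .pair_resamples(unclass_table(tab), a, b, B, seed, measures,
                          what = c("null", "boot"))
    for (mm in measures) {
      o <- obs_map[[paste(a, b, mm, sep = "\r")]]
      obs_a[i, mm] <- o
      nl <- .to_association(rs$null[mm, ], mm)
      bt <- .to_association(rs$boot[mm, ], mm)
      ep <- edge_pvalue(o, nl, bt)
      p_edge[i, mm] <- ep$p_value
      stable_m[i, mm] <- isTRUE(ep$stable)
      nlv <- nl[!is.na(nl)]
      if (!is.na(o) && length(nlv) >= 20L && stats::sd(nlv) > 0) {
        mu_n[i, mm] <- mean(nlv)
        sd_n[i, mm] <- stats::sd(nlv)
        z_obs[i, mm] <- (o - mu_n[i, mm]) / sd_n[i, mm]
        z_null[i, mm, seq_along(nl)] <- (nl - mu_n[i, mm]) / sd_n[i, mm]
      }
      sign_m[i, mm] <- if (is.na(o)) NA_character_
        else if (is_dissimilarity(mm)) {
          if (-o < stats::median(-nl, na.rm = TRUE)) "+" else "-"
        } else {
          if (o > 0) "+" else "-"
        }
    }
  }

  # pass 2: measure-specific p-values
  p_meas <- p_edge
  if (p_method == "pooled") {
    for (mm in measures) {
      pool <- sort(abs(as.vector(z_null[, mm, ])))
      pool <- pool[!is.na(pool)]
      if (length(pool) >= 20L) {
        npool <- length(pool)
        hits <- npool - findInterval(abs(z_obs[, mm]) - 1e-12, pool)
        p_meas[, mm] <- (1 + hits) / (1 + npool)
        p_meas[is.na(z_obs[, mm]), mm] <- NA_real_
      }
    }
  }

  rows <- vector("list", nc)
  n_unstable <- 0L
  for (i in seq_len(nc)) {
    valid <- !is.na(p_meas[i, ]) & stable_m[i, ]
    if (!any(valid)) n_unstable <- n_unstable + 1L
    support <- intersect(sel_by[[cand_key[i]]], measures[valid])
    signs <- sign_m[i, support]
    signs <- signs[!is.na(signs)]
    consensus <- if (length(signs) == 0L) NA_character_
      else if (length(unique(signs)) == 1L) signs[1]
      else "conflict"
    rows[[i]] <- data.frame(
      otu_a = cand[i, 1], otu_b = cand[i, 2],
      merged_p = if (any(valid)) simes_merge(p_meas[i, valid]) else NA_real_,
      sign = consensus,
      supporting_measures = paste(support, collapse = ","),
      n_valid_measures = sum(valid),
      t(p_meas[i, ]), stringsAsFactors = FALSE)
  }
  candidates <- do.call(rbind, rows)

  if (is.null(candidates) || nrow(candidates) == 0L) {
    warning("no stable candidate edges")
    return(list(network = igraph::make_empty_graph(0, directed = FALSE),
                edges = data.frame(), candidates = data.frame(),
                n_sign_conflict = 0L, n_unstable = n_unstable,
                params = list(measures = measures, B = B, top_n = top_n,
                              alpha = alpha, seed = seed,
                              genus_mode = genus_mode, p_method = p_method)))
  }
  bh <- bh_correct(candidates$merged_p, alpha)
  candidates$q <- bh$q
  kept <- candidates[bh$keep, , drop = FALSE]
  n_conflict <- sum(kept$sign == "conflict" | is.na(kept$sign))
  kept <- kept[!is.na(kept$sign) & kept$sign != "conflict", , drop = FALSE]

  mean_ab <- colMeans(rel)
  net <- if (nrow(kept) > 0L) {
    build_network(kept[, c("otu_a", "otu_b", "sign", "merged_p", "q",
                           "supporting_measures")],
                  taxonomy, mean_ab)
  } else {
    suppressWarnings(build_network(kept[0, c("otu_a", "otu_b", "sign",
                                             "merged_p", "q",
                                             "supporting_measures")]))
  }
  list(network = net, edges = kept, candidates = candidates,
       n_sign_conflict = n_conflict, n_unstable = n_unstable,
       params = list(measures = measures, B = B, top_n = top_n,
                     alpha = alpha, seed = seed, genus_mode = genus_mode, p_method = p_method))
}

#' Write an edge list as TSV
#' @param edges kept edge table from [infer_network].
#' @param path output file.
#' @export
write_edge_list <- function(edges, path) {
  cols <- c("otu_a", "otu_b", "sign", "merged_p", "q",
            "supporting_measures")
  utils::write.table(edges[, intersect(cols, names(edges)), drop = FALSE],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network as GraphML
#' @param net igraph network.
#' @param path output file.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
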