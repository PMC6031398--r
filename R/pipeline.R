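#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis. A single master seed
#' deterministically derives all stage seeds (hash of seed and stage name),
#' so stages can be rerun in isolation and a config + seed pins the entire
#' run.
#'
#' @param depth rarefaction depth (`"min"` or integer).
#' @param low_abundance within-sample relative-abundance floor (strict).
#' @param low_abundance_mode `"cell"` or `"otu-max"` (see
#'   [filter_low_abundance]).
#' @param prevalence prevalence threshold (strict, fraction of samples).
#' @param prevalence_scope `"per_habitat"` (default; each habitat's network
#'   uses prevalence within its own sample set) or `"global"`.
#' @param measures,B,top_n,alpha network-inference parameters (see
#'   [infer_network]).
#' @param genus_mode `"restrict"`, `"aggregate"` or `"none"`.
#' @param n_perm permutations for PERMANOVA and Mantel.
#' @param nmds_k,nmds_restarts NMDS settings.
#' @param top_k_keystones keystones reported per network.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(depth = "min", low_abundance = 1e-4,
                            low_abundance_mode = "cell",
                            prevalence = 0.8,
                            prevalence_scope = c("per_habitat", "global"),
                            measures = COOC_MEASURES, B = 100, top_n = 250,
                            alpha = 0.05, genus_mode = "restrict",
                            n_perm = 999, nmds_k = 2, nmds_restarts = 20,
                            top_k_keystones = 3, seed = 1L) {
  cfg <- as.list(environment())
  cfg$prevalence_scope <- match.arg(prevalence_scope)
  class(cfg) <- "pipeline_config"
  cfg
}

stage_seed <- function(seed, stage) pair_seed(seed, stage, "stage")

#' Run the full analysis pipeline
#'
#' Executes, in order: rarefaction to common depth; the within-sample
#' low-abundance filter; alpha diversity with habitat t-tests; Hellinger +
#' Bray-Curtis beta diversity with NMDS, UPGMA and PERMANOVA; geodesic
#' distance-decay Mantel tests within each habitat; per-habitat prevalence
#' filtering and co-occurrence network inference; topology reports and the
#' fragmentation comparison. Each stage records its input/output sizes in
#' the manifest.
#'
#' @param table an [otu_table] of raw counts.
#' @param taxonomy taxonomy data.frame covering every OTU in `table`.
#' @param metadata sample metadata data.frame (see [read_metadata]).
#' @param config a [pipeline_config].
#' @return list of class `pipeline_result` with elements `prep`,
#'   `diversity`, `beta`, `distance_decay`, `networks`, `topology`,
#'   `comparison`, `manifest`.
#' @export
run_pipeline <- function(table, taxonomy, metadata,
                         config = pipeline_config()) {
  stopifnot(inherits(table, "otu_table"), inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  missing_tax <- setdiff(colnames(table), taxonomy$otu_id)
  if (length(missing_tax) > 0)
    stop("table_prep validation: ", length(missing_tax),
         " OTUs missing from taxonomy (e.g. ", missing_tax[1], ")")
  missing_meta <- setdiff(rownames(table), metadata$sample_id)
  if (length(missing_meta) > 0)
    stop("table_prep validation: samples missing from metadata: ",
         paste(missing_meta, collapse = ", "))
  metadata <- metadata[rownames(table), ]
  funnel <- list(input = dim(table))

  # --- prep ---------------------------------------------------------------
  rar <- rarefy_table(table, depth = config$depth,
                      seed = stage_seed(config$seed, "rarefy"))
  funnel$rarefied <- dim(rar)
  filt <- filter_low_abundance(rar, config$low_abundance,
                               mode = config$low_abundance_mode)
  funnel$low_abundance <- dim(filt)
  funnel$zeroed_cells <- attr(filt, "zeroed_cells")

  # --- alpha diversity ----------------------------------------------------
  # computed on the rarefied, unfiltered table: the rare tail is real signal
  # for richness and Good's coverage; the low-abundance filter serves the
  # composition/network analyses
  div <- alpha_diversity(rar)
  div$habitat <- metadata[div$sample_id, "habitat"]
  tests <- lapply(c(richness = "richness", shannon = "shannon",
                    pielou = "pielou"), function(v)
    group_ttest(div[[v]], div$habitat))

  # --- beta diversity -----------------------------------------------------
  hel <- hellinger(filt)
  bc <- bray_curtis(hel)
  ord <- nmds(bc, k = config$nmds_k, n_restarts = config$nmds_restarts,
              seed = stage_seed(config$seed, "nmds"))
  tree <- upgma(bc)
  perm <- permanova(bc, metadata$habitat, n_perm = config$n_perm,
                    seed = stage_seed(config$seed, "permanova"))

  # --- distance decay per habitat -----------------------------------------
  decay <- list()
  for (hab in c("mainstream", "tributary")) {
    sel <- metadata$habitat == hab
    if (sum(sel) < 4) next
    sub <- filt[sel, , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    bc_h <- bray_curtis(hellinger(otu_table(sub)))
    geo <- geodesic_distance(metadata[sel, ])
    decay[[hab]] <- mantel_test(bc_h, geo, n_perm = config$n_perm,
                                seed = stage_seed(config$seed,
                                                  paste0("mantel_", hab)))
  }

  # --- per-habitat networks -----------------------------------------------
  networks <- list()
  topo <- list()
  for (hab in c("mainstream", "tributary")) {
    sel <- metadata$habitat == hab
    if (sum(sel) < 4) next
    sub <- unclass_table(filt)[sel, , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    subtab <- otu_table(sub)
    if (config$prevalence_scope == "global") {
      prev_tab <- filter_prevalence(filt, config$prevalence)
      subtab <- otu_table(unclass_table(prev_tab)[sel, , drop = FALSE])
    } else {
      subtab <- filter_prevalence(subtab, config$prevalence)
    }
    funnel[[paste0("prevalence_", hab)]] <- dim(subtab)
    networks[[hab]] <- infer_network(
      subtab, taxonomy, measures = config$measures, B = config$B,
      top_n = config$top_n, alpha = config$alpha,
      seed = stage_seed(config$seed, paste0("network_", hab)),
      genus_mode = config$genus_mode)
    topo[[hab]] <- topology_report(networks[[hab]]$network, taxonomy,
                                   top_k = config$top_k_keystones)
  }
  comparison <- if (length(topo) == 2L)
    compare_networks(topo$mainstream, topo$tributary,
                     labels = c("mainstream", "tributary"))
  else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("coflownet")),
    timestamp = format(t0, "%Y-%m-%d %H:%M:%S"),
    config = unclass(config),
    stage_seeds = list(
      rarefy = stage_seed(config$seed, "rarefy"),
      nmds = stage_seed(config$seed, "nmds"),
      permanova = stage_seed(config$seed, "permanova")),
    funnel = funnel)

  out <- list(prep = filt, diversity = div, diversity_tests = tests,
              beta = list(bray_curtis = bc, nmds = ord, upgma = tree,
                          permanova = perm),
              distance_decay = decay, networks = networks, topology = topo,
              comparison = comparison, manifest = manifest)
  class(out) <- "pipeline_result"
  out
}

#' Write all pipeline outputs to a directory
#'
#' Diversity report, NMDS coordinates, Bray-Curtis matrix, Newick
#' dendrogram, per-habitat edge lists and GraphML networks, topology
#' reports (JSON), module assignments, the comparison table and the run
#' manifest (JSON).
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  utils::write.table(result$diversity, p("alpha_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.matrix(result$beta$bray_curtis),
                     p("bray_curtis.tsv"), sep = "\t", quote = FALSE)
  utils::write.table(result$beta$nmds$points, p("nmds_coordinates.tsv"),
                     sep = "\t", quote = FALSE)
  write_newick(result$beta$upgma, p("upgma.nwk"))
  for (hab in names(result$networks)) {
    nw <- result$networks[[hab]]
    if (nrow(nw$edges) > 0)
      write_edge_list(nw$edges, p(paste0("edges_", hab, ".tsv")))
    if (igraph::vcount(nw$network) > 0)
      write_graphml(nw$network, p(paste0("network_", hab, ".graphml")))
    tp <- result$topology[[hab]]
    jsonlite::write_json(
      list(n_nodes = tp$n_nodes, n_edges = tp$n_edges,
           n_positive = tp$n_positive,
           clustering_coefficient = tp$clustering_coefficient,
           Q = tp$Q, n_modules = tp$n_modules,
           same_phylum_fraction = tp$same_phylum$fraction),
      p(paste0("topology_", hab, ".json")), auto_unbox = TRUE, digits = NA)
    if (length(tp$membership) > 0)
      utils::write.table(
        data.frame(otu_id = names(tp$membership),
                   module = unname(tp$membership)),
        p(paste0("modules_", hab, ".tsv")), sep = "\t", quote = FALSE,
        row.names = FALSE)
  }
  if (!is.null(result$comparison))
    utils::write.table(result$comparison$table, p("comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(report_markdown(result), p("report.md"))
  invisible(dir)
}

#' Human-readable run summary
#'
#' Renders the run as markdown in the reporting shape of a field study:
#' alpha-diversity table, PERMANOVA and Mantel results, per-network
#' node/edge/positive-edge/module/modularity/clustering metrics, and the
#' top keystone taxa with relative abundances.
#'
#' @param result a `pipeline_result`.
#' @return character vector of markdown lines.
#' @export
report_markdown <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  ln <- c("# Co-occurrence pipeline report", "")
  ln <- c(ln, "## Alpha diversity", "",
          "| sample | habitat | richness | Shannon | Pielou | coverage |",
          "|---|---|---|---|---|---|")
  d <- result$diversity
  ln <- c(ln, sprintf("| %s | %s | %d | %.3f | %.3f | %.3f |",
                      d$sample_id, d$habitat, d$richness, d$shannon,
                      d$pielou, d$goods_coverage))
  tt <- result$diversity_tests
  ln <- c(ln, "", sprintf(
    "t-tests (habitat): richness p=%.3f, Shannon p=%.3f, Pielou p=%.3f",
    tt$richness$p_value, tt$shannon$p_value, tt$pielou$p_value))
  pv <- result$beta$permanova
  ln <- c(ln, "", "## Beta diversity", "",
          sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.3f, p = %.4f",
                  pv$statistic, pv$r2, pv$p_value),
          sprintf("NMDS stress = %.4f", result$beta$nmds$stress))
  if (length(result$distance_decay) > 0) {
    ln <- c(ln, "", "## Distance decay (Mantel)", "")
    for (hab in names(result$distance_decay)) {
      mt <- result$distance_decay[[hab]]
      ln <- c(ln, sprintf("- %s: r = %.3f, p = %.4f", hab, mt$statistic,
                          mt$p_value))
    }
  }
  ln <- c(ln, "", "## Networks", "")
  if (length(result$topology) == 0)
    ln <- c(ln, "no networks inferred")
  for (hab in names(result$topology)) {
    tp <- result$topology[[hab]]
    if (tp$n_edges == 0) {
      ln <- c(ln, sprintf("### %s", hab), "", "no significant edges", "")
      next
    }
    ln <- c(ln, sprintf("### %s", hab), "",
            sprintf(paste0("%d nodes, %d edges (%d positive, %.1f%%), ",
                           "clustering = %.3f, %d modules, Q = %.3f"),
                    tp$n_nodes, tp$n_edges, tp$n_positive,
                    100 * tp$n_positive / tp$n_edges,
                    tp$clustering_coefficient, tp$n_modules, tp$Q))
    if (!is.na(tp$same_phylum$fraction))
      ln <- c(ln, sprintf("same-phylum co-presence: %.2f%%",
                          100 * tp$same_phylum$fraction))
    if (nrow(tp$keystones) > 0) {
      ln <- c(ln, "", "keystones:")
      ks <- tp$keystones
      for (i in seq_len(nrow(ks))) {
        ab <- if (!is.null(ks$mean_rel_abundance))
          sprintf(" (%.2f%%)", 100 * ks$mean_rel_abundance[i]) else ""
        gn <- if (!is.null(ks$genus)) paste0(" ", ks$genus[i]) else ""
        ln <- c(ln, sprintf(
          "- %s%s%s: betweenness %.1f, closeness %.3f",
          ks$node[i], gn, ab, ks$betweenness[i], ks$closeness[i]))
      }
    }
    ln <- c(ln, "")
  }
  if (!is.null(result$comparison))
    ln <- c(ln, "## Comparison", "",
            sprintf("more fragmented: %s",
                    result$comparison$more_fragmented))
  ln
}
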