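#' Parameterization of the synthetic river community generator
#'
#' Describes a two-habitat study design: `n_mainstream` sites on a river
#' chain plus `n_tributary` scattered tributary sites, a species pool of
#' `n_core + n_tail` OTUs in which a prevalent core carries planted
#' co-occurrence blocks (modules) and mutual-exclusion pairs, a habitat
#' composition shift, and a spatial distance-decay drift along the
#' mainstream chain only. Counts follow a log-normal/softmax/multinomial
#' compositional chain: latent log-abundances are block-structured Gaussian,
#' each sample's composition is the softmax of its latent vector, and reads
#' are drawn multinomially at a uniformly random depth.
#'
#' @param n_mainstream,n_tributary samples per habitat (defaults 8 and 9).
#' @param n_core prevalent OTUs (high baseline abundance; hosts the planted
#'   structure and survives the prevalence filter).
#' @param n_tail rare OTUs (low baseline; mostly removed by the filters).
#' @param n_blocks,block_size planted co-occurring blocks within the core.
#' @param rho within-block latent correlation in [0, 1].
#' @param n_exclusion planted mutual-exclusion pairs (latent correlation
#'   -rho), drawn from core OTUs outside the blocks.
#' @param delta habitat shift on log-abundance, applied to a random
#'   `shift_frac` of all OTUs in tributary samples.
#' @param shift_frac fraction of OTUs receiving the habitat shift.
#' @param decay_rate distance-decay strength: the latent variance of the
#'   random longitudinal gradient, per km of mainstream chain (0 disables
#'   distance decay).
#' @param chain_km length of the mainstream chain.
#' @param sigma latent log-abundance standard deviation.
#' @param mu_core,mu_core_sd,mu_tail,mu_tail_sd log-scale baseline means.
#' @param depth_range read-depth range, uniform integer draw per sample
#'   (minimum depth must be >= 1000).
#' @param unclassified_frac fraction of tail OTUs with unclassified genus.
#' @param seed integer seed driving all randomness.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_mainstream = 8, n_tributary = 9,
                           n_core = 60, n_tail = 840,
                           n_blocks = 6, block_size = 8, rho = 0.8,
                           n_exclusion = 5, delta = 2, shift_frac = 0.3,
                           decay_rate = 0.05, chain_km = 150,
                           sigma = 1.5, mu_core = 3, mu_core_sd = 0.5,
                           mu_tail = -2.5, mu_tail_sd = 1,
                           depth_range = c(24000, 43000),
                           unclassified_frac = 0.15, seed = 1L) {
  spec <- as.list(environment())
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  if (n_blocks * block_size + 2 * n_exclusion > n_core)
    stop("block layout infeasible: blocks plus exclusion pairs exceed n_core")
  if (depth_range[1] < 1000) stop("minimum depth must be >= 1000")
  if (depth_range[1] > depth_range[2]) stop("bad depth range")
  class(spec) <- "synthetic_spec"
  spec
}

SYNTH_PHYLA <- c("Proteobacteria", "Bacteroidetes", "Actinobacteria",
                 "Cyanobacteria", "Firmicutes", "Verrucomicrobia",
                 "Planctomycetes", "Chloroflexi")

#' Generate a synthetic two-habitat community with known ground truth
#'
#' Draws OTU counts, taxonomy and sample metadata under a
#' [synthetic_spec]. Within-block OTUs share a latent factor giving
#' pairwise correlation `rho`; exclusion pairs get correlation `-rho`;
#' tributary samples receive the habitat shift `delta` on a fixed OTU
#' subset; mainstream samples sit on a `chain_km` line along which latent
#' abundances follow random longitudinal gradients (full-span variance
#' `decay_rate * chain_km`), planting a distance-decay signal in the
#' mainstream only. Block factors drift coherently, so the gradient does
#' not erode within-block correlation. Each planted block has one phylum, so
#' same-phylum co-occurrence is planted as well. All randomness derives
#' from `spec$seed`; a fixed seed yields byte-identical tables.
#'
#' @param spec a [synthetic_spec].
#' @return list with `table` ([otu_table]), `taxonomy`, `metadata`, and
#'   `truth` (planted positive/exclusion pairs, block membership, shifted
#'   OTUs, coordinates).
#' @export
generate_community <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(as.integer(spec$seed))
  n_otus <- spec$n_core + spec$n_tail
  n_samp <- spec$n_mainstream + spec$n_tributary
  otu_ids <- sprintf("OTU%04d", seq_len(n_otus))
  sample_ids <- c(sprintf("KD%d", seq_len(spec$n_mainstream)),
                  sprintf("TR%d", seq_len(spec$n_tributary)))
  is_main <- c(rep(TRUE, spec$n_mainstream), rep(FALSE, spec$n_tributary))

  core <- seq_len(spec$n_core)
  tail_idx <- setdiff(seq_len(n_otus), core)
  mu <- numeric(n_otus)
  mu[core] <- stats::rnorm(spec$n_core, spec$mu_core, spec$mu_core_sd)
  mu[tail_idx] <- stats::rnorm(spec$n_tail, spec$mu_tail, spec$mu_tail_sd)

  # block layout: blocks first, then exclusion pairs, inside the core
  block_of <- rep(NA_integer_, n_otus)
  nb <- spec$n_blocks * spec$block_size
  if (nb > 0)
    block_of[seq_len(nb)] <- rep(seq_len(spec$n_blocks),
                                 each = spec$block_size)
  excl_idx <- if (spec$n_exclusion > 0)
    matrix(nb + seq_len(2 * spec$n_exclusion), ncol = 2, byrow = TRUE)
  else matrix(integer(0), 0, 2)

  # spatial layout of the mainstream chain; the distance-decay engine is a
  # random linear gradient along it (river-continuum-style longitudinal
  # succession): each OTU/factor responds with a random slope whose latent
  # variance at full span is decay_rate * chain_km
  pos <- seq(0, spec$chain_km, length.out = spec$n_mainstream)
  bm_chain <- function() {
    if (spec$decay_rate == 0 || spec$n_mainstream < 2)
      return(rep(0, spec$n_mainstream))
    slope <- stats::rnorm(1, 0, sqrt(spec$decay_rate * spec$chain_km))
    slope * (pos - mean(pos)) / spec$chain_km
  }

  # latent log-abundances: shared block/exclusion factors drift coherently
  # along the chain (a module responds to the river gradient as a unit, so
  # distance decay does not erode within-block correlation); free OTUs
  # drift independently
  L <- matrix(stats::rnorm(n_samp * n_otus, 0, 1), n_samp, n_otus)
  in_factor <- !is.na(block_of)
  in_factor[as.vector(excl_idx)] <- TRUE
  resid_scale <- spec$sigma * sqrt(1 - ifelse(in_factor, spec$rho, 0))
  L <- L * rep(resid_scale, each = n_samp)
  if (spec$n_blocks > 0 && spec$rho > 0) {
    for (k in seq_len(spec$n_blocks)) {
      f <- stats::rnorm(n_samp)
      f[is_main] <- f[is_main] + bm_chain() / spec$sigma
      idx <- which(block_of == k)
      L[, idx] <- L[, idx] + sqrt(spec$rho) * spec$sigma * f
    }
  }
  if (nrow(excl_idx) > 0 && spec$rho > 0) {
    for (e in seq_len(nrow(excl_idx))) {
      g <- stats::rnorm(n_samp)
      g[is_main] <- g[is_main] + bm_chain() / spec$sigma
      L[, excl_idx[e, 1]] <- L[, excl_idx[e, 1]] +
        sqrt(spec$rho) * spec$sigma * g
      L[, excl_idx[e, 2]] <- L[, excl_idx[e, 2]] -
        sqrt(spec$rho) * spec$sigma * g
    }
  }
  free <- which(!in_factor)
  if (spec$decay_rate > 0 && spec$n_mainstream > 1) {
    for (j in free) L[is_main, j] <- L[is_main, j] + bm_chain()
  }
  L <- L + rep(mu, each = n_samp)

  # habitat composition shift on a guild disjoint from the planted factors
  n_shift <- min(floor(spec$shift_frac * n_otus), length(free))
  shift_otus <- sort(sample(free, n_shift))
  if (spec$delta != 0 && n_shift > 0)
    L[!is_main, shift_otus] <- L[!is_main, shift_otus] + spec$delta

  # counts: softmax composition, multinomial reads at random depth
  depths <- sample(seq(spec$depth_range[1], spec$depth_range[2]), n_samp,
                   replace = TRUE)
  counts <- matrix(0L, n_samp, n_otus,
                   dimnames = list(sample_ids, otu_ids))
  for (i in seq_len(n_samp)) {
    w <- exp(L[i, ] - max(L[i, ]))
    counts[i, ] <- stats::rmultinom(1, depths[i], w / sum(w))
  }
  # the constructor requires every OTU label; all-zero columns are fine

  # taxonomy: one phylum per block; classified genera in the core
  phyla <- rep(NA_character_, n_otus)
  block_phyla <- SYNTH_PHYLA[((seq_len(max(spec$n_blocks, 1)) - 1) %%
                                length(SYNTH_PHYLA)) + 1]
  phyla[!is.na(block_of)] <- block_phyla[block_of[!is.na(block_of)]]
  rest <- which(is.na(phyla))
  phyla[rest] <- sample(SYNTH_PHYLA, length(rest), replace = TRUE)
  genus <- paste0("Genus_", otu_ids)
  uncl <- tail_idx[stats::runif(length(tail_idx)) < spec$unclassified_frac]
  genus[uncl] <- "unclassified"
  taxonomy <- data.frame(
    otu_id = otu_ids, phylum = phyla,
    class = paste0(phyla, "_class"), order = paste0(phyla, "_order"),
    family = paste0(phyla, "_family"), genus = genus,
    stringsAsFactors = FALSE, row.names = otu_ids)

  # metadata: mainstream chain northward at fixed longitude, tributaries
  # scattered without gradient
  lat0 <- 42.2
  lat <- c(lat0 + pos / 111.195,
           stats::runif(spec$n_tributary, 42.0, 43.5))
  lon <- c(rep(84.0, spec$n_mainstream),
           stats::runif(spec$n_tributary, 83.0, 86.0))
  metadata <- data.frame(
    sample_id = sample_ids,
    habitat = ifelse(is_main, "mainstream", "tributary"),
    lat = lat, lon = lon, stringsAsFactors = FALSE,
    row.names = sample_ids)

  pairs_in <- function(idx) {
    if (length(idx) < 2) return(NULL)
    cmb <- utils::combn(otu_ids[idx], 2)
    data.frame(otu_a = pmin(cmb[1, ], cmb[2, ]),
               otu_b = pmax(cmb[1, ], cmb[2, ]), stringsAsFactors = FALSE)
  }
  pos_pairs <- do.call(rbind, lapply(seq_len(spec$n_blocks), function(k)
    pairs_in(which(block_of == k))))
  excl_pairs <- if (nrow(excl_idx) > 0)
    data.frame(otu_a = pmin(otu_ids[excl_idx[, 1]], otu_ids[excl_idx[, 2]]),
               otu_b = pmax(otu_ids[excl_idx[, 1]], otu_ids[excl_idx[, 2]]),
               stringsAsFactors = FALSE)
  else data.frame(otu_a = character(0), otu_b = character(0))

  truth <- list(
    positive_pairs = if (is.null(pos_pairs))
      data.frame(otu_a = character(0), otu_b = character(0)) else pos_pairs,
    exclusion_pairs = excl_pairs,
    block = stats::setNames(block_of, otu_ids),
    shifted_otus = otu_ids[shift_otus],
    coordinates = metadata[, c("sample_id", "lat", "lon")],
    depths = stats::setNames(depths, sample_ids))

  list(table = otu_table(counts), taxonomy = taxonomy,
       metadata = metadata, truth = truth, spec = spec)
}

#' Generate a fragmentation contrast: two habitat datasets
#'
#' Builds two single-habitat communities differing only in planted module
#' layout: habitat A carries many small blocks (high fragmentation — more
#' modules, higher modularity expected in the inferred network) and habitat
#' B fewer, larger, internally denser blocks (low fragmentation). Habitat
#' shift and distance decay are disabled so the contrast isolates module
#' structure; each dataset keeps the full 17-sample design for comparable
#' inferential power. Ground truth records the intended ordering.
#'
#' @param spec_base a [synthetic_spec]; its core size, noise and depth
#'   settings are reused.
#' @param seed integer seed (the two datasets use `seed` and `seed + 1`).
#' @return list with `fragmented`, `cohesive` (each a [generate_community]
#'   result) and `expected_more_fragmented = "fragmented"`.
#' @export
make_fragmentation_pair <- function(spec_base = synthetic_spec(),
                                    seed = spec_base$seed) {
  base <- unclass(spec_base)
  tweak <- function(n_blocks, block_size, rho, seed) {
    s <- base
    s$n_blocks <- n_blocks
    s$block_size <- block_size
    s$rho <- rho
    s$n_exclusion <- 0
    s$delta <- 0
    s$decay_rate <- 0
    s$n_core <- max(s$n_core, n_blocks * block_size)
    s$n_tail <- min(s$n_tail, 300L)
    s$seed <- seed
    do.call(synthetic_spec, s[names(formals(synthetic_spec))])
  }
  frag <- generate_community(tweak(10, 4, spec_base$rho, as.integer(seed)))
  cohes <- generate_community(tweak(3, 13, min(1, spec_base$rho + 0.05),
                                    as.integer(seed) + 1L))
  list(fragmented = frag, cohesive = cohes,
       expected_more_fragmented = "fragmented")
}
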