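#' Construct a validated OTU count table
#'
#' An OTU table is an integer count matrix with samples on rows and OTUs on
#' columns, the universal currency of the pipeline. The constructor enforces
#' the contract every downstream step relies on: unique sample and OTU IDs,
#' non-negative integer counts, at least two samples and two OTUs, and no
#' empty samples.
#'
#' @param counts numeric matrix of non-negative integers, samples x OTUs.
#' @param sample_ids,otu_ids optional character vectors; taken from
#'   `dimnames(counts)` when omitted.
#' @return a matrix of class `otu_table` (samples x OTUs, dimnames set).
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      otu_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(counts)))
  if (is.null(otu_ids)) otu_ids <- paste0("OTU", seq_len(ncol(counts)))
  sample_ids <- as.character(sample_ids)
  otu_ids <- as.character(otu_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs")
  if (anyDuplicated(otu_ids)) stop("duplicate OTU IDs")
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("an OTU table needs at least 2 samples and 2 OTUs")
  storage.mode(counts) <- "double"
  if (anyNA(counts) || !all(is.finite(counts)))
    stop("counts must be finite numbers")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) stop("counts must be integers")
  counts <- round(counts)
  if (any(rowSums(counts) == 0))
    stop("samples with zero total counts: ",
         paste(sample_ids[rowSums(counts) == 0], collapse = ", "))
  dimnames(counts) <- list(sample_ids, otu_ids)
  class(counts) <- c("otu_table", "matrix", "array")
  counts
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d OTUs, depth %d-%d reads\n",
              nrow(x), ncol(x), min(rowSums(x)), max(rowSums(x))))
  invisible(x)
}

# strip the class so plain matrix maths applies
unclass_table <- function(x) {
  class(x) <- c("matrix", "array")
  x
}

#' Read an OTU table from TSV
#'
#' Accepts either samples-on-rows orientation or the classic BIOM-style TSV
#' with a leading `#OTU_ID` column and samples across the columns (OTUs on
#' rows). With `orientation = "auto"`, a first column named `#OTU_ID` (or
#' `OTU_ID`/`otu_id`) marks the BIOM-style layout and the matrix is
#' transposed to the internal samples x OTUs convention.
#'
#' @param path TSV file; first row and first column hold IDs.
#' @param orientation `"auto"`, `"samples"` (rows are samples) or `"otus"`
#'   (rows are OTUs, transposed on read).
#' @return an [otu_table].
#' @export
read_otu_table <- function(path, orientation = c("auto", "samples", "otus")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric cell in OTU table: ", path)
  if (orientation == "auto") {
    orientation <- if (grepl("^#?OTU[_ ]?ID$", header[1], ignore.case = TRUE))
      "otus" else "samples"
  }
  if (orientation == "otus") m <- t(m)
  otu_table(m)
}

#' Write an OTU table as BIOM-style TSV
#'
#' Writes the transposed (OTUs on rows) layout with a `#OTU_ID` first column,
#' the conventional interchange format; [read_otu_table] inverts it exactly.
#'
#' @param table an [otu_table].
#' @param path output file.
#' @export
write_otu_table <- function(table, path) {
  m <- t(unclass_table(table))
  df <- data.frame("#OTU_ID" = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table
#'
#' TSV with columns `otu_id`, `phylum`, `class`, `order`, `family`, `genus`.
#' Missing or empty labels become the sentinel `"unclassified"`.
#'
#' @param path TSV file.
#' @return data.frame with one row per OTU, rownames = otu_id.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "")
  need <- c("otu_id", "phylum", "class", "order", "family", "genus")
  if (!all(need %in% names(df)))
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  for (r in need[-1]) {
    v <- as.character(df[[r]])
    v[is.na(v) | v == ""] <- "unclassified"
    df[[r]] <- v
  }
  if (anyDuplicated(df$otu_id)) stop("duplicate OTU IDs in taxonomy")
  rownames(df) <- df$otu_id
  df
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `habitat` (`mainstream` or `tributary`),
#' `lat`, `lon` in decimal degrees.
#'
#' @param path TSV file.
#' @return data.frame with rownames = sample_id.
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "habitat", "lat", "lon")
  if (!all(need %in% names(df)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (!all(df$habitat %in% c("mainstream", "tributary")))
    stop("habitat must be 'mainstream' or 'tributary'")
  if (any(!is.finite(df$lat)) || any(!is.finite(df$lon)))
    stop("missing coordinates")
  if (any(abs(df$lat) > 90) || any(abs(df$lon) > 180))
    stop("coordinates out of range")
  rownames(df) <- df$sample_id
  df
}

#' Subsample every sample to equal depth
#'
#' Rarefaction draws reads without replacement (hypergeometric) within each
#' sample so that all samples end at the same depth, removing
#' sequencing-effort differences before diversity comparisons. With
#' `depth = "min"` the target is the smallest sample total, mirroring the
#' convention of subsampling to the lowest number of sequences among sites.
#'
#' @param table an [otu_table].
#' @param depth positive integer target depth, or `"min"`.
#' @param seed integer seed; subsampling is reproducible under a fixed seed.
#' @return an [otu_table] whose every row sums exactly to `depth`.
#' @export
rarefy_table <- function(table, depth = "min", seed = 1L) {
  stopifnot(inherits(table, "otu_table"))
  n <- rowSums(table)
  if (identical(depth, "min")) depth <- min(n)
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be positive")
  if (any(n < depth))
    stop("depth ", depth, " exceeds total reads of sample(s): ",
         paste(rownames(table)[n < depth], collapse = ", "))
  set.seed(as.integer(seed))
  # rrarefy's "smallest count" heuristic warning misfires on valid tables
  out <- suppressWarnings(vegan::rrarefy(unclass_table(table), depth))
  otu_table(out, rownames(table), colnames(table))
}

#' Zero out within-sample rare OTU observations
#'
#' Any cell whose within-sample relative abundance is strictly below
#' `threshold_frac` (default 0.01\%) is set to zero, guarding against
#' spurious rare OTUs from sequencing error. The default `"cell"` mode zeroes
#' individual observations because an OTU rare in one sample may be abundant
#' in another; `"otu-max"` instead drops an OTU everywhere when its maximum
#' within-sample relative abundance is below the threshold. OTU columns that
#' end up all-zero are dropped. The counts of zeroed cells and dropped OTUs
#' are attached as attributes `zeroed_cells` and `dropped_otus`.
#'
#' @param table an [otu_table].
#' @param threshold_frac strict lower bound on within-sample relative
#'   abundance, in (0,1); 0 disables the filter.
#' @param mode `"cell"` (default) or `"otu-max"`.
#' @return filtered [otu_table] with a filter report in attributes.
#' @export
filter_low_abundance <- function(table, threshold_frac = 1e-4,
                                 mode = c("cell", "otu-max")) {
  stopifnot(inherits(table, "otu_table"))
  mode <- match.arg(mode)
  if (threshold_frac < 0 || threshold_frac >= 1)
    stop("threshold_frac must be in [0, 1)")
  m <- unclass_table(table)
  rel <- m / rowSums(m)
  if (mode == "cell") {
    zero <- m > 0 & rel < threshold_frac
  } else {
    below <- apply(rel, 2, max) < threshold_frac
    zero <- m > 0 & matrix(below, nrow(m), ncol(m), byrow = TRUE)
  }
  m[zero] <- 0
  dropped <- colnames(m)[colSums(m) == 0]
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (ncol(m) < 2L) stop("fewer than 2 OTUs survive the abundance filter")
  out <- otu_table(m)
  attr(out, "zeroed_cells") <- sum(zero)
  attr(out, "dropped_otus") <- dropped
  out
}

#' Keep OTUs present in more than a given fraction of samples
#'
#' Prevalence filtering retains OTU j iff the fraction of samples with a
#' non-zero count strictly exceeds `min_prevalence_frac` ("more than 80\% of
#' all samples" at the default). The strict inequality means an OTU seen in
#' exactly 80\% of samples is removed.
#'
#' @param table an [otu_table].
#' @param min_prevalence_frac fraction in (0, 1].
#' @return filtered [otu_table].
#' @export
filter_prevalence <- function(table, min_prevalence_frac = 0.8) {
  stopifnot(inherits(table, "otu_table"))
  if (min_prevalence_frac <= 0 || min_prevalence_frac > 1)
    stop("min_prevalence_frac must be in (0, 1]")
  prev <- colMeans(unclass_table(table) > 0)
  keep <- prev > min_prevalence_frac
  if (sum(keep) == 0L)
    stop("no OTU exceeds prevalence ", min_prevalence_frac,
         ": empty table")
  if (sum(keep) < 2L)
    stop("fewer than 2 OTUs exceed prevalence ", min_prevalence_frac)
  otu_table(unclass_table(table)[, keep, drop = FALSE])
}

#' Relative-abundance transform
#'
#' Divides every row by its total so rows sum to one.
#'
#' @param table an [otu_table] (or non-negative matrix with positive
#'   row sums).
#' @return numeric matrix, rows summing to 1.
#' @export
to_relative <- function(table) {
  m <- unclass_table(as.matrix(table))
  rs <- rowSums(m)
  if (any(rs <= 0)) stop("zero row sum: relative abundance undefined")
  m / rs
}

#' Hellinger transform
#'
#' Square root of relative abundances: `sqrt(count / rowsum)`. Squared
#' values in each row sum to one; the transform tempers the influence of
#' dominant taxa and makes Bray-Curtis/Euclidean analyses robust to double
#' zeros.
#'
#' @inheritParams to_relative
#' @return numeric matrix of Hellinger-transformed abundances.
#' @export
hellinger <- function(table) {
  sqrt(to_relative(table))
}
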