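#' Filter barcodes on minimum counts
#'
#' Keeps only barcodes whose DNA and RNA counts are at least \code{min_count}
#' in every replicate of the table; a barcode absent from a replicate counts
#' as zero there and is removed.
#'
#' @param counts An \code{\link{mpra_counts}} table.
#' @param min_count Minimum count required in each replicate (default 1).
#' @return Filtered \code{\link{mpra_counts}} table.
#' @export
filter_min_counts <- function(counts, min_count = 1L) {
  n_rep <- nlevels(counts$replicate)
  ok_rec <- counts$dna_count >= min_count & counts$rna_count >= min_count
  n_ok <- tapply(ok_rec, counts$barcode, sum)
  n_seen <- tapply(ok_rec, counts$barcode, length)
  keep_bc <- names(n_ok)[n_ok == n_rep & n_seen == n_rep]
  removed <- length(n_ok) - length(keep_bc)
  if (removed > 0) {
    message(sprintf("filter_min_counts: removed %d barcode(s)", removed))
  }
  out <- counts[counts$barcode %in% keep_bc, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter oligos on minimum barcode multiplicity
#'
#' Drops all records of oligos tagged by fewer than \code{min_barcodes}
#' distinct barcodes.
#'
#' @param counts An \code{\link{mpra_counts}} table.
#' @param min_barcodes Minimum number of barcodes per oligo (default 10).
#' @return Filtered \code{\link{mpra_counts}} table.
#' @export
filter_min_barcodes <- function(counts, min_barcodes = 10L) {
  bc <- counts[!duplicated(counts$barcode), c("barcode", "oligo")]
  n_bc <- table(bc$oligo)
  keep_oligo <- names(n_bc)[n_bc >= min_barcodes]
  dropped <- length(n_bc) - length(keep_oligo)
  if (dropped > 0) {
    message(sprintf("filter_min_barcodes: dropped %d oligo(s)", dropped))
  }
  out <- counts[counts$oligo %in% keep_oligo, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove RNA-count outlier barcodes
#'
#' Within each (oligo, replicate) group, flags barcodes whose RNA count lies
#' more than \code{n_sd} sample standard deviations from the group mean; a
#' barcode flagged in any replicate is removed from all replicates. Groups
#' with zero standard deviation (or fewer than two barcodes) remove nothing.
#'
#' @param counts An \code{\link{mpra_counts}} table.
#' @param n_sd Deviation threshold in standard deviations (default 3).
#' @return Filtered \code{\link{mpra_counts}} table.
#' @export
remove_outlier_barcodes <- function(counts, n_sd = 3) {
  g <- interaction(counts$oligo, counts$replicate, drop = TRUE)
  mu <- stats::ave(as.numeric(counts$rna_count), g, FUN = mean)
  sd_ <- stats::ave(as.numeric(counts$rna_count), g,
                    FUN = function(x) if (length(x) > 1) stats::sd(x) else 0)
  flagged <- sd_ > 0 & abs(counts$rna_count - mu) > n_sd * sd_
  bad_bc <- unique(counts$barcode[flagged])
  if (length(bad_bc) > 0) {
    message(sprintf("remove_outlier_barcodes: removed %d barcode(s)",
                    length(bad_bc)))
  }
  out <- counts[!(counts$barcode %in% bad_bc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Downsample barcode multiplicity to a percentile cap
#'
#' Computes the given percentile (linear interpolation, floored to an
#' integer) of the per-oligo barcode multiplicity distribution; oligos with
#' more barcodes than the cap keep a uniformly random subset of exactly the
#' cap size. Deterministic for a given seed.
#'
#' @param counts An \code{\link{mpra_counts}} table.
#' @param percentile Percentile (0-100 scale) of the multiplicity
#'   distribution used as the cap (default 95).
#' @param seed Integer seed for the random subset selection.
#' @return Filtered \code{\link{mpra_counts}} table.
#' @export
downsample_barcodes <- function(counts, percentile = 95, seed) {
  if (missing(seed) || is.null(seed)) {
    stop_mprabc("downsample_barcodes requires a seed for reproducibility")
  }
  bc <- barcode_slots(counts)
  mult <- table(bc$oligo)
  cap <- floor(interp_quantile(as.numeric(mult), percentile / 100))
  over <- names(mult)[mult > cap]
  if (length(over) == 0) return(counts)
  drop_bc <- with_seed(seed, {
    unlist(lapply(over, function(o) {
      bcs <- sort(bc$barcode[bc$oligo == o])
      bcs[-sample.int(length(bcs), cap)]
    }), use.names = FALSE)
  })
  message(sprintf(
    "downsample_barcodes: cap %d barcodes; reduced %d oligo(s), removed %d barcode(s)",
    cap, length(over), length(drop_bc)))
  out <- counts[!(counts$barcode %in% drop_bc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Standard preprocessing pipeline
#'
#' Applies, in order: the minimum-count filter, the minimum-barcode filter,
#' optional 3-SD RNA outlier removal, a re-check of the minimum-barcode
#' filter, and optional percentile-capped downsampling.
#'
#' @inheritParams filter_min_counts
#' @inheritParams filter_min_barcodes
#' @inheritParams remove_outlier_barcodes
#' @param downsample_percentile Percentile cap for
#'   \code{\link{downsample_barcodes}}, or NULL to skip downsampling.
#' @param outlier_removal Apply \code{\link{remove_outlier_barcodes}}
#'   (default TRUE).
#' @param seed Seed for downsampling (required when downsampling).
#' @return Preprocessed \code{\link{mpra_counts}} table.
#' @export
preprocess_counts <- function(counts, min_count = 1L, min_barcodes = 10L,
                              n_sd = 3, outlier_removal = TRUE,
                              downsample_percentile = NULL, seed = NULL) {
  counts <- filter_min_counts(counts, min_count)
  counts <- filter_min_barcodes(counts, min_barcodes)
  if (outlier_removal) {
    counts <- remove_outlier_barcodes(counts, n_sd)
    counts <- filter_min_barcodes(counts, min_barcodes)
  }
  if (!is.null(downsample_percentile)) {
    counts <- downsample_barcodes(counts, downsample_percentile, seed)
  }
  counts
}
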