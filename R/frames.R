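#' Wide barcode-as-sample count frames
#'
#' The model consumes counts arranged as a wide frame: one row per variant
#' (ref/alt design) or per oligo (element design), and one column per
#' (replicate, barcode slot). Barcode multiplicity varies between sequences,
#' so slots a sequence does not use are explicit missing cells (NA); they are
#' never imputed and later receive zero weight in fitting.
#'
#' Column ordering is deterministic: replicates ascending; within a replicate,
#' ref slots before alt slots (variant mode); barcodes in lexicographic order
#' within each oligo.
#'
#' @name mpra_frame
#' @return A list of class \code{mpra_frame} with elements \code{row_ids},
#'   \code{dna} and \code{rna} (row x column count matrices, NA = unused
#'   slot), \code{block} (per-column replicate factor), \code{allele}
#'   (per-column 0 = ref / 1 = alt indicator, variant mode only; otherwise
#'   NULL), \code{mode} (\code{"variant"} or \code{"element"}), and
#'   \code{labels} (per-row group label or NA, element mode only).
NULL

new_mpra_frame <- function(row_ids, dna, rna, block, allele, mode,
                           labels = NULL) {
  dimnames(rna) <- dimnames(dna)
  structure(list(
    row_ids = row_ids, dna = dna, rna = rna,
    block = factor(block), allele = allele,
    mode = mode, labels = labels
  ), class = "mpra_frame")
}

# Lexicographic barcode slot index within each oligo; returns a data.frame
# keyed by barcode (each barcode belongs to exactly one oligo).
barcode_slots <- function(counts) {
  bc <- counts[!duplicated(counts$barcode), c("barcode", "oligo")]
  bc <- bc[order(bc$oligo, bc$barcode), ]
  bc$slot <- stats::ave(seq_len(nrow(bc)), bc$oligo, FUN = seq_along)
  bc
}

#' Build the variant-mode count frame
#'
#' Combines a barcode count table with a variant map into a frame with one
#' row per variant. For each replicate the columns hold the reference oligo's
#' barcode slots followed by the alternative oligo's slots; variants whose
#' two alleles have unequal barcode multiplicities are padded with missing
#' slots on the smaller side.
#'
#' @param counts An \code{\link{mpra_counts}} table.
#' @param map An \code{\link{variant_map}} table.
#' @return A variant-mode \code{\link{mpra_frame}}.
#' @export
create_variant_frame <- function(counts, map) {
  map <- variant_map(map)
  all_oligos <- unique(c(map$ref_oligo, map$alt_oligo))
  absent <- setdiff(all_oligos, counts$oligo)
  if (length(absent) > 0) {
    stop_mprabc("variant map oligo(s) absent from count table: %s%s",
                paste(utils::head(absent, 10), collapse = ", "),
                if (length(absent) > 10) ", ..." else "",
                class = "mprabc_lookup_error")
  }
  bc <- barcode_slots(counts)
  n_bc <- table(bc$oligo)
  # common slot width for both allele sides, so a variant whose alleles
  # have unequal barcode multiplicities is padded on the smaller side
  max_ref <- max(n_bc[c(map$ref_oligo, map$alt_oligo)])
  max_alt <- max_ref
  reps <- sort(unique(as.character(counts$replicate)))
  n_rep <- length(reps)
  per_rep <- max_ref + max_alt

  # map each count record to (variant row, allele); oligos shared between
  # variants replicate their records across rows
  roles <- rbind(
    data.frame(oligo = map$ref_oligo, variant = map$variant_id, allele = 0L,
               stringsAsFactors = FALSE),
    data.frame(oligo = map$alt_oligo, variant = map$variant_id, allele = 1L,
               stringsAsFactors = FALSE)
  )
  rec <- as.data.frame(counts)
  rec <- rec[rec$oligo %in% all_oligos, ]
  if (anyDuplicated(roles$oligo)) {
    rec <- merge(rec, roles, by = "oligo")
  } else {
    idx <- match(rec$oligo, roles$oligo)
    rec$variant <- roles$variant[idx]
    rec$allele <- roles$allele[idx]
  }

  slot <- bc$slot[match(rec$barcode, bc$barcode)]
  rep_idx <- match(as.character(rec$replicate), reps)
  col <- (rep_idx - 1L) * per_rep + ifelse(rec$allele == 0L, 0L, max_ref) + slot
  row <- match(rec$variant, map$variant_id)

  dna <- matrix(NA_real_, nrow = nrow(map), ncol = n_rep * per_rep)
  rna <- dna
  dna[cbind(row, col)] <- rec$dna_count
  rna[cbind(row, col)] <- rec$rna_count
  rownames(dna) <- map$variant_id
  colnames(dna) <- paste0(
    "rep", rep(reps, each = per_rep), "_",
    rep(c(paste0("ref", seq_len(max_ref)), paste0("alt", seq_len(max_alt))),
        n_rep))
  block <- rep(reps, each = per_rep)
  allele <- rep(c(rep(0L, max_ref), rep(1L, max_alt)), n_rep)
  new_mpra_frame(map$variant_id, dna, rna, block, allele, "variant")
}

#' Build the element-mode count frame
#'
#' One row per oligo (sorted by name), one column per (replicate, barcode
#' slot); oligos with fewer barcodes than the widest oligo are padded with
#' missing slots. Optional labels are attached to rows; labels referring to
#' unknown oligos raise a warning, not an error.
#'
#' @param counts An \code{\link{mpra_counts}} table.
#' @param labels Optional \code{\link{label_table}}.
#' @return An element-mode \code{\link{mpra_frame}}.
#' @export
create_element_frame <- function(counts, labels = NULL) {
  bc <- barcode_slots(counts)
  oligos <- sort(unique(counts$oligo))
  n_bc <- table(bc$oligo)
  max_bc <- max(n_bc)
  reps <- sort(unique(as.character(counts$replicate)))
  n_rep <- length(reps)

  rec <- as.data.frame(counts)
  slot <- bc$slot[match(rec$barcode, bc$barcode)]
  rep_idx <- match(as.character(rec$replicate), reps)
  col <- (rep_idx - 1L) * max_bc + slot
  row <- match(rec$oligo, oligos)

  dna <- matrix(NA_real_, nrow = length(oligos), ncol = n_rep * max_bc)
  rna <- dna
  dna[cbind(row, col)] <- rec$dna_count
  rna[cbind(row, col)] <- rec$rna_count
  rownames(dna) <- oligos
  colnames(dna) <- paste0("rep", rep(reps, each = max_bc), "_bc",
                          rep(seq_len(max_bc), n_rep))
  block <- rep(reps, each = max_bc)

  row_labels <- NULL
  if (!is.null(labels)) {
    labels <- label_table(labels)
    unknown <- setdiff(labels$oligo, oligos)
    if (length(unknown) > 0) {
      warning(sprintf("label(s) for %d oligo(s) absent from count table: %s%s",
                      length(unknown),
                      paste(utils::head(unknown, 5), collapse = ", "),
                      if (length(unknown) > 5) ", ..." else ""))
    }
    row_labels <- labels$label[match(oligos, labels$oligo)]
  }
  new_mpra_frame(oligos, dna, rna, block, NULL, "element", labels = row_labels)
}

#' Missing-slot mask of a frame
#' @param frame An \code{\link{mpra_frame}}.
#' @return Logical matrix, TRUE where the slot is unused.
#' @export
missing_mask <- function(frame) {
  is.na(frame$dna)
}

#' Collapse a frame to aggregated counts
#'
#' Sums raw counts over barcode slots within each (replicate, allele) column
#' group (variant mode) or each replicate (element mode), reproducing the
#' classical aggregated analysis. Summation happens on raw counts, before any
#' normalization.
#'
#' @param frame An \code{\link{mpra_frame}}.
#' @return An \code{\link{mpra_frame}} with one (variant: two) column(s) per
#'   replicate.
#' @export
aggregate_frame <- function(frame) {
  reps <- levels(frame$block)
  sep <- "\036"
  if (frame$mode == "variant") {
    groups <- factor(paste(frame$block, frame$allele, sep = sep),
                     levels = paste(rep(reps, each = 2), c(0L, 1L), sep = sep))
  } else {
    groups <- frame$block
  }
  glev <- levels(droplevels(groups))
  sum_group <- function(m) {
    out <- vapply(glev, function(g) {
      cols <- which(groups == g)
      s <- rowSums(m[, cols, drop = FALSE], na.rm = TRUE)
      all_na <- rowSums(!is.na(m[, cols, drop = FALSE])) == 0
      s[all_na] <- NA_real_
      s
    }, numeric(nrow(m)))
    matrix(out, nrow = nrow(m), dimnames = list(rownames(m), glev))
  }
  dna <- sum_group(frame$dna)
  rna <- sum_group(frame$rna)
  if (frame$mode == "variant") {
    parts <- strsplit(glev, sep, fixed = TRUE)
    block <- vapply(parts, `[`, character(1), 1L)
    allele <- as.integer(vapply(parts, `[`, character(1), 2L))
    pretty <- paste0("rep", block, c("_ref", "_alt")[allele + 1L])
    colnames(dna) <- colnames(rna) <- pretty
  } else {
    block <- glev
    allele <- NULL
  }
  new_mpra_frame(frame$row_ids, dna, rna, block, allele, frame$mode,
                 labels = frame$labels)
}

#' @export
print.mpra_frame <- function(x, ...) {
  cat(sprintf("MPRA %s-mode count frame: %d rows x %d columns (%d replicates)\n",
              x$mode, nrow(x$dna), ncol(x$dna), nlevels(x$block)))
  cat(sprintf("  missing slots: %d of %d cells\n",
              sum(is.na(x$dna)), length(x$dna)))
  if (!is.null(x$labels)) {
    cat(sprintf("  labelled rows: %d\n", sum(!is.na(x$labels))))
  }
  invisible(x)
}
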