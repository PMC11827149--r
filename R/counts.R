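#' Barcode-level MPRA count table
#'
#' The canonical long-format container for MPRA counts: one record per
#' (replicate, barcode), carrying the assigned oligo and the DNA and RNA
#' counts. All preprocessing and frame-building functions operate on this
#' class.
#'
#' @param x A data.frame with columns \code{replicate}, \code{barcode},
#'   \code{oligo}, \code{dna_count}, \code{rna_count}.
#' @return An object of class \code{mpra_counts} (a validated data.frame).
#'
#' Invariants enforced: counts are non-negative integers, each
#' (replicate, barcode) pair occurs once, and every barcode is assigned to
#' exactly one oligo across all replicates.
#' @export
mpra_counts <- function(x) {
  required <- c("replicate", "barcode", "oligo", "dna_count", "rna_count")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop_mprabc("count table is missing column(s): %s",
                paste(missing_cols, collapse = ", "),
                class = "mprabc_format_error")
  }
  x <- as.data.frame(x)[required]
  x$replicate <- factor(x$replicate)
  x$barcode <- as.character(x$barcode)
  x$oligo <- as.character(x$oligo)
  for (col in c("dna_count", "rna_count")) {
    v <- x[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v != floor(v))) {
      stop_mprabc("column '%s' must contain non-negative integers", col,
                  class = "mprabc_validation_error")
    }
    x[[col]] <- as.integer(round(v))
  }
  key <- paste(x$replicate, x$barcode, sep = "\r")
  if (anyDuplicated(key)) {
    stop_mprabc("duplicated (replicate, barcode) pairs in count table",
                class = "mprabc_validation_error")
  }
  n_oligo <- tapply(x$oligo, x$barcode, function(o) length(unique(o)))
  if (any(n_oligo > 1)) {
    bad <- names(n_oligo)[n_oligo > 1]
    stop_mprabc("barcode(s) assigned to more than one oligo: %s%s",
                paste(utils::head(bad, 5), collapse = ", "),
                if (length(bad) > 5) ", ..." else "",
                class = "mprabc_validation_error")
  }
  rownames(x) <- NULL
  class(x) <- c("mpra_counts", "data.frame")
  x
}

#' @export
print.mpra_counts <- function(x, ...) {
  cat(sprintf(
    "MPRA barcode count table: %d records, %d barcodes, %d oligos, %d replicates\n",
    nrow(x), length(unique(x$barcode)), length(unique(x$oligo)),
    nlevels(x$replicate)))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat(sprintf("... and %d more records\n", nrow(x) - 6L))
  invisible(x)
}

#' Read a barcode count table
#'
#' Two dialects are supported. The canonical \code{"long"} dialect is a single
#' tab-separated file with header columns \code{replicate}, \code{barcode},
#' \code{oligo}, \code{dna_count}, \code{rna_count}. The
#' \code{"per_replicate"} dialect, matching common count-pipeline layouts,
#' takes one tab-separated file per replicate (columns \code{barcode},
#' \code{dna_count}, \code{rna_count}) plus a separate barcode-to-oligo
#' assignment file (columns \code{barcode}, \code{oligo}); barcodes without
#' an assignment are dropped with a message.
#'
#' @param path File path (long dialect) or character vector of per-replicate
#'   file paths.
#' @param dialect \code{"long"} or \code{"per_replicate"}.
#' @param assignment Path to the barcode-to-oligo assignment file
#'   (per-replicate dialect only).
#' @param replicate_ids Optional replicate labels for the per-replicate
#'   dialect; defaults to \code{1, 2, ...} in file order.
#' @return An \code{\link{mpra_counts}} table.
#' @export
read_count_table <- function(path, dialect = c("long", "per_replicate"),
                             assignment = NULL, replicate_ids = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "long") {
    if (length(path) != 1 || !file.exists(path)) {
      stop_mprabc("count table file not found: %s", paste(path, collapse = ", "),
                  class = "mprabc_io_error")
    }
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    required <- c("replicate", "barcode", "oligo", "dna_count", "rna_count")
    if (!all(required %in% names(tab))) {
      stop_mprabc("malformed header in %s: expected columns %s", path,
                  paste(required, collapse = ", "),
                  class = "mprabc_format_error")
    }
    return(mpra_counts(tab))
  }
  if (is.null(assignment)) {
    stop_mprabc("per_replicate dialect requires an assignment file",
                class = "mprabc_format_error")
  }
  for (f in c(path, assignment)) {
    if (!file.exists(f)) stop_mprabc("file not found: %s", f,
                                     class = "mprabc_io_error")
  }
  asn <- utils::read.delim(assignment, stringsAsFactors = FALSE)
  if (!all(c("barcode", "oligo") %in% names(asn))) {
    stop_mprabc("malformed header in assignment file %s", assignment,
                class = "mprabc_format_error")
  }
  if (is.null(replicate_ids)) replicate_ids <- seq_along(path)
  if (length(replicate_ids) != length(path)) {
    stop_mprabc("replicate_ids must match the number of count files",
                class = "mprabc_format_error")
  }
  parts <- vector("list", length(path))
  n_unknown <- 0L
  for (i in seq_along(path)) {
    tab <- utils::read.delim(path[i], stringsAsFactors = FALSE)
    if (!all(c("barcode", "dna_count", "rna_count") %in% names(tab))) {
      stop_mprabc("malformed header in %s: expected barcode, dna_count, rna_count",
                  path[i], class = "mprabc_format_error")
    }
    idx <- match(tab$barcode, asn$barcode)
    n_unknown <- n_unknown + sum(is.na(idx))
    keep <- !is.na(idx)
    parts[[i]] <- data.frame(
      replicate = rep(replicate_ids[i], sum(keep)),
      barcode = tab$barcode[keep],
      oligo = asn$oligo[idx[keep]],
      dna_count = tab$dna_count[keep],
      rna_count = tab$rna_count[keep],
      stringsAsFactors = FALSE
    )
  }
  if (n_unknown > 0) {
    message(sprintf("read_count_table: dropped %d record(s) with unassigned barcodes",
                    n_unknown))
  }
  mpra_counts(do.call(rbind, parts))
}

#' Read a variant map
#'
#' Tab-separated file with columns \code{variant_id}, \code{ref_oligo},
#' \code{alt_oligo}: one row per variant, naming the oligos carrying the
#' reference and alternative allele.
#' @param path File path.
#' @return A validated data.frame of class \code{mpra_variant_map}.
#' @export
read_variant_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  variant_map(tab)
}

#' @rdname read_variant_map
#' @param x A data.frame with columns \code{variant_id}, \code{ref_oligo},
#'   \code{alt_oligo}.
#' @export
variant_map <- function(x) {
  required <- c("variant_id", "ref_oligo", "alt_oligo")
  if (!all(required %in% names(x))) {
    stop_mprabc("variant map must have columns %s",
                paste(required, collapse = ", "),
                class = "mprabc_format_error")
  }
  x <- as.data.frame(x)[required]
  for (col in required) x[[col]] <- as.character(x[[col]])
  if (anyDuplicated(x$variant_id)) {
    stop_mprabc("variant_id values must be unique",
                class = "mprabc_validation_error")
  }
  if (any(x$ref_oligo == x$alt_oligo)) {
    stop_mprabc("ref_oligo and alt_oligo must differ for every variant",
                class = "mprabc_validation_error")
  }
  class(x) <- c("mpra_variant_map", "data.frame")
  x
}

#' Read an oligo label table
#'
#' Tab-separated file with columns \code{oligo}, \code{label} assigning a
#' group label (e.g. \code{"negative_control"}) to oligos; at most one label
#' per oligo.
#' @param path File path.
#' @return A data.frame with columns \code{oligo} and \code{label}.
#' @export
read_label_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  label_table(tab)
}

#' @rdname read_label_table
#' @param x A data.frame with columns \code{oligo} and \code{label}.
#' @export
label_table <- function(x) {
  if (!all(c("oligo", "label") %in% names(x))) {
    stop_mprabc("label table must have columns oligo, label",
                class = "mprabc_format_error")
  }
  x <- as.data.frame(x)[c("oligo", "label")]
  x$oligo <- as.character(x$oligo)
  x$label <- as.character(x$label)
  if (anyDuplicated(x$oligo)) {
    stop_mprabc("each oligo may carry at most one label",
                class = "mprabc_validation_error")
  }
  x
}

#' Write a count table to its canonical long TSV form
#' @param counts An \code{\link{mpra_counts}} table.
#' @param path Output file path.
#' @export
write_count_table <- function(counts, path) {
  utils::write.table(as.data.frame(counts), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write fit results to a TSV file
#'
#' Columns: \code{id}, \code{logFC} (variant mode) or \code{activity}
#' (element mode), \code{t}, \code{p_value}, \code{adj_p_value},
#' \code{n_barcodes}, in the fit's row order.
#' @param fit An \code{\link{mpra_fit}} object.
#' @param path Output file path.
#' @export
write_results <- function(fit, path) {
  tab <- as.data.frame(fit)
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop_mprabc("cannot write to %s: %s", path, conditionMessage(e),
                class = "mprabc_io_error")
  })
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
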