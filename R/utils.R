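# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Deterministic short DNA identifiers: integer index -> base-4 ACGT string.
int_to_dna <- function(i, width = 12L) {
  bases <- c("A", "C", "G", "T")
  out <- matrix("A", nrow = length(i), ncol = width)
  x <- as.integer(i)
  for (pos in width:1) {
    out[, pos] <- bases[x %% 4L + 1L]
    x <- x %/% 4L
  }
  do.call(paste0, as.data.frame(out, stringsAsFactors = FALSE))
}

# Linear-interpolation percentile (quantile type 7), the convention used for
# both barcode downsampling and negative-control thresholds.
interp_quantile <- function(x, prob) {
  unname(stats::quantile(x, probs = prob, type = 7, names = FALSE))
}

stop_mprabc <- function(fmt, ..., class = "mprabc_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
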