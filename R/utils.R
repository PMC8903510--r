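# Internal helpers shared across modules.

# Central quantile convention for the whole package (IQR trimming, the
# low-intensity PSM percentile).  Linear interpolation between order
# statistics (type 7).  Changing the convention here changes it everywhere.
pb_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE, na.rm = FALSE)
}

pb_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "plexbridge_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

pb_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic substream seeding: keep derived seeds in 32-bit range.
pb_substream_seed <- function(seed, index) {
  (as.integer(seed) + 104729L * as.integer(index)) %% 2147483629L
}
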