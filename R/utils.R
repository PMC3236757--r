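# Counter-based seed streams: a master seed expands to per-unit seeds so each
# simulated subject/draw is reproducible on its own, independent of how many
# units are generated before it.
derive_seeds <- function(master, k, stream = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, k >= 0)
  m <- 2147483629                      # large prime below 2^31
  idx <- seq_len(k) + stream * 1e6
  as.integer((master %% m + 48271 * idx) %% m + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
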