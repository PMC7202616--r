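# internal helpers shared across modules

# Derive a reproducible substream seed from a root seed and a counter.
# Arithmetic stays below 2^53 so it is exact in doubles; result < 2^31
# (R seeds are 32-bit integers). Scaled-down runs over replicate indices
# 1..k are therefore prefixes of full runs with the same root seed.
derive_seed <- function(seed, index) {
  s <- (abs(as.numeric(seed)) %% 2147483646) + 1
  as.integer((s * 69621 + as.numeric(index) * 1000003) %% 2147483647)
}

# Weighted mean / sample SD with reliability weights: for unit weights the
# SD denominator reduces to n - 1.
weighted_mean <- function(x, w) sum(w * x) / sum(w)

weighted_sd <- function(x, w) {
  sw <- sum(w)
  m <- sum(w * x) / sw
  denom <- sw - sum(w^2) / sw
  if (denom <= 0) return(0)
  sqrt(sum(w * (x - m)^2) / denom)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_usage <- function(...) {
  stop(structure(class = c("nof1_usage_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
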