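# Internal helpers shared across modules.

# Deterministic integer seed derived from a master seed and a purpose tag.
# Simple multiplicative hash; keeps every stochastic step independently
# reproducible without touching the global RNG stream.
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1)
  h <- 5381
  for (ch in utf8ToInt(as.character(tag))) h <- (h * 33 + ch) %% 2147483647
  as.integer((abs(as.numeric(master)) * 48271 + h) %% 2147483629 + 1)
}

stop_altriage <- function(msg, class) {
  rlang::abort(msg, class = paste0("altriage_", class))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

# Locale-independent lexicographic sort (radix uses C ordering).
sort_terms <- function(x) sort(x, method = "radix")
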