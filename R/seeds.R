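# Deterministic seed fan-out: every stage / cell seed is derived from the
# master seed by stable string hashing, so a pipeline rerun is bit-identical
# and cells can be re-estimated in any order.

# FNV-1a style 32-bit hash folded into [0, 2^31 - 2]; pure integer arithmetic
# via doubles (exact below 2^53).
.hash_string <- function(key) {
  h <- 2166136261
  for (b in utf8ToInt(key)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  h
}

#' Derive a child seed from a master seed and a key
#'
#' @param master_seed Integer master seed.
#' @param key Character key naming the stage or cell.
#' @return Integer seed in `[1, 2^31 - 2]`, a stable function of both inputs.
#' @export
derive_seed <- function(master_seed, key) {
  h <- (.hash_string(key) + as.double(master_seed) * 2654435761) %% (2^31 - 2)
  as.integer(h) + 1L
}
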