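#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. seed = NULL runs the code on the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage sub-seeds from a single root seed; kept below
# 2^31 so they remain valid R integers.
split_seed <- function(seed, k) {
  (as.double(seed) * 1103L + 7919L * seq_len(k)) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a
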