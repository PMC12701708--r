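# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. Keeps all exported functions pure in
# their seed argument without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic sub-seed derivation (Lehmer step); stays below 2^31 - 1.
# 48271 * (2^31 - 1) < 2^53, so the double arithmetic is exact.
derive_seed <- function(seed, offset) {
  x <- as.numeric(seed) %% 2147483647
  as.integer((x * 48271 + as.numeric(offset)) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == floor(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

stop_bs <- function(...) rlang::abort(paste0(...), class = "breastsim_error")
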