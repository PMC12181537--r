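# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so package functions never clobber the user's random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Derive a child seed for a sub-task; kept below 2^31 - 1 (R integers are 32-bit).
child_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1000 + offset) %% (.Machine$integer.max - 1L) + 1)
}

# Deterministic k-fold partition: shuffle indices, deal them round-robin.
make_folds <- function(n, k, seed) {
  stopifnot(k >= 2, n >= k)
  with_seed(seed, {
    idx <- sample.int(n)
  })
  folds <- integer(n)
  folds[idx] <- rep_len(seq_len(k), n)
  folds
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
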