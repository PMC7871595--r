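# Internal helpers shared across modules.

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")
BASES <- c("A", "C", "G", "T")

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic per-stage seed derivation from a single run seed.
# Kept below 2^31 - 1 so it is always a valid R integer.
derive_seed <- function(seed, stage) {
  stopifnot(length(stage) == 1L)
  as.integer((as.numeric(seed) * 48271 + sum(utf8ToInt(as.character(stage)))) %%
               2147483647)
}

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_pct <- function(x) round(100 * x, 1)
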