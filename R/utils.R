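# Seed plumbing: every function that consumes randomness takes one integer
# seed and expands it into independent sub-streams deterministically, so a run
# is reproducible from its top-level seed alone and no hidden RNG state leaks
# between components.

# Derive a child seed from (seed, key1[, key2]).  Arithmetic stays below 2^53
# so it is exact in doubles; results lie in [1, 2^31 - 2] (valid set.seed()
# input and exactly representable as an R integer).
derive_seed <- function(seed, key, key2 = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  a <- (abs(seed) %% 2147483647) + 1
  a <- (a * 48271) %% 2147483647
  a <- (a + (key %% 2147483647) * 69621) %% 2147483647
  a <- (a * 16807) %% 2147483647
  a <- (a + (key2 %% 2147483647) * 40503) %% 2147483647
  a <- (a * 48271) %% 2147483647
  as.integer(a %% 2147483645 + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# order-invariant polynomial hash of a character vector, below 2^31
snpset_hash <- function(ids) {
  h <- 17
  for (ch in utf8ToInt(paste(sort(ids), collapse = "\r"))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min &&
    x == as.integer(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x <= 1
}
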