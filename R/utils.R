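# Internal helpers shared across modules.

# Canonical unordered-edge key; a and b may be vectors.
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# Split an edge key back into its two endpoints (matrix with 2 columns).
split_edge_key <- function(key) {
  parts <- strsplit(key, "\r", fixed = TRUE)
  matrix(unlist(parts), ncol = 2L, byrow = TRUE)
}

# Draw n reproducible sub-seeds (< 2^31) from a master seed without
# disturbing the caller's RNG stream more than once.
derive_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(master_seed))
  out <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  out
}

stop_param <- function(msg) stop(msg, call. = FALSE)

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop_param(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_param(sprintf("'%s' must be a fraction in [0, 1]", name))
  as.numeric(x)
}

check_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min)
    stop_param(sprintf("'%s' must be a single number >= %s", name, format(min)))
  as.numeric(x)
}
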