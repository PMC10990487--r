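# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage child seed from a master seed; stays within 32-bit range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483629)
}

# Small polynomial rolling hash for provenance stamps (not cryptographic).
config_hash <- function(x) {
  s <- yaml::as.yaml(x)
  b <- utf8ToInt(s)
  h <- 0
  for (i in seq_along(b)) h <- (h * 31 + b[i]) %% 2147483647
  sprintf("%08x", as.integer(h))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_window <- function(w, name) {
  if (!is.numeric(w) || length(w) != 2L || !all(is.finite(w)) || w[1] >= w[2])
    stopf("`%s` must be a finite (lo, hi) pair with lo < hi", name)
  invisible(w)
}
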