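# Internal helpers shared across the package.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Draw `n` sub-seeds (31-bit) reproducibly from a master seed.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

# Column-standardize samples x loci matrix by its own mean/sd; constant
# columns are set to zero so they can never attract weight.
standardize_cols <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) scale <- apply(x, 2L, stats::sd)
  xs <- sweep(x, 2L, center, "-")
  ok <- is.finite(scale) & scale > 0
  xs[, ok] <- sweep(xs[, ok, drop = FALSE], 2L, scale[ok], "/")
  xs[, !ok] <- 0
  attr(xs, "center") <- center
  attr(xs, "scale") <- scale
  xs
}

# Max-normalize a nonnegative weight vector to [0,1]; all-zero stays zero.
max_normalize <- function(w) {
  w <- abs(w)
  m <- max(w)
  if (m > 0) w / m else w
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

check_flag <- function(x, nm) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_("'%s' must be TRUE or FALSE", nm)
  x
}

check_count <- function(x, nm, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop_("'%s' must be a single integer >= %d", nm, min)
  as.integer(x)
}

check_number <- function(x, nm, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop_("'%s' must be a single number in [%s, %s]", nm, min, max)
  as.numeric(x)
}
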