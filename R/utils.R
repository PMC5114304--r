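# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators are pure in (inputs, seed).
with_seed <- function(seed, expr) {
  if (length(seed) != 1L || is.na(seed) || seed != round(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Fold (seed, stream ids) into a derived 32-bit seed, kept positive.
derive_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 0
  for (x in ids) h <- (h * 7919 + as.double(x) + 1) %% 2147483629
  as.integer(h) + 1L
}

check_scalar_positive <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name),
         call. = FALSE)
  }
  invisible(x)
}

# sample sd along rows of a matrix (n-1 denominator)
row_sds <- function(m) {
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
}

#' Cortical depth grid
#'
#' The 11 relative cortical depth fractions used throughout: 0 (white-matter
#' boundary) to 1 (pial surface) in steps of 0.1.
#'
#' @return Numeric vector of length 11.
#' @export
depth_fractions <- function() seq(0, 1, by = 0.1)
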