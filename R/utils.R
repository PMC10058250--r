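# Internal helpers shared across modules.

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Deterministic integer substream seed from a root seed and string labels.
# Polynomial rolling hash mod (2^31 - 1) so derived seeds stay valid R
# integers regardless of the root seed the caller supplies.
substream_seed <- function(root, ...) {
  labels <- paste(c(...), collapse = "\x1f")
  h <- as.double(root %% 2147483647L)
  for (code in utf8ToInt(labels)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr with a temporarily-set RNG state, restoring on exit.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, min, max))
  }
  invisible(x)
}

# Dirichlet draws via normalized gammas; rows are draws.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  sweep(x, 1, rowSums(x), "/")
}

# Canonical unordered pair key "a|b" with a < b lexicographically.
pair_key <- function(id1, id2) {
  paste(pmin(id1, id2), pmax(id1, id2), sep = "\x1f")
}
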