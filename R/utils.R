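# Internal helpers: seed scoping, Dirichlet draws, permutation p-values.

# Set the RNG to `seed` and return a restorer for the caller's RNG state,
# so generators are pure functions of (parameters, seed) without clobbering
# the session stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
}

#' Derive independent stage seeds from a master seed
#'
#' Deterministic, keeps every derived seed in `[1, 2^31 - 1]`.
#'
#' @param master integer master seed
#' @param n number of seeds
#' @export
derive_seeds <- function(master, n) {
  rs <- local_seed(master)
  on.exit(rs$restore())
  sample.int(.Machine$integer.max - 1L, n)
}

# Dirichlet draws via gamma normalisation; rows sum to 1.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha), n, k, byrow = TRUE)
  # guard against all-zero rows at tiny alpha
  z <- rowSums(x)
  bad <- z == 0
  if (any(bad)) {
    x[bad, ] <- 1 / k
    z[bad] <- 1
  }
  x / z
}

# Add-one permutation p-value: (b + 1) / (m + 1), always in (0, 1].
perm_pvalue <- function(n_as_extreme, n_perm) {
  (n_as_extreme + 1) / (n_perm + 1)
}

# Hypergeometric absence probability C(N - Ni, g) / C(N, g): the chance a
# subsample of g gene copies misses an allele with Ni copies out of N.
# Computed on the log scale; exact (0/1) at the boundaries.
absence_prob <- function(N, Ni, g) {
  if (g > N - Ni) return(0)
  exp(lchoose(N - Ni, g) - lchoose(N, g))
}
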