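#' Derive a reproducible sub-seed from a master seed
#'
#' Hierarchical seeding: every randomized stage of the package draws its own
#' sub-stream from a single master seed via this hash, so e.g. adding
#' subjects to a simulated dataset does not reshuffle the stimulus set.
#' The result is always a valid 32-bit R seed.
#'
#' @param seed integer master seed.
#' @param key integer stream key (stable per purpose).
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, key) {
  s <- as.double(seed) %% 2147483647
  k <- as.double(key) %% 2147483647
  ## two rounds of a multiplicative-congruential mix keep low-entropy
  ## (seed, key) pairs from colliding on adjacent streams
  h <- (s * 48271 + k * 8191 + 12345) %% 2147483647
  h <- (h * 69621 + 7919) %% 2147483647
  as.integer(h)
}

#' Draw ex-Gaussian variates
#'
#' Convolution of a Gaussian (`mu`, `sigma`) and an exponential with mean
#' `tau`; the standard model for right-skewed fixation durations. The mean
#' is `mu + tau`. `tau = 0` degenerates to the Gaussian.
#'
#' @param n number of draws.
#' @param mu,sigma Gaussian component parameters (ms); `sigma > 0`.
#' @param tau exponential component mean (ms), vectorized, `>= 0`.
#' @return numeric vector of length `n`.
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  stopifnot(all(sigma > 0), all(tau >= 0))
  rate <- ifelse(tau > 0, 1 / tau, Inf)
  rnorm(n, mu, sigma) + rexp(n, rate)
}

#' Model-count bookkeeping for a permuted multiverse
#'
#' Total number of mixed models fitted when a multiverse of `n_universes`
#' pipelines is run once on the observed data and once per label
#' permutation: `n_universes * (n_perm + 1)`.
#'
#' @param n_universes number of universes in the multiverse.
#' @param n_perm number of label permutations.
#' @return integer-valued count.
#' @export
multiverse_model_count <- function(n_universes, n_perm) {
  stopifnot(n_universes >= 1, n_perm >= 0)
  n_universes * (n_perm + 1)
}

#' Relative spread of an effect-size range
#'
#' Fraction (in percent) of the largest observed effect attributable to
#' pipeline choice: `100 * (hi - lo) / hi`.
#'
#' @param lo,hi smallest and largest effect in comparable units (`hi > 0`).
#' @return percentage.
#' @export
effect_range_spread <- function(lo, hi) {
  stopifnot(hi > 0, hi >= lo)
  100 * (hi - lo) / hi
}

#' Fingerprint an observation table
#'
#' Digest of the canonical serialization of a single-fixation-duration
#' observation table. Two tables share a fingerprint iff they are
#' identical up to row order (rows are canonically sorted first).
#'
#' @param obs a `data.frame`/`data.table` with columns `subject_id`,
#'   `item_id`, `condition`, `sfd_ms`.
#' @return a character scalar (md5 hex digest).
#' @export
fingerprint_observations <- function(obs) {
  obs <- as.data.table(obs)
  stopifnot(all(c("subject_id", "item_id", "condition", "sfd_ms") %in% names(obs)))
  o <- obs[order(subject_id, item_id)]
  lines <- sprintf("%s\t%s\t%s\t%.6f",
                   as.character(o$subject_id), as.character(o$item_id),
                   as.character(o$condition), o$sfd_ms)
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  unname(tools::md5sum(tf))
}

## run a block of code under a derived seed, restoring RNG state afterwards
with_subseed <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(derive_seed(seed, key))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}
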