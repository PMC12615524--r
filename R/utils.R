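#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{code} with the global random-number stream set from \code{seed}
#' and restores the previous stream afterwards, so that seeded helpers do not
#' perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != round(seed)) {
    stop("`seed` must be a single integer")
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a participant-level seed from a master seed
#'
#' Deterministic stream-splitting rule used throughout the package: the
#' seed for participant \code{index}, sub-stream \code{stream}, is
#' \code{(master * 69941 + index * 7919 + stream) mod (2^31 - 1)}.
#' Sub-streams 0, 1 and 2 are used for the trial-order randomisation, the
#' parameter draw and the response sampling respectively.
#'
#' @param master master integer seed.
#' @param index participant index (1-based).
#' @param stream sub-stream offset (default 0).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, index, stream = 0L) {
  m <- 2147483647
  s <- (as.numeric(master) %% m) * 69941 + as.numeric(index) * 7919 +
    as.numeric(stream)
  as.integer(s %% m)
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
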