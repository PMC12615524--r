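#' SoftMax response probabilities
#'
#' Maps outcome strengths to probabilities of the three available responses
#' (predict X, predict Y, predict no outcome Z) via
#' \eqn{P(R_k) = \exp(g V_k) / \sum_j \exp(g V_j)} with \eqn{V_Z = 0}.
#' Computed with a log-sum-exp shift, so it is stable for \eqn{g V} far
#' outside the exponent range and invariant to adding a constant to all
#' strengths. As \eqn{g \to 0} all probabilities approach 1/3; as
#' \eqn{g \to \infty} the largest-strength response approaches probability 1.
#'
#' @param strengths named vector with \code{V_X} and \code{V_Y} (e.g. from
#'   \code{\link{predict_strengths}}); \code{V_Z} is fixed at 0 unless
#'   supplied.
#' @param g SoftMax sensitivity, in [0.0001, 15].
#' @return Named numeric \code{c(p_X, p_Y, p_Z)} summing to 1.
#' @export
#' @examples
#' response_probabilities(c(V_X = 1, V_Y = 0), g = 15)
response_probabilities <- function(strengths, g) {
  vz <- if ("V_Z" %in% names(strengths)) strengths[["V_Z"]] else 0
  a <- g * c(strengths[["V_X"]], strengths[["V_Y"]], vz)
  e <- exp(a - max(a))
  p <- e / sum(e)
  c(p_X = p[1], p_Y = p[2], p_Z = p[3])
}

#' Negative log-likelihood of an observed response sequence
#'
#' \eqn{L = -\sum_i \ln P(R_i)} over the trials of a design, where
#' \eqn{P(R_i)} is the SoftMax probability of the observed response on trial
#' i under the model's one-step-lookahead prediction. Learning uses the
#' scheduled outcomes only; observed responses never feed back into the
#' associative state. The guessing baseline assigns probability 1/3
#' everywhere, giving \eqn{L = n \ln 3}.
#'
#' @inheritParams run_sequence
#' @param responses character vector of observed responses (\code{"X"},
#'   \code{"Y"}, \code{"Z"}), one per trial.
#' @param compiled optional pre-compiled design (internal fitting fast path).
#' @param beta_mode outcome learning-rate selection rule (see
#'   \code{\link{run_sequence}}).
#' @return Non-negative likelihood value \eqn{L}.
#' @export
negative_log_likelihood <- function(model, params, design, responses,
                                    compiled = NULL,
                                    beta_mode = c("dimension", "trial")) {
  beta_mode <- match.arg(beta_mode)
  model <- match.arg(model, model_tags())
  n <- nrow(design)
  if (length(responses) != n) {
    stop("length of `responses` (", length(responses),
         ") does not match the design (", n, " trials)")
  }
  if (!all(responses %in% c("X", "Y", "Z"))) {
    stop("responses must be 'X', 'Y' or 'Z'")
  }
  if (model == "guess") return(n * log(3))
  theta <- check_params(model, params)
  resp <- match(responses, c("X", "Y", "Z")) - 1L
  core_run(model, theta, design, resp = resp, traj = FALSE,
           compiled = compiled, beta_mode = beta_mode)$L
}

#' Recompute a likelihood from an exported trajectory
#'
#' Round-trip check: sums \eqn{-\ln p} of the observed responses using the
#' per-trial probabilities of a \code{\link{run_sequence}} trajectory. Equal
#' to \code{\link{negative_log_likelihood}} on the same inputs.
#'
#' @param trajectory a \code{\link{run_sequence}} result.
#' @param responses observed responses, one per trajectory row.
#' @return Likelihood value \eqn{L}.
#' @export
loglik_from_trajectory <- function(trajectory, responses) {
  stopifnot(length(responses) == nrow(trajectory))
  p <- cbind(trajectory$p_X, trajectory$p_Y, trajectory$p_Z)
  idx <- match(responses, c("X", "Y", "Z"))
  -sum(log(p[cbind(seq_len(nrow(p)), idx)]))
}
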