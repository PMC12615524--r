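#' Small-sample corrected Akaike information criterion
#'
#' \eqn{AIC_c = 2L + 2V + 2V(V+1)/(n - V - 1)}, where L is the minimised
#' negative log-likelihood, V the number of free parameters and n the number
#' of data points. With V = 0 (the guessing baseline) this reduces to 2L.
#'
#' @param L minimised negative log-likelihood.
#' @param V number of free parameters.
#' @param n number of data points.
#' @return The AICc value.
#' @export
#' @examples
#' aicc(100, 5, 179)  # 210.3468
aicc <- function(L, V, n) {
  if (any(n <= V + 1)) stop("AICc requires n > V + 1")
  2 * L + 2 * V + 2 * V * (V + 1) / (n - V - 1)
}

# log Akaike weights from AICc values; all arithmetic in log space so that
# differences of thousands of units (log gAIC ~ 1e4) remain representable
log_akaike_weights <- function(aicc_values) {
  delta <- aicc_values - min(aicc_values, na.rm = TRUE)
  -delta / 2 - logsumexp(-delta / 2)
}

#' Akaike weights
#'
#' Normalised model evidence \eqn{w_i = \exp(-\Delta_i/2) / \sum_k
#' \exp(-\Delta_k/2)} with \eqn{\Delta_i} the AICc difference from the best
#' model. Computed in log space; weights smaller than 1e-300 underflow to 0
#' on exponentiation (the log-space forms used internally do not).
#'
#' @param aicc_values numeric vector of AICc values.
#' @return Weights summing to 1.
#' @export
#' @examples
#' akaike_weights(c(0, 2))  # 0.7311, 0.2689
akaike_weights <- function(aicc_values) {
  if (!any(is.finite(aicc_values))) stop("need at least one finite AICc")
  exp(log_akaike_weights(aicc_values))
}

#' Group Akaike information criterion
#'
#' \eqn{gAIC_i = \prod_j wAIC_{ij} / wAIC_{0j}}: the weight of evidence that
#' model i is best for all participants j relative to a baseline model
#' (conventionally the guessing model). Returned on the log scale,
#' \eqn{\log gAIC_i = \sum_j (\ln w_{ij} - \ln w_{0j})}; the baseline maps to
#' exactly 0. Zero weights are floored at 1e-300 before taking logs.
#'
#' @param weights matrix of per-participant Akaike weights (rows =
#'   participants, columns = models, column names = model tags).
#' @param baseline column name of the baseline model.
#' @return Named vector of log gAIC values.
#' @export
group_aic <- function(weights, baseline = "guess") {
  weights <- as.matrix(weights)
  if (!baseline %in% colnames(weights)) {
    stop("baseline model '", baseline, "' not in weight columns")
  }
  lw <- log(pmax(weights, 1e-300))
  out <- colSums(lw) - sum(lw[, baseline])
  out[baseline] <- 0
  out
}

#' Dirichlet probability-best analysis
#'
#' Per-participant Akaike weights parameterise a Dirichlet distribution with
#' \eqn{\alpha_i = 1 + \sum_j wAIC_{ij}}; the probability that model i is the
#' best model for a randomly chosen participant is then
#' \eqn{P(best_i) = \alpha_i / \sum_k \alpha_k}.
#'
#' @inheritParams group_aic
#' @return List with \code{alpha} and \code{p_best}, both named by model.
#' @export
dirichlet_p_best <- function(weights) {
  weights <- as.matrix(weights)
  alpha <- 1 + colSums(weights)
  list(alpha = alpha, p_best = alpha / sum(alpha))
}

#' Per-participant best-model census
#'
#' Counts, for each model, the participants for which it attains the lowest
#' AICc. Ties are broken by the canonical model order
#' guessing < Rescorla-Wagner < configural Rescorla-Wagner < Pearce.
#'
#' @param aicc_matrix matrix of per-participant AICc values (rows =
#'   participants, columns = models).
#' @return Named integer vector of counts (summing to the number of rows).
#' @export
best_model_census <- function(aicc_matrix) {
  aicc_matrix <- as.matrix(aicc_matrix)
  canon <- intersect(model_tags(), colnames(aicc_matrix))
  extra <- setdiff(colnames(aicc_matrix), canon)
  ord <- c(canon, extra)
  aicc_matrix <- aicc_matrix[, ord, drop = FALSE]
  best <- apply(aicc_matrix, 1, which.min)  # first minimum = canonical order
  counts <- stats::setNames(integer(length(ord)), ord)
  tab <- table(factor(ord[best], levels = ord))
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Full model-comparison tables for a fitted cohort
#'
#' Builds the pooled and per-participant comparison from a
#' \code{\link{fit_cohort}} table: per-participant AICc, delta-AICc and
#' Akaike weights (n = trials per participant); a pooled table under two
#' labelled conventions -- \code{aicc_pooled}, Eq.-style AICc on the summed
#' likelihood with V = parameters x participants and n = trials x
#' participants, and \code{aicc_sum}, the sum of per-participant AICc values
#' -- plus the log group AIC against the guessing baseline, the Dirichlet
#' alpha / P(best) analysis and the best-model census.
#'
#' @param fits a \code{\link{fit_cohort}} data frame.
#' @param n_trials trials per participant (default 179).
#' @param baseline baseline model for the group AIC.
#' @return Object of class \code{"model_comparison"}: \code{pooled} (data
#'   frame), \code{per_participant} (data frame), \code{weights} (matrix),
#'   \code{log_gaic}, \code{alpha}, \code{p_best}, \code{census},
#'   \code{n_participants}, \code{n_points}.
#' @export
compare_models <- function(fits, n_trials = 179, baseline = "guess") {
  models <- intersect(model_tags(), unique(fits$model))
  pids <- unique(fits$participant_id)
  n_sub <- length(pids)

  Lmat <- matrix(NA_real_, n_sub, length(models),
                 dimnames = list(pids, models))
  for (i in seq_len(nrow(fits))) {
    Lmat[fits$participant_id[i], fits$model[i]] <- fits$L_min[i]
  }
  V <- vapply(models, function(m) length(model_params(m)), integer(1))

  # per participant
  amat <- sweep(2 * Lmat, 2, 2 * V + 2 * V * (V + 1) / (n_trials - V - 1), `+`)
  wmat <- t(apply(amat, 1, akaike_weights))
  dmat <- amat - apply(amat, 1, min)
  per <- data.frame(
    participant_id = rep(pids, times = length(models)),
    model = rep(models, each = n_sub),
    aicc = as.vector(amat), delta_aicc = as.vector(dmat),
    w_aicc = as.vector(wmat), stringsAsFactors = FALSE
  )

  # pooled
  L_tot <- colSums(Lmat)
  N <- n_sub * n_trials
  Vtot <- V * n_sub
  pooled_a <- aicc(L_tot, Vtot, N)
  sum_a <- colSums(amat)
  pooled <- data.frame(
    model = models, n_params = V, total_2L = 2 * L_tot,
    aicc_pooled = pooled_a, delta_aicc_pooled = pooled_a - min(pooled_a),
    w_aicc_pooled = akaike_weights(pooled_a),
    aicc_sum = sum_a, delta_aicc_sum = sum_a - min(sum_a),
    w_aicc_sum = akaike_weights(sum_a),
    stringsAsFactors = FALSE, row.names = NULL
  )

  dir <- dirichlet_p_best(wmat)
  structure(list(
    pooled = pooled,
    per_participant = per,
    weights = wmat,
    log_gaic = if (baseline %in% models) group_aic(wmat, baseline) else NULL,
    alpha = dir$alpha,
    p_best = dir$p_best,
    census = best_model_census(amat),
    n_participants = n_sub,
    n_points = N
  ), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>", x$n_participants, "participants,",
      x$n_points, "data points\n\nPooled:\n")
  print(cbind(x$pooled[, c("model", "n_params")],
              round(x$pooled[, c("total_2L", "aicc_pooled", "aicc_sum")], 1)),
        row.names = FALSE)
  cat("\nlog gAIC: ")
  if (is.null(x$log_gaic)) cat("(no baseline fitted)\n") else {
    cat(paste(names(x$log_gaic), round(x$log_gaic, 1), sep = " = ",
              collapse = ", "), "\n")
  }
  cat("P(best):  ",
      paste(names(x$p_best), round(x$p_best, 3), sep = " = ",
            collapse = ", "), "\n")
  cat("Best-model census: ",
      paste(names(x$census), x$census, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Write a model comparison to CSV
#'
#' Writes the pooled table (plus log gAIC, Dirichlet alpha, P(best), census
#' columns) and, optionally, the per-participant table.
#'
#' @param comparison a \code{\link{compare_models}} result.
#' @param file path for the pooled table.
#' @param per_participant_file optional path for the per-participant table.
#' @return Invisibly, the pooled data frame written.
#' @export
write_comparison_csv <- function(comparison, file,
                                 per_participant_file = NULL) {
  pooled <- comparison$pooled
  pooled$log_gaic <- if (is.null(comparison$log_gaic)) NA_real_ else {
    comparison$log_gaic[pooled$model]
  }
  pooled$dirichlet_alpha <- comparison$alpha[pooled$model]
  pooled$p_best <- comparison$p_best[pooled$model]
  pooled$census <- comparison$census[pooled$model]
  utils::write.csv(pooled, file, row.names = FALSE, quote = FALSE)
  if (!is.null(per_participant_file)) {
    utils::write.csv(comparison$per_participant, per_participant_file,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(pooled)
}
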