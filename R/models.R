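#' Pearce similarity between two configurations
#'
#' \eqn{S(a,b) = (n_{ab} / (\sqrt{n_a}\sqrt{n_b}))^d}, where \eqn{n_{ab}} is
#' the number of base units common to both configurations and \eqn{n_a},
#' \eqn{n_b} are their sizes. Symmetric, equal to 1 iff the member sets are
#' identical; larger \code{d} sharpens discrimination between distinct
#' configurations.
#'
#' @param a,b configurations: either results of \code{\link{encode_pearce}}
#'   or plain character vectors of base-unit labels.
#' @param d discrimination exponent, > 0.
#' @return Similarity in [0, 1].
#' @export
#' @examples
#' similarity(c("A"), c("A", "B"), d = 2)  # 0.5
similarity <- function(a, b, d) {
  ma <- if (is.list(a)) a$members else a
  mb <- if (is.list(b)) b$members else b
  if (length(ma) == 0L || length(mb) == 0L) stop("empty configuration")
  if (!is.numeric(d) || d <= 0) stop("`d` must be positive")
  nab <- length(intersect(ma, mb))
  if (nab == 0L) return(0)
  # algebraically (n_ab / (sqrt(n_a) sqrt(n_b)))^d; the squared-ratio form
  # is exact for even d (e.g. d = 2 on a half-overlap gives exactly 0.5)
  (nab^2 / (length(ma) * length(mb)))^(d / 2)
}

# classify a unit label into its learning-rate category
unit_alpha <- function(unit, params) {
  if (grepl(".", unit, fixed = TRUE)) params[["alpha_cfg"]]
  else if (unit %in% c("a", "b", "c")) params[["alpha_ctx"]]
  else params[["alpha_cue"]]
}

#' Fresh associative state for a model
#'
#' All strengths start at exactly zero, so the first trial of any sequence
#' yields a uniform response prediction.
#'
#' @param model model tag (\code{"rw"}, \code{"crw"} or \code{"pearce"}).
#' @return An associative-state list: a strength matrix \code{V} (rows are
#'   stimulus units or configurations, columns the outcome dimensions X and
#'   Y) plus, for Pearce, the registry of configuration member sets.
#' @export
new_state <- function(model) {
  model <- match.arg(model, c("rw", "crw", "pearce"))
  V <- matrix(numeric(0), nrow = 0, ncol = 2,
              dimnames = list(NULL, c("X", "Y")))
  st <- list(model = model, V = V)
  if (model == "pearce") st$registry <- list()
  structure(st, class = "assoc_state")
}

# rows of V for the given ids, zeros where absent
state_strengths <- function(state, ids) {
  out <- matrix(0, length(ids), 2, dimnames = list(ids, c("X", "Y")))
  hit <- ids %in% rownames(state$V)
  if (any(hit)) out[hit, ] <- state$V[ids[hit], , drop = FALSE]
  out
}

#' Predicted outcome strengths for a trial
#'
#' For the elemental and configural Rescorla-Wagner models the predicted
#' strength toward each outcome is the sum of the strengths of the units
#' present on the trial. For the Pearce model it is the similarity-weighted
#' sum over every configuration known to the system (a configuration first
#' seen on the current trial holds strength 0 and so contributes nothing).
#' The "no outcome" option Z has constant strength 0 and is never learned.
#'
#' @param state an \code{\link{new_state}} associative state.
#' @param encoding model-matching encoding: unit vector from
#'   \code{\link{encode_elemental}} / \code{\link{encode_configural_rw}}, or
#'   an \code{\link{encode_pearce}} configuration.
#' @param params named parameter vector (Pearce needs \code{d}).
#' @return Named numeric \code{c(V_X, V_Y, V_Z = 0)}.
#' @export
predict_strengths <- function(state, encoding, params) {
  if (state$model %in% c("rw", "crw")) {
    if (!is.character(encoding)) stop("encoding/model mismatch")
    v <- colSums(state_strengths(state, encoding))
  } else {
    if (!is.list(encoding)) stop("encoding/model mismatch")
    v <- c(X = 0, Y = 0)
    for (id in rownames(state$V)) {
      s <- similarity(encoding$members, state$registry[[id]], params[["d"]])
      v <- v + s * state$V[id, ]
    }
  }
  c(V_X = unname(v[1]), V_Y = unname(v[2]), V_Z = 0)
}

#' Per-outcome prediction error
#'
#' The error-correction term \eqn{\lambda_k - \Sigma V_k} for each reinforced
#' outcome dimension.
#'
#' @param strengths result of \code{\link{predict_strengths}}.
#' @param outcome outcome letter (\code{"X"}, \code{"Y"}, \code{"Z"}) or a
#'   named vector \code{c(lambda_X = , lambda_Y = )}.
#' @return Named numeric \code{c(err_X, err_Y)}.
#' @export
prediction_error <- function(strengths, outcome) {
  lam <- outcome_lambda(outcome)
  c(err_X = unname(lam[1] - strengths[["V_X"]]),
    err_Y = unname(lam[2] - strengths[["V_Y"]]))
}

outcome_lambda <- function(outcome) {
  if (is.character(outcome)) {
    c(lambda_X = as.numeric(outcome == "X"),
      lambda_Y = as.numeric(outcome == "Y"))
  } else {
    c(lambda_X = as.numeric(outcome[[1]]), lambda_Y = as.numeric(outcome[[2]]))
  }
}

#' Apply one learning update
#'
#' Elemental / configural Rescorla-Wagner: every unit present on the trial
#' changes by \eqn{\alpha_j \beta_k (\lambda_k - \Sigma V_k)} on both outcome
#' dimensions, with \eqn{\alpha_j} chosen by unit category (context, cue,
#' conjunction) and \eqn{\beta_k = \beta_{us}} if outcome k occurred on the
#' trial, else \eqn{\beta_{\sim us}}; absent units are unchanged. Pearce:
#' only the configuration present on the trial changes, by
#' \eqn{\alpha \beta_k} times its generalised prediction error; all other
#' configurations keep their strengths.
#'
#' By default the outcome learning rate is chosen per outcome dimension
#' (\code{beta_mode = "dimension"}: dimension k uses \eqn{\beta_{us}} iff
#' outcome k occurred); \code{beta_mode = "trial"} instead applies
#' \eqn{\beta_{us}} to both dimensions on any reinforced trial.
#'
#' @inheritParams predict_strengths
#' @param outcome scheduled trial outcome (\code{"X"}, \code{"Y"} or
#'   \code{"Z"}).
#' @param beta_mode outcome learning-rate selection rule (see Details).
#' @return The updated associative state.
#' @export
update_state <- function(state, encoding, outcome, params,
                         beta_mode = c("dimension", "trial")) {
  beta_mode <- match.arg(beta_mode)
  strengths <- predict_strengths(state, encoding, params)
  err <- prediction_error(strengths, outcome)
  lam <- outcome_lambda(outcome)
  beta <- if (beta_mode == "dimension") {
    ifelse(lam == 1, params[["beta_us"]], params[["beta_nous"]])
  } else {
    rep(if (any(lam == 1)) params[["beta_us"]] else params[["beta_nous"]], 2)
  }
  if (state$model %in% c("rw", "crw")) {
    ids <- encoding
    cur <- state_strengths(state, ids)
    alph <- vapply(ids, unit_alpha, numeric(1), params = params)
    cur <- cur + cbind(alph * beta[1] * err[1], alph * beta[2] * err[2])
    keep <- !(rownames(state$V) %in% ids)
    state$V <- rbind(state$V[keep, , drop = FALSE], cur)
  } else {
    id <- encoding$id
    if (!id %in% names(state$registry)) state$registry[[id]] <- encoding$members
    cur <- state_strengths(state, id)
    cur <- cur + params[["alpha_pat"]] * beta * err
    keep <- !(rownames(state$V) %in% id)
    state$V <- rbind(state$V[keep, , drop = FALSE], cur)
  }
  state
}

#' Run a model trial-by-trial over a design
#'
#' One-step-lookahead trajectory: the prediction (and response probability)
#' for trial n is computed from learning over trials 1 .. n-1, after which
#' the state is updated with trial n's scheduled outcome. Responses never
#' feed back into learning.
#'
#' @param model model tag (\code{"guess"}, \code{"rw"}, \code{"crw"},
#'   \code{"pearce"}).
#' @param params named parameter vector (ignored for \code{"guess"}).
#' @param design an \code{\link{build_design}} design.
#' @param beta_mode outcome learning-rate selection: \code{"dimension"}
#'   (default; the k-th outcome dimension uses beta_us iff outcome k occurred
#'   on the trial) or \code{"trial"} (beta_us on reinforced trials for both
#'   dimensions).
#' @return Data frame with one row per trial: \code{trial}, \code{phase},
#'   \code{block}, \code{context}, \code{cues}, \code{outcome},
#'   predicted strengths \code{V_X}/\code{V_Y}, prediction errors
#'   \code{err_X}/\code{err_Y} and SoftMax response probabilities
#'   \code{p_X}/\code{p_Y}/\code{p_Z}.
#' @export
run_sequence <- function(model, params, design,
                         beta_mode = c("dimension", "trial")) {
  beta_mode <- match.arg(beta_mode)
  model <- match.arg(model, model_tags())
  n <- nrow(design)
  base <- as.data.frame(design)[, c("trial", "phase", "block", "context",
                                    "cues", "outcome")]
  if (model == "guess") {
    lam <- cbind(as.numeric(design$outcome == "X"),
                 as.numeric(design$outcome == "Y"))
    return(cbind(base, V_X = 0, V_Y = 0, err_X = lam[, 1], err_Y = lam[, 2],
                 p_X = 1 / 3, p_Y = 1 / 3, p_Z = 1 / 3))
  }
  theta <- check_params(model, params)
  res <- core_run(model, theta, design, resp = integer(0), traj = TRUE,
                  beta_mode = beta_mode)
  cbind(base, V_X = res$V_X, V_Y = res$V_Y, err_X = res$err_X,
        err_Y = res$err_Y, p_X = res$p_X, p_Y = res$p_Y, p_Z = res$p_Z)
}

# dispatch into the compiled trial loop; `compiled` can be passed to avoid
# re-encoding the design on every likelihood evaluation
core_run <- function(model, theta, design, resp, traj, compiled = NULL,
                     beta_mode = "dimension") {
  per_trial <- identical(beta_mode, "trial")
  if (model %in% c("rw", "crw")) {
    cp <- compiled %||% compile_design_rw(design, configural = model == "crw")
    alphas <- c(theta[["alpha_ctx"]], theta[["alpha_cue"]],
                if (model == "crw") theta[["alpha_cfg"]] else 0)
    rw_core(cp$units, cp$offsets, cp$utype, length(cp$universe), alphas,
            theta[["beta_us"]], theta[["beta_nous"]], theta[["g"]],
            cp$lamX, cp$lamY, as.integer(resp), traj, per_trial)
  } else {
    cp <- compiled %||% compile_design_pearce(design)
    pearce_core(cp$cfg, cp$ratio, theta[["d"]], theta[["alpha_pat"]],
                theta[["beta_us"]], theta[["beta_nous"]], theta[["g"]],
                cp$lamX, cp$lamY, as.integer(resp), traj, per_trial)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Asymptotic test strength in a simplified extinction procedure
#'
#' Fixed-point analysis of the three extinction procedures in their simplest
#' form (no context, no fillers): cues A and B are first trained to asymptote
#' (A+, B+), then the procedure runs to convergence -- super-extinction: AB-;
#' deepened-extinction: A- then AB-; control: A- -- and the associative
#' strength toward the outcome of test stimulus A alone (via generalisation
#' for Pearce) is returned. Each phase is iterated with a fixed learning-rate
#' product until the largest per-pass strength change falls below \code{tol}.
#'
#' The elemental Rescorla-Wagner model drives A to 0 under both control and
#' super-extinction and to -1/2 under deepened-extinction, so it cannot
#' produce more recovery after super-extinction; the configural models leave
#' residual positive strength on A after super-extinction (1/3 for the
#' configural Rescorla-Wagner model, 1/2 for Pearce at d = 2) because an
#' inhibitory conjunction unit or compound configuration absorbs the error.
#'
#' @param model \code{"rw"}, \code{"crw"} or \code{"pearce"}.
#' @param procedure \code{"super"}, \code{"deepened"} or \code{"control"}.
#' @param d Pearce discrimination exponent (default 2).
#' @param alpha_beta learning-rate product used for the iteration.
#' @param tol convergence tolerance on the largest per-pass change.
#' @param max_iter iteration cap per phase (error on non-convergence).
#' @return Fixed-point test strength of A toward the trained outcome.
#' @export
#' @examples
#' asymptotic_test_strength("crw", "super")  # 1/3
asymptotic_test_strength <- function(model, procedure = c("super", "deepened",
                                                          "control"),
                                     d = 2, alpha_beta = 0.1, tol = 1e-10,
                                     max_iter = 1e6) {
  model <- match.arg(model, c("rw", "crw", "pearce"))
  procedure <- match.arg(procedure)

  stim <- function(cues) {
    if (model == "rw") cues
    else if (model == "crw") {
      if (length(cues) == 2L) c(cues, conj_unit(cues[1], cues[2])) else cues
    } else sort(cues, method = "radix")
  }
  universe <- unique(c(stim("A"), stim("B"), stim(c("A", "B")),
                       if (model == "pearce") NULL))
  if (model == "pearce") {
    configs <- list(A = "A", B = "B", AB = c("A", "B"))
    V <- stats::setNames(numeric(3), names(configs))
    Smat <- outer(names(configs), names(configs),
                  Vectorize(function(i, j) similarity(configs[[i]],
                                                      configs[[j]], d)))
    dimnames(Smat) <- list(names(configs), names(configs))
    pred <- function(key) sum(Smat[key, ] * V)
  } else {
    V <- stats::setNames(numeric(length(universe)), universe)
    pred <- function(units) sum(V[units])
  }

  run_phase <- function(trials) {
    for (it in seq_len(max_iter)) {
      delta <- 0
      for (tr in trials) {
        if (model == "pearce") {
          err <- tr$lambda - pred(tr$key)
          ch <- alpha_beta * err
          V[tr$key] <<- V[tr$key] + ch
          delta <- max(delta, abs(ch))
        } else {
          err <- tr$lambda - pred(tr$units)
          ch <- alpha_beta * err
          V[tr$units] <<- V[tr$units] + ch
          delta <- max(delta, abs(ch))
        }
      }
      if (delta < tol) return(invisible(NULL))
    }
    stop("fixed-point iteration did not converge within ", max_iter,
         " iterations")
  }
  trial <- function(cues, lambda) {
    if (model == "pearce") {
      list(key = paste(sort(cues, method = "radix"), collapse = ""),
           lambda = lambda)
    } else list(units = stim(cues), lambda = lambda)
  }

  run_phase(list(trial("A", 1), trial("B", 1)))
  if (procedure == "super") {
    run_phase(list(trial(c("A", "B"), 0)))
  } else if (procedure == "deepened") {
    run_phase(list(trial("A", 0)))
    run_phase(list(trial(c("A", "B"), 0)))
  } else {
    run_phase(list(trial("A", 0)))
  }

  if (model == "pearce") pred("A") else pred("A")
}
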