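# invertible sigmoidal map between a parameter box and unconstrained space;
# keeps Nelder-Mead unconstrained while every evaluated theta stays in-box
box_to_z <- function(theta, box) {
  u <- (theta - box["lower", ]) / (box["upper", ] - box["lower", ])
  u <- pmin(pmax(u, 1e-10), 1 - 1e-10)
  stats::qlogis(u)
}

z_to_box <- function(z, box) {
  theta <- box["lower", ] + (box["upper", ] - box["lower", ]) * stats::plogis(z)
  names(theta) <- colnames(box)
  theta
}

# likelihood closure over a pre-compiled design (one encoding pass per fit)
nll_closure <- function(model, design, responses, beta_mode = "dimension") {
  resp <- match(responses, c("X", "Y", "Z")) - 1L
  compiled <- if (model %in% c("rw", "crw")) {
    compile_design_rw(design, configural = model == "crw")
  } else {
    compile_design_pearce(design)
  }
  function(theta) {
    L <- core_run(model, theta, design, resp = resp, traj = FALSE,
                  compiled = compiled, beta_mode = beta_mode)$L
    # divergent strength trajectories can overflow; a huge finite penalty
    # keeps the simplex well-defined
    if (!is.finite(L)) 1e10 else L
  }
}

#' Starting points for the multi-start optimisation
#'
#' Three starts are used for every fit: (1) the best of 64 Latin-hypercube
#' samples of the parameter box (a cheap, reproducible exploratory search);
#' (2) all parameters 0.1 except the SoftMax sensitivity g, set to 2;
#' (3) a uniform random draw inside the box. Starts 1 and 3 are seeded.
#'
#' @param model model tag (\code{"rw"}, \code{"crw"} or \code{"pearce"}).
#' @param design an \code{\link{build_design}} design.
#' @param responses observed responses, one per trial.
#' @param seed integer seed for starts 1 and 3.
#' @param beta_mode outcome learning-rate selection rule (see
#'   \code{\link{run_sequence}}).
#' @return List of three named parameter vectors.
#' @export
make_starts <- function(model, design, responses, seed,
                        beta_mode = c("dimension", "trial")) {
  model <- match.arg(model, c("rw", "crw", "pearce"))
  beta_mode <- match.arg(beta_mode)
  box <- param_box(model)
  k <- ncol(box)
  nll <- nll_closure(model, design, responses, beta_mode)
  with_seed(seed, {
    grid <- lhs::randomLHS(64, k)
    cand <- t(box["lower", ] + t(grid) * (box["upper", ] - box["lower", ]))
    colnames(cand) <- colnames(box)
    Ls <- apply(cand, 1, function(th) nll(stats::setNames(th, colnames(box))))
    start1 <- stats::setNames(cand[which.min(Ls), ], colnames(box))
    start2 <- stats::setNames(rep(0.1, k), colnames(box))
    start2["g"] <- 2
    start3 <- random_params(model)
    list(start1, start2, start3)
  })
}

#' Fit one participant by constrained maximum likelihood
#'
#' Minimises the negative log-likelihood (\code{\link{negative_log_likelihood}})
#' by Nelder-Mead simplex from each of the three \code{\link{make_starts}}
#' starting points, with box constraints enforced through an invertible
#' sigmoidal reparameterisation to an unconstrained space. Convergence uses a
#' relative tolerance of 1e-6 on L with at most 2000 iterations per start;
#' non-convergence is reported, not an error. Ties between starts are broken
#' by the lowest start id.
#'
#' @inheritParams make_starts
#' @return An object of class \code{"fit_result"}: \code{model},
#'   \code{theta_hat} (named, inside its box), \code{L_min}, \code{start_id},
#'   \code{start_L} (L at each start point), \code{n_evaluations} and
#'   \code{converged}.
#' @export
fit_participant <- function(model, design, responses, seed = 1L,
                            beta_mode = c("dimension", "trial")) {
  model <- match.arg(model, model_tags())
  beta_mode <- match.arg(beta_mode)
  if (model == "guess") {
    return(structure(list(model = "guess", theta_hat = numeric(0),
                          L_min = nrow(design) * log(3), start_id = NA_integer_,
                          start_L = numeric(0), n_evaluations = 0L,
                          converged = TRUE),
                     class = "fit_result"))
  }
  box <- param_box(model)
  nll <- nll_closure(model, design, responses, beta_mode)
  starts <- make_starts(model, design, responses, seed, beta_mode)
  start_L <- vapply(starts, nll, numeric(1))
  if (!any(is.finite(start_L))) {
    stop("no start point produced a finite likelihood; malformed data?")
  }

  best <- NULL
  n_eval <- 0L
  for (s in seq_along(starts)) {
    opt <- stats::optim(box_to_z(starts[[s]], box),
                        function(z) nll(z_to_box(z, box)),
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-6, maxit = 2000))
    n_eval <- n_eval + opt$counts[["function"]]
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      best$start_id <- s
    }
  }
  structure(list(
    model = model,
    theta_hat = z_to_box(best$par, box),
    L_min = min(best$value, start_L[best$start_id]),
    start_id = best$start_id,
    start_L = start_L,
    n_evaluations = n_eval,
    converged = best$convergence == 0
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$model, " L =", format(x$L_min, digits = 6),
      " start", x$start_id,
      if (isTRUE(x$converged)) "(converged)" else "(NOT converged)", "\n")
  if (length(x$theta_hat)) {
    print(round(x$theta_hat, 4))
  }
  invisible(x)
}

#' Fit every participant of a cohort under one or more models
#'
#' @param cohort an \code{\link{simulate_cohort}} cohort (or compatible list
#'   of participant records).
#' @param models model tags to fit (default: all four).
#' @param seed master seed; participant-level fit seeds are derived with
#'   \code{\link{derive_seed}} (sub-stream 3).
#' @return Data frame with one row per participant x model:
#'   \code{participant_id}, \code{group}, \code{model}, one column per
#'   parameter (NA where a model lacks it), \code{L_min}, \code{start_id},
#'   \code{converged}.
#' @export
fit_cohort <- function(cohort, models = model_tags(), seed = 1L) {
  participants <- cohort$participants
  all_pars <- unique(unlist(lapply(models, model_params)))
  rows <- list()
  for (i in seq_along(participants)) {
    p <- participants[[i]]
    for (m in models) {
      fit <- fit_participant(m, p$design, p$responses,
                             seed = derive_seed(seed, i, 3L))
      row <- data.frame(participant_id = p$participant_id, group = p$group,
                        model = m, L_min = fit$L_min,
                        start_id = fit$start_id, converged = fit$converged,
                        stringsAsFactors = FALSE)
      for (par in all_pars) {
        row[[par]] <- if (par %in% names(fit$theta_hat)) {
          fit$theta_hat[[par]]
        } else NA_real_
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) {
    return(data.frame(participant_id = character(0), group = character(0),
                      model = character(0), L_min = numeric(0),
                      start_id = integer(0), converged = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
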