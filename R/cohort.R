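#' Simulate a response sequence from a model
#'
#' Runs the model over the design with one-step lookahead and samples a
#' response for every trial. In \code{"categorical"} mode (used for data
#' generation) the response is drawn from the full SoftMax distribution
#' (p_X, p_Y, p_Z); in \code{"bernoulli_x"} mode only the X / not-X
#' indicator is drawn from \eqn{P(R_x)}, replicating the Bernoulli-deviate
#' traces used for model-fit figures. The same seed gives identical output.
#'
#' @inheritParams run_sequence
#' @param seed integer seed.
#' @param mode \code{"categorical"} or \code{"bernoulli_x"}.
#' @param beta_mode outcome learning-rate selection rule (see
#'   \code{\link{run_sequence}}).
#' @return \code{"categorical"}: character vector of \code{"X"}/\code{"Y"}/
#'   \code{"Z"} responses; \code{"bernoulli_x"}: integer 0/1 vector.
#' @export
simulate_responses <- function(model, params, design, seed,
                               mode = c("categorical", "bernoulli_x"),
                               beta_mode = c("dimension", "trial")) {
  mode <- match.arg(mode)
  traj <- run_sequence(model, params, design, beta_mode = match.arg(beta_mode))
  with_seed(seed, {
    if (mode == "bernoulli_x") {
      stats::rbinom(nrow(traj), 1L, traj$p_X)
    } else {
      u <- stats::runif(nrow(traj))
      ifelse(u < traj$p_X, "X",
             ifelse(u < traj$p_X + traj$p_Y, "Y", "Z"))
    }
  })
}

#' Specify a synthetic cohort
#'
#' Describes a cohort of simulated participants standing in for the human
#' dataset: group sizes for the control, deepened-extinction and
#' super-extinction conditions (the study analysed 174 participants, 58 per
#' group), the generating model (a single tag, or one tag per participant)
#' and the generating parameters (a named vector used for every participant,
#' or NULL for independent uniform draws inside each parameter's box).
#'
#' @param n_control,n_deepened,n_super group sizes.
#' @param model generating model tag(s) from \code{\link{model_tags}}.
#' @param theta named parameter vector, or NULL to draw per participant.
#' @param seed master seed; all participant-level randomisation is derived
#'   from it with \code{\link{derive_seed}}.
#' @return A list of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(n_control = 58, n_deepened = 58, n_super = 58,
                        model = "pearce", theta = NULL, seed = 1L) {
  n <- c(control = n_control, deepened = n_deepened, super = n_super)
  if (any(n < 0)) stop("group sizes must be >= 0")
  total <- sum(n)
  if (!length(model) %in% c(1L, total)) {
    stop("`model` must be one tag or one per participant")
  }
  stopifnot(all(model %in% model_tags()))
  structure(list(n = n, model = model, theta = theta,
                 seed = as.integer(seed)), class = "cohort_spec")
}

#' Simulate a cohort of participants
#'
#' For each participant a design is built with a derived seed (trial order is
#' randomised independently per participant), generating parameters are fixed
#' or drawn uniformly inside the box, and a full X/Y/Z response sequence is
#' sampled. The generating model and parameters are retained as ground truth
#' for recovery studies.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return Object of class \code{"ext_cohort"}: \code{participants}, a list
#'   of records (\code{participant_id}, \code{group}, \code{design},
#'   \code{responses}, \code{model}, \code{theta}), plus the \code{spec}.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- rep(names(spec$n), times = spec$n)
  total <- length(groups)
  models <- if (length(spec$model) == 1L) rep(spec$model, total) else spec$model
  participants <- vector("list", total)
  for (i in seq_len(total)) {
    m <- models[i]
    design <- build_design(groups[i], seed = derive_seed(spec$seed, i, 0L))
    theta <- if (m == "guess") numeric(0) else if (is.null(spec$theta)) {
      with_seed(derive_seed(spec$seed, i, 1L), random_params(m))
    } else {
      check_params(m, spec$theta)
    }
    responses <- simulate_responses(m, theta, design,
                                    seed = derive_seed(spec$seed, i, 2L))
    participants[[i]] <- list(
      participant_id = sprintf("p%03d", i), group = groups[i],
      design = design, responses = responses, model = m, theta = theta
    )
  }
  structure(list(participants = participants, spec = spec),
            class = "ext_cohort")
}

#' @export
print.ext_cohort <- function(x, ...) {
  groups <- vapply(x$participants, `[[`, character(1), "group")
  models <- vapply(x$participants, `[[`, character(1), "model")
  cat("<ext_cohort>", length(x$participants), "participants\n")
  if (length(groups)) {
    cat("  groups:", paste(names(table(groups)), table(groups), sep = " = ",
                           collapse = ", "), "\n")
    cat("  generating models:", paste(names(table(models)), table(models),
                                      sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flatten a cohort to a trial-level data frame
#'
#' @param cohort an \code{\link{simulate_cohort}} cohort.
#' @return Data frame with one row per participant x trial:
#'   \code{participant_id}, \code{group}, \code{phase}, \code{block},
#'   \code{trial_index}, \code{context}, \code{cues}, \code{outcome},
#'   \code{response}.
#' @export
cohort_to_df <- function(cohort) {
  rows <- lapply(cohort$participants, function(p) {
    df <- as.data.frame(p$design)
    names(df)[names(df) == "trial"] <- "trial_index"
    cbind(participant_id = p$participant_id, group = p$group, df,
          response = p$responses, stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(participant_id = character(0), group = character(0),
                      phase = character(0), block = integer(0),
                      trial_index = integer(0), context = character(0),
                      cues = character(0), outcome = character(0),
                      response = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a cohort to CSV plus a ground-truth sidecar
#'
#' The trial table uses the same dialect as \code{\link{write_design_csv}}
#' with an added \code{response} column; the sidecar JSON records each
#' participant's generating model and parameters.
#'
#' @param cohort an \code{\link{simulate_cohort}} cohort.
#' @param file CSV path.
#' @param truth_file optional JSON path for the ground truth.
#' @return Invisibly, the trial data frame.
#' @export
write_cohort_csv <- function(cohort, file, truth_file = NULL) {
  df <- cohort_to_df(cohort)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  if (!is.null(truth_file)) {
    truth <- lapply(cohort$participants, function(p) {
      list(participant_id = p$participant_id, group = p$group,
           model = p$model, theta = as.list(p$theta))
    })
    jsonlite::write_json(truth, truth_file, auto_unbox = TRUE, digits = NA)
  }
  invisible(df)
}

#' Read a trial-level cohort CSV
#'
#' Rebuilds an \code{"ext_cohort"} from a trial table written by
#' \code{\link{write_cohort_csv}} (or real data in the same dialect).
#' Generating model and parameters are unknown (NULL) unless a ground-truth
#' sidecar is supplied.
#'
#' @param file CSV path.
#' @param truth_file optional JSON ground-truth path.
#' @return An \code{"ext_cohort"}.
#' @export
read_cohort_csv <- function(file, truth_file = NULL) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  truth <- if (!is.null(truth_file)) jsonlite::read_json(truth_file) else NULL
  pids <- unique(df$participant_id)
  participants <- lapply(seq_along(pids), function(i) {
    sub <- df[df$participant_id == pids[i], ]
    sub <- sub[order(sub$trial_index), ]
    design <- data.frame(phase = sub$phase, block = sub$block,
                         trial = sub$trial_index, context = sub$context,
                         cues = sub$cues, outcome = sub$outcome,
                         stringsAsFactors = FALSE)
    design <- structure(design, group = sub$group[1], seed = NA_integer_,
                        class = c("ext_design", "data.frame"))
    rec <- list(participant_id = pids[i], group = sub$group[1],
                design = design, responses = sub$response,
                model = NULL, theta = NULL)
    if (!is.null(truth)) {
      t <- Filter(function(x) x$participant_id == pids[i], truth)
      if (length(t)) {
        rec$model <- t[[1]]$model
        rec$theta <- unlist(t[[1]]$theta)
      }
    }
    rec
  })
  structure(list(participants = participants, spec = NULL),
            class = "ext_cohort")
}
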