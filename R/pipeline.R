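#' One-sided exact rank-sum p-value
#'
#' Permutation rank-sum test that sample \code{a} is stochastically greater
#' than sample \code{b}: pooled values are midranked, the observed rank sum
#' of \code{a} is compared against its exact permutation distribution over
#' all \code{choose(na + nb, na)} arrangements (1820 for the 4-vs-12
#' inclusion comparison). Suitable for tiny tied samples where the normal
#' approximation is unreliable.
#'
#' @param a,b numeric vectors.
#' @return One-sided p-value, \code{Pr(rank sum >= observed)}.
#' @export
ranksum_exact_p <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)  # midranks for ties
  obs <- sum(r[seq_len(na)])
  combos <- utils::combn(length(pooled), na)
  sums <- colSums(matrix(r[combos], nrow = na))
  mean(sums >= obs - 1e-9)
}

#' Acquisition-performance inclusion filter
#'
#' Participants are included only if they acquired the A -> X response:
#' a length-4 binary vector (X responses on the last four cue-A acquisition
#' trials) is tested one-sided against a length-12 binary vector (X
#' responses on the last four presentations each of cues C, D and E, none of
#' which ever signalled X) with a rank-sum test; the participant is included
#' iff p < .05. Uniform guessers are overwhelmingly excluded, committed
#' learners pass.
#'
#' @param record a participant record (list with \code{design} and
#'   \code{responses}, e.g. an element of a cohort's \code{participants}).
#' @param method \code{"exact"} (permutation enumeration with midranks,
#'   default) or \code{"normal"} (large-sample approximation via
#'   \code{\link[stats]{wilcox.test}} with continuity correction).
#' @return List of class \code{"inclusion_decision"}:
#'   \code{participant_id}, \code{statistic} (rank sum of the cue-A vector),
#'   \code{p_value}, \code{included}.
#' @export
inclusion_filter <- function(record, method = c("exact", "normal")) {
  method <- match.arg(method)
  design <- record$design
  acq <- which(design$phase == "acquisition")
  if (!length(acq)) stop("record lacks an acquisition phase")
  x <- as.integer(record$responses == "X")

  last4 <- function(cue) {
    idx <- acq[design$cues[acq] == cue]
    if (length(idx) < 4L) stop("fewer than 4 acquisition trials of cue ", cue)
    utils::tail(idx, 4L)
  }
  a_vec <- x[last4("A")]
  cde_vec <- x[c(last4("C"), last4("D"), last4("E"))]

  if (method == "exact") {
    p <- ranksum_exact_p(a_vec, cde_vec)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(a_vec, cde_vec, alternative = "greater",
                         exact = FALSE, correct = TRUE)$p.value
    )
  }
  stat <- sum(rank(c(a_vec, cde_vec))[1:4])
  structure(list(participant_id = record$participant_id, statistic = stat,
                 p_value = p, included = p < 0.05),
            class = "inclusion_decision")
}

#' Inclusion decisions for a whole cohort
#'
#' Applies \code{\link{inclusion_filter}} to every participant.
#'
#' @param cohort an \code{ext_cohort}.
#' @param method rank-sum method, as in \code{\link{inclusion_filter}}.
#' @return Data frame: \code{participant_id}, \code{group},
#'   \code{statistic}, \code{p_value}, \code{included}.
#' @export
inclusion_table <- function(cohort, method = "exact") {
  rows <- lapply(cohort$participants, function(p) {
    d <- inclusion_filter(p, method = method)
    data.frame(participant_id = d$participant_id, group = p$group,
               statistic = d$statistic, p_value = d$p_value,
               included = d$included, stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(participant_id = character(0), group = character(0),
                      statistic = numeric(0), p_value = numeric(0),
                      included = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-presentation X-response curve for a cue
#'
#' For every trial containing the target cue, aligned by presentation number
#' (trial order is randomised per participant, so absolute trial indices do
#' not align), the mean and standard error of the X-response indicator per
#' group.
#'
#' @param cohort an \code{ext_cohort}.
#' @param cue target cue label (default \code{"A"}).
#' @return Data frame: \code{group}, \code{position}, \code{phase},
#'   \code{n}, \code{mean_x}, \code{se} (NA when n < 2).
#' @export
response_curve <- function(cohort, cue = "A") {
  if (!length(cohort$participants)) stop("empty cohort")
  rows <- lapply(cohort$participants, function(p) {
    has_cue <- vapply(split_cues(p$design$cues),
                      function(cs) cue %in% cs, logical(1))
    idx <- which(has_cue)
    data.frame(group = p$group, position = seq_along(idx),
               phase = p$design$phase[idx],
               x = as.integer(p$responses[idx] == "X"),
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(long, long[c("group", "position")],
                                     drop = TRUE), function(s) {
    data.frame(group = s$group[1], position = s$position[1],
               phase = s$phase[1], n = nrow(s), mean_x = mean(s$x),
               se = if (nrow(s) >= 2L) stats::sd(s$x) / sqrt(nrow(s))
                    else NA_real_,
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$group, agg$position), ]
  rownames(agg) <- NULL
  agg
}

#' Recovery-test and summation-test summaries
#'
#' Recovery: the proportion of each group responding X on the single
#' recovery-test trial (cue A in the novel context). Summation: each
#' participant's count of X responses (0-2) over the two non-reinforced
#' G-trials in the extinction context, summarised by group and by
#' recovery-responder status (a probe of contextual inhibition).
#'
#' @param cohort an \code{ext_cohort}.
#' @return List with \code{recovery} (group, n, rate), \code{summation}
#'   (per participant: group, x_count, recovered) and
#'   \code{summation_by_recovery} (mean count for responders vs
#'   non-responders).
#' @export
recovery_and_summation_summary <- function(cohort) {
  per <- lapply(cohort$participants, function(p) {
    rec_idx <- which(p$design$phase == "recovery")
    sum_idx <- which(p$design$phase == "summation")
    if (!length(rec_idx) || !length(sum_idx)) {
      stop("cohort lacks summation/recovery phases")
    }
    data.frame(participant_id = p$participant_id, group = p$group,
               x_count = sum(p$responses[sum_idx] == "X"),
               recovered = p$responses[rec_idx] == "X",
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  recovery <- do.call(rbind, lapply(split(per, per$group), function(s) {
    data.frame(group = s$group[1], n = nrow(s), rate = mean(s$recovered),
               stringsAsFactors = FALSE)
  }))
  rownames(recovery) <- NULL
  by_rec <- do.call(rbind, lapply(split(per, per$recovered), function(s) {
    data.frame(recovered = s$recovered[1], n = nrow(s),
               mean_x_count = mean(s$x_count), stringsAsFactors = FALSE)
  }))
  rownames(by_rec) <- NULL
  list(recovery = recovery, summation = per, summation_by_recovery = by_rec)
}

#' One-parameter-at-a-time likelihood sensitivity
#'
#' Perturbs each parameter of a fitted vector by the given relative
#' fractions in both directions (clipped to its constraint box), recomputes
#' the likelihood and reports the relative change
#' \eqn{|L' - L_{min}| / L_{min}}. The zero-perturbation row is always 0.
#'
#' @param model model tag.
#' @param theta_hat fitted (named) parameter vector.
#' @param design the participant's design.
#' @param responses the participant's responses.
#' @param fractions relative perturbation sizes (default 1%, 2.5%, 5%).
#' @return Data frame of class \code{"sensitivity_report"}: \code{param},
#'   \code{fraction} (signed; 0 row included per parameter), \code{value}
#'   (perturbed parameter value), \code{L}, \code{rel_change}.
#' @export
sensitivity <- function(model, theta_hat, design, responses,
                        fractions = c(0.01, 0.025, 0.05)) {
  stopifnot(all(fractions >= 0), all(fractions <= 0.05))
  theta_hat <- check_params(model, theta_hat)
  box <- param_box(model)
  nll <- nll_closure(model, design, responses)
  L0 <- nll(theta_hat)
  fr <- sort(unique(c(0, fractions, -fractions)))
  rows <- list()
  for (p in names(theta_hat)) {
    for (f in fr) {
      theta <- theta_hat
      theta[p] <- min(max(theta[p] * (1 + f), box["lower", p]),
                      box["upper", p])
      L <- if (f == 0) L0 else nll(theta)
      rows[[length(rows) + 1L]] <- data.frame(
        param = p, fraction = f, value = theta[[p]], L = L,
        rel_change = abs(L - L0) / L0, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sensitivity_report", "data.frame")
  out
}

# sensitivity over a fitted cohort: one report row-set per participant/model
cohort_sensitivity <- function(cohort, fits, models = c("rw", "crw", "pearce"),
                               fractions = c(0.01, 0.025, 0.05),
                               max_participants = Inf) {
  recs <- cohort$participants
  ids <- vapply(recs, `[[`, character(1), "participant_id")
  use <- ids[seq_len(min(length(ids), max_participants))]
  rows <- list()
  for (pid in use) {
    p <- recs[[match(pid, ids)]]
    for (m in intersect(models, unique(fits$model))) {
      row <- fits[fits$participant_id == pid & fits$model == m, ]
      if (!nrow(row)) next
      theta <- unlist(row[1, model_params(m)])
      rep <- sensitivity(m, theta, p$design, p$responses, fractions)
      rep <- cbind(participant_id = pid, model = m, rep,
                   stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- rep
    }
  }
  if (!length(rows)) {
    return(data.frame(participant_id = character(0), model = character(0),
                      param = character(0), fraction = numeric(0),
                      value = numeric(0), L = numeric(0),
                      rel_change = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' End-to-end orchestration: simulate (or read) a cohort, apply the
#' inclusion filter, fit every requested model to every included
#' participant, build the model-comparison tables, compute cue-A response
#' curves and recovery/summation summaries, and run the one-at-a-time
#' sensitivity analysis on the fitted parameters. All stages log their seed
#' and row counts; with an \code{out_dir} every artefact is written as CSV
#' alongside a JSON manifest, and identical configs produce byte-identical
#' tables.
#'
#' @param config a list, or path to a YAML/JSON config file, with fields:
#'   \code{cohort} (arguments for \code{\link{cohort_spec}}, or a list with
#'   \code{csv} and optional \code{truth} paths), \code{models} (tags to
#'   fit; default all four), \code{seed} (default 1), \code{out_dir}
#'   (optional output directory), \code{ranksum_method} (\code{"exact"} or
#'   \code{"normal"}), \code{sensitivity_fractions},
#'   \code{sensitivity_max_participants}, \code{curve_cue}.
#' @return Invisibly, a list with \code{cohort}, \code{inclusion},
#'   \code{fits}, \code{comparison}, \code{curves}, \code{recovery},
#'   \code{sensitivity} and \code{manifest}.
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  seed <- config$seed %||% 1L
  models <- config$models %||% model_tags()
  method <- config$ranksum_method %||% "exact"
  fractions <- config$sensitivity_fractions %||% c(0.01, 0.025, 0.05)
  sens_max <- config$sensitivity_max_participants %||% Inf
  cue <- config$curve_cue %||% "A"
  out_dir <- config$out_dir

  msg <- function(stage, ...) message("[", stage, "] ", ...)

  # stage: cohort
  cohort <- if (!is.null(config$cohort$csv)) {
    msg("cohort", "reading ", config$cohort$csv)
    read_cohort_csv(config$cohort$csv, config$cohort$truth)
  } else {
    spec <- do.call(cohort_spec, c(config$cohort,
                                   if (is.null(config$cohort$seed)) {
                                     list(seed = seed)
                                   }))
    msg("cohort", "simulating ", sum(spec$n), " participants (seed ",
        spec$seed, ")")
    simulate_cohort(spec)
  }
  n_total <- length(cohort$participants)

  empty <- function() {
    list(cohort = cohort, inclusion = inclusion_table(cohort),
         fits = NULL, comparison = NULL, curves = NULL, recovery = NULL,
         sensitivity = NULL,
         manifest = list(seed = seed, models = models, n_total = 0L,
                         n_included = 0L))
  }
  if (n_total == 0L) {
    msg("pipeline", "empty cohort; nothing to do")
    return(invisible(empty()))
  }

  # stage: inclusion
  inclusion <- inclusion_table(cohort, method = method)
  msg("inclusion", sum(inclusion$included), "/", n_total,
      " participants pass (", method, " rank-sum, p < .05)")
  keep <- inclusion$participant_id[inclusion$included]
  included <- cohort
  included$participants <- Filter(function(p) p$participant_id %in% keep,
                                  cohort$participants)

  fits <- NULL; comparison <- NULL; curves <- NULL; recov <- NULL; sens <- NULL
  if (length(included$participants)) {
    # stage: fits
    msg("fit", "fitting models {", paste(models, collapse = ", "),
        "} to ", length(included$participants), " participants")
    fits <- fit_cohort(included, models = models, seed = seed)

    # stage: comparison
    if (length(unique(fits$model)) >= 2L) {
      comparison <- compare_models(fits,
                                   n_trials = nrow(included$participants[[1]]$design))
      msg("compare", "best-model census: ",
          paste(names(comparison$census), comparison$census, sep = "=",
                collapse = " "))
    }

    # stage: descriptives
    curves <- response_curve(included, cue = cue)
    recov <- recovery_and_summation_summary(included)
    msg("describe", "recovery rates: ",
        paste(recov$recovery$group, round(recov$recovery$rate, 3),
              sep = "=", collapse = " "))

    # stage: sensitivity
    sens <- cohort_sensitivity(included, fits, fractions = fractions,
                               max_participants = sens_max)
    msg("sensitivity", nrow(sens), " likelihood evaluations recorded")
  }

  manifest <- list(
    seed = seed, models = models, ranksum_method = method,
    sensitivity_fractions = fractions, curve_cue = cue,
    n_total = n_total, n_included = length(included$participants),
    package_version = as.character(utils::packageVersion("extinctr"))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_csv(cohort, file.path(out_dir, "trials.csv"),
                     truth_file = file.path(out_dir, "ground_truth.json"))
    utils::write.csv(inclusion, file.path(out_dir, "inclusion.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(fits)) {
      utils::write.csv(fits, file.path(out_dir, "fits.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    if (!is.null(comparison)) {
      write_comparison_csv(comparison, file.path(out_dir, "comparison.csv"),
                           file.path(out_dir, "comparison_participants.csv"))
    }
    if (!is.null(curves)) {
      utils::write.csv(curves, file.path(out_dir, "curves.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    if (!is.null(sens)) {
      utils::write.csv(sens, file.path(out_dir, "sensitivity.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    msg("pipeline", "artefacts written to ", out_dir)
  }

  invisible(list(cohort = cohort, inclusion = inclusion, fits = fits,
                 comparison = comparison, curves = curves, recovery = recov,
                 sensitivity = sens, manifest = manifest))
}
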