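#' Build the 179-trial experimental design for one participant
#'
#' Constructs the full five-phase design of the predictive-learning task:
#' 144 acquisition trials (4 blocks of 36) in context \code{A:}, two
#' extinction phases of 16 trials each (8 blocks of 2) in context \code{B:},
#' a two-trial summation test (\code{G -> Z}) in context \code{B:}, and a
#' single-trial recovery test (\code{A -> Z}) in context \code{C:}.
#'
#' Each acquisition block presents every cue four times: \code{A} and
#' \code{B} on a 3 X / 1 Z partial schedule, \code{K} and \code{L} on a
#' 3 Y / 1 Z schedule, \code{C} 4 Y, \code{G} 4 X, \code{D} and \code{E}
#' 4 Z, and the \code{KL} compound 4 Y (an additivity demonstration).
#' The extinction phases differ by group: the control group extinguishes
#' \code{A} alone in both phases, the deepened-extinction group extinguishes
#' \code{A} alone and then the \code{AB} compound, and the super-extinction
#' group extinguishes \code{AB} in both phases; every group also receives
#' \code{C -> Y} in each extinction block.
#'
#' Trial order is randomised independently within each block from a single
#' participant-level stream: \code{set.seed(seed)} is applied once and blocks
#' are then shuffled in experiment order (acquisition blocks 1-4, extinction 1
#' blocks 1-8, extinction 2 blocks 1-8), so the same seed reproduces the
#' design bit-exactly. The summation and recovery phases have fixed order.
#'
#' @param group one of \code{"control"}, \code{"deepened"}, \code{"super"}.
#' @param seed integer randomisation seed.
#' @return A data frame of class \code{"ext_design"} with one row per trial
#'   and columns \code{phase}, \code{block}, \code{trial}, \code{context}
#'   (\code{"A:"}, \code{"B:"} or \code{"C:"}), \code{cues} (cue labels
#'   joined by \code{"+"}, e.g. \code{"A+B"}) and \code{outcome} (\code{"X"},
#'   \code{"Y"} or \code{"Z"}). The group and seed are stored as attributes.
#' @export
#' @examples
#' d <- build_design("super", seed = 1)
#' table(d$phase)
build_design <- function(group = c("control", "deepened", "super"), seed) {
  group <- match.arg(group)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != round(seed)) {
    stop("`seed` must be a single integer")
  }

  acq_types <- data.frame(
    cues    = rep(c("A", "B", "C", "D", "E", "G", "K", "L", "K+L"), each = 4),
    outcome = c("X", "X", "X", "Z",  # A: 3X + 1Z
                "X", "X", "X", "Z",  # B: 3X + 1Z
                "Y", "Y", "Y", "Y",  # C: 4Y
                "Z", "Z", "Z", "Z",  # D: 4Z
                "Z", "Z", "Z", "Z",  # E: 4Z
                "X", "X", "X", "X",  # G: 4X
                "Y", "Y", "Y", "Z",  # K: 3Y + 1Z
                "Y", "Y", "Y", "Z",  # L: 3Y + 1Z
                "Y", "Y", "Y", "Y"), # KL: 4Y
    stringsAsFactors = FALSE
  )
  ext_target <- switch(group,
    control  = c("A", "A"),
    deepened = c("A", "A+B"),
    super    = c("A+B", "A+B")
  )

  rows <- with_seed(seed, {
    out <- vector("list", 4 + 8 + 8 + 2)
    k <- 0L
    for (b in 1:4) {
      ord <- sample.int(nrow(acq_types))
      k <- k + 1L
      out[[k]] <- data.frame(
        phase = "acquisition", block = b, context = "A:",
        cues = acq_types$cues[ord], outcome = acq_types$outcome[ord],
        stringsAsFactors = FALSE
      )
    }
    for (ph in 1:2) {
      types <- data.frame(
        cues = c(ext_target[ph], "C"), outcome = c("Z", "Y"),
        stringsAsFactors = FALSE
      )
      for (b in 1:8) {
        ord <- sample.int(2L)
        k <- k + 1L
        out[[k]] <- data.frame(
          phase = paste0("extinction", ph), block = b, context = "B:",
          cues = types$cues[ord], outcome = types$outcome[ord],
          stringsAsFactors = FALSE
        )
      }
    }
    out[[k + 1L]] <- data.frame(
      phase = "summation", block = 1L, context = "B:",
      cues = c("G", "G"), outcome = c("Z", "Z"), stringsAsFactors = FALSE
    )
    out[[k + 2L]] <- data.frame(
      phase = "recovery", block = 1L, context = "C:",
      cues = "A", outcome = "Z", stringsAsFactors = FALSE
    )
    out
  })

  design <- do.call(rbind, rows)
  design$trial <- seq_len(nrow(design))
  design <- design[, c("phase", "block", "trial", "context", "cues", "outcome")]
  rownames(design) <- NULL
  structure(design, group = group, seed = as.integer(seed),
            class = c("ext_design", "data.frame"))
}

# split a "+"-joined cue string into individual cue labels
split_cues <- function(cues) strsplit(cues, "+", fixed = TRUE)

# context unit label: lowercase letter of the context ("A:" -> "a")
context_unit <- function(context) tolower(substr(context, 1L, 1L))

#' Elemental stimulus encoding of a trial
#'
#' The elemental (Rescorla-Wagner) encoding of a trial is one context unit
#' plus one unit per cue; context units are the lowercase letter of the
#' context label.
#'
#' @param trial a one-row design data frame (a row of an
#'   \code{\link{build_design}} result), or a list with elements
#'   \code{context} and \code{cues}.
#' @return Character vector of stimulus-unit labels.
#' @export
#' @examples
#' encode_elemental(list(context = "A:", cues = "A"))     # "a" "A"
#' encode_elemental(list(context = "B:", cues = "A+B"))   # "b" "A" "B"
encode_elemental <- function(trial) {
  c(context_unit(trial$context), split_cues(trial$cues)[[1]])
}

# stable conjunction-unit label for an unordered pair of base units
conj_unit <- function(u1, u2) {
  p <- sort(c(u1, u2), method = "radix")
  paste0(p[1], ".", p[2])
}

#' Configural Rescorla-Wagner encoding of a trial
#'
#' Base units as in \code{\link{encode_elemental}} plus one conjunction unit
#' per unordered pair of co-present base units, so a trial with n base units
#' yields n + n(n-1)/2 units. Conjunction-unit identity is stable across the
#' experiment (same pair, same unit); labels join the sorted pair with a dot,
#' e.g. \code{"A.a"}.
#'
#' @inheritParams encode_elemental
#' @return Character vector of stimulus-unit labels.
#' @export
#' @examples
#' encode_configural_rw(list(context = "A:", cues = "A"))   # 3 units
#' encode_configural_rw(list(context = "B:", cues = "A+B")) # 6 units
encode_configural_rw <- function(trial) {
  base <- encode_elemental(trial)
  n <- length(base)
  conj <- character(0)
  if (n >= 2L) {
    idx <- utils::combn(n, 2L)
    conj <- vapply(seq_len(ncol(idx)), function(i) {
      conj_unit(base[idx[1, i]], base[idx[2, i]])
    }, character(1))
  }
  c(base, conj)
}

#' Pearce configuration of a trial
#'
#' In the Pearce configural model the whole stimulus pattern on a trial
#' (context plus cues) is a single associative unit. Identical member sets
#' map to the same canonical configuration id.
#'
#' @inheritParams encode_elemental
#' @return A list with elements \code{id} (canonical id string),
#'   \code{members} (sorted base-unit labels) and \code{size}.
#' @export
#' @examples
#' encode_pearce(list(context = "A:", cues = "A"))$id
encode_pearce <- function(trial) {
  members <- sort(encode_elemental(trial), method = "radix")
  list(id = paste(members, collapse = "."), members = members,
       size = length(members))
}

#' @export
print.ext_design <- function(x, ...) {
  cat("<ext_design> group =", attr(x, "group"),
      " seed =", attr(x, "seed"), "\n")
  cat(nrow(x), "trials:",
      paste(names(table(x$phase)), table(x$phase), collapse = ", ",
            sep = " = "), "\n")
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more trials\n")
  invisible(x)
}

#' Write a design (or cohort trial table) to CSV
#'
#' One row per trial with columns \code{participant_id}, \code{group},
#' \code{phase}, \code{block}, \code{trial_index}, \code{context},
#' \code{cues} and \code{outcome} (plus \code{response} when present).
#'
#' @param design an \code{ext_design} or a trial data frame already carrying
#'   \code{participant_id}/\code{group} columns.
#' @param file path to write.
#' @param participant_id,group identifiers used when \code{design} is a bare
#'   \code{ext_design}.
#' @return Invisibly, the data frame written.
#' @export
write_design_csv <- function(design, file, participant_id = "p001",
                             group = attr(design, "group")) {
  df <- as.data.frame(design)
  if (!"participant_id" %in% names(df)) {
    df <- cbind(participant_id = participant_id, group = group, df)
  }
  names(df)[names(df) == "trial"] <- "trial_index"
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(df)
}

# ---- compiled representations used by the C++ likelihood core -------------

# trial-by-unit index structure for the elemental / configural RW models
compile_design_rw <- function(design, configural = FALSE) {
  enc <- if (configural) encode_configural_rw else encode_elemental
  units_by_trial <- lapply(seq_len(nrow(design)), function(i) {
    enc(list(context = design$context[i], cues = design$cues[i]))
  })
  universe <- unique(unlist(units_by_trial))
  utype <- ifelse(grepl(".", universe, fixed = TRUE), 2L,
                  ifelse(universe %in% c("a", "b", "c"), 0L, 1L))
  idx <- lapply(units_by_trial, function(u) match(u, universe) - 1L)
  list(
    units = as.integer(unlist(idx)),
    offsets = as.integer(c(0L, cumsum(lengths(idx)))),
    utype = as.integer(utype),
    universe = universe,
    lamX = as.integer(design$outcome == "X"),
    lamY = as.integer(design$outcome == "Y")
  )
}

# configuration indices + squared similarity base-ratio matrix
# (n_ab^2 / (n_a n_b); the core raises it to d/2) for the Pearce model
compile_design_pearce <- function(design) {
  cfgs <- lapply(seq_len(nrow(design)), function(i) {
    encode_pearce(list(context = design$context[i], cues = design$cues[i]))
  })
  ids <- vapply(cfgs, `[[`, character(1), "id")
  uids <- unique(ids)
  members <- lapply(uids, function(id) cfgs[[match(id, ids)]]$members)
  m <- length(uids)
  ratio <- matrix(0, m, m, dimnames = list(uids, uids))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      nab <- length(intersect(members[[i]], members[[j]]))
      ratio[i, j] <- nab^2 / (length(members[[i]]) * length(members[[j]]))
    }
  }
  list(
    cfg = match(ids, uids) - 1L,
    ratio = ratio,
    ids = uids,
    members = members,
    lamX = as.integer(design$outcome == "X"),
    lamY = as.integer(design$outcome == "Y")
  )
}
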