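# Independent plain-R reference implementations of the three learning models
# and the SoftMax likelihood, written directly from the update equations with
# their own encodings and state-keeping. Used as oracles against the
# package's compiled trial loop.

ref_softmax <- function(vx, vy, g) {
  a <- c(g * vx, g * vy, 0)
  e <- exp(a - max(a))
  e / sum(e)
}

ref_run <- function(model, th, design, responses = NULL,
                    beta_mode = "dimension") {
  n <- nrow(design)
  V <- list()     # unit/config id -> c(x, y)
  members <- list()
  getV <- function(id) if (is.null(V[[id]])) c(0, 0) else V[[id]]
  out <- data.frame(V_X = numeric(n), V_Y = numeric(n), p_X = numeric(n),
                    p_Y = numeric(n), p_Z = numeric(n))
  L <- 0
  for (i in seq_len(n)) {
    ctx <- tolower(substr(design$context[i], 1, 1))
    cues <- strsplit(design$cues[i], "+", fixed = TRUE)[[1]]
    base <- c(ctx, cues)
    if (model %in% c("rw", "crw")) {
      units <- base
      if (model == "crw" && length(base) >= 2) {
        for (a in seq_along(base)) for (b in seq_along(base)) {
          if (a < b) {
            pr <- sort(c(base[a], base[b]), method = "radix")
            units <- c(units, paste(pr, collapse = "."))
          }
        }
      }
      vx <- sum(vapply(units, function(u) getV(u)[1], 0))
      vy <- sum(vapply(units, function(u) getV(u)[2], 0))
    } else {
      mem <- sort(base, method = "radix")
      id <- paste(mem, collapse = ".")
      if (is.null(members[[id]])) members[[id]] <- mem
      vx <- 0; vy <- 0
      for (j in names(members)) {
        nab <- length(intersect(mem, members[[j]]))
        s <- if (nab == 0) 0 else {
          (nab / (sqrt(length(mem)) * sqrt(length(members[[j]]))))^th[["d"]]
        }
        vx <- vx + s * getV(j)[1]
        vy <- vy + s * getV(j)[2]
      }
    }
    p <- ref_softmax(vx, vy, th[["g"]])
    if (!is.null(responses)) {
      L <- L - log(p[match(responses[i], c("X", "Y", "Z"))])
    }
    lx <- as.numeric(design$outcome[i] == "X")
    ly <- as.numeric(design$outcome[i] == "Y")
    if (beta_mode == "dimension") {
      bx <- if (lx == 1) th[["beta_us"]] else th[["beta_nous"]]
      by <- if (ly == 1) th[["beta_us"]] else th[["beta_nous"]]
    } else {
      b <- if (lx == 1 || ly == 1) th[["beta_us"]] else th[["beta_nous"]]
      bx <- b; by <- b
    }
    ex <- lx - vx; ey <- ly - vy
    if (model %in% c("rw", "crw")) {
      for (u in units) {
        a <- if (grepl(".", u, fixed = TRUE)) th[["alpha_cfg"]]
             else if (u %in% c("a", "b", "c")) th[["alpha_ctx"]]
             else th[["alpha_cue"]]
        V[[u]] <- getV(u) + c(a * bx * ex, a * by * ey)
      }
    } else {
      V[[id]] <- getV(id) + th[["alpha_pat"]] * c(bx * ex, by * ey)
    }
    out$V_X[i] <- vx; out$V_Y[i] <- vy
    out$p_X[i] <- p[1]; out$p_Y[i] <- p[2]; out$p_Z[i] <- p[3]
  }
  attr(out, "L") <- L
  out
}

# exact one-sided Mann-Whitney p (a > b) by enumeration over the U statistic
# with ties counted 1/2 -- an oracle independent of the rank-sum route
ref_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_stat <- function(xs, ys) {
    sum(outer(xs, ys, function(x, y) (x > y) + 0.5 * (x == y)))
  }
  obs <- u_stat(a, b)
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  mean(us >= obs - 1e-9)
}

# a small hand-rolled design data frame for closed-form checks
ref_single_cue_design <- function(n, cue = "A", outcome = "X",
                                  context = "A:") {
  structure(
    data.frame(phase = "acquisition", block = 1L, trial = seq_len(n),
               context = context, cues = cue, outcome = outcome,
               stringsAsFactors = FALSE),
    class = c("ext_design", "data.frame"), group = "control", seed = 0L
  )
}

# canonical mid-range generating parameters used in recovery suites
ref_teacher_theta <- function(model) {
  pars <- model_params(model)
  th <- stats::setNames(rep(0.3, length(pars)), pars)
  th["g"] <- 5
  if ("d" %in% pars) th["d"] <- 2
  th
}
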