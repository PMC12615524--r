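rw_params <- c(alpha_ctx = 0.1, alpha_cue = 0.5, beta_us = 0.5,
               beta_nous = 0.4, g = 2)
pearce_params <- c(alpha_pat = 0.3, beta_us = 0.5, beta_nous = 0.4,
                   d = 2, g = 2)

# build a state holding given strengths toward X
seed_state <- function(model, strengths, members = NULL) {
  st <- new_state(model)
  st$V <- cbind(X = strengths, Y = rep(0, length(strengths)))
  rownames(st$V) <- names(strengths)
  if (model == "pearce") st$registry <- members
  st
}

test_that("extinction-onset prediction errors match the analytic cases", {
  # single cue at asymptote: error approaches -1
  st <- seed_state("rw", c(A = 1))
  s <- predict_strengths(st, c("A"), rw_params)
  expect_identical(prediction_error(s, "Z")[["err_X"]], -1)
  # compound of two asymptotic excitors: summed prediction 2, error -2
  st2 <- seed_state("rw", c(A = 1, B = 1))
  s2 <- predict_strengths(st2, c("A", "B"), rw_params)
  expect_identical(s2[["V_X"]], 2)
  expect_identical(prediction_error(s2, "Z")[["err_X"]], -2)
  # acquisition start: error +1
  expect_identical(
    prediction_error(predict_strengths(new_state("rw"), "A", rw_params),
                     "X")[["err_X"]], 1)
  # Pearce: elements A and B at 1, novel AB generalises 1/2 from each,
  # V_AB = 0, so the compound-extinction error is -1, same as single-cue
  stp <- seed_state("pearce", c(A = 1, B = 1),
                    members = list(A = "A", B = "B"))
  sp <- predict_strengths(stp, list(id = "A.B", members = c("A", "B"),
                                    size = 2), pearce_params)
  expect_equal(sp[["V_X"]], 1)
  expect_equal(prediction_error(sp, "Z")[["err_X"]], -1)
})

test_that("the update rule applies alpha, beta and the error term exactly", {
  # DV_A = alpha_cue * beta_nous * (0 - 1) = 0.5 * 0.4 * (-1) = -0.2
  st <- seed_state("rw", c(A = 1, a = 0))
  st2 <- update_state(st, c("a", "A"), "Z", rw_params)
  expect_equal(st2$V["A", "X"], 1 - 0.2)
  expect_equal(st2$V["a", "X"], -0.1 * 0.4)  # alpha_ctx path
  # zero error changes nothing
  st0 <- new_state("rw")
  expect_equal(update_state(st0, "A", "Z", rw_params)$V["A", "X"], 0)
  # Pearce compound extinction touches only the current configuration
  stp <- seed_state("pearce", c(A = 1, B = 1),
                    members = list(A = "A", B = "B"))
  stp2 <- update_state(stp, list(id = "A.B", members = c("A", "B"), size = 2),
                       "Z", pearce_params)
  expect_equal(stp2$V["A", "X"], 1)
  expect_equal(stp2$V["B", "X"], 1)
  expect_equal(stp2$V["A.B", "X"], 0.3 * 0.4 * (-1))
})

test_that("similarity follows the common-element formula", {
  expect_identical(similarity(c("a", "A"), c("a", "A"), d = 7), 1)
  expect_equal(similarity("A", c("A", "B"), d = 2), 0.5)
  expect_equal(similarity(c("a", "A"), c("b", "A", "B"), d = 1), 1 / sqrt(6))
  # symmetry, and encode_pearce objects accepted
  cfgA <- encode_pearce(list(context = "A:", cues = "A"))
  cfgAB <- encode_pearce(list(context = "B:", cues = "A+B"))
  expect_equal(similarity(cfgA, cfgAB, 3), similarity(cfgAB, cfgA, 3))
  expect_error(similarity(character(0), "A", 2), "empty")
  expect_error(similarity("A", "A", d = -1), "positive")
})

test_that("single-cue acquisition follows the geometric closed form", {
  # summed strength over the two present units obeys
  # V_t = 1 - (1 - (alpha_ctx + alpha_cue) * beta_us)^t
  d <- ref_single_cue_design(40)
  th <- c(alpha_ctx = 0.2, alpha_cue = 0.3, beta_us = 0.5, beta_nous = 0.3,
          g = 1)
  tr <- run_sequence("rw", th, d)
  v_pred <- 1 - 0.75^(d$trial - 1)  # prediction before each trial's update
  expect_equal(tr$V_X, v_pred, tolerance = 1e-12)
  expect_true(all(diff(tr$V_X) > 0))
  # and decays geometrically toward 0 once reinforcement stops
  dext <- ref_single_cue_design(60)
  dext$outcome[31:60] <- "Z"
  th2 <- th; th2["beta_nous"] <- 0.5  # extinction rate also 0.25
  trext <- run_sequence("rw", th2, dext)
  v30 <- 1 - 0.75^30
  expect_equal(trext$V_X[31:60], v30 * 0.75^(0:29), tolerance = 1e-12)
  expect_true(all(diff(trext$V_X[31:60]) < 0))
})

test_that("compiled trajectories agree with the plain-R reference", {
  set.seed(42)
  for (model in c("rw", "crw", "pearce")) {
    for (grp in c("control", "super")) {
      d <- build_design(grp, seed = sample.int(1000, 1))
      box <- param_box(model)
      th <- setNames(runif(ncol(box), box["lower", ], box["upper", ]),
                     colnames(box))
      resp <- sample(c("X", "Y", "Z"), 179, replace = TRUE)
      for (bm in c("dimension", "trial")) {
        ref <- ref_run(model, th, d, resp, beta_mode = bm)
        tr <- run_sequence(model, th, d, beta_mode = bm)
        expect_equal(tr$V_X, ref$V_X, tolerance = 1e-10)
        expect_equal(tr$p_X, ref$p_X, tolerance = 1e-10)
        expect_equal(negative_log_likelihood(model, th, d, resp,
                                             beta_mode = bm),
                     attr(ref, "L"), tolerance = 1e-10)
      }
    }
  }
})

test_that("configural RW collapses to elemental RW as alpha_cfg vanishes", {
  d <- build_design("super", seed = 17)
  th_rw <- c(alpha_ctx = 0.2, alpha_cue = 0.4, beta_us = 0.5,
             beta_nous = 0.35, g = 4)
  th_crw <- c(th_rw[1:2], alpha_cfg = 1e-4, th_rw[3:5])
  t1 <- run_sequence("rw", th_rw, d)
  t2 <- run_sequence("crw", th_crw, d)
  expect_lt(max(abs(t1$p_X - t2$p_X)), 10 * 1e-4)
  expect_lt(max(abs(t1$V_X - t2$V_X)), 10 * 1e-4)
})

test_that("maximal discrimination (d = 20) isolates configurations", {
  expect_lt(similarity(c("a", "A"), c("b", "A", "B"), d = 20), 1e-7)
  # a trained configuration's prediction approaches its own strength
  d <- build_design("control", seed = 4)
  th <- c(alpha_pat = 0.5, beta_us = 0.7, beta_nous = 0.5, d = 20, g = 2)
  tr <- run_sequence("pearce", th, d)
  ref <- ref_run("pearce", th, d)
  # recompute the last A-trial prediction from the isolated geometric path
  acqA <- which(d$phase == "acquisition" & d$cues == "A")
  own <- 0
  for (i in acqA) {
    lam <- as.numeric(d$outcome[i] == "X")
    b <- if (lam == 1) th[["beta_us"]] else th[["beta_nous"]]
    if (i == acqA[length(acqA)]) expect_equal(tr$V_X[i], own, tolerance = 1e-6)
    own <- own + th[["alpha_pat"]] * b * (lam - own)
  }
  expect_equal(tr$V_X, ref$V_X, tolerance = 1e-10)
})

test_that("asymptotic test strengths hit the analytic fixed points", {
  # closed forms derived by solving the linear fixed-point equations
  expect_equal(asymptotic_test_strength("rw", "control"), 0, tolerance = 1e-6)
  expect_equal(asymptotic_test_strength("rw", "super"), 0, tolerance = 1e-6)
  expect_equal(asymptotic_test_strength("rw", "deepened"), -1 / 2,
               tolerance = 1e-6)
  expect_equal(asymptotic_test_strength("crw", "super"), 1 / 3,
               tolerance = 1e-6)
  expect_equal(asymptotic_test_strength("crw", "deepened"), -1 / 3,
               tolerance = 1e-6)
  expect_equal(asymptotic_test_strength("pearce", "super", d = 2), 1 / 2,
               tolerance = 1e-6)
  expect_equal(asymptotic_test_strength("pearce", "deepened", d = 2), -1 / 4,
               tolerance = 1e-6)
  # only the configural models leave recoverable strength after
  # super-extinction
  for (m in c("crw", "pearce")) {
    s <- asymptotic_test_strength(m, "super")
    c0 <- asymptotic_test_strength(m, "control")
    de <- asymptotic_test_strength(m, "deepened")
    expect_true(s > c0 && c0 > de)
  }
  expect_equal(asymptotic_test_strength("rw", "super"),
               asymptotic_test_strength("rw", "control"), tolerance = 1e-6)
})
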