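test_that("every group gets the full five-phase 179-trial design", {
  for (g in c("control", "deepened", "super")) {
    d <- build_design(g, seed = 3)
    expect_equal(nrow(d), 179)
    counts <- table(d$phase)
    expect_equal(unname(counts[c("acquisition", "extinction1", "extinction2",
                                 "summation", "recovery")]),
                 c(144L, 16L, 16L, 2L, 1L), ignore_attr = TRUE)
    # context is tied to phase
    expect_true(all(d$context[d$phase == "acquisition"] == "A:"))
    expect_true(all(d$context[d$phase %in% c("extinction1", "extinction2",
                                             "summation")] == "B:"))
    expect_true(all(d$context[d$phase == "recovery"] == "C:"))
  }
})

test_that("acquisition blocks follow the partial/continuous schedules", {
  d <- build_design("control", seed = 9)
  acq <- d[d$phase == "acquisition", ]
  for (b in 1:4) {
    blk <- acq[acq$block == b, ]
    expect_equal(nrow(blk), 36)
    tab <- table(blk$cues, blk$outcome)
    expect_equal(tab["A", "X"], 3); expect_equal(tab["A", "Z"], 1)
    expect_equal(tab["B", "X"], 3); expect_equal(tab["B", "Z"], 1)
    expect_equal(tab["C", "Y"], 4)
    expect_equal(tab["D", "Z"], 4)
    expect_equal(tab["E", "Z"], 4)
    expect_equal(tab["G", "X"], 4)
    expect_equal(tab["K", "Y"], 3); expect_equal(tab["K", "Z"], 1)
    expect_equal(tab["L", "Y"], 3); expect_equal(tab["L", "Z"], 1)
    expect_equal(tab["K+L", "Y"], 4)
  }
  # whole-phase totals: the x12 / x4 / x16 schedule
  tot <- table(acq$cues, acq$outcome)
  expect_equal(tot["A", "X"], 12); expect_equal(tot["A", "Z"], 4)
  expect_equal(tot["C", "Y"], 16)
  expect_equal(tot["K+L", "Y"], 16)
})

test_that("extinction phases carry the group-specific compound treatments", {
  types <- function(g, ph) {
    d <- build_design(g, seed = 5)
    sub <- d[d$phase == ph, ]
    expect_equal(nrow(sub), 16)
    # 8 two-trial blocks, each with one trial of each type
    for (b in 1:8) {
      blk <- sub[sub$block == b, ]
      expect_equal(nrow(blk), 2)
      expect_setequal(paste(blk$cues, blk$outcome), unique(paste(sub$cues, sub$outcome)))
    }
    sort(unique(paste0(sub$cues, "->", sub$outcome)))
  }
  expect_equal(types("control", "extinction1"), c("A->Z", "C->Y"))
  expect_equal(types("control", "extinction2"), c("A->Z", "C->Y"))
  expect_equal(types("deepened", "extinction1"), c("A->Z", "C->Y"))
  expect_equal(types("deepened", "extinction2"), c("A+B->Z", "C->Y"))
  expect_equal(types("super", "extinction1"), c("A+B->Z", "C->Y"))
  expect_equal(types("super", "extinction2"), c("A+B->Z", "C->Y"))
})

test_that("randomisation is within block only, and seed-reproducible", {
  d1 <- build_design("super", seed = 21)
  d2 <- build_design("super", seed = 21)
  d3 <- build_design("super", seed = 22)
  expect_identical(d1, d2)
  expect_false(identical(d1$cues, d3$cues))
  # the multiset of trial types within each block is seed-invariant
  key <- function(d) {
    lapply(split(paste(d$cues, d$outcome), list(d$phase, d$block), drop = TRUE),
           sort)
  }
  expect_identical(key(d1), key(d3))
})

test_that("invalid group or seed is rejected", {
  expect_error(build_design("bogus", seed = 1))
  expect_error(build_design("super", seed = 1.5), "integer")
})

test_that("stimulus encodings match their definitions", {
  tr1 <- list(context = "A:", cues = "A")
  tr2 <- list(context = "B:", cues = "A+B")
  tr3 <- list(context = "A:", cues = "K+L")

  expect_setequal(encode_elemental(tr1), c("a", "A"))
  expect_setequal(encode_elemental(tr2), c("b", "A", "B"))
  expect_setequal(encode_elemental(tr3), c("a", "K", "L"))

  # single-cue trial: 3 units; two-cue trial: 6 units (n + n(n-1)/2)
  e1 <- encode_configural_rw(tr1)
  e2 <- encode_configural_rw(tr2)
  expect_length(e1, 3)
  expect_length(e2, 6)
  expect_true("A.a" %in% e1)
  expect_setequal(setdiff(e2, encode_elemental(tr2)), c("A.b", "B.b", "A.B"))
  for (n_cues in 1:2) {
    n <- n_cues + 1
    tr <- list(context = "B:", cues = paste(LETTERS[seq_len(n_cues)],
                                            collapse = "+"))
    expect_length(encode_configural_rw(tr), n + n * (n - 1) / 2)
  }

  p1 <- encode_pearce(tr1)
  expect_equal(p1$size, 2)
  expect_setequal(p1$members, c("a", "A"))
  p2 <- encode_pearce(tr2)
  expect_equal(p2$size, 3)
  # identical patterns map to the same configuration id
  expect_identical(encode_pearce(list(context = "B:", cues = "A+B"))$id, p2$id)
  # conjunction-unit identity is stable across trials
  expect_identical(encode_configural_rw(tr2), encode_configural_rw(tr2))
})

test_that("designs serialise to the trial CSV dialect", {
  d <- build_design("deepened", seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_design_csv(d, f, participant_id = "p007")
  df <- read.csv(f)
  expect_equal(nrow(df), 179)
  expect_named(df, c("participant_id", "group", "phase", "block",
                     "trial_index", "context", "cues", "outcome"))
  expect_equal(df$cues[df$phase == "extinction2"][1:2] != "",
               c(TRUE, TRUE))
  expect_true(any(df$cues == "A+B"))
})
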