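test_that("the switch-duration grid has the published structure", {
  g <- makeConditionGrid(1, nReps = 10, baseSeed = 1)
  sw <- Filter(function(s) s@conditionLabel == "exp1", g)
  expect_length(sw, 180L)
  pairs <- unique(vapply(sw, function(s)
    paste(s@preswitch, s@switchAngle), ""))
  expect_length(pairs, 18L)
  ## postswitch arithmetic, e.g. -6 preswitch with +12 switch -> +6
  one <- Filter(function(s) s@preswitch == -6 && s@switchAngle == 12, sw)
  expect_true(all(vapply(one, function(s) s@postswitch == 6, TRUE)))
  expect_true(all(vapply(sw, function(s)
    s@nFrames == 34L && s@switchFrame == 30L, TRUE)))
  ## every switch trial has a matched no-switch trial with the same
  ## postswitch heading, repetition and seed
  no <- Filter(function(s) s@conditionLabel == "noswitch", g)
  noKey <- vapply(no, function(s)
    paste(s@postswitch, s@repetition, s@seed), "")
  swKey <- vapply(sw, function(s)
    paste(s@postswitch, s@repetition, s@seed), "")
  expect_true(all(swKey %in% noKey))
  ## 11 unique postswitch headings
  expect_length(unique(vapply(no, function(s) s@postswitch, 0)), 11L)
})

test_that("the blackout grid follows the one-step blackout schedules", {
  g <- makeConditionGrid(2, nReps = 2, baseSeed = 5)
  sw <- Filter(function(s) s@conditionLabel != "noswitch", g)
  expect_length(sw, 18L * 4L * 2L)
  byLab <- split(sw, vapply(sw, function(s) s@conditionLabel, ""))
  ## preblackout: one frame of flow separates blackout and switch
  for (s in byLab$preblackout) {
    expect_identical(s@blackoutFrames, 28L)
    expect_identical(s@switchFrame - max(s@blackoutFrames), 2L)
    expect_identical(s@nFrames, 32L)
  }
  ## postblackout: exactly one frame of postswitch flow precedes the
  ## blackout, which runs to the end of the trial
  for (s in byLab$postblackout) {
    postFlow <- setdiff(s@switchFrame:s@nFrames, s@blackoutFrames)
    expect_identical(postFlow, 30L)
    expect_identical(max(s@blackoutFrames), s@nFrames)
  }
  ## midblackout: blank inserted between preswitch and postswitch flow,
  ## extending the trial by one frame; three postswitch flow frames
  for (s in byLab$midblackout) {
    expect_identical(s@nFrames, 33L)
    expect_identical(s@blackoutFrames, s@switchFrame - 1L)
    expect_length(setdiff(s@switchFrame:s@nFrames, s@blackoutFrames), 3L)
  }
  for (s in byLab$noblackout) {
    expect_length(s@blackoutFrames, 0L)
    expect_length(setdiff(s@switchFrame:s@nFrames, s@blackoutFrames), 3L)
  }
  expect_error(makeConditionGrid(3, 1, 1), "unknown experiment")
})

test_that("a two-condition micro-grid reproduces bit-identical artifacts", {
  cfg <- SceneConfig()
  mdl <- defaultModel()
  runMicro <- function(dir) {
    dir.create(dir, showWarnings = FALSE)
    rows <- list()
    for (sw in c(-12, 12)) {
      sp <- TrialSpec(0, sw, seed = 71L + sw)
      smp <- renderSequence(sp, cfg)
      writeFlowSample(smp, file.path(dir, paste0("s", sw, ".hcd")))
      rows[[length(rows) + 1L]] <- runTrial(mdl, smp, c(32L, 34L))
    }
    csv <- file.path(dir, "results.csv")
    write.csv(do.call(rbind, rows), csv, row.names = FALSE)
    dir
  }
  d1 <- runMicro(tempfile("micro1"))
  d2 <- runMicro(tempfile("micro2"))
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), raw(), 1e7),
                     readBin(file.path(d2, f), raw(), 1e7))
  }
})

test_that("experiment plans carry protocol defaults", {
  p1 <- experimentPlan(1)
  expect_identical(p1@readoutFrames, c(32L, 34L))
  p2 <- experimentPlan(2, nReps = 5, baseSeed = 9)
  expect_identical(p2@readoutFrames, 32L)
  expect_error(experimentPlan(3), "experiment")
})
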