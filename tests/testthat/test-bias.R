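test_that("heading error is the signed judged-minus-true difference", {
  expect_equal(headingError(4, 6), -2)
  expect_equal(headingError(7.5, 7.5), 0)
  expect_equal(headingError(-3, 6), -9)
  expect_equal(headingError(c(1, 2), c(3, -1)), c(-2, 3))
})

test_that("heading bias subtracts matched no-switch error and applies the sign convention", {
  no <- data.frame(postswitch = c(6, 6), switchAngle = 0,
                   error = c(-1, -1))
  sw <- data.frame(postswitch = 6, switchAngle = 12, error = -3)
  b <- headingBias(sw, no)
  expect_equal(b$rawBias, -2)
  expect_equal(b$bias, 2)          # attraction is positive
  ## equal errors cancel
  sw0 <- data.frame(postswitch = 6, switchAngle = 12, error = -1)
  expect_equal(headingBias(sw0, no)$bias, 0)
  ## no-switch mean over {-1, -3} is -2
  no2 <- data.frame(postswitch = 3, switchAngle = 0, error = c(-1, -3))
  sw2 <- data.frame(postswitch = 3, switchAngle = -6, error = -2)
  expect_equal(headingBias(sw2, no2)$bias, 0)
  ## unmatched postswitch heading
  swx <- data.frame(postswitch = 9, switchAngle = 3, error = 0)
  expect_error(headingBias(swx, no), "unmatched")
})

test_that("feeding no-switch results against themselves yields zero mean bias", {
  set.seed(51)
  no <- data.frame(postswitch = rep(c(-6, 0, 6), each = 8),
                   switchAngle = 0,
                   error = rnorm(24))
  b <- headingBias(no, no)
  means <- tapply(b$bias, b$postswitch, mean)
  expect_true(all(abs(means) < 1e-12))
})

test_that("judgments displaced toward the preswitch heading always give positive bias", {
  set.seed(53)
  for (i in 1:50) {
    pre <- sample(c(-6, 0, 6), 1)
    sw <- sample(c(-12, -6, -3, 3, 6, 12), 1)
    post <- pre + sw
    disp <- runif(1, 0.1, 3)            # displacement toward preswitch
    judged <- post - sign(sw) * disp
    no <- data.frame(postswitch = post, switchAngle = 0,
                     error = c(0, 0))
    swd <- data.frame(postswitch = post, switchAngle = sw,
                      error = judged - post)
    expect_equal(headingBias(swd, no)$bias, disp)
  }
})

test_that("precision is the sd across repetitions, shift invariant, and needs 2+ reps", {
  d <- data.frame(cond = rep(c("a", "b", "c"), c(2, 5, 3)),
                  judged = c(5, 7, 1, 2, 3, 4, 5, 2.2, 2.2, 2.2))
  p <- precisionTable(d, by = "cond")
  expect_equal(p$sdJudged[p$cond == "a"], sqrt(2), tolerance = 1e-12)
  expect_equal(p$sdJudged[p$cond == "b"], 1.5811388, tolerance = 1e-6)
  expect_equal(p$sdJudged[p$cond == "c"], 0)
  shifted <- d; shifted$judged <- shifted$judged + 17
  expect_equal(precisionTable(shifted, by = "cond")$sdJudged, p$sdJudged)
  expect_error(precisionTable(rbind(d, data.frame(cond = "d", judged = 1)),
                              by = "cond"), "insufficient")
})

test_that("collapsing across sign averages symmetric entries and rejects gaps", {
  tab <- data.frame(switchAngle = c(-12, 12, -6, 6),
                    meanBias = c(2, 3, 1, 1))
  col <- collapseBySign(tab)
  expect_equal(col$meanBias[col$absSwitchAngle == 12], 2.5)
  expect_equal(col$meanBias[col$absSwitchAngle == 6], 1)
  bad <- tab[tab$switchAngle != 6, ]
  expect_error(collapseBySign(bad), "asymmetric")
})

test_that("bias summaries report group means, CIs and counts", {
  df <- data.frame(switchAngle = rep(c(-3, 3), each = 4),
                   bias = c(1, 2, 3, 2, 0.5, 1.5, 1, 1))
  s <- summarizeBias(df)
  expect_equal(s$meanBias, c(2, 1))
  expect_equal(s$n, c(4L, 4L))
  expect_equal(s$ciHalfwidth[1], qnorm(0.975) * sd(c(1, 2, 3, 2)) / 2,
               tolerance = 1e-12)
})
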