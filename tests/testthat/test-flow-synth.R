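test_that("dot clouds are reproducible, sized and bounded as configured", {
  cfg <- SceneConfig(nDots = 10000L)
  c1 <- makeDotCloud(cfg, seed = 1)
  c2 <- makeDotCloud(cfg, seed = 1)
  expect_identical(c1@positions, c2@positions)
  expect_equal(nrow(c1@positions), 10000L)
  expect_true(all(c1@positions[, 3] >= 1.5 & c1@positions[, 3] <= 9))
  c3 <- makeDotCloud(cfg, seed = 2)
  expect_false(identical(c1@positions, c3@positions))
})

test_that("invalid scene configurations are rejected", {
  expect_error(SceneConfig(nDots = 0), "nDots")
  expect_error(SceneConfig(depthRange = c(9, 1.5)), "depthRange")
  expect_error(SceneConfig(resolution = -1), "resolution")
})

test_that("single-dot flow follows translational geometry", {
  cfg <- SceneConfig(nDots = 1L, frameRate = 30)
  ## dot on the optical axis, straight-ahead heading: zero flow everywhere
  axis <- new("DotCloud", positions = cbind(0, 0, 4), seed = 1L)
  fr <- flowFrame(axis, heading = 0, config = cfg)
  expect_equal(max(abs(fr$flow)), 0)
  ## same image position, depths 3 m and 6 m: flow magnitudes 2:1
  p1 <- c(0.8, 0.5, 3)
  near <- new("DotCloud", positions = rbind(p1), seed = 1L)
  far <- new("DotCloud", positions = rbind(2 * p1), seed = 1L)
  m1 <- max(abs(flowFrame(near, 0, cfg)$flow))
  m2 <- max(abs(flowFrame(far, 0, cfg)$flow))
  expect_equal(m1 / m2, 2, tolerance = 1e-12)
})

test_that("deposited flow matches a finite-difference projection oracle", {
  cfg <- SceneConfig(nDots = 1L, frameRate = 30)
  proj <- function(p) c(atan2(p[1], p[3]), atan2(p[2], p[3])) * 180 / pi
  for (case in list(list(h = 0, p = c(1.2, -0.7, 5)),
                    list(h = -6, p = c(-2.0, 1.1, 3.5)),
                    list(h = 12, p = c(0.3, 0.4, 7)))) {
    cl <- new("DotCloud", positions = rbind(case$p), seed = 1L)
    fr <- flowFrame(cl, case$h, cfg)$flow
    got <- c(fr[, , 1][fr[, , 1] != 0], fr[, , 2][fr[, , 2] != 0])
    ## displace the dot along -T for a small fraction of a frame
    hr <- case$h * pi / 180
    Tv <- cfg@speed * c(sin(hr), 0, cos(hr))
    eps <- 1e-4
    p2 <- case$p - Tv * eps / cfg@frameRate
    want <- (proj(p2) - proj(case$p)) / eps
    expect_equal(got, want, tolerance = 1e-4)
  }
})

test_that("scaling the scene scales the flow inversely (depth law)", {
  cfg <- SceneConfig(nDots = 500L)
  cl <- makeDotCloud(SceneConfig(nDots = 500L, depthRange = c(2, 4),
                                 lateralExtent = 1.5), seed = 3)
  f1 <- flowFrame(cl, 0, cfg)$flow
  cl2 <- new("DotCloud", positions = cl@positions * 2, seed = 3L)
  f2 <- flowFrame(cl2, 0, cfg)$flow
  expect_equal(f2, f1 / 2, tolerance = 1e-12)
})

test_that("rendered sequences switch heading and honor blackout masks", {
  cfg <- smallConfig()
  sp <- TrialSpec(preswitch = -6, switchAngle = 12, nFrames = 34L,
                  switchFrame = 30L, seed = 5)
  smp <- renderSequence(sp, cfg)
  expect_equal(dim(flowArray(smp)), c(32L, 32L, 2L, 34L))
  ## FoE azimuth before and after the switch
  expect_lt(abs(estimateFoe(smp, 10, cfg)["azimuth"] + 6), 1)
  expect_lt(abs(estimateFoe(smp, 32, cfg)["azimuth"] - 6), 1)
  ## no-switch: one heading throughout
  ns <- renderSequence(TrialSpec(6, 0, conditionLabel = "noswitch",
                                 seed = 5), cfg)
  for (t in c(1, 15, 34))
    expect_lt(abs(estimateFoe(ns, t, cfg)["azimuth"] - 6), 1)
  ## blackout frames are zeroed and masked, others untouched
  bs <- TrialSpec(0, 12, nFrames = 32L, switchFrame = 30L,
                  blackoutFrames = c(31L, 32L),
                  conditionLabel = "postblackout", seed = 5)
  bsmp <- renderSequence(bs, cfg)
  expect_identical(validMask(bsmp), c(rep(TRUE, 30), FALSE, FALSE))
  expect_equal(max(abs(flowArray(bsmp)[, , , 31:32])), 0)
  expect_gt(max(abs(flowArray(bsmp)[, , , 30])), 0)
})

test_that("rendering is a pure function of spec and config", {
  cfg <- smallConfig()
  sp <- TrialSpec(0, -6, seed = 11)
  a <- renderSequence(sp, cfg)
  b <- renderSequence(sp, cfg)
  expect_identical(flowArray(a), flowArray(b))
})

test_that("flow fields are radial about the focus of expansion", {
  cfg <- SceneConfig(nDots = 4000L)
  sp <- TrialSpec(6, 0, conditionLabel = "noswitch", seed = 9)
  fr <- flowArray(renderSequence(sp, cfg))[, , , 8]
  n <- dim(fr)[1]
  ctr <- (n + 1) / 2
  foeCol <- 6 / degPerPixel(cfg) + ctr
  U <- fr[, , 1]; V <- fr[, , 2]
  nz <- which(U != 0 | V != 0)
  rw <- ((nz - 1) %% n) + 1
  cl <- ((nz - 1) %/% n) + 1
  dx <- cl - foeCol
  dy <- ctr - rw
  d <- sqrt(dx^2 + dy^2)
  keep <- d > 5            # rasterization dominates very near the FoE
  mag <- sqrt(U[nz]^2 + V[nz]^2)
  cosang <- (U[nz] * dx + V[nz] * dy) / (mag * d)
  expect_true(all(cosang[keep] > cos(10 * pi / 180)))
})

test_that("least-squares FoE recovery returns the commanded heading", {
  cfg <- SceneConfig()
  for (h in c(-12, -6, 0, 3, 6)) {
    smp <- renderSequence(TrialSpec(h, 0, conditionLabel = "noswitch",
                                    seed = 13 + h), cfg)
    foe <- estimateFoe(smp, 15, cfg)
    expect_lt(abs(foe["azimuth"] - h), 0.8)
    expect_lt(abs(foe["elevation"]), 0.8)
  }
})

test_that("degenerate frames and out-of-view headings are rejected", {
  cfg <- SceneConfig(nDots = 1L)
  behind <- new("DotCloud", positions = cbind(0, 0, -3), seed = 1L)
  expect_error(flowFrame(behind, 0, cfg), "degenerate")
  cl <- makeDotCloud(cfg, 1)
  expect_error(flowFrame(cl, 60, cfg), "fov")
})
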