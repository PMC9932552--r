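test_that("MT pooling matches a brute-force convolution on 16x16 crops", {
  prm <- ModelParams(rMT = 3, sigmaMT = 2)
  k <- mtKernel(prm)
  expect_equal(sum(k), 1)
  set.seed(42)
  fr <- array(0, c(16, 16, 2))
  idx <- sample(16 * 16, 30)
  fr[, , 1][idx] <- rnorm(30)
  fr[, , 2][idx] <- rnorm(30)
  got <- mtPool(fr, prm)
  r <- (nrow(k) - 1) / 2
  brute <- array(0, c(16, 16, 2))
  for (comp in 1:2) for (i in 1:16) for (j in 1:16) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- i - di; jj <- j - dj
      if (ii >= 1 && ii <= 16 && jj >= 1 && jj <= 16)
        acc <- acc + k[di + r + 1, dj + r + 1] * fr[ii, jj, comp]
    }
    brute[i, j, comp] <- acc
  }
  expect_lt(max(abs(got - brute)), 1e-9)
})

test_that("MT pooling preserves constants and spreads impulses", {
  prm <- ModelParams(rMT = 3, sigmaMT = 2)
  uni <- array(1, c(16, 16, 2))
  p <- mtPool(uni, prm)
  expect_equal(p[5:12, 5:12, ], uni[5:12, 5:12, ])   # interior
  imp <- array(0, c(16, 16, 2))
  imp[8, 8, 1] <- 1
  pi1 <- mtPool(imp, prm)[, , 1]
  expect_equal(which.max(pi1), 8L + 16L * 7L)
  expect_equal(pi1[8, 8], max(mtKernel(prm)))
  expect_equal(sum(pi1), 1)
})

test_that("the template bank has one inverse-distance radial template per column", {
  cfg <- smallConfig()
  bank <- buildTemplates(32L, cfg)
  expect_equal(nTemplates(bank), 32L)
  expect_equal(templateHeadings(bank),
               ((1:32) - 16.5) * degPerPixel(cfg))
  ## radial direction and inverse-distance weight law at sample pixels
  n <- 32L; ctr <- 16.5
  k <- 10L
  tm <- bank@templates[, k]
  U <- matrix(tm[1:(n * n)], n, n)
  V <- matrix(tm[n * n + 1:(n * n)], n, n)
  for (px in list(c(5, 25), c(16, 10), c(30, 11), c(17, 10))) {
    r <- px[1]; cc <- px[2]
    dx <- cc - k; dy <- ctr - r
    d <- sqrt(dx^2 + dy^2)
    vec <- c(U[r, cc], V[r, cc])
    expect_equal(vec * d / min(1, 1 / d), c(dx, dy), tolerance = 1e-12)
    expect_equal(sqrt(sum(vec^2)), min(1, 1 / d), tolerance = 1e-12)
  }
})

test_that("template matching rectifies contraction and zero frames to zero", {
  mdl <- smallModel()
  f <- analyticExpansion(smallConfig())
  expect_true(all(templateMatch(-f, mdl@bank) == 0))
  expect_true(all(templateMatch(array(0, dim(f)), mdl@pooledBank) == 0))
})

test_that("dense radial flow peaks at the template whose FoE it shares", {
  mdl <- defaultModel()
  f <- analyticExpansion(SceneConfig(), foeCol = 64)
  a <- templateMatch(f, mdl@pooledBank)
  expect_true(abs(which.max(a) - 64L) <= 1L)
  ## off-center FoE as well (within the broad-tuning quantization)
  f2 <- analyticExpansion(SceneConfig(), foeCol = 40)
  expect_lt(which.max(templateMatch(f2, mdl@pooledBank)), 64L)
})

test_that("matching pooled flow against raw templates equals raw flow against pooled templates", {
  mdl <- smallModel()
  set.seed(7)
  f <- array(rnorm(32 * 32 * 2, sd = 0.01), c(32, 32, 2))
  a1 <- templateMatch(mtPool(f, mdl@params), mdl@bank)
  a2 <- templateMatch(f, mdl@pooledBank)
  expect_equal(a1, a2, tolerance = 1e-10)
})

test_that("across-heading smoothing matches its brute-force oracle", {
  prm <- ModelParams(rMST = 4, sigmaMST = 2)
  set.seed(3)
  v <- runif(20)
  got <- smoothActivations(v, prm)
  kern <- exp(-(-4:4)^2 / (2 * 4))
  brute <- numeric(20)
  for (i in 1:20) {
    j <- i + (-4:4)
    ok <- j >= 1 & j <= 20
    brute[i] <- sum(kern[ok] * v[j[ok]]) / sum(kern[ok])
  }
  expect_equal(got, brute, tolerance = 1e-12)
  ## uniform preserved everywhere (renormalized edges), impulse spreads
  expect_equal(smoothActivations(rep(2, 20), prm), rep(2, 20))
  imp <- c(rep(0, 9), 1, rep(0, 10))
  sm <- smoothActivations(imp, prm)
  expect_equal(which.max(sm), 10L)
  expect_true(all(diff(sm[6:10]) > 0) && all(diff(sm[10:14]) < 0))
})
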