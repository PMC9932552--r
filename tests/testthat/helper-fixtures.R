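## Shared fixtures. Unit tests use a 32 px raster with proportionally
## scaled filter sizes so each test runs in milliseconds; the full-scale
## 128 px model and the complete experiment grids are built lazily and
## cached for the session (they back the acceptance checks).

.fx <- new.env(parent = emptyenv())

smallConfig <- function(nDots = 1500L)
  SceneConfig(nDots = nDots, resolution = 32L)

smallParams <- function(...)
  ModelParams(rMT = 2, sigmaMT = 2.4, rMST = 5, sigmaMST = 2.5, ...)

smallModel <- function() {
  if (is.null(.fx$smallModel))
    .fx$smallModel <- CDModel(smallParams(), smallConfig())
  .fx$smallModel
}

defaultModel <- function() {
  if (is.null(.fx$defaultModel))
    .fx$defaultModel <- CDModel(ModelParams(), SceneConfig())
  .fx$defaultModel
}

## analytic full-field radial expansion with the FoE at template column
## `foeCol` on the midline; magnitude grows as sin(eccentricity)
analyticExpansion <- function(config, foeCol = NULL) {
  n <- config@resolution
  ctr <- (n + 1) / 2
  if (is.null(foeCol)) foeCol <- ctr
  dpp <- degPerPixel(config)
  rw <- matrix(seq_len(n), n, n)
  cl <- matrix(seq_len(n), n, n, byrow = TRUE)
  dx <- cl - foeCol
  dy <- ctr - rw
  d <- sqrt(dx^2 + dy^2)
  d[d == 0] <- 1
  ecc <- d * dpp * pi / 180
  m <- 0.01 * sin(pmin(ecc, pi / 2))
  out <- array(0, c(n, n, 2))
  out[, , 1] <- m * dx / d
  out[, , 2] <- m * dy / d
  out
}

exp1Run <- function() {
  if (is.null(.fx$exp1)) {
    plan <- experimentPlan(1, nReps = 10L, baseSeed = 101L)
    .fx$exp1 <- runExperiment(plan)
  }
  .fx$exp1
}

exp2Run <- function() {
  if (is.null(.fx$exp2)) {
    plan <- experimentPlan(2, nReps = 10L, baseSeed = 202L)
    .fx$exp2 <- runExperiment(plan)
  }
  .fx$exp2
}
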