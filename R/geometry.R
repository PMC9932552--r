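## Image geometry. One linear angle<->pixel mapping is used everywhere
## (rasterization, template FoE placement, decoding): a point at azimuth a
## and elevation e (degrees) maps to the continuous 1-based pixel
## coordinates col = a/degPerPx + center, row = center - e/degPerPx, with
## center = (resolution + 1) / 2. Azimuth/elevation are the independent
## angles atan2(X, Z) and atan2(Y, Z) (equidistant mapping, not gnomonic),
## which keeps stimulus, templates and decoder mutually consistent across
## the full 90 degree field.

.pixelCenter <- function(resolution) (resolution + 1) / 2

## temporarily seed the RNG, restoring any prior state afterwards
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## angular position of dots, degrees
.dotAngles <- function(p) {
  list(az = atan2(p[, 1], p[, 3]) * 180 / pi,
       el = atan2(p[, 2], p[, 3]) * 180 / pi)
}

## instantaneous angular velocity (deg/frame) of dots under pure
## translation along `heading` (azimuth, degrees, horizontal plane)
.dotFlow <- function(p, heading, config) {
  h <- heading * pi / 180
  Tx <- config@speed * sin(h)
  Tz <- config@speed * cos(h)
  X <- p[, 1]; Y <- p[, 2]; Z <- p[, 3]
  dadt <- (-Tx * Z + X * Tz) / (X^2 + Z^2)
  dedt <- (Y * Tz) / (Y^2 + Z^2)
  scale <- 180 / pi / config@frameRate
  cbind(u = dadt * scale, v = dedt * scale)
}

## canonical noise-free full-field expansion frame used for drive
## normalization: FoE at the image center, radial direction, magnitude
## (speed/frameRate) / geometric-mean depth * sin(eccentricity)
canonicalExpansionFrame <- function(config) {
  n <- config@resolution
  ctr <- .pixelCenter(n)
  dpp <- degPerPixel(config)
  rw <- matrix(seq_len(n), n, n)
  cl <- matrix(seq_len(n), n, n, byrow = TRUE)
  dx <- cl - ctr
  dy <- ctr - rw
  d <- sqrt(dx^2 + dy^2)
  d[d == 0] <- 1
  ecc <- sqrt((dx * dpp)^2 + (dy * dpp)^2) * pi / 180
  zbar <- sqrt(prod(config@depthRange))
  m <- (config@speed / config@frameRate) / zbar * sin(ecc) * 180 / pi
  out <- array(0, c(n, n, 2))
  out[, , 1] <- m * dx / d
  out[, , 2] <- m * dy / d
  out
}
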