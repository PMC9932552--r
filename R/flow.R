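#' Create a random dot cloud
#'
#' Places `nDots` dots uniformly in the box
#' `[-L, L] x [-L, L] x [near, far]` (L = `lateralExtent`). The same
#' `(config, seed)` always produces the identical cloud; the ambient RNG
#' state is left untouched.
#'
#' @param config a [SceneConfig-class].
#' @param seed integer seed.
#' @return A [DotCloud-class].
#' @examples
#' cl <- makeDotCloud(SceneConfig(nDots = 100), seed = 1)
#' range(cl@positions[, 3])
#' @export
makeDotCloud <- function(config, seed) {
  stopifnot(is(config, "SceneConfig"))
  validObject(config)
  n <- config@nDots
  L <- config@lateralExtent
  dr <- config@depthRange
  pos <- withSeed(seed, {
    cbind(X = runif(n, -L, L), Y = runif(n, -L, L),
          Z = runif(n, dr[1], dr[2]))
  })
  new("DotCloud", positions = pos, seed = as.integer(seed))
}

## respawn out-of-volume dots uniformly in the far half of the depth range
## with fresh lateral positions (keeps density stationary over a trial);
## consumes the ambient RNG stream
.recycleDots <- function(pos, config) {
  L <- config@lateralExtent
  dr <- config@depthRange
  out <- pos[, 3] < dr[1] | pos[, 3] > dr[2] |
    abs(pos[, 1]) > L | abs(pos[, 2]) > L
  n <- sum(out)
  if (n > 0L) {
    pos[out, 1] <- runif(n, -L, L)
    pos[out, 2] <- runif(n, -L, L)
    pos[out, 3] <- runif(n, mean(dr), dr[2])
  }
  pos
}

#' Compute one dense optic-flow frame and advect the cloud
#'
#' Each dot visible in the field of view deposits its instantaneous angular
#' velocity (degrees of visual angle per frame) at its nearest pixel; dots
#' sharing a pixel are averaged, and dot-free pixels are zero (downstream
#' MT pooling densifies the field). The returned cloud is the input cloud
#' advected one frame along `heading` (pure translation) with
#' out-of-volume dots recycled; recycling draws from the ambient RNG
#' stream, which [renderSequence()] seeds per trial.
#'
#' @param cloud a [DotCloud-class].
#' @param heading azimuth, degrees; must lie within the half field of view.
#' @param config a [SceneConfig-class].
#' @return `list(flow = H x W x 2 array, cloud = advected DotCloud)`.
#' @export
flowFrame <- function(cloud, heading, config) {
  stopifnot(is(cloud, "DotCloud"), is(config, "SceneConfig"))
  if (abs(heading) > config@fov / 2)
    stop("heading must lie within +/- fov/2")
  p <- cloud@positions
  n <- config@resolution
  ctr <- .pixelCenter(n)
  dpp <- degPerPixel(config)
  ang <- .dotAngles(p)
  uv <- .dotFlow(p, heading, config)
  col <- round(ang$az / dpp + ctr)
  row <- round(ctr - ang$el / dpp)
  half <- config@fov / 2
  vis <- p[, 3] > 0 & abs(ang$az) < half & abs(ang$el) < half &
    col >= 1L & col <= n & row >= 1L & row <= n
  if (!any(vis))
    stop("degenerate frame: no dot is visible (scene too sparse)")
  idx <- (col[vis] - 1L) * n + row[vis]
  acc <- rowsum(cbind(uv[vis, 1L], uv[vis, 2L], 1), idx)
  ii <- as.integer(rownames(acc))
  flow <- array(0, c(n, n, 2L))
  flow[ii] <- acc[, 1L] / acc[, 3L]
  flow[ii + n * n] <- acc[, 2L] / acc[, 3L]
  ## advect: scene points move opposite to observer translation
  h <- heading * pi / 180
  step <- config@speed / config@frameRate
  p[, 1] <- p[, 1] - step * sin(h)
  p[, 3] <- p[, 3] - step * cos(h)
  p <- .recycleDots(p, config)
  list(flow = flow,
       cloud = new("DotCloud", positions = p, seed = cloud@seed))
}

#' Render the full optic-flow sequence for a trial
#'
#' Frames before `switchFrame` use the preswitch heading; frames at or
#' after it use the postswitch heading. Blacked-out frames contain all-zero
#' flow and are flagged invalid; the scene keeps moving underneath them.
#' The whole sequence (dot placement and recycling) is a pure function of
#' `(spec, config)`.
#'
#' @param spec a [TrialSpec-class].
#' @param config a [SceneConfig-class].
#' @return A [FlowSample-class].
#' @examples
#' sp <- TrialSpec(preswitch = -6, switchAngle = 12, seed = 7)
#' smp <- renderSequence(sp, SceneConfig(nDots = 2000, resolution = 64L))
#' dim(flowArray(smp))
#' @export
renderSequence <- function(spec, config = SceneConfig()) {
  stopifnot(is(spec, "TrialSpec"), is(config, "SceneConfig"))
  validObject(spec)
  n <- config@resolution
  nf <- spec@nFrames
  flow <- array(0, c(n, n, 2L, nf))
  mask <- rep(TRUE, nf)
  withSeed(spec@seed, {
    cloud <- makeDotCloud(config, spec@seed)
    for (t in seq_len(nf)) {
      hd <- if (t < spec@switchFrame) spec@preswitch else spec@postswitch
      fr <- flowFrame(cloud, hd, config)
      cloud <- fr$cloud
      if (t %in% spec@blackoutFrames) {
        mask[t] <- FALSE            # flow stays zero
      } else {
        flow[, , , t] <- fr$flow
      }
    }
  })
  new("FlowSample", flow = flow, validMask = mask, spec = spec)
}

#' Recover the focus of expansion of a flow frame by least squares
#'
#' Every flow vector of a pure radial field lies on a line through the
#' focus of expansion. The FoE is recovered as the least-squares
#' intersection of those lines (normal equations of
#' `v*(xf - px) - u*(yf - py) = 0` over all nonzero pixels, implicitly
#' magnitude-weighted) and mapped back to degrees.
#'
#' @param flow an `H x W x 2` array (one frame), or a [FlowSample-class]
#'   together with `frame`.
#' @param frame frame index when `flow` is a `FlowSample`.
#' @param config a [SceneConfig-class] fixing the angle-pixel mapping.
#' @return Named numeric: `azimuth`, `elevation` (degrees).
#' @export
estimateFoe <- function(flow, frame = NULL, config = SceneConfig()) {
  if (is(flow, "FlowSample")) {
    stopifnot(!is.null(frame))
    flow <- flow@flow[, , , frame]
  }
  n <- dim(flow)[1]
  ctr <- .pixelCenter(n)
  dpp <- config@fov / n
  U <- flow[, , 1]; V <- flow[, , 2]
  nz <- which(U != 0 | V != 0)
  if (length(nz) < 2L) stop("too few flow vectors to estimate a FoE")
  rw <- ((nz - 1L) %% n) + 1L
  cl <- ((nz - 1L) %/% n) + 1L
  px <- cl
  py <- 2 * ctr - rw          # row -> upward pixel coordinate
  u <- U[nz]; v <- V[nz]
  a11 <- sum(v * v); a12 <- -sum(u * v); a22 <- sum(u * u)
  rhs <- v * px - u * py
  b1 <- sum(v * rhs); b2 <- -sum(u * rhs)
  det <- a11 * a22 - a12 * a12
  if (abs(det) < .Machine$double.eps * max(a11, a22, 1))
    stop("degenerate flow field: FoE is not identifiable")
  xf <- (a22 * b1 - a12 * b2) / det
  yf <- (a11 * b2 - a12 * b1) / det
  c(azimuth = (xf - ctr) * dpp, elevation = (yf - ctr) * dpp)
}
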