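#' Across-heading smoothing operator (model MSTd pooling)
#'
#' One-dimensional unit-sum Gaussian of SD `sigmaMST` templates, truncated
#' at radius `rMST`, applied across the template-heading axis. Kernels that
#' overhang the ends of the axis are renormalized, so a uniform activation
#' vector is preserved everywhere, including at the edges.
#'
#' @param n number of templates.
#' @param params a [ModelParams-class].
#' @return An `n x n` row-stochastic matrix.
#' @export
smootherMatrix <- function(n, params = ModelParams()) {
  r <- ceiling(params@rMST)
  off <- -r:r
  kern <- exp(-off^2 / (2 * params@sigmaMST^2)) * (abs(off) <= params@rMST)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + off
    ok <- j >= 1L & j <= n
    S[i, j[ok]] <- kern[ok]
    S[i, ] <- S[i, ] / sum(S[i, ])
  }
  S
}

#' Smooth raw template activations
#'
#' @param raw numeric vector of activations.
#' @param params a [ModelParams-class].
#' @param S optional precomputed [smootherMatrix()] (recomputed otherwise).
#' @return Smoothed vector of the same length.
#' @export
smoothActivations <- function(raw, params = ModelParams(), S = NULL) {
  if (is.null(S)) S <- smootherMatrix(length(raw), params)
  as.numeric(S %*% raw)
}

## saturating (Naka-Rushton) recurrent signal: faster than linear at low
## activity (contrast enhancement), bounded at high activity so the
## competition stays integrable and winners remain displaceable
.signalFun <- function(x, params) {
  params@recurrentGain * x^2 / (params@sigmoidK^2 + x^2)
}

#' Advance the MSTd network by one frame
#'
#' The drive first updates the exponential input trace,
#' `trace <- c * trace + (1 - c) * drive`, and the trace then feeds
#' `substepsPerFrame` explicit Euler steps of the recurrent
#' on-center/off-surround shunting field
#' \deqn{\dot x_i = -A x_i + (B - x_i)(I_i + f(x_i)) - x_i \sum_{j \ne i} f(x_j)}
#' with `f(x) = recurrentGain * x^2 / (sigmoidK^2 + x^2)`. Activations are
#' clipped to `[0, B]` after every substep. On a blackout frame pass an
#' all-zero drive: the state then evolves on the recurrent dynamics and
#' the decaying trace alone.
#'
#' @param state an [MSTdState-class].
#' @param drive non-negative numeric vector (smoothed, normalized
#'   activations), one entry per unit.
#' @param params a [ModelParams-class].
#' @return The updated [MSTdState-class].
#' @export
stepDynamics <- function(state, drive, params = ModelParams()) {
  stopifnot(is(state, "MSTdState"))
  if (any(!is.finite(drive)))
    stop("non-finite drive passed to stepDynamics")
  if (length(drive) != length(state@x))
    stop("drive length must match the number of units")
  tr <- params@c * state@trace + (1 - params@c) * drive
  x <- state@x
  A <- params@A; B <- params@B; dt <- params@dt
  for (s in seq_len(params@substepsPerFrame)) {
    f <- .signalFun(x, params)
    sf <- sum(f)
    x <- x + dt * (-A * x + (B - x) * (tr + f) - x * (sf - f))
    x <- pmin(pmax(x, 0), B)
  }
  new("MSTdState", x = x, trace = tr)
}

#' Decode heading from the network state (population vector)
#'
#' Activation-weighted mean of the units' preferred headings,
#' \deqn{i^* = \sum_i x_i h_i / \sum_i x_i .}
#'
#' @param state an [MSTdState-class].
#' @param bank a [TemplateBank-class] (or [CDModel-class]) supplying the
#'   preferred headings.
#' @return Decoded heading azimuth, degrees.
#' @examples
#' bank <- buildTemplates(32L, SceneConfig(resolution = 32L))
#' st <- MSTdState(nTemplates(bank))
#' st@x[which.min(abs(templateHeadings(bank) - 12))] <- 1
#' decodeHeading(st, bank)
#' @export
decodeHeading <- function(state, bank) {
  h <- templateHeadings(bank)
  x <- state@x
  stopifnot(length(x) == length(h))
  tot <- sum(x)
  if (!is.finite(tot) || tot <= 0)
    stop("undefined heading estimate: total activation is zero")
  sum(x * h) / tot
}
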