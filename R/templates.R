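#' Build the radial-expansion template bank
#'
#' One template per pixel column, FoE positions sampled along the
#' horizontal midline. Template k prefers the heading
#' `(k - center) * degPerPx`; its vector at pixel p is the unit vector
#' pointing from the FoE to p, weighted by `min(1, 1/d)` with d the
#' pixel distance to the FoE (inverse distance sharpens FoE selectivity;
#' the cap keeps near-FoE weights finite). The geometric midline of an
#' even-resolution raster falls between pixel rows, so no pixel ever
#' coincides with a FoE.
#'
#' @param resolution raster resolution (pixels per side), > 1.
#' @param config optional [SceneConfig-class]; fixes the field of view used
#'   for the angle-pixel scale (default 90 degrees).
#' @return An unpooled [TemplateBank-class].
#' @examples
#' bank <- buildTemplates(32L, SceneConfig(resolution = 32L))
#' nTemplates(bank)
#' @export
buildTemplates <- function(resolution = 128L, config = SceneConfig()) {
  n <- as.integer(resolution)
  if (n <= 1L) stop("resolution must exceed 1")
  dpp <- config@fov / n
  ctr <- .pixelCenter(n)
  rw <- matrix(seq_len(n), n, n)
  cl <- matrix(seq_len(n), n, n, byrow = TRUE)
  dy <- ctr - rw                       # FoE elevation is 0 (midline)
  tm <- matrix(0, 2L * n * n, n)
  for (k in seq_len(n)) {
    dx <- cl - k
    d <- sqrt(dx^2 + dy^2)
    w <- pmin(1, 1 / d)
    ## a pixel can coincide with the FoE at odd resolutions: the radial
    ## direction is undefined there, so it carries the zero vector
    w[d == 0] <- 0
    d[d == 0] <- 1
    tm[, k] <- c(w * dx / d, w * dy / d)
  }
  stopifnot(all(is.finite(tm)))
  new("TemplateBank",
      templates = tm, headings = (seq_len(n) - ctr) * dpp,
      resolution = n, degPerPx = dpp, pooled = FALSE)
}

#' Match a flow frame against the template bank
#'
#' Dot product of the frame with every template (both components), then
#' half-wave rectification at zero: contraction-like patterns that
#' anti-correlate with an expansion template contribute nothing, and an
#' all-zero (blackout) frame yields all-zero activations. Pass an MT-pooled
#' frame with a raw bank, or equivalently a raw frame with a pooled bank.
#'
#' @param frame `H x W x 2` numeric array.
#' @param bank a [TemplateBank-class] of matching resolution.
#' @return Numeric vector of `nTemplates(bank)` non-negative activations.
#' @export
templateMatch <- function(frame, bank) {
  stopifnot(is(bank, "TemplateBank"))
  if (length(frame) != nrow(bank@templates))
    stop("frame shape does not match the template bank resolution")
  pmax(0, as.numeric(crossprod(bank@templates, as.numeric(frame))))
}

## pooled-bank construction: convolve each template component with the MT
## kernel once, so per-frame matching needs no convolution (adjoint of a
## symmetric-kernel convolution is the same convolution)
.poolBank <- function(bank, params) {
  n <- bank@resolution
  plan <- .mtConvPlan(n, params)
  tm <- bank@templates
  for (k in seq_len(ncol(tm))) {
    tm[seq_len(n * n), k] <-
      as.numeric(.mtConvApply(matrix(tm[seq_len(n * n), k], n, n), plan))
    tm[n * n + seq_len(n * n), k] <-
      as.numeric(.mtConvApply(matrix(tm[n * n + seq_len(n * n), k], n, n), plan))
  }
  new("TemplateBank", templates = tm, headings = bank@headings,
      resolution = n, degPerPx = bank@degPerPx, pooled = TRUE)
}
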