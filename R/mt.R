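#' MT pooling kernel
#'
#' Unit-sum 2-D Gaussian of standard deviation `sigmaMT` pixels, truncated
#' to the disc of radius `rMT` pixels (circular receptive field).
#'
#' @param params a [ModelParams-class].
#' @return A square numeric matrix of odd side `2*rMT + 1`.
#' @export
mtKernel <- function(params = ModelParams()) {
  r <- ceiling(params@rMT)
  off <- -r:r
  k <- outer(off, off, function(dx, dy)
    exp(-(dx^2 + dy^2) / (2 * params@sigmaMT^2)) *
      (dx^2 + dy^2 <= params@rMT^2))
  k / sum(k)
}

## FFT plan for zero-padded linear convolution with the MT kernel
.mtConvPlan <- function(n, params) {
  k <- mtKernel(params)
  r <- (nrow(k) - 1L) / 2L
  pad <- n + 2L * r
  kp <- matrix(0, pad, pad)
  kp[seq_len(nrow(k)), seq_len(nrow(k))] <- k
  list(kfft = fft(kp), n = n, r = r, pad = pad)
}

.mtConvApply <- function(x, plan) {
  xp <- matrix(0, plan$pad, plan$pad)
  xp[plan$r + seq_len(plan$n), plan$r + seq_len(plan$n)] <- x
  y <- Re(fft(fft(xp) * plan$kfft, inverse = TRUE)) / plan$pad^2
  y[2L * plan$r + seq_len(plan$n), 2L * plan$r + seq_len(plan$n)]
}

#' Spatially pool a flow frame (model MT)
#'
#' Convolves the horizontal and vertical flow components separately with
#' the unit-sum truncated Gaussian of [mtKernel()], zero-padded at the
#' image border. Linear and shift-equivariant; a spatially uniform field
#' is preserved at interior pixels.
#'
#' @param frame `H x W x 2` numeric array.
#' @param params a [ModelParams-class].
#' @return Pooled array of the same shape.
#' @export
mtPool <- function(frame, params = ModelParams()) {
  d <- dim(frame)
  stopifnot(length(d) == 3L, d[3] == 2L, d[1] == d[2])
  plan <- .mtConvPlan(d[1], params)
  out <- array(0, d)
  out[, , 1] <- .mtConvApply(frame[, , 1], plan)
  out[, , 2] <- .mtConvApply(frame[, , 2], plan)
  out
}
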