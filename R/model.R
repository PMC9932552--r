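#' Assemble the competitive-dynamics model
#'
#' Builds the template bank for the configured resolution, passes it
#' through the MT pooling filter (so per-frame matching is a single matrix
#' product), precomputes the across-heading smoothing operator, and fixes
#' the drive normalization: raw rectified activations are multiplied by a
#' constant chosen so that the canonical noise-free full-field expansion
#' frame produces a peak raw activation of `driveScale`.
#'
#' @param params a [ModelParams-class].
#' @param config a [SceneConfig-class].
#' @return A [CDModel-class].
#' @examples
#' \donttest{
#' mdl <- CDModel(ModelParams(), SceneConfig())
#' mdl
#' }
#' @export
CDModel <- function(params = ModelParams(), config = SceneConfig()) {
  validObject(params)
  validObject(config)
  bank <- buildTemplates(config@resolution, config)
  pooled <- .poolBank(bank, params)
  S <- smootherMatrix(nTemplates(bank), params)
  canon <- canonicalExpansionFrame(config)
  peak <- max(templateMatch(canon, pooled))
  if (peak <= 0) stop("degenerate template bank: zero canonical response")
  new("CDModel", bank = bank, pooledBank = pooled, smoother = S,
      params = params, config = config,
      driveGain = params@driveScale / peak)
}

## drive for one frame: match (pooled form), rectify, normalize, smooth
.frameDrive <- function(model, frame) {
  raw <- templateMatch(frame, model@pooledBank) * model@driveGain
  as.numeric(model@smoother %*% raw)
}

#' Run one trial through the model
#'
#' Processes every frame of a [FlowSample-class] through the model
#' pipeline (MT pooling, template match, rectification and normalization,
#' across-heading smoothing, input-trace update, recurrent competition)
#' and decodes the population-vector heading at each requested readout
#' frame. The state starts from zero; nothing carries over between trials.
#' Blackout frames contribute an all-zero drive, so the state evolves on
#' the recurrent dynamics alone.
#'
#' @param model a [CDModel-class].
#' @param sample a [FlowSample-class] of matching resolution.
#' @param readoutFrames 1-based frame indices at which to decode (readouts
#'   on frame 1 of an otherwise silent network are undefined and raise an
#'   error).
#' @return A data.frame with one row per readout: the trial descriptors,
#'   `readoutFrame`, the decoded heading `judged`, the postswitch heading
#'   `trueHeading` and the heading error `error = judged - trueHeading`.
#' @export
runTrial <- function(model, sample, readoutFrames = nFrames(sample)) {
  stopifnot(is(model, "CDModel"), is(sample, "FlowSample"))
  nf <- nFrames(sample)
  readoutFrames <- as.integer(readoutFrames)
  if (any(readoutFrames < 1L) || any(readoutFrames > nf))
    stop("readoutFrames must lie in [1, nFrames]")
  n <- model@config@resolution
  if (dim(sample@flow)[1] != n)
    stop("sample resolution does not match the model")
  state <- MSTdState(nTemplates(model))
  est <- rep(NA_real_, length(readoutFrames))
  for (t in seq_len(nf)) {
    drive <- .frameDrive(model, sample@flow[, , , t])
    state <- stepDynamics(state, drive, model@params)
    hit <- which(readoutFrames == t)
    if (length(hit))
      est[hit] <- decodeHeading(state, model@bank)
  }
  sp <- sample@spec
  data.frame(
    conditionLabel = sp@conditionLabel,
    preswitch = sp@preswitch,
    switchAngle = sp@switchAngle,
    postswitch = sp@postswitch,
    repetition = sp@repetition,
    seed = sp@seed,
    readoutFrame = readoutFrames,
    judged = est,
    trueHeading = sp@postswitch,
    error = est - sp@postswitch,
    stringsAsFactors = FALSE)
}
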