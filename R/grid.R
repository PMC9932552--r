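#' Build the full condition grid of an experiment
#'
#' Experiment 1 crosses 3 preswitch headings (0, +/-6 deg) with 6 switch
#' angles (+/-3, +/-6, +/-12 deg) into 18 switch conditions of 34 frames
#' with the switch at frame 30. Experiment 2 crosses the same 18 heading
#' conditions with 4 blackout conditions on a 32-frame protocol:
#' `noblackout` (no blank frame), `preblackout` (frame 28 blanked, one
#' frame of flow before the switch at 30), `midblackout` (one blank frame
#' inserted between the preswitch and postswitch flow: 33 frames, switch
#' at 31), and `postblackout` (frames 31-32 blanked, so a single frame of
#' postswitch flow precedes the blackout that runs to the end of the
#' trial). Each (postswitch heading, repetition) pair also yields one
#' matched no-switch trial that shares the switch trials' dot-placement
#' seed, for variance-reduced bias estimates; the 18 conditions produce 11
#' unique postswitch headings.
#'
#' Repetitions differ only in the random placement of dots.
#'
#' @param experiment 1 or 2.
#' @param nReps repetitions per condition.
#' @param baseSeed integer; per-trial seeds are derived deterministically
#'   from it.
#' @return A list of [TrialSpec-class] objects (switch trials first, then
#'   the no-switch trials).
#' @examples
#' g <- makeConditionGrid(1, nReps = 1, baseSeed = 1)
#' sum(vapply(g, function(s) s@conditionLabel == "exp1", TRUE))  # 18
#' @export
makeConditionGrid <- function(experiment, nReps = 10L, baseSeed = 1L) {
  experiment <- as.integer(experiment)
  if (!experiment %in% c(1L, 2L))
    stop("unknown experiment id: ", experiment)
  nReps <- as.integer(nReps)
  pres <- c(-6, 0, 6)
  sws <- c(-12, -6, -3, 3, 6, 12)
  conds <- expand.grid(preswitch = pres, switchAngle = sws,
                       KEEP.OUT.ATTRS = FALSE)
  posts <- sort(unique(conds$preswitch + conds$switchAngle))
  seedFor <- function(rep, post)
    as.integer(baseSeed + 1009L * rep + match(post, posts))

  specs <- list()
  if (experiment == 1L) {
    for (r in seq_len(nReps)) {
      for (i in seq_len(nrow(conds))) {
        post <- conds$preswitch[i] + conds$switchAngle[i]
        specs[[length(specs) + 1L]] <- TrialSpec(
          preswitch = conds$preswitch[i],
          switchAngle = conds$switchAngle[i],
          nFrames = 34L, switchFrame = 30L,
          conditionLabel = "exp1",
          repetition = r, seed = seedFor(r, post))
      }
    }
    for (r in seq_len(nReps)) for (p in posts) {
      specs[[length(specs) + 1L]] <- TrialSpec(
        preswitch = p, switchAngle = 0,
        nFrames = 34L, switchFrame = 30L,
        conditionLabel = "noswitch",
        repetition = r, seed = seedFor(r, p))
    }
  } else {
    schedules <- list(
      noblackout  = list(nFrames = 32L, switchFrame = 30L, blackout = integer()),
      preblackout = list(nFrames = 32L, switchFrame = 30L, blackout = 28L),
      midblackout = list(nFrames = 33L, switchFrame = 31L, blackout = 30L),
      postblackout = list(nFrames = 32L, switchFrame = 30L, blackout = c(31L, 32L)))
    for (r in seq_len(nReps)) {
      for (bl in names(schedules)) {
        sch <- schedules[[bl]]
        for (i in seq_len(nrow(conds))) {
          post <- conds$preswitch[i] + conds$switchAngle[i]
          specs[[length(specs) + 1L]] <- TrialSpec(
            preswitch = conds$preswitch[i],
            switchAngle = conds$switchAngle[i],
            nFrames = sch$nFrames, switchFrame = sch$switchFrame,
            blackoutFrames = sch$blackout,
            conditionLabel = bl,
            repetition = r, seed = seedFor(r, post))
        }
      }
    }
    for (r in seq_len(nReps)) for (p in posts) {
      specs[[length(specs) + 1L]] <- TrialSpec(
        preswitch = p, switchAngle = 0,
        nFrames = 32L, switchFrame = 30L,
        conditionLabel = "noswitch",
        repetition = r, seed = seedFor(r, p))
    }
  }
  specs
}
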