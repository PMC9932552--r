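#' Random-search sampling intervals for the model parameters
#'
#' Neurophysiologically motivated uniform sampling ranges. Receptive-field
#' radii and filter SDs are expressed in degrees of visual angle and
#' converted to pixels through the linear angle-pixel scale when a
#' candidate is instantiated.
#'
#' @return Named list of `c(lo, hi)` intervals: `rMT` (2-12.5 deg),
#'   `rMST` (7.5-22 deg), `A` (0.1-1), `c` (0.2-0.8), `sigmaMT`
#'   (0.1-28 deg), `sigmaMST` (0.1-35 deg), `B` (1-150).
#' @export
searchSpace <- function() {
  list(rMT = c(2, 12.5), rMST = c(7.5, 22),
       A = c(0.1, 1.0), c = c(0.2, 0.8),
       sigmaMT = c(0.1, 28), sigmaMST = c(0.1, 35),
       B = c(1, 150))
}

## degrees -> pixels for the spatial entries of a sampled candidate
.candidateParams <- function(deg, config, base) {
  dpp <- degPerPixel(config)
  ModelParams(
    rMT = deg[["rMT"]] / dpp, sigmaMT = deg[["sigmaMT"]] / dpp,
    rMST = deg[["rMST"]] / dpp, sigmaMST = deg[["sigmaMST"]] / dpp,
    A = deg[["A"]], B = deg[["B"]], c = deg[["c"]],
    dt = base@dt, substepsPerFrame = base@substepsPerFrame,
    driveScale = base@driveScale, recurrentGain = base@recurrentGain,
    sigmoidK = base@sigmoidK)
}

#' Signed-bias profile of a parameter set on a reduced condition grid
#'
#' Runs a (configurably reduced) version of the switch-duration protocol
#' and returns the mean signed bias per switch angle and readout -- the
#' summary a search objective scores.
#'
#' @param params a [ModelParams-class].
#' @param config a [SceneConfig-class].
#' @param nReps repetitions per condition.
#' @param preswitch,switchAngles condition subsets.
#' @param readoutFrames decode frames.
#' @param baseSeed seed for dot placement.
#' @return data.frame with `switchAngle`, `readoutLabel`, `meanBias`.
#' @export
evaluateBiasProfile <- function(params, config = SceneConfig(),
                                nReps = 2L,
                                preswitch = c(-6, 0, 6),
                                switchAngles = c(-12, -6, 6, 12),
                                readoutFrames = c(32L, 34L),
                                baseSeed = 1L) {
  model <- CDModel(params, config)
  conds <- expand.grid(preswitch = preswitch, switchAngle = switchAngles,
                       KEEP.OUT.ATTRS = FALSE)
  posts <- sort(unique(conds$preswitch + conds$switchAngle))
  seedFor <- function(rep, post)
    as.integer(baseSeed + 1009L * rep + match(post, posts))
  runOne <- function(spec) {
    res <- runTrial(model, renderSequence(spec, config), readoutFrames)
    res$readoutLabel <- paste0("frame", res$readoutFrame)
    res
  }
  swRows <- list(); noRows <- list()
  for (r in seq_len(nReps)) {
    for (i in seq_len(nrow(conds))) {
      post <- conds$preswitch[i] + conds$switchAngle[i]
      swRows[[length(swRows) + 1L]] <- runOne(TrialSpec(
        preswitch = conds$preswitch[i], switchAngle = conds$switchAngle[i],
        nFrames = 34L, switchFrame = 30L, conditionLabel = "exp1",
        repetition = r, seed = seedFor(r, post)))
    }
    for (p in posts) {
      noRows[[length(noRows) + 1L]] <- runOne(TrialSpec(
        preswitch = p, switchAngle = 0,
        nFrames = 34L, switchFrame = 30L, conditionLabel = "noswitch",
        repetition = r, seed = seedFor(r, p)))
    }
  }
  bias <- headingBias(do.call(rbind, swRows), do.call(rbind, noRows))
  tab <- summarizeBias(bias, by = c("switchAngle", "readoutLabel"))
  tab[c("switchAngle", "readoutLabel", "meanBias")]
}

#' Qualitative search objective
#'
#' Scores a bias profile against the qualitative pattern of the published
#' behavior as soft constraints: the signed bias should be positive for
#' every switch angle, increase with the absolute switch angle, and
#' decrease from the earlier to the later readout. Violations contribute
#' their squared magnitude; a perfect qualitative match scores 0.
#'
#' @param profile data.frame from [evaluateBiasProfile()].
#' @return Non-negative penalty.
#' @export
qualitativeObjective <- function(profile) {
  pen <- sum(pmax(0, -profile$meanBias)^2)
  for (lab in unique(profile$readoutLabel)) {
    sub <- profile[profile$readoutLabel == lab, ]
    m <- tapply(sub$meanBias, abs(sub$switchAngle), mean)
    if (length(m) > 1L)
      pen <- pen + sum(pmax(0, -diff(m))^2)   # must grow with |switch|
  }
  labs <- sort(unique(profile$readoutLabel))
  if (length(labs) > 1L) {
    for (th in unique(abs(profile$switchAngle))) {
      sub <- profile[abs(profile$switchAngle) == th, ]
      m <- tapply(sub$meanBias, sub$readoutLabel, mean)[labs]
      pen <- pen + sum(pmax(0, diff(m))^2)    # must shrink over time
    }
  }
  pen
}

#' Squared-distance objective against a target profile
#'
#' @param target data.frame with `switchAngle`, `readoutLabel`,
#'   `meanBias` (e.g. a profile produced by the published parameter set).
#' @return A function mapping a profile to the summed squared difference
#'   of matched `meanBias` entries.
#' @export
profileDistanceObjective <- function(target) {
  function(profile) {
    m <- merge(profile, target, by = c("switchAngle", "readoutLabel"),
               suffixes = c("", ".target"))
    if (nrow(m) != nrow(target))
      stop("profile does not cover the target conditions")
    sum((m$meanBias - m$meanBias.target)^2)
  }
}

#' Random search over the model parameter space
#'
#' Samples `nIter` parameter sets uniformly from the intervals of
#' [searchSpace()], evaluates each candidate by running the reduced
#' switch-duration grid and scoring its bias profile with `objective`, and
#' returns the candidates ranked by score. Candidates whose simulation
#' fails (e.g. degenerate dynamics) receive an infinite score and a
#' warning instead of aborting the search.
#'
#' @param space named list of sampling intervals (see [searchSpace()]).
#' @param nIter number of candidates, >= 1.
#' @param seed RNG seed for the sampling.
#' @param objective profile-scoring function.
#' @param config a [SceneConfig-class].
#' @param baseParams [ModelParams-class] supplying the non-searched
#'   constants (integration, drive normalization, recurrent signal).
#' @param ... further arguments to [evaluateBiasProfile()] (`nReps`,
#'   `preswitch`, `switchAngles`, `readoutFrames`, `baseSeed`).
#' @return data.frame of candidates (parameter values in the units of the
#'   space, i.e. degrees for the spatial entries) with a `score` column,
#'   sorted ascending.
#' @export
parameterSearch <- function(space = searchSpace(), nIter = 10L,
                            seed = 1L, objective = qualitativeObjective,
                            config = SceneConfig(),
                            baseParams = ModelParams(), ...) {
  stopifnot(nIter >= 1L)
  draws <- withSeed(seed, {
    t(vapply(seq_len(nIter), function(i)
      vapply(space, function(rg) runif(1L, rg[1], rg[2]), numeric(1)),
      numeric(length(space))))
  })
  colnames(draws) <- names(space)
  scores <- numeric(nIter)
  for (i in seq_len(nIter)) {
    scores[i] <- tryCatch({
      prof <- evaluateBiasProfile(
        .candidateParams(draws[i, ], config, baseParams), config, ...)
      objective(prof)
    }, error = function(e) {
      warning("candidate ", i, " failed: ", conditionMessage(e),
              call. = FALSE)
      Inf
    })
  }
  out <- as.data.frame(draws)
  out$score <- scores
  out[order(out$score), , drop = FALSE]
}
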