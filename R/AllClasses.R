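## Central S4 classes. Angles are degrees of visual angle, azimuth positive
## rightward and elevation positive upward; pixel indices are 1-based with
## row 1 at the top; frames are 1-based.

#' Scene and rasterization configuration
#'
#' Describes the simulated 3D dot-cloud scene and the raster grid onto which
#' optic flow is digitized. The defaults reproduce the simulation stimulus:
#' 10,000 dots, a 90 degree square field of view digitized at 128 x 128
#' pixels, observer speed 1.5 m/s through a volume spanning depths
#' 1.5-9 m. `lateralExtent` is the half-width of the volume in X and Y;
#' the default `farDepth * tan(fov/2)` lets every depth plane fill the
#' field of view. `frameRate` converts metric speed into per-frame dot
#' displacement (one video frame is one model time step).
#'
#' @slot nDots number of dots in the cloud.
#' @slot depthRange numeric(2), near and far depth in meters.
#' @slot lateralExtent half-width of the volume in meters.
#' @slot speed observer translation speed, m/s.
#' @slot fov square field of view, degrees.
#' @slot resolution raster resolution, pixels per side.
#' @slot frameRate notional frames per second used to scale per-frame flow.
#' @export
setClass("SceneConfig",
  slots = c(
    nDots = "integer",
    depthRange = "numeric",
    lateralExtent = "numeric",
    speed = "numeric",
    fov = "numeric",
    resolution = "integer",
    frameRate = "numeric"
  )
)

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (object@nDots <= 0L) msg <- c(msg, "nDots must be positive")
  if (length(object@depthRange) != 2L ||
      !(0 < object@depthRange[1] && object@depthRange[1] < object@depthRange[2]))
    msg <- c(msg, "depthRange must satisfy 0 < near < far")
  if (object@lateralExtent <= 0) msg <- c(msg, "lateralExtent must be positive")
  if (object@fov <= 0) msg <- c(msg, "fov must be positive")
  if (object@resolution <= 0L) msg <- c(msg, "resolution must be positive")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be positive")
  if (length(msg)) msg else TRUE
})

#' @param nDots,depthRange,lateralExtent,speed,fov,resolution,frameRate see slots.
#' @return A `SceneConfig` object.
#' @examples
#' cfg <- SceneConfig()
#' degPerPixel(cfg)
#' @rdname SceneConfig-class
#' @export
SceneConfig <- function(nDots = 10000L,
                        depthRange = c(1.5, 9),
                        lateralExtent = NULL,
                        speed = 1.5,
                        fov = 90,
                        resolution = 128L,
                        frameRate = 30) {
  if (is.null(lateralExtent))
    lateralExtent <- depthRange[2] * tan(fov / 2 * pi / 180)
  new("SceneConfig",
      nDots = as.integer(nDots), depthRange = as.numeric(depthRange),
      lateralExtent = as.numeric(lateralExtent), speed = as.numeric(speed),
      fov = as.numeric(fov), resolution = as.integer(resolution),
      frameRate = as.numeric(frameRate))
}

#' @rdname SceneConfig-class
#' @aliases degPerPixel,SceneConfig-method
#' @export
setMethod("degPerPixel", "SceneConfig", function(object)
  object@fov / object@resolution)

setMethod("show", "SceneConfig", function(object) {
  cat("SceneConfig:", object@nDots, "dots, depths",
      paste(object@depthRange, collapse = "-"), "m, fov",
      object@fov, "deg @", object@resolution, "px,",
      object@speed, "m/s,", object@frameRate, "fps\n")
})

#' 3D dot cloud
#'
#' Dot positions in the observer frame (X rightward, Y upward, Z forward,
#' meters) together with the seed it was created from. Advected in place by
#' [flowFrame()]; dots leaving the volume are recycled into its far half.
#'
#' @slot positions numeric matrix n x 3 with columns X, Y, Z.
#' @slot seed integer seed used to create the cloud.
#' @export
setClass("DotCloud",
  slots = c(positions = "matrix", seed = "integer"))

setValidity("DotCloud", function(object) {
  if (ncol(object@positions) != 3L) return("positions must have 3 columns")
  TRUE
})

setMethod("show", "DotCloud", function(object) {
  cat("DotCloud:", nrow(object@positions), "dots, seed", object@seed, "\n")
})

#' Trial specification
#'
#' Everything that defines one simulated trial: the heading before the
#' switch, the switch angle (0 for no-switch trials), the number of frames,
#' the 1-based frame at which the heading changes (frames at or after
#' `switchFrame` use the postswitch heading), the set of blacked-out frames
#' (zero flow, invalid mask), a condition label, the repetition index and
#' the RNG seed that fixes dot placement and recycling.
#'
#' @slot preswitch,switchAngle,postswitch degrees azimuth; `postswitch`
#'   always equals `preswitch + switchAngle`.
#' @slot nFrames,switchFrame,repetition,seed integers.
#' @slot blackoutFrames integer vector of 1-based blacked-out frames.
#' @slot conditionLabel one of "exp1", "noswitch", "noblackout",
#'   "preblackout", "midblackout", "postblackout".
#' @export
setClass("TrialSpec",
  slots = c(
    preswitch = "numeric",
    switchAngle = "numeric",
    postswitch = "numeric",
    nFrames = "integer",
    switchFrame = "integer",
    blackoutFrames = "integer",
    conditionLabel = "character",
    repetition = "integer",
    seed = "integer"
  )
)

.trialLabels <- c("exp1", "noswitch", "noblackout", "preblackout",
                  "midblackout", "postblackout")

setValidity("TrialSpec", function(object) {
  msg <- character()
  if (!isTRUE(all.equal(object@postswitch,
                        object@preswitch + object@switchAngle)))
    msg <- c(msg, "postswitch must equal preswitch + switchAngle")
  if (object@switchFrame > object@nFrames)
    msg <- c(msg, "switchFrame must not exceed nFrames")
  if (length(object@blackoutFrames) &&
      (any(object@blackoutFrames < 1L) ||
       any(object@blackoutFrames > object@nFrames)))
    msg <- c(msg, "blackoutFrames must lie in [1, nFrames]")
  if (!object@conditionLabel %in% .trialLabels)
    msg <- c(msg, paste("conditionLabel must be one of",
                        paste(.trialLabels, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @param preswitch,switchAngle,nFrames,switchFrame,blackoutFrames,conditionLabel,repetition,seed
#'   see slots.
#' @return A `TrialSpec`.
#' @rdname TrialSpec-class
#' @export
TrialSpec <- function(preswitch, switchAngle,
                      nFrames = 34L, switchFrame = 30L,
                      blackoutFrames = integer(),
                      conditionLabel = "exp1",
                      repetition = 1L, seed = 1L) {
  new("TrialSpec",
      preswitch = as.numeric(preswitch),
      switchAngle = as.numeric(switchAngle),
      postswitch = as.numeric(preswitch) + as.numeric(switchAngle),
      nFrames = as.integer(nFrames), switchFrame = as.integer(switchFrame),
      blackoutFrames = as.integer(sort(blackoutFrames)),
      conditionLabel = conditionLabel,
      repetition = as.integer(repetition), seed = as.integer(seed))
}

#' @rdname TrialSpec-class
#' @aliases nFrames,TrialSpec-method
#' @export
setMethod("nFrames", "TrialSpec", function(object) object@nFrames)

setMethod("show", "TrialSpec", function(object) {
  cat(sprintf(
    "TrialSpec [%s] pre %+.1f -> post %+.1f deg (switch %+.1f @ frame %d), %d frames%s, rep %d, seed %d\n",
    object@conditionLabel, object@preswitch, object@postswitch,
    object@switchAngle, object@switchFrame, object@nFrames,
    if (length(object@blackoutFrames))
      paste0(", blackout {", paste(object@blackoutFrames, collapse = ","), "}")
    else "",
    object@repetition, object@seed))
})

#' Rasterized optic-flow sequence for one trial
#'
#' Dense optic flow digitized on the raster grid: an array
#' `resolution x resolution x 2 x nFrames` whose third dimension holds the
#' horizontal (azimuthal, positive rightward) and vertical (elevational,
#' positive upward) components in degrees of visual angle per frame.
#' Blacked-out frames are all-zero and flagged FALSE in `validMask`.
#'
#' @slot flow four-dimensional numeric array, H x W x 2 x T.
#' @slot validMask logical, one flag per frame.
#' @slot spec the generating [TrialSpec-class].
#' @export
setClass("FlowSample",
  slots = c(flow = "array", validMask = "logical", spec = "TrialSpec"))

setValidity("FlowSample", function(object) {
  d <- dim(object@flow)
  msg <- character()
  if (length(d) != 4L || d[3] != 2L)
    msg <- c(msg, "flow must be an H x W x 2 x T array")
  else {
    if (d[4] != object@spec@nFrames)
      msg <- c(msg, "frame count must match the spec")
    if (length(object@validMask) != d[4])
      msg <- c(msg, "validMask must have one entry per frame")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname FlowSample-class
#' @aliases flowArray,FlowSample-method
#' @export
setMethod("flowArray", "FlowSample", function(object) object@flow)

#' @rdname FlowSample-class
#' @aliases validMask,FlowSample-method
#' @export
setMethod("validMask", "FlowSample", function(object) object@validMask)

#' @rdname FlowSample-class
#' @aliases trialSpec,FlowSample-method
#' @export
setMethod("trialSpec", "FlowSample", function(object) object@spec)

#' @rdname FlowSample-class
#' @aliases nFrames,FlowSample-method
#' @export
setMethod("nFrames", "FlowSample", function(object) dim(object@flow)[4])

setMethod("show", "FlowSample", function(object) {
  d <- dim(object@flow)
  cat(sprintf("FlowSample %d x %d x %d x %d (%d blackout frame%s)\n",
              d[1], d[2], d[3], d[4], sum(!object@validMask),
              if (sum(!object@validMask) == 1L) "" else "s"))
  show(object@spec)
})

#' Model parameters
#'
#' All tunable constants of the simplified competitive-dynamics model.
#' Spatial parameters are in pixels of the 128 x 128 raster
#' (0.703 deg/px at the default 90 degree field of view): `rMT`/`sigmaMT`
#' are the truncation radius and SD of the MT pooling Gaussian, and
#' `rMST`/`sigmaMST` those of the one-dimensional Gaussian applied across
#' template headings. `A` is the passive decay rate, `B` the shunting
#' excitatory upper bound, and `c` the exponential moving-average constant
#' of the input trace. `dt` and `substepsPerFrame` control the explicit
#' Euler integration (their product is the integration time per video
#' frame, in frame units). `driveScale` sets the peak drive produced by a
#' canonical noise-free expansion frame after normalization, and
#' `recurrentGain`/`sigmoidK` parameterize the saturating recurrent signal
#' function f(x) = recurrentGain * x^2 / (sigmoidK^2 + x^2).
#'
#' @slot rMT,sigmaMT,rMST,sigmaMST,A,B,c,dt,driveScale,recurrentGain,sigmoidK numeric.
#' @slot substepsPerFrame integer.
#' @export
setClass("ModelParams",
  slots = c(
    rMT = "numeric", sigmaMT = "numeric",
    rMST = "numeric", sigmaMST = "numeric",
    A = "numeric", B = "numeric", c = "numeric",
    dt = "numeric", substepsPerFrame = "integer",
    driveScale = "numeric", recurrentGain = "numeric", sigmoidK = "numeric"
  )
)

setValidity("ModelParams", function(object) {
  msg <- character()
  if (object@A <= 0) msg <- c(msg, "A must be positive")
  if (object@B <= 0) msg <- c(msg, "B must be positive")
  if (object@c < 0 || object@c > 1) msg <- c(msg, "c must lie in [0, 1]")
  if (object@rMT < 0 || object@rMST < 0) msg <- c(msg, "radii must be >= 0")
  if (object@sigmaMT <= 0 || object@sigmaMST <= 0)
    msg <- c(msg, "sigmas must be positive")
  if (object@dt <= 0 || object@substepsPerFrame < 1L)
    msg <- c(msg, "dt must be positive and substepsPerFrame >= 1")
  if (object@recurrentGain < 0 || object@sigmoidK <= 0)
    msg <- c(msg, "recurrentGain must be >= 0 and sigmoidK positive")
  if (length(msg)) msg else TRUE
})

#' @param rMT,sigmaMT,rMST,sigmaMST,A,B,c,dt,substepsPerFrame,driveScale,recurrentGain,sigmoidK
#'   see slots; defaults are the published simulation values plus the
#'   package's calibrated dynamics constants.
#' @return A `ModelParams` object.
#' @rdname ModelParams-class
#' @export
ModelParams <- function(rMT = 6, sigmaMT = 9.51,
                        rMST = 19, sigmaMST = 10.08,
                        A = 0.81, B = 146, c = 0.7,
                        dt = 0.05, substepsPerFrame = 20L,
                        driveScale = 1, recurrentGain = 8, sigmoidK = 16) {
  new("ModelParams",
      rMT = rMT, sigmaMT = sigmaMT, rMST = rMST, sigmaMST = sigmaMST,
      A = A, B = B, c = c, dt = dt,
      substepsPerFrame = as.integer(substepsPerFrame),
      driveScale = driveScale, recurrentGain = recurrentGain,
      sigmoidK = sigmoidK)
}

setMethod("show", "ModelParams", function(object) {
  cat(sprintf(paste0(
    "ModelParams: rMT=%g sigmaMT=%g rMST=%g sigmaMST=%g px | ",
    "A=%g B=%g c=%g | dt=%g x %d substeps | driveScale=%g gain=%g K=%g\n"),
    object@rMT, object@sigmaMT, object@rMST, object@sigmaMST,
    object@A, object@B, object@c, object@dt, object@substepsPerFrame,
    object@driveScale, object@recurrentGain, object@sigmoidK))
})

#' Radial-expansion template bank
#'
#' One radial-expansion template per pixel column, with the focus of
#' expansion (FoE) on the horizontal midline. Template k prefers the
#' heading azimuth of column k under the linear angle-pixel mapping; its
#' vector at pixel p is the unit vector from the FoE to p, weighted by
#' inverse distance (capped at 1). Templates are stored as a
#' `(2*H*W) x Ntemps` matrix (u-plane stacked over v-plane, column-major)
#' so that template matching is a single matrix product.
#'
#' @slot templates numeric matrix, `2*resolution^2` rows by `Ntemps` columns.
#' @slot headings preferred heading azimuths, degrees.
#' @slot resolution raster resolution the bank was built for.
#' @slot degPerPx linear angle-to-pixel scale, degrees per pixel.
#' @slot pooled TRUE if the templates have been passed through the MT
#'   pooling filter (the adjoint-trick form used by [CDModel()]).
#' @export
setClass("TemplateBank",
  slots = c(
    templates = "matrix", headings = "numeric",
    resolution = "integer", degPerPx = "numeric", pooled = "logical"
  )
)

setValidity("TemplateBank", function(object) {
  msg <- character()
  if (ncol(object@templates) != length(object@headings))
    msg <- c(msg, "one heading per template required")
  if (nrow(object@templates) != 2L * object@resolution^2)
    msg <- c(msg, "template rows must equal 2 * resolution^2")
  if (length(msg)) msg else TRUE
})

#' @rdname TemplateBank-class
#' @aliases nTemplates,TemplateBank-method
#' @export
setMethod("nTemplates", "TemplateBank", function(object)
  ncol(object@templates))

#' @rdname TemplateBank-class
#' @aliases templateHeadings,TemplateBank-method
#' @export
setMethod("templateHeadings", "TemplateBank", function(object)
  object@headings)

#' @rdname TemplateBank-class
#' @aliases degPerPixel,TemplateBank-method
#' @export
setMethod("degPerPixel", "TemplateBank", function(object) object@degPerPx)

setMethod("show", "TemplateBank", function(object) {
  cat(sprintf(
    "TemplateBank: %d templates @ %d px (%spooled), headings %.2f..%.2f deg\n",
    nTemplates(object), object@resolution,
    if (object@pooled) "" else "un",
    min(object@headings), max(object@headings)))
})

#' MSTd network state
#'
#' Activations of the heading-template units and the exponentially averaged
#' input trace that drives them.
#'
#' @slot x unit activations, bounded in `[0, B]`.
#' @slot trace exponentially averaged drive.
#' @export
setClass("MSTdState", slots = c(x = "numeric", trace = "numeric"))

setValidity("MSTdState", function(object) {
  if (length(object@x) != length(object@trace))
    return("x and trace must have equal length")
  TRUE
})

#' @param n number of units.
#' @return A zero-initialized `MSTdState`.
#' @rdname MSTdState-class
#' @export
MSTdState <- function(n) new("MSTdState", x = numeric(n), trace = numeric(n))

#' @rdname MSTdState-class
#' @aliases activations,MSTdState-method
#' @export
setMethod("activations", "MSTdState", function(object) object@x)

#' @rdname MSTdState-class
#' @aliases inputTrace,MSTdState-method
#' @export
setMethod("inputTrace", "MSTdState", function(object) object@trace)

setMethod("show", "MSTdState", function(object) {
  cat(sprintf("MSTdState: %d units, total activation %.3f, peak %.3f\n",
              length(object@x), sum(object@x), max(object@x)))
})

#' Assembled competitive-dynamics model
#'
#' Holds the template bank (raw and MT-pooled forms), the across-heading
#' smoothing operator, the drive-normalization constant and the parameter
#' set, precomputed once so that trials run as a sequence of matrix
#' products. Because MT pooling is linear with a symmetric kernel, matching
#' a pooled flow frame against the raw templates equals matching the raw
#' frame against pooled templates; `CDModel` stores the pooled bank and
#' uses that equivalent form.
#'
#' @slot bank raw [TemplateBank-class].
#' @slot pooledBank MT-pooled [TemplateBank-class].
#' @slot smoother row-renormalized 1-D Gaussian smoothing matrix.
#' @slot params [ModelParams-class].
#' @slot config [SceneConfig-class] the model raster is matched to.
#' @slot driveGain scalar drive normalization (set so a canonical
#'   noise-free expansion frame yields peak drive `driveScale`).
#' @export
setClass("CDModel",
  slots = c(
    bank = "TemplateBank", pooledBank = "TemplateBank",
    smoother = "matrix", params = "ModelParams",
    config = "SceneConfig", driveGain = "numeric"
  )
)

#' @rdname CDModel-class
#' @aliases modelParams,CDModel-method
#' @export
setMethod("modelParams", "CDModel", function(object) object@params)

#' @rdname CDModel-class
#' @aliases sceneConfig,CDModel-method
#' @export
setMethod("sceneConfig", "CDModel", function(object) object@config)

#' @rdname CDModel-class
#' @aliases nTemplates,CDModel-method
#' @export
setMethod("nTemplates", "CDModel", function(object) nTemplates(object@bank))

#' @rdname CDModel-class
#' @aliases templateHeadings,CDModel-method
#' @export
setMethod("templateHeadings", "CDModel", function(object)
  templateHeadings(object@bank))

setMethod("show", "CDModel", function(object) {
  cat("CDModel\n  ")
  show(object@bank)
  cat("  ")
  show(object@params)
  cat(sprintf("  driveGain = %.6g\n", object@driveGain))
})

#' Experiment plan
#'
#' Bundles a condition grid recipe (experiment id, repetitions, base seed)
#' with the scene configuration, model parameters and readout frames for
#' [runExperiment()].
#'
#' @slot experiment 1 (switch/duration protocol, 34 frames) or 2
#'   (blackout protocol, 32/33 frames).
#' @slot nReps repetitions per condition.
#' @slot baseSeed integer base seed for dot placement.
#' @slot readoutFrames frames at which heading is decoded (experiment 1);
#'   experiment 2 always reads out at each trial's final frame.
#' @slot config [SceneConfig-class].
#' @slot params [ModelParams-class].
#' @export
setClass("ExperimentPlan",
  slots = c(
    experiment = "integer", nReps = "integer", baseSeed = "integer",
    readoutFrames = "integer", config = "SceneConfig", params = "ModelParams"
  )
)

setValidity("ExperimentPlan", function(object) {
  if (!object@experiment %in% c(1L, 2L))
    return("experiment must be 1 or 2")
  TRUE
})

#' @param experiment,nReps,baseSeed,readoutFrames,config,params see slots.
#' @return An `ExperimentPlan`.
#' @rdname ExperimentPlan-class
#' @export
experimentPlan <- function(experiment, nReps = 10L, baseSeed = 1L,
                           readoutFrames = NULL,
                           config = SceneConfig(),
                           params = ModelParams()) {
  experiment <- as.integer(experiment)
  if (is.null(readoutFrames))
    readoutFrames <- if (experiment == 1L) c(32L, 34L) else 32L
  new("ExperimentPlan",
      experiment = experiment, nReps = as.integer(nReps),
      baseSeed = as.integer(baseSeed),
      readoutFrames = as.integer(readoutFrames),
      config = config, params = params)
}

setMethod("show", "ExperimentPlan", function(object) {
  cat(sprintf(
    "ExperimentPlan: experiment %d, %d reps, base seed %d, readouts {%s}\n",
    object@experiment, object@nReps, object@baseSeed,
    paste(object@readoutFrames, collapse = ", ")))
})
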