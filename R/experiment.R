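#' Run a full experiment protocol
#'
#' Generates the condition grid of the plan, renders every optic-flow
#' sample, runs each through the model and assembles trial results, the
#' per-trial and per-condition heading-bias tables and the precision
#' table. Everything is a pure function of the plan, so rerunning an
#' identical plan reproduces the bundle exactly.
#'
#' Experiment 1 trials are decoded at the plan's readout frames (default
#' 32 and 34: shorter and longer postswitch viewing). Experiment 2 trials
#' are decoded at their final frame (32, or 33 for the extended
#' midblackout schedule), labelled `"final"`.
#'
#' @param plan an [ExperimentPlan-class].
#' @param verbose print progress every 50 trials.
#' @return A list: `results` (one row per trial and readout), `bias`
#'   (per-trial signed biases), `biasTable` (per switch angle and readout,
#'   or per blackout condition), `precision`, and the `plan`.
#' @examples
#' \donttest{
#' plan <- experimentPlan(1, nReps = 1, baseSeed = 1)
#' bundle <- runExperiment(plan)
#' head(bundle$biasTable)
#' }
#' @export
runExperiment <- function(plan, verbose = FALSE) {
  stopifnot(is(plan, "ExperimentPlan"))
  model <- CDModel(plan@params, plan@config)
  specs <- makeConditionGrid(plan@experiment, plan@nReps, plan@baseSeed)
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    sample <- renderSequence(sp, plan@config)
    ro <- if (plan@experiment == 1L) plan@readoutFrames else sp@nFrames
    res <- runTrial(model, sample, ro)
    res$readoutLabel <- if (plan@experiment == 1L)
      paste0("frame", res$readoutFrame) else "final"
    rows[[i]] <- res
    if (verbose && i %% 50L == 0L)
      message(sprintf("  processed %d / %d trials", i, length(specs)))
  }
  results <- do.call(rbind, rows)
  results$experiment <- plan@experiment
  isSwitch <- results$conditionLabel != "noswitch"
  bias <- headingBias(results[isSwitch, ], results[!isSwitch, ],
                      pairBy = c("postswitch", "readoutLabel"))
  biasTable <- if (plan@experiment == 1L)
    summarizeBias(bias, by = c("switchAngle", "readoutLabel"))
  else
    summarizeBias(bias, by = "conditionLabel")
  precBy <- if (plan@experiment == 1L)
    c("preswitch", "switchAngle", "readoutLabel")
  else
    c("preswitch", "switchAngle", "conditionLabel")
  precision <- precisionTable(results[isSwitch, ], by = precBy)
  list(results = results, bias = bias, biasTable = biasTable,
       precision = precision, plan = plan)
}
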