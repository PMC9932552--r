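#' Heading error
#'
#' Signed difference between the judged (decoded) heading and the true
#' heading, `E = Hjudged - Htrue`, in degrees. On switch trials the true
#' heading is the postswitch heading.
#'
#' @param judged,trueHeading numeric vectors, degrees.
#' @return `judged - trueHeading`.
#' @examples
#' headingError(4, 6)    # -2
#' @export
headingError <- function(judged, trueHeading) {
  stopifnot(all(is.finite(judged)), all(is.finite(trueHeading)))
  judged - trueHeading
}

#' Per-trial heading bias relative to matched no-switch trials
#'
#' For every switch trial, the bias is its heading error minus the mean
#' error of the no-switch trials that share the same pairing key (by
#' default the postswitch heading and, when present, the readout
#' condition). The sign convention then makes positive values denote
#' attraction toward the preswitch heading: biases of trials with positive
#' switch angles are negated.
#'
#' @param switchResults,noswitchResults data.frames of trial results (as
#'   produced by [runTrial()] / [runExperiment()]) with at least columns
#'   `postswitch`, `switchAngle`, `error`.
#' @param pairBy columns used to match switch to no-switch trials; columns
#'   absent from either input are dropped.
#' @return `switchResults` with two extra columns: `rawBias` (error minus
#'   matched mean no-switch error) and `bias` (after the sign convention).
#' @examples
#' sw <- data.frame(postswitch = 6, switchAngle = 12, error = -3)
#' no <- data.frame(postswitch = 6, switchAngle = 0, error = -1)
#' headingBias(sw, no)$bias   # +2: attraction
#' @export
headingBias <- function(switchResults, noswitchResults,
                        pairBy = c("postswitch", "readoutLabel")) {
  pairBy <- pairBy[pairBy %in% names(switchResults) &
                   pairBy %in% names(noswitchResults)]
  if (!"postswitch" %in% pairBy)
    stop("pairing requires a shared 'postswitch' column")
  keyOf <- function(d) do.call(paste, c(d[pairBy], sep = "\r"))
  noMean <- tapply(noswitchResults$error, keyOf(noswitchResults), mean)
  m <- noMean[keyOf(switchResults)]
  if (any(is.na(m)))
    stop("unmatched postswitch heading: no-switch trials missing for ",
         paste(unique(keyOf(switchResults)[is.na(m)]), collapse = "; "))
  out <- switchResults
  out$rawBias <- out$error - as.numeric(m)
  out$bias <- ifelse(out$switchAngle > 0, -out$rawBias, out$rawBias)
  out
}

#' Aggregate per-trial biases into a condition table
#'
#' Mean signed bias per group with a normal-approximation 95% confidence
#' halfwidth across trials (descriptive only).
#'
#' @param biasDf output of [headingBias()].
#' @param by grouping columns.
#' @return data.frame with the grouping columns, `meanBias`, `ciHalfwidth`
#'   and `n`.
#' @export
summarizeBias <- function(biasDf, by = "switchAngle") {
  stopifnot(all(by %in% names(biasDf)), "bias" %in% names(biasDf))
  agg <- aggregate(biasDf["bias"], biasDf[by], function(v)
    c(mean = mean(v), sd = sd(v), n = length(v)))
  out <- agg[by]
  out$meanBias <- agg$bias[, "mean"]
  nn <- agg$bias[, "n"]
  out$ciHalfwidth <- ifelse(nn > 1,
                            qnorm(0.975) * agg$bias[, "sd"] / sqrt(nn), NA_real_)
  out$n <- as.integer(nn)
  out
}

#' Precision of decoded headings
#'
#' Standard deviation (denominator n - 1) of the judged heading across the
#' repetitions of each condition.
#'
#' @param results trial-results data.frame with a `judged` column.
#' @param by grouping columns defining a condition.
#' @return data.frame with the grouping columns, `sdJudged` and `n`.
#' @examples
#' d <- data.frame(cond = c(1, 1), judged = c(5, 7))
#' precisionTable(d, by = "cond")$sdJudged   # 1.4142...
#' @export
precisionTable <- function(results, by = c("preswitch", "switchAngle")) {
  stopifnot(all(by %in% names(results)), "judged" %in% names(results))
  cnt <- aggregate(results["judged"], results[by], length)
  if (any(cnt$judged < 2L))
    stop("insufficient repetitions: every group needs at least 2 trials")
  agg <- aggregate(results["judged"], results[by], sd)
  out <- agg[by]
  out$sdJudged <- agg$judged
  out$n <- as.integer(cnt$judged)
  out
}

#' Collapse a condition table across the sign of an angle
#'
#' Merges the rows for +theta and -theta by averaging their values (signed
#' biases are already sign-normalized by the convention in
#' [headingBias()], so averaging is meaningful). Every nonzero angle must
#' appear with both signs within each residual group.
#'
#' @param table a data.frame (e.g. from [summarizeBias()] or
#'   [precisionTable()]).
#' @param signCol name of the signed-angle column.
#' @param valueCols columns to average; defaults to all numeric columns
#'   other than `signCol` and `n` (`n` is summed).
#' @return data.frame keyed by `abs<SignCol>` and any remaining
#'   non-value columns.
#' @export
collapseBySign <- function(table, signCol = "switchAngle",
                           valueCols = NULL) {
  stopifnot(signCol %in% names(table))
  if (is.null(valueCols))
    valueCols <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                         c(signCol, "n"))
  absCol <- paste0("abs",
                   toupper(substring(signCol, 1, 1)), substring(signCol, 2))
  keyCols <- setdiff(names(table), c(signCol, valueCols, "n"))
  tab <- table
  tab[[absCol]] <- abs(tab[[signCol]])
  grp <- c(absCol, keyCols)
  cnt <- aggregate(tab[signCol],
                   tab[grp],
                   function(v) length(unique(v)))
  expected <- ifelse(cnt[[absCol]] == 0, 1L, 2L)
  if (any(cnt[[signCol]] != expected))
    stop("asymmetric grid: each nonzero |", signCol,
         "| needs entries of both signs")
  out <- aggregate(tab[valueCols], tab[grp], mean)
  if ("n" %in% names(table))
    out$n <- aggregate(tab["n"], tab[grp], sum)$n
  out
}
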