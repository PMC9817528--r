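## Confusion matrices, micro / one-vs-all / macro accuracies, and
## leave-one-horse-out cross-validation. Reference result tables from the
## published mobile-phone study are bundled for worked-example arithmetic.

#' Confusion matrix over the five gaits
#'
#' @param truth,pred factors or character vectors of gait labels.
#' @return 5 x 5 integer matrix, rows = truth, columns = prediction.
#' @export
gaitConfusion <- function(truth, pred) {
  truth <- gaitFactor(as.character(truth))
  pred <- gaitFactor(as.character(pred))
  table(truth = truth, pred = pred)
}

#' Accuracy measures from a confusion matrix
#'
#' \code{microAccuracy} is the sum of the diagonal divided by the sum of all
#' entries. \code{ovaAccuracy} binarizes the problem into "this gait vs all
#' others" and counts both true positives and true negatives.
#' \code{macroAverage} is the unweighted mean over the present values only;
#' values for gaits a horse never performed are marked missing upstream and
#' excluded here.
#'
#' @param cm confusion matrix (rows truth, columns prediction).
#' @return a fraction in [0, 1].
#' @examples
#' cm <- matrix(0, 5, 5); diag(cm) <- c(10, 5, 8, 4, 2)
#' microAccuracy(cm)  # 1
#' @export
microAccuracy <- function(cm) {
  tot <- sum(cm)
  if (tot <= 0) eqMetricError("empty confusion matrix")
  sum(diag(as.matrix(cm))) / tot
}

#' @rdname microAccuracy
#' @param gait gait name or index for the one-vs-all binarization.
#' @export
ovaAccuracy <- function(cm, gait) {
  cm <- as.matrix(cm)
  tot <- sum(cm)
  if (tot <= 0) eqMetricError("empty confusion matrix")
  k <- if (is.character(gait)) match(gait, gaitLevels()) else gait
  tp <- cm[k, k]
  tn <- sum(cm[-k, -k])
  (tp + tn) / tot
}

#' @rdname microAccuracy
#' @param values numeric vector of per-gait or per-horse fractions.
#' @param present logical mask of values to include (default: non-NA).
#' @export
macroAverage <- function(values, present = !is.na(values)) {
  if (!any(present)) eqMetricError("no present values to average")
  mean(values[present])
}

#' Per-gait accuracy report for one evaluation
#'
#' One-vs-all accuracy per gait plus the micro average. Gaits with zero
#' truth rows are reported as \code{NA} (the horse has no data for them).
#'
#' @param cm 5 x 5 confusion matrix.
#' @return list with \code{perGait} (named numeric, NA = missing),
#'   \code{micro}, and \code{macro} (mean over present gaits).
#' @export
accuracyReport <- function(cm) {
  cm <- as.matrix(cm)
  perGait <- vapply(seq_len(5), function(k) {
    if (sum(cm[k, ]) == 0) NA_real_ else ovaAccuracy(cm, k)
  }, numeric(1))
  names(perGait) <- gaitLevels()
  list(perGait = perGait, micro = microAccuracy(cm),
       macro = macroAverage(perGait))
}

#' Leave-one-horse-out cross-validation
#'
#' For each horse: train the configured model on all other horses' segments
#' (with an internal train/validation split) and evaluate on the held-out
#' horse; repeat with fresh seeds and average. Emits a per-horse table of
#' one-vs-all gait accuracies and micro averages, plus macro summaries.
#'
#' @param segments \linkS4class{SegmentSet} covering several horses.
#' @param modelCfg a \code{\link{modelConfig}}.
#' @param trainCfg a \code{\link{trainConfig}}; repeat \code{r} uses seed
#'   \code{trainCfg$seed + r - 1}.
#' @param repeats number of repeats per fold (default 5).
#' @param valFraction internal validation fraction (default 0.15).
#' @return list with \code{perHorse} (data.frame: horseId, one column per
#'   gait, micro), \code{gaitMacro} (named means over horses with data for
#'   the gait), \code{overallMacro} (mean of the per-gait macros) and
#'   \code{horseMacro} (mean per-horse micro accuracy, the model-comparison
#'   summary).
#' @export
lohoCv <- function(segments, modelCfg, trainCfg, repeats = 5,
                   valFraction = 0.15) {
  horses <- sort(unique(segmentInfo(segments)$horseId))
  if (length(horses) < 2) eqConfigError("need at least 2 horses")
  rows <- list()
  for (h in horses) {
    acc <- matrix(NA_real_, repeats, 5)
    mic <- numeric(repeats)
    for (r in seq_len(repeats)) {
      seed <- trainCfg$seed + r - 1L
      sp <- splitDataset(segments, testHorses = h,
                         valFraction = valFraction, seed = seed)
      cfgR <- trainCfg; cfgR$seed <- seed
      model <- buildModel(modelCfg, seed = seed)
      model <- trainModel(model, sp$train, sp$val, cfgR)
      pred <- predictGait(model, sp$test)
      cm <- gaitConfusion(segmentLabels(sp$test), pred)
      rep_ <- accuracyReport(cm)
      acc[r, ] <- rep_$perGait
      mic[r] <- rep_$micro
    }
    rows[[as.character(h)]] <- c(colMeans(acc), mean(mic))
  }
  perHorse <- as.data.frame(do.call(rbind, rows))
  names(perHorse) <- c(gaitLevels(), "micro")
  perHorse <- cbind(horseId = horses, perHorse)
  gaitMacro <- vapply(gaitLevels(), function(g) {
    v <- perHorse[[g]]
    if (all(is.na(v))) NA_real_ else macroAverage(v)
  }, numeric(1))
  list(perHorse = perHorse,
       gaitMacro = gaitMacro,
       overallMacro = macroAverage(gaitMacro),
       horseMacro = mean(perHorse$micro))
}

## ---------------------------------------------------------------------------
## bundled reference tables
## ---------------------------------------------------------------------------

#' Bundled reference results from the published mobile-phone gait study
#'
#' Two small tables bundled as package data: the per-horse, per-gait
#' one-vs-all accuracies of a Bi-LSTM classifier under leave-one-horse-out
#' cross-validation on 17 Icelandic horses
#' (\code{referenceAccuracyTable()}; \code{NA} marks gaits the evaluation
#' did not report for a horse), and the seconds of labelled data each horse
#' contributed per gait (\code{referenceGaitDurations()}). Together they
#' support the macro-average arithmetic: a horse's accuracy for a gait
#' enters a macro average only when that horse contributed nonzero data for
#' the gait.
#'
#' @return data.frame, one row per horse.
#' @export
referenceAccuracyTable <- function() {
  utils::read.csv(system.file("extdata", "reference_loho_accuracy.csv",
                              package = "EquiGait"))
}

#' @rdname referenceAccuracyTable
#' @export
referenceGaitDurations <- function() {
  utils::read.csv(system.file("extdata", "reference_gait_durations.csv",
                              package = "EquiGait"))
}

#' Macro averages from the bundled reference tables
#'
#' Recomputes the per-gait macro averages (mean of per-horse one-vs-all
#' accuracies over horses that contributed data for the gait) and the
#' overall macro (mean of the five per-gait macros).
#'
#' @return list with \code{gaitMacro} (named numeric of length 5) and
#'   \code{overallMacro}.
#' @export
referenceMacroAverages <- function() {
  acc <- referenceAccuracyTable()
  dur <- referenceGaitDurations()
  stopifnot(identical(acc$horseId, dur$horseId))
  gaitMacro <- vapply(gaitLevels(), function(g) {
    v <- acc[[g]]
    present <- !is.na(v) & dur[[g]] > 0
    macroAverage(v, present)
  }, numeric(1))
  list(gaitMacro = gaitMacro, overallMacro = macroAverage(gaitMacro))
}
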