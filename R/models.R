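## Public model surface: configuration, construction, training, prediction.

#' Model and training configuration
#'
#' \code{modelConfig} describes one of the four sequence architectures:
#' a single-layer LSTM or GRU (200 units by default), a bidirectional LSTM
#' (200 units per direction, 400 total), or a 4-layer dilated 1-D CNN
#' (kernel 3, dilations 12/8/4/1, output channels 16/32/64/128). Every
#' architecture feeds a 128-unit linear layer and a 5-class softmax output.
#' \code{trainConfig} holds the optimization settings: Adam with
#' cross-entropy loss, 20 epochs, batch size 64, early stopping on the
#' validation loss with a patience of 3 epochs (best checkpoint restored).
#'
#' The \code{units = 64, epochs = 10} "small" settings keep synthetic-corpus
#' experiments fast while preserving the architecture.
#'
#' @param arch one of \code{"lstm"}, \code{"bilstm"}, \code{"gru"},
#'   \code{"cnn1d"}.
#' @param ni number of input channels (3, 6 or 7).
#' @param units recurrent units per direction (ignored for \code{cnn1d}).
#' @param headUnits width of the linear head (default 128).
#' @return \code{modelConfig}: a named list; \code{trainConfig}: a named
#'   list.
#' @examples
#' modelConfig("bilstm", ni = 6, units = 64)
#' @export
modelConfig <- function(arch = c("lstm", "bilstm", "gru", "cnn1d"), ni,
                        units = 200, headUnits = 128) {
  if (length(arch) != 1L || !arch %in% c("lstm", "bilstm", "gru", "cnn1d"))
    eqConfigError("unsupported architecture '%s'", paste(arch, collapse = "/"))
  if (!ni %in% c(3L, 6L, 7L))
    eqConfigError("ni must be 3, 6 or 7, got %d", ni)
  list(arch = arch, ni = as.integer(ni), units = as.integer(units),
       headUnits = as.integer(headUnits), nClasses = 5L,
       cnnDilations = c(12L, 8L, 4L, 1L),
       cnnChannels = c(16L, 32L, 64L, 128L))
}

#' @rdname modelConfig
#' @param epochs maximum training epochs.
#' @param batchSize minibatch size.
#' @param lr Adam step size.
#' @param patience early-stopping patience in epochs.
#' @param seed RNG seed controlling initialization and shuffling.
#' @export
trainConfig <- function(epochs = 20, batchSize = 64, lr = 1e-3,
                        patience = 3, seed = 1L) {
  if (epochs < 1 || batchSize < 1)
    eqConfigError("epochs and batchSize must be at least 1")
  list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
       lr = lr, patience = as.integer(patience), seed = as.integer(seed))
}

#' Build an untrained gait classifier
#'
#' Initializes the parameters of the configured architecture (Glorot-uniform
#' weights, forget-gate bias 1 for LSTM cells) deterministically from
#' \code{seed}.
#'
#' @param cfg a \code{\link{modelConfig}}.
#' @param seed initialization seed.
#' @return a \linkS4class{GaitClassifier}.
#' @export
buildModel <- function(cfg, seed = 1L) {
  set.seed(seed)
  params <- .initParams(cfg)
  new("GaitClassifier", arch = cfg$arch, params = params, config = cfg,
      norm = list(), history = data.frame())
}

.segTensor <- function(segments, norm = NULL) {
  X <- segmentArray(segments)
  if (!is.null(norm) && length(norm)) {
    for (j in seq_len(dim(X)[2]))
      X[, j, ] <- (X[, j, ] - norm$mu[j]) / norm$sd[j]
  }
  X
}

.channelStats <- function(segments) {
  X <- segmentArray(segments)
  mu <- apply(X, 2, mean)
  sd <- apply(X, 2, stats::sd)
  sd[sd < 1e-8] <- 1
  list(mu = mu, sd = sd)
}

#' Train a gait classifier
#'
#' Minimizes cross-entropy with Adam over minibatches for at most
#' \code{cfg$epochs} passes, monitoring the validation loss after every
#' epoch and restoring the parameters of the best epoch (early stopping,
#' patience \code{cfg$patience}). Input channels are standardized with
#' statistics computed on the training set only; the statistics travel with
#' the model and are re-applied at prediction time. Fully reproducible for
#' a fixed \code{cfg$seed}.
#'
#' @param model a \linkS4class{GaitClassifier} from \code{\link{buildModel}}.
#' @param train,val \linkS4class{SegmentSet}s with matching channel count.
#' @param cfg a \code{\link{trainConfig}}.
#' @param verbose print per-epoch losses.
#' @return the trained \linkS4class{GaitClassifier}; its
#'   \code{trainingHistory()} has one row per completed epoch.
#' @export
trainModel <- function(model, train, val, cfg, verbose = FALSE) {
  if (!nSegments(train)) eqInsufficientData("empty training set")
  if (!nSegments(val))
    eqConfigError("validation set empty with early stopping enabled")
  if (dim(segmentArray(train))[2] != model@config$ni)
    eqShapeError("training channels (%d) do not match model ni (%d)",
                 dim(segmentArray(train))[2], model@config$ni)
  set.seed(cfg$seed)
  norm <- .channelStats(train)
  Xtr <- .segTensor(train, norm)
  ytr <- as.integer(segmentLabels(train))
  Xva <- .segTensor(val, norm)
  yva <- as.integer(segmentLabels(val))
  params <- model@params
  state <- .adamInit(params)
  arch <- model@arch; mcfg <- model@config
  n <- dim(Xtr)[1]
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- list()
  wait <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batchSize))
    trLoss <- 0
    for (bi in batches) {
      Xb <- Xtr[bi, , , drop = FALSE]
      fw <- .modelForward(arch, params, mcfg, Xb)
      trLoss <- trLoss + .xentLoss(fw$probs, ytr[bi]) * length(bi)
      gr <- .modelBackward(arch, params, mcfg, fw$cache,
                           .xentGrad(fw$probs, ytr[bi]))
      upd <- .adamStep(params, gr, state, lr = cfg$lr)
      params <- upd$params; state <- upd$state
    }
    trLoss <- trLoss / n
    vp <- .batchedForward(arch, params, mcfg, Xva)
    vaLoss <- .xentLoss(vp, yva)
    vaAcc <- mean(max.col(vp, ties.method = "first") == yva)
    hist[[ep]] <- data.frame(epoch = ep, trainLoss = trLoss,
                             valLoss = vaLoss, valAcc = vaAcc)
    if (verbose)
      message(sprintf("epoch %2d  train %.4f  val %.4f  acc %.3f",
                      ep, trLoss, vaLoss, vaAcc))
    if (vaLoss < best$loss - 1e-9) {
      best <- list(loss = vaLoss, params = params, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  new("GaitClassifier", arch = arch, params = best$params, config = mcfg,
      norm = norm, history = do.call(rbind, hist))
}

.batchedForward <- function(arch, params, cfg, X, chunk = 256L) {
  n <- dim(X)[1]
  out <- matrix(0, n, cfg$nClasses)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    out[s:e, ] <- .modelForward(arch, params, cfg,
                                X[s:e, , , drop = FALSE])$probs
  }
  out
}

#' Per-segment class probabilities
#'
#' Runs the classifier over the segments in input order and returns the
#' softmax probability stream as a \linkS4class{ProbSeries} (times taken
#' from the segments' start times).
#'
#' @param model a \linkS4class{GaitClassifier}.
#' @param segments a \linkS4class{SegmentSet} with channel count matching
#'   the model.
#' @return a \linkS4class{ProbSeries}.
#' @export
predictProba <- function(model, segments) {
  if (dim(segmentArray(segments))[2] != model@config$ni)
    eqShapeError("segment channels (%d) do not match model ni (%d)",
                 dim(segmentArray(segments))[2], model@config$ni)
  X <- .segTensor(segments, model@norm)
  probs <- .batchedForward(model@arch, model@params, model@config, X)
  ProbSeries(segmentInfo(segments)$tStart, probs)
}

#' @rdname predictProba
#' @return \code{predictGait}: factor of argmax gaits in segment order.
#' @export
predictGait <- function(model, segments) {
  X <- .segTensor(segments, model@norm)
  probs <- .batchedForward(model@arch, model@params, model@config, X)
  gaitFactor(gaitLevels()[max.col(probs, ties.method = "first")])
}
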