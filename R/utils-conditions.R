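## Classed conditions so callers can distinguish failure modes programmatically.
## Every user-facing error in the package goes through one of these.

eqStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "eqError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

eqFormatError       <- function(fmt, ...) eqStop("eqFormatError", fmt, ...)
eqIntegrityError    <- function(fmt, ...) eqStop("eqIntegrityError", fmt, ...)
eqVocabularyError   <- function(fmt, ...) eqStop("eqVocabularyError", fmt, ...)
eqInsufficientData  <- function(fmt, ...) eqStop("eqInsufficientDataError", fmt, ...)
eqNormalizationErr  <- function(fmt, ...) eqStop("eqNormalizationError", fmt, ...)
eqFrameError        <- function(fmt, ...) eqStop("eqFrameError", fmt, ...)
eqConfigError       <- function(fmt, ...) eqStop("eqConfigError", fmt, ...)
eqShapeError        <- function(fmt, ...) eqStop("eqShapeError", fmt, ...)
eqMissingChannel    <- function(fmt, ...) eqStop("eqMissingChannelError", fmt, ...)
eqMetricError       <- function(fmt, ...) eqStop("eqMetricError", fmt, ...)
eqCoverageError     <- function(fmt, ...) eqStop("eqCoverageError", fmt, ...)
eqUndefinedHeading  <- function(fmt, ...) eqStop("eqUndefinedHeadingError", fmt, ...)
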