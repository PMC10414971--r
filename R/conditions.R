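## Classed conditions used across the package. Each stage signals a condition
## whose class states what went wrong, so callers (and tests) can distinguish
## a malformed input from a numerical breakdown without parsing messages.

gpStop <- function(class, message, call. = sys.call(-1)) {
  stop(structure(
    class = c(class, "gpError", "error", "condition"),
    list(message = message, call = call.)
  ))
}

inputShapeError  <- function(msg) gpStop("InputShapeError", msg)
inputValueError  <- function(msg) gpStop("InputValueError", msg)
designError      <- function(msg) gpStop("DesignError", msg)
configError      <- function(msg) gpStop("ConfigError", msg)
meshError        <- function(msg) gpStop("MeshError", msg)
samplingError    <- function(msg) gpStop("SamplingError", msg)
parcellationError<- function(msg) gpStop("ParcellationError", msg)
graphError       <- function(msg) gpStop("GraphError", msg)
numericalError   <- function(msg) gpStop("NumericalError", msg)
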