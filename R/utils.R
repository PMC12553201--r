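#' @keywords internal
"_PACKAGE"

# Inverse logit / logit shorthands used throughout the likelihoods.
expit <- stats::plogis
logit <- stats::qlogis

#' Signal a configuration error
#'
#' All user-facing configuration problems (invalid probabilities, empty year
#' ranges, malformed catalogues) raise a condition of class
#' `morbcompress_config_error` so callers can distinguish them from numeric
#' failures.
#'
#' @param msg character message.
#' @noRd
stop_config <- function(msg) {
  stop(errorCondition(msg, class = c("morbcompress_config_error", "error", "condition")))
}

#' Deterministic hash of an R object
#'
#' Serializes the object to a temporary file and returns its MD5 digest.
#' Used for run metadata so a report records exactly which configuration
#' produced it.
#'
#' @param x any serializable R object.
#' @return a character scalar (32 hex digits).
#' @noRd
object_hash <- function(x) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f), add = TRUE)
  # Deparse rather than serialize: the binary serialization is sensitive to
  # internal vector representation (e.g. compact sequences), which would
  # make the hash depend on how a configuration was constructed.
  writeLines(deparse(x, control = c("exact", "showAttributes")), f)
  unname(tools::md5sum(f))
}
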