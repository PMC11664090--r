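#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Internal stop with class so callers can distinguish error families
#' @noRd
mvc_stop <- function(msg, class) {
  stop(structure(class = c(class, "mvc_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

mvc_io_error <- function(msg) mvc_stop(msg, "mvc_io_error")
mvc_validation_error <- function(msg) mvc_stop(msg, "mvc_validation_error")
mvc_config_error <- function(msg) mvc_stop(msg, "mvc_config_error")
mvc_training_error <- function(msg) mvc_stop(msg, "mvc_training_error")

#' Timestamped stage logging used by the pipeline driver
#' @noRd
mvc_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    paste0(..., collapse = "")))
  }
  invisible(NULL)
}

#' md5 of an arbitrary R object (serialized with fixed version)
#' @noRd
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

#' Canonicalize a label vector to 0-based contiguous integers
#'
#' Cluster and domain labels coming from files or clusterers can be
#' arbitrary integers, factors or strings.  Metrics and consensus need a
#' comparable space, so labels are mapped to `0..K-1` in order of first
#' appearance.
#'
#' @param labels vector of labels (any atomic type)
#' @return integer vector in `0..K-1`
#' @export
canonicalize_labels <- function(labels) {
  if (anyNA(labels)) mvc_validation_error("labels contain NA")
  u <- unique(labels)
  as.integer(match(labels, u) - 1L)
}
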