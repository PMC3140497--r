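# Internal helpers shared across the pipeline.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; displayed percentages and the
#' extraction interval follow the conventional half-up rule instead, so that
#' e.g. 18.5 renders as 19.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, sprintf(...)), call. = FALSE)
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

# Parse Y/N/true/false/1/0 (case-insensitive) into logical; NA if unparseable.
parse_flag <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("y", "yes", "true", "t", "1")] <- TRUE
  out[x %in% c("n", "no", "false", "f", "0")] <- FALSE
  out
}

# Canonical family key: trimmed, title case.  The UNKNOWN sentinel (any case)
# stays upper case so it can never collide with a real taxon name.
normalize_family <- function(x) {
  x <- trimws(as.character(x))
  out <- ifelse(nchar(x) == 0, x,
                paste0(toupper(substr(x, 1, 1)), tolower(substring(x, 2))))
  out[toupper(x) == "UNKNOWN"] <- "UNKNOWN"
  out
}
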