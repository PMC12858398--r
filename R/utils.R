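## Shared logging and validation helpers.
##
## All warnings and non-fatal data drops are routed through ss_log() so that
## nothing is silently discarded; messages go to standard error.

.log_levels <- c(DEBUG = 10L, INFO = 20L, WARN = 30L, ERROR = 40L)

#' Set the package log level
#'
#' Messages below the chosen level are suppressed. The default is `"INFO"`.
#'
#' @param level One of `"DEBUG"`, `"INFO"`, `"WARN"`, `"ERROR"`.
#' @return The previous level, invisibly.
#' @export
set_log_level <- function(level = c("INFO", "DEBUG", "WARN", "ERROR")) {
  level <- match.arg(level)
  old <- getOption("screenselect.log_level", "INFO")
  options(screenselect.log_level = level)
  invisible(old)
}

ss_log <- function(level, fmt, ...) {
  threshold <- .log_levels[[getOption("screenselect.log_level", "INFO")]]
  if (.log_levels[[level]] >= threshold) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
  invisible(NULL)
}

## Stop with a message naming the offending field; used by config validators.
fail_field <- function(field, why) {
  stop(sprintf("invalid configuration field '%s': %s", field, why), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    fail_field(field, sprintf("must be a single integer >= %d", min))
  }
  as.integer(x)
}

check_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    fail_field(field, "must be a single number in [0, 1]")
  }
  as.numeric(x)
}

check_positive <- function(x, field, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) fail_field(field, if (strict) "must be > 0" else "must be >= 0")
  as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
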