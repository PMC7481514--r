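#' @keywords internal
"_PACKAGE"

# Run code under a local RNG state seeded with `seed`, restoring the caller's
# .Random.seed afterwards so generators are pure functions of (args, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage seed below 2^31, derived from a master seed and a
# stage label so independent stages draw from independent streams.
derive_seed <- function(master_seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(master_seed) * 7919 + h) %% 2147483647)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    stop(sprintf("`%s` must be a positive integer (got %s)", name,
                 paste(format(x), collapse = ",")), call. = FALSE)
  }
  as.integer(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  x
}

#' Log a pipeline message
#'
#' Messages go to the console via [message()] and, when a log file has been
#' registered with `ryenue_log_file()`, are appended to that file with a
#' severity tag. Used throughout the pipeline for WARN/ERROR bookkeeping of
#' flagged observations.
#'
#' @param msg character message.
#' @param level one of `"INFO"`, `"WARN"`, `"ERROR"`.
#' @return `invisible(msg)`.
#' @export
ryenue_log <- function(msg, level = c("INFO", "WARN", "ERROR")) {
  level <- match.arg(level)
  line <- sprintf("[%s] %s", level, msg)
  file <- getOption("ryeNUE.log_file", NULL)
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE, sep = "")
  if (level == "ERROR") message(line) else if (!isTRUE(getOption("ryeNUE.quiet", FALSE))) message(line)
  invisible(msg)
}

#' Register a log file for pipeline messages
#'
#' @param path file path, or `NULL` to disable file logging.
#' @return previous value, invisibly.
#' @export
ryenue_log_file <- function(path) {
  old <- getOption("ryeNUE.log_file", NULL)
  options(ryeNUE.log_file = path)
  invisible(old)
}
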