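#' @keywords internal
"_PACKAGE"

#' Round half away from zero
#'
#' Fixed-point rounding where ties go up (`0.905 -> 0.91`), matching how
#' field-trial percentages are conventionally reported. Base `round()` uses
#' round-half-to-even, which would print e.g. 92.5 as 92.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Derive a module-specific RNG seed from a global seed
#'
#' One user-facing seed fans out deterministically to independent sub-seeds,
#' one per pipeline stage, so adding a stage never perturbs the random
#' stream of an earlier one. The derivation hashes the tag characters into
#' a 31-bit integer.
#'
#' @param seed integer global seed.
#' @param tag character scalar naming the consumer (e.g. `"scene"`).
#' @return a positive integer seed below `2^31`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.character(tag), length(tag) == 1L)
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(tag)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

# stop() with a classed condition so callers can distinguish config errors
stop_config <- function(msg, class = "spotspray_config_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop_config(sprintf("`%s` must be a single positive number, got %s",
                        name, deparse(substitute(x))))
  }
  invisible(x)
}
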