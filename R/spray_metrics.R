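# Spray-trial accounting. A trial area contains n_total weeds; the vision
# system identifies n_identified of them; n_hit water-sensitive labels turn
# red. Three rates summarise a pass:
#   effective recognition rate  u      = n_identified / n_total
#   relative hit rate           w_rel  = n_hit / n_identified
#   absolute hit rate           w_abs  = n_hit / n_total = u * w_rel

# report a rate in [0,1] as a percentage truncated to 2 decimals (the
# published trial-table convention); tiny epsilon guards fp representation
percent_floor <- function(rate) {
  floor(100 * rate * 100 + 1e-9) / 100
}

#' Trial counts
#'
#' @param n_total weeds present in the trial area.
#' @param n_identified weeds identified by the detector (at least once).
#' @param n_hit weeds whose water-sensitive label turned red.
#' @return an object of class `trial_counts`.
#' @export
trial_counts <- function(n_total, n_identified, n_hit) {
  for (v in list(n_total, n_identified, n_hit)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        v != round(v)) {
      stop_config("trial counts must be single non-negative whole numbers")
    }
  }
  if (!(n_hit <= n_identified && n_identified <= n_total)) {
    stop_config("need n_hit <= n_identified <= n_total")
  }
  structure(list(n_total = as.integer(n_total),
                 n_identified = as.integer(n_identified),
                 n_hit = as.integer(n_hit)),
            class = "trial_counts")
}

#' Spray rates from trial counts
#'
#' Computes the effective recognition rate, relative hit rate and absolute
#' hit rate from raw counts. Rates are returned unrounded in `[0, 1]`;
#' the matching percentages in `percent` are truncated (floored) to 2
#' decimals, the convention used in published trial tables (e.g. 89/103 =
#' 86.4078% is reported as 86.40). When no weed was identified the
#' relative hit rate is undefined; it is reported as 0 with
#' `degenerate = TRUE`.
#'
#' @param counts a [trial_counts()] object.
#' @return an object of class `trial_rates`: list with `u`, `w_rel`,
#'   `w_abs`, `percent` (named numeric vector), `degenerate`, `counts`.
#' @examples
#' rates_from_counts(trial_counts(87, 83, 79))$percent
#' @export
rates_from_counts <- function(counts) {
  stopifnot(inherits(counts, "trial_counts"))
  if (counts$n_total == 0L) {
    stop_config("undefined trial: n_total must be positive",
                class = "spotspray_undefined_trial")
  }
  degenerate <- counts$n_identified == 0L
  u <- counts$n_identified / counts$n_total
  w_rel <- if (degenerate) 0 else counts$n_hit / counts$n_identified
  w_abs <- counts$n_hit / counts$n_total
  structure(list(
    u = u, w_rel = w_rel, w_abs = w_abs,
    percent = c(u = percent_floor(u),
                w_rel = percent_floor(w_rel),
                w_abs = percent_floor(w_abs)),
    degenerate = degenerate,
    counts = counts), class = "trial_rates")
}

#' @export
print.trial_rates <- function(x, ...) {
  cat(sprintf(paste0(
    "<trial_rates> %d weeds, %d identified, %d hit\n",
    "  effective recognition rate u     = %6.2f%%\n",
    "  relative hit rate          w'    = %6.2f%%%s\n",
    "  absolute hit rate          w     = %6.2f%%\n"),
    x$counts$n_total, x$counts$n_identified, x$counts$n_hit,
    x$percent[["u"]], x$percent[["w_rel"]],
    if (x$degenerate) " (degenerate: nothing identified)" else "",
    x$percent[["w_abs"]]))
  invisible(x)
}

#' Compose the absolute hit rate from its two factors
#'
#' The absolute hit rate is the product of the effective recognition rate
#' and the relative hit rate: `w = u * w'`. On unrounded rates this is an
#' exact identity with the direct ratio `n_hit / n_total`; on percentages
#' truncated to 2 decimals the composition can differ from the direct
#' ratio by up to ~0.02 percentage points.
#'
#' @param u effective recognition rate in `[0, 1]`.
#' @param w_rel relative hit rate in `[0, 1]`.
#' @return the absolute hit rate `u * w_rel`.
#' @examples
#' compose_absolute(0.9540, 0.9518)  # ~0.9080
#' @export
compose_absolute <- function(u, w_rel) {
  stopifnot(is.numeric(u), is.numeric(w_rel),
            all(u >= 0 & u <= 1), all(w_rel >= 0 & w_rel <= 1))
  u * w_rel
}

#' Tabulate trial results across speeds
#'
#' Formats one row per pass in the conventional field-trial layout:
#' speed, counts, and the three percentage rates.
#'
#' @param counts_by_speed named list of [trial_counts()]; names are
#'   forward speeds in km/h.
#' @return a data.frame with one row per speed.
#' @export
trial_table <- function(counts_by_speed) {
  stopifnot(is.list(counts_by_speed), length(counts_by_speed) > 0)
  rows <- lapply(names(counts_by_speed), function(sp) {
    r <- rates_from_counts(counts_by_speed[[sp]])
    data.frame(speed_kmh = as.numeric(sp),
               n_total = r$counts$n_total,
               n_identified = r$counts$n_identified,
               recognition_rate_pct = r$percent[["u"]],
               n_hit = r$counts$n_hit,
               relative_hit_rate_pct = r$percent[["w_rel"]],
               absolute_hit_rate_pct = r$percent[["w_abs"]])
  })
  do.call(rbind, rows)
}
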