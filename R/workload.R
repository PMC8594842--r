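#' @title Screening-burden calculator
#' @description
#' Converts a daily ECG screening volume, an AFib prevalence and two
#' algorithms' error rates into daily false-positive and false-negative
#' counts and their differences. Each algorithm's count is rounded (half
#' away from zero) *before* differencing; this per-term convention is what
#' makes burden figures internally consistent when quoted per algorithm.
#' @name workload
NULL

# round half away from zero (2686.5 -> 2687), unlike R's round-half-even
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Parse a prevalence value
#'
#' @param x a fraction in (0,1), or a string with an explicit percent
#'   suffix such as `"0.5%"`. A bare number >= 1 is rejected rather than
#'   guessed at.
#' @return prevalence as a fraction.
#' @export
parse_prevalence <- function(x) {
  if (is.character(x)) {
    if (!grepl("%$", trimws(x)))
      stop("prevalence string must carry an explicit % suffix, got '",
           x, "'")
    x <- as.numeric(sub("%$", "", trimws(x))) / 100
  }
  if (!is.finite(x) || x <= 0 || x >= 1)
    stop("prevalence must lie in (0,1), got ", x)
  x
}

#' Screening scenario
#'
#' @param volume_per_day number of ECG recordings per day.
#' @param prevalence AFib prevalence: fraction in (0,1) or string with a
#'   `%` suffix.
#' @return A `screening_scenario` with `n_pos`/`n_neg` daily AFib and
#'   non-AFib record counts (`n_pos = round(volume * prevalence)`).
#' @examples
#' scenario(100000, "0.5%")
#' @export
scenario <- function(volume_per_day, prevalence) {
  stopifnot(volume_per_day > 0, volume_per_day == round(volume_per_day))
  prevalence <- parse_prevalence(prevalence)
  n_pos <- as.integer(round_half_up(volume_per_day * prevalence))
  structure(list(volume_per_day = as.integer(volume_per_day),
                 prevalence = prevalence,
                 n_pos = n_pos,
                 n_neg = as.integer(volume_per_day) - n_pos),
            class = "screening_scenario")
}

#' Daily error counts of one algorithm
#'
#' @param scn a [scenario()].
#' @param fpr false-positive rate (1 - specificity), in \[0,1\].
#' @param fnr false-negative rate (1 - sensitivity), in \[0,1\].
#' @return list with integer `fp` and `fn` per day, rounded half away
#'   from zero.
#' @examples
#' daily_errors(scenario(100000, "0.5%"), fpr = 0.027, fnr = 0.071)
#' @export
daily_errors <- function(scn, fpr, fnr) {
  stopifnot(inherits(scn, "screening_scenario"),
            fpr >= 0, fpr <= 1, fnr >= 0, fnr <= 1)
  list(fp = as.integer(round_half_up(scn$n_neg * fpr)),
       fn = as.integer(round_half_up(scn$n_pos * fnr)))
}

#' Compare the daily burden of two algorithms
#'
#' @param scn a [scenario()].
#' @param rates_a,rates_b lists with `fpr` and `fnr` for the two
#'   algorithms (a = reference, e.g. the fusion; b = comparator).
#' @return A `workload_report`: per-algorithm `fp`/`fn` per day and the
#'   integer differences `delta_fp = fp_b - fp_a`,
#'   `delta_fn = fn_b - fn_a`, computed on the rounded per-algorithm
#'   counts.
#' @examples
#' compare_workload(scenario(100000, "0.5%"),
#'                  rates_a = list(fpr = 0.027, fnr = 0.071),
#'                  rates_b = list(fpr = 0.031, fnr = 0.084))
#' @export
compare_workload <- function(scn, rates_a, rates_b) {
  a <- daily_errors(scn, rates_a$fpr, rates_a$fnr)
  b <- daily_errors(scn, rates_b$fpr, rates_b$fnr)
  structure(list(scenario = scn, a = a, b = b,
                 delta_fp = b$fp - a$fp,
                 delta_fn = b$fn - a$fn),
            class = "workload_report")
}

#' @export
print.workload_report <- function(x, ...) {
  cat(sprintf("screening %d/day at prevalence %.3f%% (%d AFib, %d non-AFib)\n",
              x$scenario$volume_per_day, 100 * x$scenario$prevalence,
              x$scenario$n_pos, x$scenario$n_neg))
  cat(sprintf("  algorithm A: %5d FP/day, %4d FN/day\n", x$a$fp, x$a$fn))
  cat(sprintf("  algorithm B: %5d FP/day, %4d FN/day\n", x$b$fp, x$b$fn))
  cat(sprintf("  delta (B-A): %5d FP/day, %4d FN/day\n",
              x$delta_fp, x$delta_fn))
  invisible(x)
}
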