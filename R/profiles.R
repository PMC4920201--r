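#' Elongation profile: position-dependent polymerase speed
#'
#' Describes how fast the transcription machinery moves through a gene body as
#' an ordered set of segments starting at the TSS, each with a length in bp
#' and a constant speed in kb/min. A single segment models the classic
#' constant-rate picture (around 1.4--2 kb/min for human Pol II); several
#' segments with increasing rates model acceleration along the gene body.
#'
#' @param lengths_bp numeric vector of segment lengths (bp), all > 0
#' @param rates_kb_min numeric vector of segment speeds (kb/min), all > 0,
#'   same length as `lengths_bp`
#' @return an object of class `elongation_profile`
#' @examples
#' elongation_profile(3e5, 2.0)                      # constant 2 kb/min
#' elongation_profile(c(3e4, 2e5), c(1.0, 2.0))      # accelerating
#' @export
elongation_profile <- function(lengths_bp, rates_kb_min) {
  if (length(lengths_bp) != length(rates_kb_min) || !length(lengths_bp))
    stopf("lengths_bp and rates_kb_min must be non-empty and equal length")
  if (any(!is.finite(lengths_bp)) || any(lengths_bp <= 0))
    stopf("segment lengths must be positive")
  if (any(!is.finite(rates_kb_min)) || any(rates_kb_min <= 0))
    stopf("segment rates must be positive")
  # knots: cumulative position (bp) and cumulative travel time (min)
  cum_bp <- c(0, cumsum(lengths_bp))
  cum_min <- c(0, cumsum((lengths_bp / 1000) / rates_kb_min))
  structure(list(lengths_bp = lengths_bp, rates_kb_min = rates_kb_min,
                 cum_bp = cum_bp, cum_min = cum_min),
            class = "elongation_profile")
}

#' @export
print.elongation_profile <- function(x, ...) {
  cat("elongation_profile:", length(x$lengths_bp), "segment(s),",
      "total", sum(x$lengths_bp), "bp\n")
  invisible(x)
}

#' Travel time from the TSS to a position
#'
#' Time (min) for a polymerase to move from the TSS to position `x` bp
#' downstream, integrating the piecewise-constant speed field. Strictly
#' increasing and piecewise linear in `x`.
#'
#' @param profile an [elongation_profile()]
#' @param x position(s) in bp downstream of the TSS; must lie within the
#'   profile's total length
#' @return travel time(s) in minutes
#' @export
travel_time <- function(profile, x) {
  stopifnot(inherits(profile, "elongation_profile"))
  total <- profile$cum_bp[length(profile$cum_bp)]
  if (any(x < 0 | x > total))
    stopf("position out of range [0, %g] bp", total)
  stats::approx(profile$cum_bp, profile$cum_min, xout = x,
                method = "linear", ties = "ordered")$y
}

#' Position of the transcription wave front at time t
#'
#' Inverse of [travel_time()]: the position (bp downstream of the TSS) reached
#' by a polymerase that initiated `t` minutes ago, capped at `cap_bp`
#' (typically the gene length). This is the model's "leading edge of the
#' transcription wave".
#'
#' @param profile an [elongation_profile()]
#' @param t elapsed time(s) in minutes, >= 0
#' @param cap_bp cap for the returned position; default = profile length
#' @return front position(s) in bp
#' @export
front_position <- function(profile, t, cap_bp = NULL) {
  stopifnot(inherits(profile, "elongation_profile"))
  if (any(t < 0)) stopf("t must be >= 0")
  total <- profile$cum_bp[length(profile$cum_bp)]
  cap_bp <- cap_bp %||% total
  tmax <- profile$cum_min[length(profile$cum_min)]
  x <- stats::approx(profile$cum_min, profile$cum_bp, xout = pmin(t, tmax),
                     method = "linear", ties = "ordered")$y
  pmin(x, cap_bp)
}

#' Initiation profile: piecewise-constant initiation rate over time
#'
#' The initiation rate I(t) (initiations/min) is `baseline_rate` for all
#' t < first change time (the starved steady state, assumed to have held
#' forever), then steps to `baseline_rate * fold_factors[i]` at
#' `change_times[i]`. Named patterns are conveniences that fill in the
#' canonical epoch structure; times are minutes relative to serum addition
#' (t = 0).
#'
#' Patterns (fold applied at the stated onset):
#' \describe{
#'   \item{constant}{no change, steady state throughout}
#'   \item{sustained_up / sustained_down}{step at `onset_time`, held}
#'   \item{transient_up / transient_down}{step at `onset_time`, back to
#'     baseline at `off_time`}
#'   \item{delayed_up / delayed_down}{as sustained but `onset_time` defaults
#'     to 30 min (second labeling window)}
#'   \item{reversal}{up by `fold` at `onset_time`, then down to
#'     `baseline/fold` at `off_time` (up-then-down order)}
#' }
#'
#' @param baseline_rate starved steady-state initiation rate (initiations/min)
#' @param pattern one of the named temporal patterns above
#' @param fold fold change applied by the pattern (> 0); for "_down" patterns
#'   the rate is divided by `fold`
#' @param onset_time minutes after serum addition at which the change starts
#' @param off_time minutes at which transient patterns revert / reversal flips
#' @param change_times,fold_factors explicit epoch structure overriding the
#'   named pattern (advanced use)
#' @param epoch_rates absolute epoch rates (initiations/min) used instead of
#'   `baseline_rate * fold_factors`; required to express switch-on from a
#'   silent baseline (baseline 0) or complete shut-off (rate 0)
#' @return an object of class `init_profile` with `times` (epoch boundaries)
#'   and `rates` (length `length(times) + 1`, first entry = rate before the
#'   first boundary)
#' @export
init_profile <- function(baseline_rate, pattern = "constant", fold = 3,
                         onset_time = 0, off_time = 30,
                         change_times = NULL, fold_factors = NULL,
                         epoch_rates = NULL) {
  if (!is.finite(baseline_rate) || baseline_rate < 0)
    stopf("baseline_rate must be >= 0")
  if (fold <= 0) stopf("fold must be > 0")
  patterns <- c("constant", "sustained_up", "sustained_down", "transient_up",
                "transient_down", "delayed_up", "delayed_down", "reversal")
  pattern <- match.arg(pattern, patterns)
  if (is.null(change_times)) {
    if (pattern %in% c("delayed_up", "delayed_down") && missing(onset_time))
      onset_time <- 30
    cf <- switch(pattern,
      constant       = list(times = numeric(0), facs = numeric(0)),
      sustained_up   = list(times = onset_time, facs = fold),
      sustained_down = list(times = onset_time, facs = 1 / fold),
      delayed_up     = list(times = onset_time, facs = fold),
      delayed_down   = list(times = onset_time, facs = 1 / fold),
      transient_up   = list(times = c(onset_time, off_time), facs = c(fold, 1)),
      transient_down = list(times = c(onset_time, off_time), facs = c(1 / fold, 1)),
      reversal       = list(times = c(onset_time, off_time), facs = c(fold, 1 / fold)))
    change_times <- cf$times
    fold_factors <- cf$facs
  } else {
    if (is.null(epoch_rates) && length(fold_factors) != length(change_times))
      stopf("fold_factors must match change_times")
  }
  if (length(change_times) && any(diff(change_times) <= 0))
    stopf("change_times must be strictly increasing")
  rates <- if (!is.null(epoch_rates)) {
    if (length(epoch_rates) != length(change_times))
      stopf("epoch_rates must match change_times")
    c(baseline_rate, epoch_rates)
  } else {
    baseline_rate * c(1, fold_factors)
  }
  if (any(rates < 0)) stopf("rates must be >= 0 in every epoch")
  structure(list(baseline_rate = baseline_rate, pattern = pattern,
                 times = change_times, rates = rates),
            class = "init_profile")
}

#' @export
print.init_profile <- function(x, ...) {
  cat("init_profile:", x$pattern, "| baseline", x$baseline_rate, "/min")
  if (length(x$times))
    cat(" | epochs at", paste(x$times, collapse = ","), "min")
  cat("\n")
  invisible(x)
}

# Cumulative initiation J(t) = number of initiations expected in (-inf, t]
# relative to J(0) = 0; piecewise linear with slopes = epoch rates. Vectorized.
cum_initiation <- function(init, t) {
  knots_t <- c(init$times)
  if (!length(knots_t)) return(init$rates[[1]] * t)
  # J at each knot, anchored so J(first knot) = rate0 * knot (J(0)=0 under
  # the convention that rate0 held for all t < knot; knots may be negative)
  Jk <- numeric(length(knots_t))
  Jk[1] <- init$rates[[1]] * knots_t[[1]]
  if (length(knots_t) > 1)
    for (i in 2:length(knots_t))
      Jk[i] <- Jk[i - 1] + init$rates[[i]] * (knots_t[[i]] - knots_t[[i - 1]])
  idx <- findInterval(t, knots_t)  # 0 = before first knot
  rate <- init$rates[idx + 1]
  base <- c(0, Jk)[idx + 1]
  tprev <- c(0, knots_t)[idx + 1]  # first entry unused when idx==0 handled below
  out <- ifelse(idx == 0,
                init$rates[[1]] * t,
                base + rate * (t - tprev))
  out
}

# Instantaneous initiation rate I(t); vectorized.
initiation_rate <- function(init, t) {
  if (!length(init$times)) return(rep(init$rates[[1]], length(t)))
  init$rates[findInterval(t, init$times) + 1]
}

#' Labeling scheme: the pulse windows of the experiment
#'
#' Non-overlapping, equal-duration labeling windows in minutes relative to
#' serum addition. The default matches the experimental design: one starved
#' baseline window (labeled before stimulation, at steady state) plus four
#' 30-min windows tiling the first two hours.
#'
#' @param starts,ends window boundaries in minutes; equal durations required
#' @param names window names
#' @return a data.frame with columns name, start, end
#' @export
labeling_scheme <- function(starts = c(-30, 0, 30, 60, 90),
                            ends = starts + 30,
                            names = c("starved", "w0_30", "w30_60",
                                      "w60_90", "w90_120")) {
  if (length(starts) != length(ends) || length(starts) != length(names))
    stopf("starts, ends, names must have equal length")
  dur <- ends - starts
  if (any(dur <= 0)) stopf("window duration must be > 0")
  if (length(unique(round(dur, 9))) != 1)
    stopf("all labeling windows must have equal duration")
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]; names <- names[o]
  if (any(starts[-1] < ends[-length(ends)]))
    stopf("labeling windows must not overlap")
  data.frame(name = names, start = starts, end = ends,
             stringsAsFactors = FALSE)
}
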