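#' Percentile-based autovalidation limits from historical results
#'
#' Computes an empirical percentile interval (default 5th-95th) of released
#' historical results, one of the standard approaches for setting an
#' autovalidation range that reflects the laboratory's own patient
#' population. The estimator is linear interpolation between order
#' statistics (`stats::quantile` type 7): with sorted values
#' \eqn{x_{(1)} \le \dots \le x_{(n)}}, the p-th percentile is
#' \eqn{x_{(k)} + g\,(x_{(k+1)} - x_{(k)})} where
#' \eqn{h = 1 + (n-1)p/100}, \eqn{k = \lfloor h \rfloor}, \eqn{g = h - k}.
#'
#' @param values Numeric vector of historical results; all entries must be
#'   finite and at least 20 are required.
#' @param p_low,p_high Percentile levels, `0 <= p_low < p_high <= 100`.
#' @return An [interval()].
#' @examples
#' percentile_limits(1:100) # [5.95, 95.05]
#' @export
percentile_limits <- function(values, p_low = 5, p_high = 95) {
  stopifnot(is.numeric(values))
  if (any(!is.finite(values))) {
    stop("non-finite values are not allowed in the history", call. = FALSE)
  }
  if (length(values) < 20L) {
    stop(sprintf("insufficient data: %d values (need >= 20)",
                 length(values)), call. = FALSE)
  }
  if (!(p_low >= 0 && p_low < p_high && p_high <= 100)) {
    stop("need 0 <= p_low < p_high <= 100", call. = FALSE)
  }
  q <- stats::quantile(values, probs = c(p_low, p_high) / 100, type = 7,
                       names = FALSE)
  interval(q[1L], q[2L])
}

#' Percentile-based delta limits from observed consecutive differences
#'
#' Same estimator as [percentile_limits()], applied to the empirical
#' distribution of same-patient consecutive differences collected within a
#' stated time window (see [paired_differences()]).
#'
#' @param paired_differences Numeric vector of same-patient differences
#'   (current minus prior), at least 20.
#' @inheritParams percentile_limits
#' @return An [interval()] for the acceptable (signed) difference.
#' @export
delta_percentile_limits <- function(paired_differences, p_low = 5,
                                    p_high = 95) {
  if (length(paired_differences) < 20L) {
    stop(sprintf("insufficient pairs: %d (need >= 20)",
                 length(paired_differences)), call. = FALSE)
  }
  percentile_limits(paired_differences, p_low, p_high)
}

#' Same-patient consecutive differences from a history table
#'
#' @param history Data frame with columns `patient_id`, `test_code`,
#'   `timestamp` (`POSIXct` or parseable), `value`.
#' @param test_code Test to extract.
#' @param window_days Maximum age of the prior result for a pair to count.
#' @return Numeric vector of `current - prior` differences.
#' @export
paired_differences <- function(history, test_code, window_days = 3) {
  stopifnot(is.data.frame(history),
            all(c("patient_id", "test_code", "timestamp", "value") %in%
                  names(history)))
  h <- history[history$test_code == test_code & is.finite(history$value), ,
               drop = FALSE]
  h$timestamp <- parse_timestamp(h$timestamp)
  diffs <- numeric()
  for (chunk in split(h, h$patient_id)) {
    if (nrow(chunk) < 2L) next
    chunk <- chunk[order(chunk$timestamp), , drop = FALSE]
    gap_h <- as.numeric(diff(chunk$timestamp), units = "hours")
    d <- diff(chunk$value)
    diffs <- c(diffs, d[gap_h > 0 & gap_h <= window_days * 24])
  }
  diffs
}

#' Midpoint limits between the reference-interval median and critical limits
#'
#' One of the catalogued approaches for an autovalidation range: each bound
#' is halfway between the median of the reference interval and the
#' corresponding critical limit.
#'
#' @param median_ri Median of the reference interval.
#' @param critical_limits An [interval()] with both bounds finite.
#' @return An [interval()].
#' @export
midpoint_limits <- function(median_ri, critical_limits) {
  stopifnot(is.finite(median_ri), inherits(critical_limits, "av_interval"),
            is_bounded(critical_limits$low), is_bounded(critical_limits$high))
  interval((median_ri + critical_limits$low) / 2,
           (median_ri + critical_limits$high) / 2)
}

#' Widen a reference interval by total allowable error
#'
#' Autovalidation range as reference-interval limits minus/plus total
#' allowable error (TEa). The TEa scale must be stated explicitly: on the
#' `"percent"` scale each bound moves by `|bound| * tea / 100`, on the
#' `"absolute"` scale by `tea` units.
#'
#' @param reference_interval An [interval()] with finite bounds.
#' @param tea Total allowable error (> 0), percent or units per `scale`.
#' @param scale `"percent"` or `"absolute"`.
#' @return A widened [interval()].
#' @export
tea_adjusted_limits <- function(reference_interval, tea,
                                scale = c("percent", "absolute")) {
  scale <- match.arg(scale)
  stopifnot(inherits(reference_interval, "av_interval"), is.finite(tea),
            tea > 0, is_bounded(reference_interval$low),
            is_bounded(reference_interval$high))
  lo <- reference_interval$low
  hi <- reference_interval$high
  if (scale == "percent") {
    interval(lo - abs(lo) * tea / 100, hi + abs(hi) * tea / 100)
  } else {
    interval(lo - tea, hi + tea)
  }
}

#' Propose autovalidation limits for a test
#'
#' Wraps the limit-setting approaches into an advisory `limit_proposal`.
#' Proposals are never applied automatically: writing them into an engine
#' configuration is a deliberate human step, since autovalidation criteria
#' must be documented and approved before use.
#'
#' @param test_code Test the proposal is for.
#' @param method One of `"percentile"`, `"reference_interval"`,
#'   `"critical"`, `"clinical_cutoff"`, `"consensus"`, `"literature"`,
#'   `"midpoint"`, `"tea"`.
#' @param values Historical values (required for `"percentile"`).
#' @param interval_in Supplied [interval()] (for interval-echoing methods;
#'   for `"midpoint"`/`"tea"` the critical limits / reference interval).
#' @param p_low,p_high Percentile levels for `"percentile"`.
#' @param median_ri Reference-interval median for `"midpoint"`.
#' @param tea,tea_scale Total allowable error and its scale for `"tea"`.
#' @return A `limit_proposal`: `test_code`, `method`, `interval`, `n_used`,
#'   `parameters`.
#' @export
propose_limits <- function(test_code, method, values = NULL,
                           interval_in = NULL, p_low = 5, p_high = 95,
                           median_ri = NULL, tea = NULL,
                           tea_scale = "percent") {
  method <- match.arg(method, c("percentile", "reference_interval",
                                "critical", "clinical_cutoff", "consensus",
                                "literature", "midpoint", "tea"))
  need_iv <- function() {
    if (is.null(interval_in) || !inherits(interval_in, "av_interval")) {
      stop(sprintf("method '%s' requires interval_in", method),
           call. = FALSE)
    }
    interval_in
  }
  out <- switch(method,
    percentile = {
      if (is.null(values)) stop("method 'percentile' requires values",
                                call. = FALSE)
      list(interval = percentile_limits(values, p_low, p_high),
           n_used = length(values),
           parameters = list(p_low = p_low, p_high = p_high))
    },
    midpoint = {
      if (is.null(median_ri)) stop("method 'midpoint' requires median_ri",
                                   call. = FALSE)
      list(interval = midpoint_limits(median_ri, need_iv()),
           n_used = NA_integer_, parameters = list(median_ri = median_ri))
    },
    tea = {
      if (is.null(tea)) stop("method 'tea' requires tea", call. = FALSE)
      list(interval = tea_adjusted_limits(need_iv(), tea, tea_scale),
           n_used = NA_integer_,
           parameters = list(tea = tea, scale = tea_scale))
    },
    # reference_interval / critical / clinical_cutoff / consensus /
    # literature: the supplied interval is the proposal
    list(interval = need_iv(), n_used = NA_integer_, parameters = list()))
  structure(list(test_code = test_code, method = method,
                 interval = out$interval, n_used = out$n_used,
                 parameters = out$parameters),
            class = "limit_proposal")
}

#' @export
print.limit_proposal <- function(x, ...) {
  cat(sprintf("<limit_proposal> %s via %s: [%g, %g]%s\n", x$test_code,
              x$method, x$interval$low, x$interval$high,
              if (!is.na(x$n_used)) sprintf(" (n = %d)", x$n_used) else ""))
  cat("  advisory only: apply by editing the engine configuration\n")
  invisible(x)
}

#' Write a limit proposal to a JSON report file
#' @param proposal A `limit_proposal`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proposal <- function(proposal, path) {
  stopifnot(inherits(proposal, "limit_proposal"))
  jsonlite::write_json(
    list(test_code = proposal$test_code, method = proposal$method,
         low = proposal$interval$low, high = proposal$interval$high,
         n_used = proposal$n_used, parameters = proposal$parameters),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}
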