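#' Delta-check difference calculations
#'
#' The four common forms of the consecutive-result comparison. The absolute
#' difference suits analytes held within tight homeostatic limits (e.g.
#' electrolytes); the percent difference suits measurands with wide dynamic
#' range (enzymes); the rate of change suits measurands whose velocity is
#' clinically meaningful (creatinine in acute kidney injury, troponin); the
#' RCV form bounds the percent difference by the reference change value.
#'
#' The percent denominator is always the PRIOR value: change is expressed
#' relative to the patient's previous state, so `delta_percent` is not
#' symmetric in its arguments (while `|delta_absolute(a, b)|` is).
#'
#' @param current,prior Finite numeric results, current and most recent
#'   prior.
#' @return `delta_absolute`: `current - prior` in test units.
#' @examples
#' delta_absolute(4.8, 4.0) # 0.8
#' delta_percent(110, 100)  # 10
#' delta_rate(120, 100, 10) # 2 per hour
#' @export
delta_absolute <- function(current, prior) {
  stopifnot(is.finite(current), is.finite(prior))
  current - prior
}

#' @rdname delta_absolute
#' @return `delta_percent`: `100 * (current - prior) / prior`, percent.
#' @export
delta_percent <- function(current, prior) {
  stopifnot(is.finite(current), is.finite(prior))
  if (prior == 0) {
    stop("delta_undefined: percent difference undefined for prior = 0",
         call. = FALSE)
  }
  100 * (current - prior) / prior
}

#' @rdname delta_absolute
#' @param interval_hours Elapsed time between the two results, hours (> 0).
#' @return `delta_rate`: `(current - prior) / interval_hours`, units/hour.
#' @export
delta_rate <- function(current, prior, interval_hours) {
  stopifnot(is.finite(current), is.finite(prior))
  if (!is.finite(interval_hours) || interval_hours <= 0) {
    stop("interval_hours must be > 0 (duplicate or misordered timestamps?)",
         call. = FALSE)
  }
  (current - prior) / interval_hours
}

#' Reference change value
#'
#' The smallest difference between two serial results that exceeds combined
#' analytical and within-subject biological variation at the chosen
#' confidence (classical form):
#' \deqn{RCV = \sqrt{2}\, z \sqrt{CV_a^2 + CV_i^2}}
#'
#' @param cv_analytical Analytical CV, percent (>= 0).
#' @param cvi Within-subject biological CV, percent (>= 0).
#' @param z Z multiplier (> 0); 1.96 gives a two-sided 95% limit.
#' @return RCV in percent.
#' @examples
#' reference_change_value(3, 4) # sqrt(2) * 1.96 * 5
#' @export
reference_change_value <- function(cv_analytical, cvi, z = 1.96) {
  stopifnot(is.finite(cv_analytical), cv_analytical >= 0,
            is.finite(cvi), cvi >= 0, is.finite(z), z > 0)
  sqrt(2) * z * sqrt(cv_analytical^2 + cvi^2)
}

#' Index of individuality
#'
#' The ratio of within-subject to between-subject biological variation,
#' `CVi / CVg`. A low index (conventionally below 0.6) means an individual's
#' results occupy a narrow band relative to the population, so a
#' population-based reference interval is insensitive to change within one
#' patient and the delta check is correspondingly informative.
#'
#' @param cvi Within-subject CV (percent), or a [biological_variation()]
#'   object (then `cvg` is taken from it).
#' @param cvg Between-subject CV, percent (> 0).
#' @return The dimensionless index.
#' @examples
#' individuality_index(4.4, 16.2) # creatinine, ~0.27
#' @export
individuality_index <- function(cvi, cvg) {
  if (inherits(cvi, "biological_variation")) {
    cvg <- cvi$cvg
    cvi <- cvi$cvi
  }
  stopifnot(is.numeric(cvi), is.numeric(cvg))
  if (any(!is.finite(cvg)) || any(cvg <= 0)) {
    stop("cvg must be > 0", call. = FALSE)
  }
  cvi / cvg
}

#' Select delta-check candidate measurands by index of individuality
#'
#' Applies the conventional II threshold: measurands whose index of
#' individuality is strictly below `threshold` (default 0.6) are worthwhile
#' delta-check candidates; the rest vary too much within subjects relative
#' to the population for a consecutive-result comparison to discriminate.
#'
#' @param table A data frame with columns `measurand`, `cvi`, `cvg` (such as
#'   the packaged biological-variation fixture, see [read_biovar()]).
#' @param threshold II cut-off (strict `<`).
#' @return The qualifying rows with a computed `ii` column, sorted ascending
#'   by `ii` (most individual first).
#' @export
select_delta_candidates <- function(table, threshold = 0.6) {
  stopifnot(is.data.frame(table),
            all(c("measurand", "cvi", "cvg") %in% names(table)))
  if (!nrow(table)) {
    return(data.frame(measurand = character(), cvi = numeric(),
                      cvg = numeric(), ii = numeric(),
                      stringsAsFactors = FALSE))
  }
  ii <- individuality_index(table$cvi, table$cvg)
  out <- data.frame(measurand = table$measurand, cvi = table$cvi,
                    cvg = table$cvg, ii = ii, stringsAsFactors = FALSE)
  out <- out[out$ii < threshold, , drop = FALSE]
  out <- out[order(out$ii), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Delta-check rule: compare against the most recent eligible prior
#'
#' Selects the most recent prior result strictly older than the record and
#' no older than the configured look-back window. With no eligible prior the
#' rule is skipped (a result out of the delta time interval autovalidates
#' when every other criterion is met). Otherwise the configured difference
#' is computed and the rule HOLDs iff its magnitude strictly exceeds the
#' limit — equality with the limit passes, consistent with the engine's
#' inclusive-PASS boundary convention. For `rcv` mode the limit is the
#' computed reference change value and the difference is a percent of the
#' prior value.
#'
#' @param record The current [result_record()].
#' @param history List of prior [result_record()]s, same patient and test.
#' @param cfg The test's [delta_config()], or `NULL` (rule skipped).
#' @param testdef The [test_definition()] (supplies `biovar` for rcv mode).
#' @return A [rule_outcome()]; when a comparison was made it carries a
#'   `delta` field: `mode`, `value`, `limit`, `prior_value`, `prior_time`,
#'   `interval_hours`, `exceeded`.
#' @export
evaluate_delta <- function(record, history, cfg, testdef) {
  if (is.null(cfg)) return(skip_("delta", "no_delta_config"))
  if (is.na(record$value)) return(skip_("delta", "missing_result"))
  if (!length(history)) return(skip_("delta", "no_prior_result"))

  ts <- do.call(c, lapply(history, `[[`, "timestamp"))
  vals <- vapply(history, `[[`, numeric(1), "value")
  age_h <- as.numeric(difftime(record$timestamp, ts, units = "hours"))
  eligible <- which(age_h > 0 & age_h <= cfg$window_days * 24 & !is.na(vals))
  if (!length(eligible)) {
    return(skip_("delta", "no_prior_in_window",
                 sprintf("no prior within %g days", cfg$window_days)))
  }
  i <- eligible[which.min(age_h[eligible])]
  prior <- vals[i]
  hours <- age_h[i]

  limit <- cfg$limit
  d <- switch(cfg$mode,
    absolute = delta_absolute(record$value, prior),
    rate = delta_rate(record$value, prior, hours),
    percent = ,
    rcv = {
      if (cfg$mode == "rcv") {
        limit <- reference_change_value(cfg$cv_analytical,
                                        testdef$biovar$cvi, cfg$z_value)
      }
      if (prior == 0) {
        out <- hold_("delta", "delta_undefined",
                     "percent difference undefined: prior result is 0")
        return(out)
      }
      delta_percent(record$value, prior)
    })

  res <- list(mode = cfg$mode, value = d, limit = limit,
              prior_value = prior, prior_time = ts[i],
              interval_hours = hours, exceeded = abs(d) > limit)
  out <- if (res$exceeded) {
    hold_("delta",
          if (d > 0) "delta_increase" else "delta_decrease",
          sprintf("|%s delta %.4g| > limit %.4g (prior %.4g, %.1f h ago)",
                  cfg$mode, d, limit, prior, hours))
  } else {
    pass_("delta", sprintf("%s delta %.4g within limit %.4g", cfg$mode, d,
                           limit))
  }
  out$delta <- res
  out
}

#' Nominal delta exceedance rate under the log-normal result model
#'
#' Under the package's synthetic result model (log-normal set-points and
#' within-subject variation; see [simulate_population()]) two consecutive
#' results of one patient satisfy `x2/x1 = exp(s * sqrt(2) * Z)` with
#' `Z ~ N(0,1)` and `s = sqrt(log(1 + (CVw/100)^2))`, `CVw` the total
#' within-subject CV. The probability that the two-sided percent delta
#' exceeds a limit `r` (percent) is therefore
#' `P(Z > log(1 + r/100) / (s * sqrt(2))) + P(Z < log(1 - r/100) / (s * sqrt(2)))`
#' (the lower term vanishing for `r >= 100`). This is the false-alarm rate
#' of a percent/RCV delta check on error-free serial data from that model.
#'
#' @param cv_within Total within-subject CV, percent (biological plus
#'   analytical, combined in quadrature).
#' @param limit Two-sided percent limit (e.g. a reference change value).
#' @return The exceedance probability.
#' @export
delta_nominal_rate <- function(cv_within, limit) {
  stopifnot(cv_within > 0, limit > 0)
  s <- sqrt(log(1 + (cv_within / 100)^2))
  r <- limit / 100
  up <- stats::pnorm(log(1 + r) / (s * sqrt(2)), lower.tail = FALSE)
  lo <- if (r < 1) stats::pnorm(log(1 - r) / (s * sqrt(2))) else 0
  up + lo
}
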