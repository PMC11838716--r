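#' Numeric interval, possibly unbounded on either side
#'
#' Intervals carry the autovalidation range, critical limits, reference
#' intervals and consistency-ratio bands. Either side may be infinite
#' (unbounded). Bounds are interpreted by the rule that uses the interval:
#' the autovalidation range and consistency bands treat their bounds as
#' inclusive-PASS, critical limits as inclusive-HOLD (a value at a critical
#' limit is critical).
#'
#' @param low Lower bound (`-Inf` for unbounded).
#' @param high Upper bound (`Inf` for unbounded).
#' @return An object of class `av_interval` with fields `low` and `high`.
#' @examples
#' interval(3, 11)
#' interval(high = 1) # one-sided band
#' @export
interval <- function(low = -Inf, high = Inf) {
  stopifnot(is.numeric(low), is.numeric(high),
            length(low) == 1L, length(high) == 1L)
  if (is.na(low) || is.na(high)) {
    stop("interval bounds must not be NA (use -Inf/Inf for unbounded)",
         call. = FALSE)
  }
  if (low > high) {
    stop(sprintf("interval low (%g) must not exceed high (%g)", low, high),
         call. = FALSE)
  }
  structure(list(low = low, high = high), class = "av_interval")
}

#' @export
print.av_interval <- function(x, ...) {
  cat(sprintf("[%g, %g]\n", x$low, x$high))
  invisible(x)
}

is_bounded <- function(x) is.finite(x)

in_interval <- function(value, iv) {
  value >= iv$low & value <= iv$high
}

#' Patient demographic context attached to a result
#'
#' @param patient_id Non-empty identifier.
#' @param date_of_birth A `Date` (or `NA` when unknown).
#' @param sex One of `"male"`, `"female"`, `"unknown"`.
#' @param location Ward / ordering physician (free text, optional).
#' @param patient_class `"inpatient"`, `"outpatient"` or `"unknown"`.
#' @return A `patient_info` object.
#' @export
patient_info <- function(patient_id, date_of_birth = NA, sex = "unknown",
                         location = NA_character_,
                         patient_class = "unknown") {
  if (!is.character(patient_id) || length(patient_id) != 1L ||
      is.na(patient_id) || !nzchar(patient_id)) {
    stop("patient_id must be a non-empty string", call. = FALSE)
  }
  sex <- match.arg(sex, c("male", "female", "unknown"))
  patient_class <- match.arg(patient_class,
                             c("inpatient", "outpatient", "unknown"))
  if (!is.na(date_of_birth[1L])) date_of_birth <- as.Date(date_of_birth)
  structure(list(patient_id = patient_id, date_of_birth = date_of_birth,
                 sex = sex, location = location,
                 patient_class = patient_class),
            class = "patient_info")
}

#' Hemolysis / icterus / lipemia interference indices
#'
#' Semi-quantitative serum indices as reported by the analyzer. `NA` means
#' the index was not measured.
#'
#' @param hemolysis,icterus,lipemia Non-negative index values or `NA`.
#' @return A `hil_indices` object.
#' @export
hil_indices <- function(hemolysis = NA_real_, icterus = NA_real_,
                        lipemia = NA_real_) {
  vals <- c(hemolysis = hemolysis, icterus = icterus, lipemia = lipemia)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.na(v) && (!is.finite(v) || v < 0)) {
      stop(sprintf("%s index must be finite and >= 0", nm), call. = FALSE)
    }
  }
  structure(as.list(vals), class = "hil_indices")
}

#' One analyzer result with its sample and patient context
#'
#' @param sample_id Non-empty sample (barcode) identifier.
#' @param test_code Test code matching a [test_definition()] in the config.
#' @param value Numeric measurement (`NA` when the analyzer produced none).
#' @param unit Reporting unit (free text).
#' @param timestamp Result date-time (`POSIXct`).
#' @param patient A [patient_info()].
#' @param flags Character vector of analyzer flag codes.
#' @param hil A [hil_indices()].
#' @param analyzer Analyzer identifier (optional).
#' @return A `result_record` object.
#' @export
result_record <- function(sample_id, test_code, value = NA_real_, unit = "",
                          timestamp, patient, flags = character(),
                          hil = hil_indices(), analyzer = NA_character_) {
  if (!nzchar(sample_id)) stop("sample_id must be non-empty", call. = FALSE)
  if (!nzchar(test_code)) stop("test_code must be non-empty", call. = FALSE)
  if (missing(timestamp) || is.na(timestamp[1L])) {
    stop("timestamp is required", call. = FALSE)
  }
  timestamp <- as.POSIXct(timestamp, tz = "UTC")
  if (!is.na(value) && !is.finite(value)) {
    stop("value, when present, must be finite", call. = FALSE)
  }
  stopifnot(inherits(patient, "patient_info"), inherits(hil, "hil_indices"))
  if (!is.na(patient$date_of_birth[1L]) &&
      as.POSIXct(patient$date_of_birth, tz = "UTC") > timestamp) {
    stop("date_of_birth lies after the result timestamp", call. = FALSE)
  }
  structure(list(sample_id = sample_id, test_code = test_code,
                 value = as.numeric(value), unit = unit,
                 timestamp = timestamp, patient = patient,
                 flags = as.character(flags), hil = hil,
                 analyzer = analyzer),
            class = "result_record")
}

#' Delta-check configuration for one test
#'
#' @param mode One of `"absolute"` (difference in test units), `"percent"`
#'   (percent of the prior value), `"rate"` (units per hour) or `"rcv"`
#'   (limit computed as the reference change value from `cv_analytical` and
#'   the test's within-subject CV; the difference itself is a percent of the
#'   prior value).
#' @param limit Positive alarm limit (ignored for `"rcv"`, where the limit is
#'   the computed RCV).
#' @param window_days Look-back window: only a prior result at most this many
#'   days older than the current one is compared.
#' @param z_value Z multiplier for `"rcv"` mode (default 1.96, two-sided 95%).
#' @param cv_analytical Analytical CV in percent, required for `"rcv"` mode.
#' @return A `delta_config` object.
#' @export
delta_config <- function(mode = c("absolute", "percent", "rate", "rcv"),
                         limit = NA_real_, window_days, z_value = 1.96,
                         cv_analytical = NA_real_) {
  mode <- match.arg(mode)
  if (mode != "rcv") {
    if (!is.finite(limit) || limit <= 0) {
      stop("delta limit must be > 0", call. = FALSE)
    }
  } else {
    if (!is.finite(cv_analytical) || cv_analytical < 0) {
      stop("rcv mode requires cv_analytical >= 0", call. = FALSE)
    }
  }
  if (!is.finite(window_days) || window_days <= 0) {
    stop("window_days must be > 0", call. = FALSE)
  }
  if (!is.finite(z_value) || z_value <= 0) {
    stop("z_value must be > 0", call. = FALSE)
  }
  structure(list(mode = mode, limit = limit, window_days = window_days,
                 z_value = z_value, cv_analytical = cv_analytical),
            class = "delta_config")
}

#' Biological-variation components of a measurand
#'
#' @param cvi Within-subject biological coefficient of variation, percent.
#' @param cvg Between-subject biological coefficient of variation, percent.
#' @return A `biological_variation` object.
#' @export
biological_variation <- function(cvi, cvg) {
  if (!is.finite(cvi) || cvi <= 0) stop("cvi must be > 0", call. = FALSE)
  if (!is.finite(cvg) || cvg <= 0) stop("cvg must be > 0", call. = FALSE)
  structure(list(cvi = cvi, cvg = cvg), class = "biological_variation")
}

#' Full rule parameterization for one test
#'
#' @param test_code Test code (non-empty).
#' @param name Human-readable test name.
#' @param unit Reporting unit.
#' @param av_range [interval()]: results inside (bounds inclusive) may be
#'   autovalidated.
#' @param critical_limits [interval()]: results at or beyond either bound are
#'   critical and always held, regardless of the autovalidation range.
#' @param hil_thresholds Named list with any of `hemolysis`, `icterus`,
#'   `lipemia`: maximum acceptable index values. Empty list disables the HIL
#'   rule for this test.
#' @param delta A [delta_config()] or `NULL` (no delta check).
#' @param biovar A [biological_variation()] or `NULL`.
#' @param age_groups_included List of `c(min, max)` age ranges in years,
#'   half-open `[min, max)`. Empty list means all (plausible) ages.
#' @param flags_blocking Analyzer flag codes that block autovalidation.
#' @param analyzers_included Analyzer ids admitted to autovalidation
#'   (empty = all analyzers).
#' @param decimals Reporting precision (decimal places); used by the
#'   verification harness to step just above/below decision points.
#' @return A `test_definition` object.
#' @export
test_definition <- function(test_code, name = test_code, unit = "",
                            av_range = interval(),
                            critical_limits = interval(),
                            hil_thresholds = list(), delta = NULL,
                            biovar = NULL, age_groups_included = list(),
                            flags_blocking = character(),
                            analyzers_included = character(),
                            decimals = 1L) {
  if (!nzchar(test_code)) stop("test_code must be non-empty", call. = FALSE)
  stopifnot(inherits(av_range, "av_interval"),
            inherits(critical_limits, "av_interval"))
  if (!is.null(delta)) stopifnot(inherits(delta, "delta_config"))
  if (!is.null(biovar)) stopifnot(inherits(biovar, "biological_variation"))
  bad <- setdiff(names(hil_thresholds),
                 c("hemolysis", "icterus", "lipemia"))
  if (length(bad)) {
    stop("unknown HIL threshold name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (thr in hil_thresholds) {
    if (!is.finite(thr) || thr < 0) {
      stop("HIL thresholds must be finite and >= 0", call. = FALSE)
    }
  }
  age_groups_included <- lapply(age_groups_included, function(g) {
    g <- as.numeric(g)
    if (length(g) != 2L || any(!is.finite(g)) || g[1L] >= g[2L]) {
      stop("age group must be c(min, max) with min < max", call. = FALSE)
    }
    g
  })
  if (length(age_groups_included) > 1L) {
    o <- order(vapply(age_groups_included, `[`, numeric(1), 1L))
    gs <- age_groups_included[o]
    for (i in seq_len(length(gs) - 1L)) {
      if (gs[[i]][2L] > gs[[i + 1L]][1L]) {
        stop("age groups must not overlap", call. = FALSE)
      }
    }
  }
  if (mode_rcv <- (!is.null(delta) && delta$mode == "rcv")) {
    if (is.null(biovar)) {
      stop("delta mode 'rcv' requires biovar (cvi) for test ", test_code,
           call. = FALSE)
    }
  }
  structure(list(test_code = test_code, name = name, unit = unit,
                 av_range = av_range, critical_limits = critical_limits,
                 hil_thresholds = hil_thresholds, delta = delta,
                 biovar = biovar,
                 age_groups_included = age_groups_included,
                 flags_blocking = as.character(flags_blocking),
                 analyzers_included = as.character(analyzers_included),
                 decimals = as.integer(decimals)),
            class = "test_definition")
}

#' Cross-test consistency (plausibility) rule
#'
#' Checks the ratio numerator/denominator of two tests measured on the same
#' sample against an acceptance band, e.g. AST/ALT inside \[0.25, 4\].
#'
#' @param rule_id Identifier for the rule.
#' @param numerator_test,denominator_test Test codes (must differ).
#' @param limits [interval()] acceptance band for the ratio (inclusive).
#' @return A `consistency_rule` object.
#' @export
consistency_rule <- function(rule_id, numerator_test, denominator_test,
                             limits) {
  if (identical(numerator_test, denominator_test)) {
    stop("numerator and denominator test must differ", call. = FALSE)
  }
  stopifnot(inherits(limits, "av_interval"))
  if (!(limits$low < limits$high)) {
    stop("consistency limits must satisfy low < high", call. = FALSE)
  }
  structure(list(rule_id = rule_id, numerator_test = numerator_test,
                 denominator_test = denominator_test, limits = limits),
            class = "consistency_rule")
}

#' Internal quality control gating state for one test
#'
#' @param test_code Test code.
#' @param in_control Logical: does IQC currently meet its criteria?
#' @param last_pass_time `POSIXct` of the last passing IQC event.
#' @param max_age_hours Hours after which a passing IQC expires and results
#'   are no longer autovalidated.
#' @return A `qc_policy` object.
#' @export
qc_policy <- function(test_code, in_control, last_pass_time,
                      max_age_hours) {
  if (!is.finite(max_age_hours) || max_age_hours <= 0) {
    stop("max_age_hours must be > 0", call. = FALSE)
  }
  structure(list(test_code = test_code, in_control = isTRUE(in_control),
                 last_pass_time = as.POSIXct(last_pass_time, tz = "UTC"),
                 max_age_hours = max_age_hours),
            class = "qc_policy")
}

#' Complete engine configuration
#'
#' @param tests List of [test_definition()] objects (names are taken from the
#'   test codes).
#' @param consistency_rules List of [consistency_rule()]s; every referenced
#'   test must be defined in `tests`.
#' @param qc_policies List of [qc_policy()]s, at most one per test.
#' @param mode `"manual_trigger"` or `"real_time"`; the decision logic is
#'   identical, only the invocation differs.
#' @param kill_switch When `TRUE`, no result is ever autovalidated (the
#'   emergency stop for real-time operation).
#' @return An `engine_config` object.
#' @export
engine_config <- function(tests, consistency_rules = list(),
                          qc_policies = list(),
                          mode = c("manual_trigger", "real_time"),
                          kill_switch = FALSE) {
  mode <- match.arg(mode)
  stopifnot(length(tests) >= 1L)
  for (td in tests) stopifnot(inherits(td, "test_definition"))
  names(tests) <- vapply(tests, `[[`, character(1), "test_code")
  if (anyDuplicated(names(tests))) {
    stop("duplicate test_code in tests", call. = FALSE)
  }
  for (cr in consistency_rules) {
    stopifnot(inherits(cr, "consistency_rule"))
    missing_ref <- setdiff(c(cr$numerator_test, cr$denominator_test),
                           names(tests))
    if (length(missing_ref)) {
      stop(sprintf("consistency rule '%s' references undefined test(s): %s",
                   cr$rule_id, paste(missing_ref, collapse = ", ")),
           call. = FALSE)
    }
  }
  for (qp in qc_policies) stopifnot(inherits(qp, "qc_policy"))
  names(qc_policies) <- vapply(qc_policies, `[[`, character(1), "test_code")
  structure(list(tests = tests, consistency_rules = consistency_rules,
                 qc_policies = qc_policies, mode = mode,
                 kill_switch = isTRUE(kill_switch)),
            class = "engine_config")
}

#' @export
print.engine_config <- function(x, ...) {
  cat(sprintf("<engine_config> %d test(s), %d consistency rule(s), %d QC policy(ies)\n",
              length(x$tests), length(x$consistency_rules),
              length(x$qc_policies)))
  cat(sprintf("  mode: %s; kill switch: %s\n", x$mode,
              if (x$kill_switch) "ENGAGED (nothing autovalidates)" else "off"))
  invisible(x)
}

# oldest age considered plausible; older (or negative) ages HOLD under the
# demographics rule even when no age groups are configured
MAX_PLAUSIBLE_AGE_YEARS <- 120

#' Patient age at a given time, in fractional calendar years
#'
#' Whole years are counted by birthday anniversaries; the fractional part is
#' the elapsed fraction of the current anniversary year, so an exact
#' anniversary yields an integer age. Age is always computed at the result
#' timestamp, never at evaluation time, so decisions are reproducible.
#'
#' @param patient A [patient_info()].
#' @param when `POSIXct` (or `Date`) reference time.
#' @return Age in years, or `NULL` when the date of birth is unknown.
#' @examples
#' p <- patient_info("P1", as.Date("2000-03-01"), "female")
#' age_at(p, as.POSIXct("2018-03-01", tz = "UTC")) # exactly 18
#' @export
age_at <- function(patient, when) {
  dob <- patient$date_of_birth
  if (is.na(dob[1L])) return(NULL)
  when <- as.POSIXct(when, tz = "UTC")
  dob_t <- as.POSIXct(as.Date(dob), tz = "UTC")
  if (dob_t > when) stop("date_of_birth lies in the future", call. = FALSE)
  lubridate::time_length(lubridate::interval(dob_t, when), unit = "years")
}
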