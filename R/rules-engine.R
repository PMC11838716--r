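#' @title Per-rule verdicts and the conjunctive decision
#' @description Every rule returns a `rule_outcome`; a result is
#'   autovalidated if and only if no applicable rule HOLDs. `SKIP` marks a
#'   rule whose preconditions are unmet (no prior result for the delta
#'   check, no HIL thresholds configured, ...) and counts as a pass in the
#'   conjunction.
#' @param rule_id One of `demographics`, `flags`, `hil`, `av_range`,
#'   `critical`, `delta`, `consistency`, `qc`, `kill_switch`.
#' @param status `PASS`, `HOLD` or `SKIP`.
#' @param reason_code Short machine-readable code; required when HOLDing.
#' @param detail Human-readable explanation.
#' @return A `rule_outcome` object.
#' @export
rule_outcome <- function(rule_id, status, reason_code = "", detail = "") {
  rule_id <- match.arg(rule_id, RULE_IDS)
  status <- match.arg(status, c("PASS", "HOLD", "SKIP"))
  if (status == "HOLD" && !nzchar(reason_code)) {
    stop("HOLD outcomes require a reason_code", call. = FALSE)
  }
  structure(list(rule_id = rule_id, status = status,
                 reason_code = reason_code, detail = detail),
            class = "rule_outcome")
}

RULE_IDS <- c("demographics", "flags", "hil", "av_range", "critical",
              "delta", "consistency", "qc", "kill_switch")

pass_ <- function(rule_id, detail = "") rule_outcome(rule_id, "PASS", "", detail)
hold_ <- function(rule_id, reason, detail = "") {
  rule_outcome(rule_id, "HOLD", reason, detail)
}
skip_ <- function(rule_id, reason = "", detail = "") {
  rule_outcome(rule_id, "SKIP", reason, detail)
}

#' @export
print.rule_outcome <- function(x, ...) {
  cat(sprintf("[%s] %s%s%s\n", x$rule_id, x$status,
              if (nzchar(x$reason_code)) paste0(" (", x$reason_code, ")") else "",
              if (nzchar(x$detail)) paste0(": ", x$detail) else ""))
  invisible(x)
}

#' Demographics rule: age and sex must be known and admissible
#'
#' A result is never autovalidated without the patient's age and sex.
#' Implausible ages (negative, or above 120 years) always hold; when age
#' groups are configured for the test, the age must fall inside one of the
#' half-open `[min, max)` ranges.
#'
#' @param record A [result_record()].
#' @param testdef The matching [test_definition()].
#' @return A [rule_outcome()].
#' @export
evaluate_demographics <- function(record, testdef) {
  p <- record$patient
  if (is.na(p$date_of_birth[1L])) {
    return(hold_("demographics", "missing_dob", "date of birth unknown"))
  }
  if (p$sex == "unknown") {
    return(hold_("demographics", "missing_sex", "patient sex unknown"))
  }
  age <- tryCatch(age_at(p, record$timestamp), error = function(e) -1)
  if (age < 0 || age > MAX_PLAUSIBLE_AGE_YEARS) {
    return(hold_("demographics", "age_absurd",
                 sprintf("implausible age %.1f y", age)))
  }
  groups <- testdef$age_groups_included
  if (length(groups)) {
    ok <- any(vapply(groups, function(g) age >= g[1L] && age < g[2L],
                     logical(1)))
    if (!ok) {
      return(hold_("demographics", "age_excluded",
                   sprintf("age %.2f y outside every included age group", age)))
    }
  }
  pass_("demographics", sprintf("age %.1f y, sex %s", age, p$sex))
}

#' Analyzer flag rule
#'
#' Holds when any analyzer flag on the record belongs to the test's blocking
#' set, or when the record's analyzer is not admitted for autovalidation.
#' Flags not listed as blocking are non-blocking but echoed in the detail
#' (logged, per the distinction between messages that do and do not affect
#' the result).
#'
#' @inheritParams evaluate_demographics
#' @return A [rule_outcome()].
#' @export
evaluate_flags <- function(record, testdef) {
  if (length(testdef$analyzers_included)) {
    if (is.na(record$analyzer)) {
      return(hold_("flags", "analyzer_unknown",
                   "analyzer not recorded but an include list is configured"))
    }
    if (!(record$analyzer %in% testdef$analyzers_included)) {
      return(hold_("flags", "analyzer_excluded",
                   sprintf("analyzer '%s' excluded from autovalidation",
                           record$analyzer)))
    }
  }
  blocking <- intersect(record$flags, testdef$flags_blocking)
  if (length(blocking)) {
    return(hold_("flags", "blocking_flag",
                 paste("blocking flag(s):", paste(blocking, collapse = ", "))))
  }
  other <- setdiff(record$flags, testdef$flags_blocking)
  pass_("flags", if (length(other)) {
    paste("non-blocking flag(s):", paste(other, collapse = ", "))
  } else "")
}

#' Interference (HIL) rule
#'
#' For each configured hemolysis/icterus/lipemia threshold the measured
#' index must be present and must not exceed the threshold (at-threshold
#' passes). A configured threshold with an unmeasured index holds with
#' reason `hil_missing`. Tests without HIL thresholds skip the rule.
#'
#' @inheritParams evaluate_demographics
#' @return A [rule_outcome()].
#' @export
evaluate_hil <- function(record, testdef) {
  thr <- testdef$hil_thresholds
  if (!length(thr)) return(skip_("hil", "no_hil_thresholds"))
  reasons <- character(); details <- character()
  for (nm in names(thr)) {
    idx <- record$hil[[nm]]
    if (is.na(idx)) {
      reasons <- c(reasons, "hil_missing")
      details <- c(details, sprintf("%s index not measured", nm))
    } else if (idx > thr[[nm]]) {
      reasons <- c(reasons, paste0(nm, "_exceeded"))
      details <- c(details, sprintf("%s index %g > limit %g", nm, idx,
                                    thr[[nm]]))
    }
  }
  if (length(reasons)) {
    return(hold_("hil", reasons[1L], paste(details, collapse = "; ")))
  }
  pass_("hil")
}

#' Autovalidation-range rule
#'
#' Passes when the value lies inside the configured range, boundaries
#' inclusive; a missing value holds with reason `missing_result`.
#'
#' @inheritParams evaluate_demographics
#' @return A [rule_outcome()].
#' @export
evaluate_av_range <- function(record, testdef) {
  v <- record$value
  if (is.na(v)) return(hold_("av_range", "missing_result", "no result value"))
  rng <- testdef$av_range
  if (v < rng$low) {
    return(hold_("av_range", "below_av_range",
                 sprintf("%g < %g", v, rng$low)))
  }
  if (v > rng$high) {
    return(hold_("av_range", "above_av_range",
                 sprintf("%g > %g", v, rng$high)))
  }
  pass_("av_range")
}

#' Critical-value rule
#'
#' A result at or beyond a critical limit is critical: it is held for
#' immediate manual validation and clinician notification even when it lies
#' inside the autovalidation range (critical limits dominate).
#'
#' @inheritParams evaluate_demographics
#' @return A [rule_outcome()]; a HOLD here raises the decision's
#'   `critical_alert`.
#' @export
evaluate_critical <- function(record, testdef) {
  v <- record$value
  if (is.na(v)) return(skip_("critical", "missing_result"))
  lim <- testdef$critical_limits
  if (is_bounded(lim$low) && v <= lim$low) {
    return(hold_("critical", "critical_low",
                 sprintf("%g <= critical low %g", v, lim$low)))
  }
  if (is_bounded(lim$high) && v >= lim$high) {
    return(hold_("critical", "critical_high",
                 sprintf("%g >= critical high %g", v, lim$high)))
  }
  pass_("critical")
}

#' Consistency (plausibility) rule over one sample
#'
#' Evaluates each configured ratio rule on the results of a single sample.
#' The ratio must lie inside the band, bounds inclusive; a violation marks
#' BOTH participating results (the error could be in either measurement).
#' Rules whose numerator or denominator was not measured on the sample are
#' skipped.
#'
#' @param sample_results List of [result_record()]s sharing one `sample_id`.
#' @param rules List of [consistency_rule()]s.
#' @return A list of [rule_outcome()]s, one per rule, each carrying a
#'   `tests` attribute naming the test codes it applies to.
#' @export
evaluate_consistency <- function(sample_results, rules) {
  sids <- unique(vapply(sample_results, `[[`, character(1), "sample_id"))
  if (length(sids) > 1L) {
    stop("all records must share one sample_id", call. = FALSE)
  }
  codes <- vapply(sample_results, `[[`, character(1), "test_code")
  lapply(rules, function(cr) {
    touches <- c(cr$numerator_test, cr$denominator_test)
    i_num <- match(cr$numerator_test, codes)
    i_den <- match(cr$denominator_test, codes)
    out <- if (is.na(i_num) || is.na(i_den)) {
      skip_("consistency", "test_absent",
            sprintf("rule %s: not all tests on sample", cr$rule_id))
    } else {
      num <- sample_results[[i_num]]$value
      den <- sample_results[[i_den]]$value
      if (is.na(num) || is.na(den)) {
        skip_("consistency", "value_missing",
              sprintf("rule %s: missing value", cr$rule_id))
      } else if (den == 0) {
        hold_("consistency", "ratio_undefined",
              sprintf("rule %s: denominator %s is zero", cr$rule_id,
                      cr$denominator_test))
      } else {
        ratio <- num / den
        if (in_interval(ratio, cr$limits)) {
          pass_("consistency", sprintf("rule %s: ratio %.3g in [%g, %g]",
                                       cr$rule_id, ratio, cr$limits$low,
                                       cr$limits$high))
        } else {
          hold_("consistency", "ratio_out_of_range",
                sprintf("rule %s: %s/%s = %.3g outside [%g, %g]",
                        cr$rule_id, cr$numerator_test, cr$denominator_test,
                        ratio, cr$limits$low, cr$limits$high))
        }
      }
    }
    attr(out, "tests") <- touches
    out
  })
}

#' Internal quality control gating rule
#'
#' Holds when IQC is out of control, or when the last passing IQC event is
#' older than the configured expiry. Tests without a QC policy skip the
#' rule.
#'
#' @param testdef The [test_definition()] being gated.
#' @param policy The test's [qc_policy()], or `NULL`.
#' @param now Evaluation time (`POSIXct`).
#' @return A [rule_outcome()].
#' @export
evaluate_qc <- function(testdef, policy, now) {
  if (is.null(policy)) return(skip_("qc", "no_qc_policy"))
  if (!policy$in_control) {
    return(hold_("qc", "qc_failed", "IQC criteria not met"))
  }
  age_h <- as.numeric(difftime(as.POSIXct(now, tz = "UTC"),
                               policy$last_pass_time, units = "hours"))
  if (age_h > policy$max_age_hours) {
    return(hold_("qc", "qc_expired",
                 sprintf("last IQC pass %.1f h ago > %g h window", age_h,
                         policy$max_age_hours)))
  }
  pass_("qc")
}

#' Validate one result against the full rule set
#'
#' All rules are evaluated (no short-circuit) so reviewers of a held result
#' see every violated rule, and the decision is the conjunction: the result
#' is `AUTOVALIDATED` if and only if no rule HOLDs. When the engine's kill
#' switch is set, a `kill_switch` HOLD is added and the result is held
#' unconditionally (the rule outcomes are still computed and reported).
#'
#' @param record A [result_record()].
#' @param history List of prior [result_record()]s for the same patient and
#'   test (any order; only results strictly older than the record are used).
#' @param sample_context List of [result_record()]s on the same sample
#'   (other tests), used by the consistency rules; the record itself is
#'   added automatically.
#' @param config An [engine_config()].
#' @param now Evaluation time used by the QC expiry check (defaults to the
#'   record timestamp).
#' @return A `validation_decision` with fields `record`, `outcomes`,
#'   `decision` (`AUTOVALIDATED`/`HELD`), `decided_at` and `critical_alert`.
#' @export
validate_record <- function(record, history = list(),
                            sample_context = list(), config,
                            now = record$timestamp) {
  stopifnot(inherits(config, "engine_config"))
  testdef <- config$tests[[record$test_code]]
  if (is.null(testdef)) {
    stop(sprintf("configuration error: unknown test_code '%s'",
                 record$test_code), call. = FALSE)
  }
  outcomes <- list()
  if (config$kill_switch) {
    outcomes <- c(outcomes, list(hold_("kill_switch", "kill_switch",
                                       "engine kill switch engaged")))
  }
  outcomes <- c(outcomes, list(
    evaluate_demographics(record, testdef),
    evaluate_flags(record, testdef),
    evaluate_hil(record, testdef),
    evaluate_critical(record, testdef),
    evaluate_av_range(record, testdef),
    evaluate_delta(record, history, testdef$delta, testdef)))

  crules <- Filter(function(cr) record$test_code %in%
                     c(cr$numerator_test, cr$denominator_test),
                   config$consistency_rules)
  if (length(crules)) {
    ctx <- sample_context
    ctx_codes <- vapply(ctx, `[[`, character(1), "test_code")
    if (!(record$test_code %in% ctx_codes)) ctx <- c(ctx, list(record))
    ctx <- Filter(function(r) r$sample_id == record$sample_id, ctx)
    outcomes <- c(outcomes, evaluate_consistency(ctx, crules))
  }

  outcomes <- c(outcomes, list(
    evaluate_qc(testdef, config$qc_policies[[record$test_code]], now)))

  statuses <- vapply(outcomes, `[[`, character(1), "status")
  rule_ids <- vapply(outcomes, `[[`, character(1), "rule_id")
  decision <- if (any(statuses == "HOLD")) "HELD" else "AUTOVALIDATED"
  structure(list(record = record, outcomes = outcomes, decision = decision,
                 decided_at = as.POSIXct(now, tz = "UTC"),
                 critical_alert = any(statuses == "HOLD" &
                                        rule_ids == "critical")),
            class = "validation_decision")
}

#' @export
print.validation_decision <- function(x, ...) {
  cat(sprintf("<%s> %s %s = %s %s\n",
              x$decision, x$record$test_code, x$record$sample_id,
              format(x$record$value),
              if (x$critical_alert) "** CRITICAL ALERT **" else ""))
  for (o in x$outcomes) print(o)
  invisible(x)
}

#' Rules that held a decision
#' @param decision A `validation_decision`.
#' @return Character vector of rule ids with status HOLD.
#' @export
held_rules <- function(decision) {
  keep <- vapply(decision$outcomes, function(o) o$status == "HOLD",
                 logical(1))
  vapply(decision$outcomes[keep], `[[`, character(1), "rule_id")
}

#' Validate a batch (or stream) of results
#'
#' Records are processed in timestamp order. The delta check for each record
#' sees the supplied external history plus any earlier records of the same
#' patient and test within the batch, so a simulated stream is
#' self-contained. Consistency rules see all batch records sharing the
#' sample id.
#'
#' @param records A data frame in the package record schema (see
#'   [read_records()]) or a list of [result_record()]s.
#' @param history Optional prior results, same formats.
#' @param config An [engine_config()].
#' @param now Evaluation time for QC expiry; defaults to the latest record
#'   timestamp so reruns are reproducible.
#' @return A list with `decisions` (list of `validation_decision`),
#'   `table` (one row per record: decision, critical alert, held rules,
#'   reasons) and `summary` (`n`, `n_autovalidated`, `percent_autovalidated`;
#'   the percentage is `NA` for an empty batch).
#' @export
validate_batch <- function(records, history = NULL, config, now = NULL) {
  recs <- as_record_list(records)
  hist <- if (is.null(history)) list() else as_record_list(history)
  if (!length(recs)) {
    return(list(decisions = list(),
                table = empty_decision_table(),
                summary = list(n = 0L, n_autovalidated = 0L,
                               percent_autovalidated = NA_real_)))
  }
  if (is.null(now)) {
    now <- max(do.call(c, lapply(recs, `[[`, "timestamp")))
  }

  key <- function(r) paste(r$patient$patient_id, r$test_code, sep = "\r")
  streams <- split(c(hist, recs),
                   vapply(c(hist, recs), key, character(1)))
  by_sample <- split(recs, vapply(recs, `[[`, character(1), "sample_id"))

  decisions <- lapply(recs, function(r) {
    stream <- streams[[key(r)]]
    prior <- Filter(function(h) h$timestamp < r$timestamp, stream)
    validate_record(r, history = prior,
                    sample_context = by_sample[[r$sample_id]],
                    config = config, now = now)
  })

  n_av <- sum(vapply(decisions, function(d) d$decision == "AUTOVALIDATED",
                     logical(1)))
  list(decisions = decisions,
       table = decisions_to_df(decisions),
       summary = list(n = length(decisions), n_autovalidated = n_av,
                      percent_autovalidated = 100 * n_av / length(decisions)))
}

empty_decision_table <- function() {
  data.frame(sample_id = character(), test_code = character(),
             patient_id = character(), timestamp = as.POSIXct(character()),
             value = numeric(), decision = character(),
             critical_alert = logical(), held_rules = character(),
             reasons = character(), stringsAsFactors = FALSE)
}

#' Flatten validation decisions to a data frame
#'
#' One row per decision with an explicit autovalidated marker for downstream
#' systems; held rules and reason codes are `;`-joined.
#'
#' @param decisions List of `validation_decision` objects.
#' @return A data frame.
#' @export
decisions_to_df <- function(decisions) {
  if (!length(decisions)) return(empty_decision_table())
  rows <- lapply(decisions, function(d) {
    holds <- Filter(function(o) o$status == "HOLD", d$outcomes)
    data.frame(
      sample_id = d$record$sample_id, test_code = d$record$test_code,
      patient_id = d$record$patient$patient_id,
      timestamp = d$record$timestamp, value = d$record$value,
      decision = d$decision, critical_alert = d$critical_alert,
      held_rules = paste(vapply(holds, `[[`, character(1), "rule_id"),
                         collapse = ";"),
      reasons = paste(vapply(holds, `[[`, character(1), "reason_code"),
                      collapse = ";"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
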