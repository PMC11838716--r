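# package-local state: release sentinel for the verification guarantee
.av_state <- new.env(parent = emptyenv())
.av_state$release_count <- 0L
.av_state$verification_active <- FALSE

#' Release autovalidated decisions to a downstream sink
#'
#' The single release path of the package. Writing through it increments an
#' internal release counter; during a verification run (see [run_phase1()])
#' any call fails hard, enforcing the guarantee that no patient result is
#' released while the algorithm is under verification.
#'
#' @param decisions List of `validation_decision`s.
#' @param path File the autovalidated results are appended to.
#' @return Number of decisions released, invisibly.
#' @export
release_decisions <- function(decisions, path) {
  if (.av_state$verification_active) {
    .av_state$release_count <- .av_state$release_count + 1L
    stop(structure(class = c("av_release_violation", "error", "condition"),
                   list(message = "release attempted during verification",
                        call = sys.call())))
  }
  av <- Filter(function(d) d$decision == "AUTOVALIDATED", decisions)
  if (length(av)) {
    df <- decisions_to_df(av)
    utils::write.table(df, path, sep = ",", row.names = FALSE,
                       col.names = !file.exists(path), append = file.exists(path))
  }
  .av_state$release_count <- .av_state$release_count + length(av)
  invisible(length(av))
}

#' Released-result counter (verification sentinel)
#' @return Number of results released through [release_decisions()] since
#'   the package was loaded.
#' @export
release_count <- function() .av_state$release_count

#' Expected autovalidation verdict from the documented conventions
#'
#' An independent, straight-line restatement of the engine's boundary
#' conventions, used to label generated verification cases: inclusive-PASS
#' at autovalidation-range, HIL and consistency bounds; inclusive-HOLD at
#' critical limits; strict exceedance for the delta limit; critical limits
#' dominate the autovalidation range. It shares no code with the rule
#' engine, so Phase I concordance is a genuine two-route check.
#'
#' @param record A [result_record()].
#' @param testdef The test's [test_definition()].
#' @param config The [engine_config()].
#' @param prior Optional prior [result_record()] for the delta check.
#' @param context Optional list of same-sample records for consistency.
#' @param qc_override Optional [qc_policy()] replacing the configured one.
#' @return `"YES"` (would autovalidate) or `"NO"`.
#' @export
expected_autovalidation <- function(record, testdef, config, prior = NULL,
                                    context = list(), qc_override = NULL) {
  NO <- "NO"
  if (config$kill_switch) return(NO)
  p <- record$patient
  if (is.na(p$date_of_birth[1L]) || p$sex == "unknown") return(NO)
  dob <- as.POSIXct(as.Date(p$date_of_birth), tz = "UTC")
  if (dob > record$timestamp) return(NO)
  age <- lubridate::time_length(lubridate::interval(dob, record$timestamp),
                                unit = "years")
  if (age < 0 || age > MAX_PLAUSIBLE_AGE_YEARS) return(NO)
  gs <- testdef$age_groups_included
  if (length(gs) &&
      !any(vapply(gs, function(g) age >= g[1L] && age < g[2L], logical(1)))) {
    return(NO)
  }
  if (length(testdef$analyzers_included) &&
      (is.na(record$analyzer) ||
         !(record$analyzer %in% testdef$analyzers_included))) {
    return(NO)
  }
  if (length(intersect(record$flags, testdef$flags_blocking))) return(NO)
  for (nm in names(testdef$hil_thresholds)) {
    idx <- record$hil[[nm]]
    if (is.na(idx) || idx > testdef$hil_thresholds[[nm]]) return(NO)
  }
  v <- record$value
  if (is.na(v)) return(NO)
  cl <- testdef$critical_limits
  if (is_bounded(cl$low) && v <= cl$low) return(NO)
  if (is_bounded(cl$high) && v >= cl$high) return(NO)
  if (v < testdef$av_range$low || v > testdef$av_range$high) return(NO)
  cfg <- testdef$delta
  if (!is.null(cfg) && !is.null(prior) && !is.na(prior$value)) {
    hours <- as.numeric(difftime(record$timestamp, prior$timestamp,
                                 units = "hours"))
    if (hours > 0 && hours <= cfg$window_days * 24) {
      lim <- cfg$limit
      if (cfg$mode == "rcv") {
        lim <- sqrt(2) * cfg$z_value *
          sqrt(cfg$cv_analytical^2 + testdef$biovar$cvi^2)
      }
      d <- switch(cfg$mode,
        absolute = v - prior$value,
        rate = (v - prior$value) / hours,
        { # percent and rcv
          if (prior$value == 0) return(NO)
          100 * (v - prior$value) / prior$value
        })
      if (abs(d) > lim) return(NO)
    }
  }
  all_recs <- c(context, list(record))
  codes <- vapply(all_recs, `[[`, character(1), "test_code")
  vals <- vapply(all_recs, `[[`, numeric(1), "value")
  for (cr in config$consistency_rules) {
    if (!(record$test_code %in% c(cr$numerator_test, cr$denominator_test)))
      next
    i_n <- match(cr$numerator_test, codes)
    i_d <- match(cr$denominator_test, codes)
    if (is.na(i_n) || is.na(i_d)) next
    if (is.na(vals[i_n]) || is.na(vals[i_d])) next
    if (vals[i_d] == 0) return(NO)
    ratio <- vals[i_n] / vals[i_d]
    if (ratio < cr$limits$low || ratio > cr$limits$high) return(NO)
  }
  pol <- qc_override %||% config$qc_policies[[record$test_code]]
  if (!is.null(pol)) {
    if (!pol$in_control) return(NO)
    age_h <- as.numeric(difftime(record$timestamp, pol$last_pass_time,
                                 units = "hours"))
    if (age_h > pol$max_age_hours) return(NO)
  }
  "YES"
}

# fixed reference time for generated verification cases: Phase I must be
# reproducible whenever it is rerun
PHASE1_TIME <- as.POSIXct("2025-03-10 08:00:00", tz = "UTC")

#' Generate Phase I (technical verification) boundary cases for one test
#'
#' Emits the simulated scenarios of a technical verification: absurd age
#' and sex, missing date of birth, missing result, each blocking and one
#' non-blocking analyzer flag, a value at / just below / just above every
#' bounded decision point (autovalidation range, each critical limit, each
#' HIL threshold, the delta limit), a prior result outside the delta time
#' window, consistency-ratio cases in and out of band, QC failed/expired
#' scenarios, and one combined multi-rule violation. "Just above/below"
#' steps by one unit in the last decimal place of the test's reporting
#' precision (`decimals` in the [test_definition()]). Unbounded limits are
#' skipped with a note. Expected YES/NO labels come from
#' [expected_autovalidation()], never from the engine under test.
#'
#' QC state is pinned to a passing policy for every non-QC case so the case
#' set is independent of wall-clock time; dedicated QC cases override it.
#'
#' @param testdef The [test_definition()] to verify.
#' @param config The full [engine_config()] (consistency partners, QC).
#' @return A list of `verification_case` objects (fields `case_id`, `rule`,
#'   `description`, `record`, `prior`, `context`, `qc_policy`, `expected`),
#'   with a `notes` attribute listing skipped unbounded limits.
#' @export
generate_phase1_cases <- function(testdef, config) {
  stopifnot(inherits(testdef, "test_definition"),
            inherits(config, "engine_config"))
  ts <- PHASE1_TIME
  eps <- 10^(-testdef$decimals)
  notes <- character()

  base_age <- if (length(testdef$age_groups_included)) {
    g <- testdef$age_groups_included[[1L]]
    (g[1L] + min(g[2L], MAX_PLAUSIBLE_AGE_YEARS)) / 2
  } else 45
  dob_for <- function(age_years) {
    as.Date(ts) - round(age_years * 365.25)
  }
  base_value <- local({
    av <- testdef$av_range
    cl <- testdef$critical_limits
    lo <- max(av$low, if (is_bounded(cl$low)) cl$low + eps else -Inf)
    hi <- min(av$high, if (is_bounded(cl$high)) cl$high - eps else Inf)
    if (lo > hi) stop("no admissible value inside AV range and strictly ",
                      "inside critical limits for test ", testdef$test_code,
                      call. = FALSE)
    if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2
    else if (is.finite(lo)) lo + 1 else if (is.finite(hi)) hi - 1 else 1
  })
  base_analyzer <- if (length(testdef$analyzers_included)) {
    testdef$analyzers_included[[1L]]
  } else NA_character_
  base_hil <- do.call(hil_indices, lapply(
    stats::setNames(nm = c("hemolysis", "icterus", "lipemia")),
    function(nm) if (nm %in% names(testdef$hil_thresholds)) 0 else NA_real_))

  qc_pass <- qc_policy(testdef$test_code, TRUE, ts - 3600, 24)
  k <- 0L
  cases <- list()
  mk_record <- function(value = base_value, sex = "female",
                        dob = dob_for(base_age), flags = character(),
                        hil = base_hil, analyzer = base_analyzer,
                        sample_id = NULL) {
    k_local <- k + 1L
    result_record(sample_id %||% sprintf("V-%03d", k_local),
                  testdef$test_code, value = value, unit = testdef$unit,
                  timestamp = ts,
                  patient = patient_info("VERIF-P", dob, sex),
                  flags = flags, hil = hil, analyzer = analyzer)
  }
  add <- function(rule, description, record, prior = NULL,
                  context = list(), qc = qc_pass) {
    k <<- k + 1L
    expected <- expected_autovalidation(record, testdef, config,
                                        prior = prior, context = context,
                                        qc_override = qc)
    cases[[k]] <<- structure(
      list(case_id = sprintf("V-%03d", k), rule = rule,
           description = description, record = record, prior = prior,
           context = context, qc_policy = qc, expected = expected,
           actual = NA_character_, concordant = NA),
      class = "verification_case")
  }

  add("none", "all rules satisfied", mk_record())
  add("demographics", "patient sex M or F; age group included in the AV",
      mk_record(sex = "male"))
  add("critical", "result strictly within critical limits", mk_record())
  add("demographics", "patient sex absurd/unknown", mk_record(sex = "unknown"))
  add("demographics", "patient age absurd value (200 y)",
      mk_record(dob = dob_for(200)))
  add("demographics", "date of birth missing", mk_record(dob = NA))
  if (length(testdef$age_groups_included)) {
    excl <- Find(function(a) {
      !any(vapply(testdef$age_groups_included,
                  function(g) a >= g[1L] && a < g[2L], logical(1)))
    }, c(10 / 365.25, seq(0.5, 119.5, by = 0.5)))
    if (!is.null(excl)) {
      add("demographics",
          sprintf("age group not included in AV (age %.2f y)", excl),
          mk_record(dob = dob_for(excl)))
    }
  }
  add("av_range", "missing result for the test", mk_record(value = NA))
  for (fl in testdef$flags_blocking) {
    add("flags", sprintf("flag affecting the result (%s)", fl),
        mk_record(flags = fl))
  }
  info_flag <- "INFO_ONLY"
  while (info_flag %in% testdef$flags_blocking) {
    info_flag <- paste0(info_flag, "_X")
  }
  add("flags", sprintf("flag not affecting the result (%s)", info_flag),
      mk_record(flags = info_flag))
  if (length(testdef$analyzers_included)) {
    add("flags", "analyzer excluded from autovalidation",
        mk_record(analyzer = "UNLISTED-ANALYZER"))
  }

  for (nm in names(testdef$hil_thresholds)) {
    thr <- testdef$hil_thresholds[[nm]]
    h_eps <- max(thr * 0.05, 0.1)
    set_idx <- function(x) {
      h <- base_hil; h[[nm]] <- x
      class(h) <- "hil_indices"
      h
    }
    add("hil", sprintf("result within %s index limits (at limit %g)", nm, thr),
        mk_record(hil = set_idx(thr)))
    add("hil", sprintf("result outside %s index limits", nm),
        mk_record(hil = set_idx(thr + h_eps)))
    if (thr - h_eps >= 0) {
      add("hil", sprintf("%s index just below limit", nm),
          mk_record(hil = set_idx(thr - h_eps)))
    }
    add("hil", sprintf("%s index not measured", nm),
        mk_record(hil = set_idx(NA_real_)))
  }

  av <- testdef$av_range
  if (is_bounded(av$low)) {
    add("av_range", "result at low limit of AV range", mk_record(value = av$low))
    add("av_range", "result below AV range", mk_record(value = av$low - eps))
    add("av_range", "result just above low AV limit",
        mk_record(value = av$low + eps))
  } else notes <- c(notes, "AV low limit unbounded: boundary cases skipped")
  if (is_bounded(av$high)) {
    add("av_range", "result at high limit of AV range",
        mk_record(value = av$high))
    add("av_range", "result above AV range", mk_record(value = av$high + eps))
    add("av_range", "result just below high AV limit",
        mk_record(value = av$high - eps))
  } else notes <- c(notes, "AV high limit unbounded: boundary cases skipped")

  cl <- testdef$critical_limits
  if (is_bounded(cl$low)) {
    add("critical", "result at critical low limit", mk_record(value = cl$low))
    add("critical", "result beyond critical low limit",
        mk_record(value = cl$low - eps))
    add("critical", "result just above critical low limit",
        mk_record(value = cl$low + eps))
  } else notes <- c(notes, "critical low unbounded: cases skipped")
  if (is_bounded(cl$high)) {
    add("critical", "result at critical high limit",
        mk_record(value = cl$high))
    add("critical", "result beyond critical high limit",
        mk_record(value = cl$high + eps))
    add("critical", "result just below critical high limit",
        mk_record(value = cl$high - eps))
  } else notes <- c(notes, "critical high unbounded: cases skipped")

  dcfg <- testdef$delta
  if (!is.null(dcfg)) {
    lim <- if (dcfg$mode == "rcv") {
      reference_change_value(dcfg$cv_analytical, testdef$biovar$cvi,
                             dcfg$z_value)
    } else dcfg$limit
    hours <- min(dcfg$window_days * 24 / 2, 24)
    prior_t <- ts - hours * 3600
    prior_value <- switch(dcfg$mode,
      absolute = base_value - lim,
      percent = base_value / (1 + lim / 100),
      rcv = base_value / (1 + lim / 100),
      rate = base_value - lim * hours)
    mk_prior <- function(value, t = prior_t) {
      result_record("V-PRIOR", testdef$test_code, value = value,
                    unit = testdef$unit, timestamp = t,
                    patient = patient_info("VERIF-P", dob_for(base_age),
                                           "female"))
    }
    add("delta", "result at delta check limit", mk_record(),
        prior = mk_prior(prior_value))
    add("delta", "result outside delta check limits",
        mk_record(value = base_value + eps), prior = mk_prior(prior_value))
    add("delta", "result within delta check limits",
        mk_record(value = base_value - eps), prior = mk_prior(prior_value))
    add("delta", "result out of delta check time interval (all other criteria met)",
        mk_record(),
        prior = mk_prior(base_value * 3,
                         t = ts - (dcfg$window_days + 2) * 86400))
  } else notes <- c(notes, "no delta config: delta cases skipped")

  for (cr in config$consistency_rules) {
    if (!(testdef$test_code %in% c(cr$numerator_test, cr$denominator_test)))
      next
    partner <- setdiff(c(cr$numerator_test, cr$denominator_test),
                       testdef$test_code)
    is_num <- identical(cr$numerator_test, testdef$test_code)
    mid <- if (is_bounded(cr$limits$high)) {
      (max(cr$limits$low, 0) + cr$limits$high) / 2
    } else cr$limits$low + 1
    bad <- if (is_bounded(cr$limits$high)) cr$limits$high * 1.5
           else cr$limits$low / 2
    partner_for <- function(ratio, rec) {
      pv <- if (is_num) rec$value / ratio else rec$value * ratio
      result_record(rec$sample_id, partner, value = pv,
                    unit = "", timestamp = ts, patient = rec$patient)
    }
    r_in <- mk_record(); r_out <- mk_record()
    add("consistency",
        sprintf("consistency check %s within limits", cr$rule_id),
        r_in, context = list(partner_for(mid, r_in)))
    add("consistency",
        sprintf("consistency check %s outside limits", cr$rule_id),
        r_out, context = list(partner_for(bad, r_out)))
  }

  if (!is.null(config$qc_policies[[testdef$test_code]]) ||
      length(config$qc_policies)) {
    add("qc", "IQC in control", mk_record(),
        qc = qc_policy(testdef$test_code, TRUE, ts - 3600, 24))
    add("qc", "IQC criteria not met", mk_record(),
        qc = qc_policy(testdef$test_code, FALSE, ts - 3600, 24))
    add("qc", "IQC pass expired", mk_record(),
        qc = qc_policy(testdef$test_code, TRUE, ts - 30 * 3600, 24))
  }

  add("multiple", "combined multi-rule violation",
      mk_record(value = av$high + eps, sex = "unknown",
                flags = utils::head(testdef$flags_blocking, 1L)))

  attr(cases, "notes") <- notes
  cases
}

#' Run Phase I technical verification
#'
#' Executes every generated case through the engine (release channel
#' disabled) and reports per-case concordance between the expected and the
#' actual autovalidation verdict. Any attempted release during the run is a
#' hard failure; the report records the release counter, which must be 0.
#'
#' @param cases List of cases from [generate_phase1_cases()].
#' @param config The [engine_config()] under verification.
#' @param engine The decision function; defaults to [validate_record()].
#'   Tests substitute deliberately mutated engines here.
#' @return A `verification_report` (phase `"I"`).
#' @export
run_phase1 <- function(cases, config, engine = validate_record) {
  old_active <- .av_state$verification_active
  .av_state$verification_active <- TRUE
  on.exit(.av_state$verification_active <- old_active)
  count0 <- .av_state$release_count

  rows <- lapply(cases, function(cs) {
    cfg <- config
    if (!is.null(cs$qc_policy)) {
      cfg$qc_policies[[cs$record$test_code]] <- cs$qc_policy
    }
    dec <- engine(cs$record,
                  history = if (is.null(cs$prior)) list() else list(cs$prior),
                  sample_context = cs$context, config = cfg,
                  now = cs$record$timestamp)
    actual <- if (dec$decision == "AUTOVALIDATED") "YES" else "NO"
    data.frame(case_id = cs$case_id, rule = cs$rule,
               description = cs$description, expected = cs$expected,
               actual = actual, concordant = actual == cs$expected,
               held_rules = paste(held_rules(dec), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case_id = character(), rule = character(),
               description = character(), expected = character(),
               actual = character(), concordant = logical(),
               held_rules = character(), stringsAsFactors = FALSE)

  released <- .av_state$release_count - count0
  if (released > 0L) {
    stop(structure(class = c("av_release_violation", "error", "condition"),
                   list(message = "results were released during verification",
                        call = sys.call())))
  }
  structure(list(
    phase = "I", n_cases = nrow(tab), n_concordant = sum(tab$concordant),
    percent_concordant = if (nrow(tab)) 100 * mean(tab$concordant) else NA_real_,
    percent_autovalidated = if (nrow(tab)) 100 * mean(tab$actual == "YES")
                            else NA_real_,
    cases = tab, discordances = tab[!tab$concordant, , drop = FALSE],
    released_results = released), class = "verification_report")
}

#' Run Phase II: manual-versus-automatic concordance
#'
#' Compares the engine's decisions with manual validation labels for the
#' same records. Records that were autovalidated but manually rejected are
#' the critical discordances (flagged for team review and a possible rule
#' change); records held by the engine but manually accepted are benign
#' discordances (reported, not flagged).
#'
#' @param decisions List of `validation_decision`s, or a decision table from
#'   [decisions_to_df()].
#' @param manual_labels Data frame with columns `sample_id`, `test_code`,
#'   `manual` (values `"accept"` / `"reject"`).
#' @param target_percent Optional predetermined percentage of autovalidated
#'   results the verification aims for; the report marks whether it was met.
#' @return A `verification_report` (phase `"II"`) with the concordance
#'   table (auto x manual), percent autovalidated and the discordance list.
#' @export
run_phase2 <- function(decisions, manual_labels, target_percent = NULL) {
  df <- if (is.data.frame(decisions)) decisions else decisions_to_df(decisions)
  stopifnot(all(c("sample_id", "test_code", "decision") %in% names(df)),
            all(c("sample_id", "test_code", "manual") %in%
                  names(manual_labels)))
  if (!all(manual_labels$manual %in% c("accept", "reject"))) {
    stop("manual labels must be 'accept' or 'reject'", call. = FALSE)
  }
  key <- function(d) paste(d$sample_id, d$test_code, sep = "\r")
  kd <- key(df); kl <- key(manual_labels)
  unmatched <- c(setdiff(kd, kl), setdiff(kl, kd))
  if (length(unmatched)) {
    stop("unmatched record id(s): ",
         paste(gsub("\r", "/", unmatched), collapse = ", "), call. = FALSE)
  }
  m <- manual_labels$manual[match(kd, kl)]
  auto <- df$decision == "AUTOVALIDATED"
  accept <- m == "accept"
  concordant <- (auto & accept) | (!auto & !accept)
  conc_tab <- table(auto = ifelse(auto, "AUTOVALIDATED", "HELD"),
                    manual = m)
  disc <- data.frame(sample_id = df$sample_id, test_code = df$test_code,
                     auto = ifelse(auto, "AUTOVALIDATED", "HELD"),
                     manual = m,
                     flagged = auto & !accept,
                     stringsAsFactors = FALSE)[!concordant, , drop = FALSE]
  pct <- if (nrow(df)) 100 * mean(auto) else NA_real_
  structure(list(
    phase = "II", n_cases = nrow(df), n_concordant = sum(concordant),
    percent_concordant = if (nrow(df)) 100 * mean(concordant) else NA_real_,
    percent_autovalidated = pct, concordance_table = conc_tab,
    discordances = disc,
    target_percent = target_percent,
    target_met = if (is.null(target_percent)) NA else pct >= target_percent,
    released_results = 0L), class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf("<verification_report> Phase %s: %d case(s), %d concordant (%.1f%%)\n",
              x$phase, x$n_cases, x$n_concordant,
              x$percent_concordant))
  cat(sprintf("  autovalidated: %.1f%%; released during verification: %d\n",
              x$percent_autovalidated, x$released_results))
  if (nrow(x$discordances)) {
    cat("  discordances:\n")
    print(x$discordances)
  }
  if (!is.null(x$target_percent)) {
    cat(sprintf("  target %% autovalidated: %g -> %s\n", x$target_percent,
                if (isTRUE(x$target_met)) "met" else "NOT met"))
  }
  invisible(x)
}

#' Export a verification spreadsheet
#'
#' Writes a delimited spreadsheet mirroring the standard technical
#' verification layout: header fields (institution, department, instrument,
#' LIS version, date, verifier), then one row per case with the rule label,
#' sample id, the yes/no autovalidation result and a remark, grouped into
#' expected-YES and expected-NO sections. Layout `"A"` is the cross-test
#' sheet (demographics, flags, missing results); layout `"B"` is the
#' single-test sheet (HIL, AV range, delta, age groups, consistency).
#'
#' @param report A phase-I `verification_report`.
#' @param path Output CSV path.
#' @param which `"A"` or `"B"`.
#' @param meta Named list of header fields: `institution`, `department`,
#'   `instrument`, `test_name`, `lis_version`, `date`, `verifier`.
#' @return `path`, invisibly.
#' @export
export_table4 <- function(report, path, which = c("A", "B"), meta = list()) {
  which <- match.arg(which)
  stopifnot(inherits(report, "verification_report"),
            identical(report$phase, "I"))
  hdr <- c(
    sprintf("# Institution: %s", meta$institution %||% ""),
    sprintf("# Department: %s", meta$department %||% ""),
    if (which == "B") sprintf("# Test name: %s", meta$test_name %||% ""),
    if (which == "B") sprintf("# Instrument: %s", meta$instrument %||% ""),
    sprintf("# LIS version: %s", meta$lis_version %||% ""),
    sprintf("# Date: %s", meta$date %||% format(Sys.Date())),
    sprintf("# Verifier name: %s", meta$verifier %||% ""))
  cross_test <- c("demographics", "flags", "none", "multiple")
  tab <- report$cases
  tab <- if (which == "A") {
    tab[tab$rule %in% cross_test | tab$description == "missing result for the test", , drop = FALSE]
  } else tab
  lines <- hdr
  for (section in c("YES", "NO")) {
    lines <- c(lines,
               sprintf("# Result with expected %s outcome for AV", section),
               "av_rule,sample_id,av_result,remark")
    sub <- tab[tab$expected == section, , drop = FALSE]
    if (nrow(sub)) {
      lines <- c(lines, sprintf("\"%s\",%s,%s,\"%s\"",
                                sub$description, sub$case_id, sub$actual,
                                ifelse(sub$concordant, "",
                                       paste0("DISCORDANT; held: ",
                                              sub$held_rules))))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
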