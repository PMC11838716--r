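td <- glucose_testdef()

test_that("demographics rule requires known age and sex", {
  expect_equal(evaluate_demographics(rec(5), td)$status, "PASS")
  out <- evaluate_demographics(rec(5, patient = adult(sex = "unknown")), td)
  expect_equal(out$status, "HOLD")
  expect_equal(out$reason_code, "missing_sex")
  out <- evaluate_demographics(
    rec(5, patient = patient_info("P1", NA, "male")), td)
  expect_equal(out$reason_code, "missing_dob")
  # 10-day-old neonate with adults-only age groups
  out <- evaluate_demographics(
    rec(5, patient = patient_info("P1", as.Date(TS0) - 10, "male")), td)
  expect_equal(out$reason_code, "age_excluded")
  # implausible age held even without configured age groups
  td_all_ages <- test_definition("GLUC", av_range = interval(3, 11))
  out <- evaluate_demographics(rec(5, patient = adult(age = 200)),
                               td_all_ages)
  expect_equal(out$reason_code, "age_absurd")
})

test_that("age-group bounds are half-open [min, max)", {
  td2 <- test_definition("GLUC", av_range = interval(3, 11),
                         age_groups_included = list(c(18, 65)))
  at18 <- rec(5, patient = patient_info(
    "P1", as.Date("2007-03-10"), "male"))  # 18th birthday on TS0
  expect_equal(evaluate_demographics(at18, td2)$status, "PASS")
  at65 <- rec(5, patient = patient_info(
    "P1", as.Date("1960-03-10"), "male"))  # 65th birthday on TS0
  expect_equal(evaluate_demographics(at65, td2)$reason_code, "age_excluded")
})

test_that("flag rule blocks configured flags and admits the rest", {
  expect_equal(evaluate_flags(rec(5), td)$status, "PASS")
  out <- evaluate_flags(rec(5, flags = "SAMPLE_CLOT"), td)
  expect_equal(out$status, "HOLD")
  expect_match(out$detail, "SAMPLE_CLOT")
  out <- evaluate_flags(rec(5, flags = "INFO_ONLY"), td)
  expect_equal(out$status, "PASS")
  expect_match(out$detail, "INFO_ONLY")  # non-blocking flags are logged
})

test_that("analyzer include list is enforced through the flag rule", {
  td2 <- glucose_testdef(analyzers_included = "AN-1")
  expect_equal(evaluate_flags(rec(5, analyzer = "AN-1"), td2)$status, "PASS")
  expect_equal(evaluate_flags(rec(5, analyzer = "AN-9"), td2)$reason_code,
               "analyzer_excluded")
  expect_equal(evaluate_flags(rec(5), td2)$reason_code, "analyzer_unknown")
})

test_that("HIL rule: exceedance holds, missing index holds, at-limit passes", {
  expect_equal(evaluate_hil(rec(5), td)$status, "PASS")  # index 0
  out <- evaluate_hil(rec(5, hil = hil_indices(150, 0, 0)), td)
  expect_equal(out$reason_code, "hemolysis_exceeded")
  expect_equal(evaluate_hil(rec(5, hil = hil_indices(100, 0, 0)),
                            td)$status, "PASS")  # at threshold
  out <- evaluate_hil(rec(5, hil = hil_indices(NA, 0, 0)), td)
  expect_equal(out$reason_code, "hil_missing")
  td_none <- test_definition("GLUC", av_range = interval(3, 11))
  expect_equal(evaluate_hil(rec(5), td_none)$status, "SKIP")
})

test_that("AV range is inclusive at both boundaries", {
  expect_equal(evaluate_av_range(rec(11.0), td)$status, "PASS")
  expect_equal(evaluate_av_range(rec(3.0), td)$status, "PASS")
  expect_equal(evaluate_av_range(rec(11.1), td)$reason_code,
               "above_av_range")
  expect_equal(evaluate_av_range(rec(2.9), td)$reason_code,
               "below_av_range")
  expect_equal(evaluate_av_range(rec(NA_real_), td)$reason_code,
               "missing_result")
})

test_that("critical limits hold inclusively and dominate the AV range", {
  expect_equal(evaluate_critical(rec(5), td)$status, "PASS")
  expect_equal(evaluate_critical(rec(25), td)$reason_code, "critical_high")
  expect_equal(evaluate_critical(rec(2.5), td)$reason_code, "critical_low")
  expect_equal(evaluate_critical(rec(2.4), td)$reason_code, "critical_low")
  # critical inside AV range still held by the full engine
  td_overlap <- test_definition("GLUC", av_range = interval(0, 30),
                                critical_limits = interval(2.5, 25))
  cfg <- engine_config(tests = list(td_overlap))
  d <- validate_record(rec(26), config = cfg)
  expect_equal(d$decision, "HELD")
  expect_true(d$critical_alert)
  expect_true("critical" %in% held_rules(d))
  expect_false("av_range" %in% held_rules(d))
})

test_that("consistency rule marks both tests, inclusive band, zero denominator", {
  rules <- list(consistency_rule("ast_alt", "AST", "ALT", interval(0.25, 4)))
  mk <- function(ast, alt) list(rec(ast, "AST"), rec(alt, "ALT"))
  out <- evaluate_consistency(mk(50, 50), rules)[[1]]
  expect_equal(out$status, "PASS")
  expect_setequal(attr(out, "tests"), c("AST", "ALT"))
  out <- evaluate_consistency(mk(250, 50), rules)[[1]]  # ratio 5
  expect_equal(out$status, "HOLD")
  expect_equal(evaluate_consistency(mk(200, 50), rules)[[1]]$status,
               "PASS")  # ratio exactly 4: inclusive
  expect_equal(evaluate_consistency(mk(50, 0), rules)[[1]]$reason_code,
               "ratio_undefined")
  expect_equal(evaluate_consistency(list(rec(50, "AST")), rules)[[1]]$status,
               "SKIP")
  expect_error(evaluate_consistency(list(rec(1, "AST", sample_id = "A"),
                                         rec(1, "ALT", sample_id = "B")),
                                    rules), "one sample_id")
})

test_that("QC rule gates on control status and pass expiry", {
  expect_equal(evaluate_qc(td, NULL, TS0)$status, "SKIP")
  ok <- qc_policy("GLUC", TRUE, TS0 - 3600, 24)
  expect_equal(evaluate_qc(td, ok, TS0)$status, "PASS")
  failed <- qc_policy("GLUC", FALSE, TS0 - 3600, 24)
  expect_equal(evaluate_qc(td, failed, TS0)$reason_code, "qc_failed")
  expired <- qc_policy("GLUC", TRUE, TS0 - 25 * 3600, 24)
  expect_equal(evaluate_qc(td, expired, TS0)$reason_code, "qc_expired")
})

test_that("validate_record is the conjunction of all rules", {
  cfg <- small_config()
  d <- validate_record(rec(5), config = cfg)
  expect_equal(d$decision, "AUTOVALIDATED")
  expect_length(held_rules(d), 0L)

  # QC failure is the only HOLD; everything else passes
  cfg_qc <- small_config()
  cfg_qc$qc_policies$GLUC <- qc_policy("GLUC", FALSE, TS0 - 3600, 24)
  d <- validate_record(rec(5), config = cfg_qc)
  expect_equal(d$decision, "HELD")
  expect_equal(held_rules(d), "qc")

  # kill switch dominates a perfectly clean record
  d <- validate_record(rec(5), config = small_config(kill_switch = TRUE))
  expect_equal(d$decision, "HELD")
  expect_true("kill_switch" %in% held_rules(d))

  expect_error(validate_record(rec(5, test_code = "NOPE"),
                               config = cfg), "unknown test_code")
})

test_that("all rules are evaluated with no short-circuit", {
  cfg <- small_config()
  bad <- rec(30, patient = adult(sex = "unknown"), flags = "SAMPLE_CLOT",
             hil = hil_indices(999, 0, 0))
  d <- validate_record(bad, config = cfg)
  expect_setequal(held_rules(d),
                  c("demographics", "flags", "hil", "critical", "av_range"))
  expect_true(d$critical_alert)
})

test_that("validate_batch reports the autovalidated percentage", {
  cfg <- small_config()
  empty <- validate_batch(list(), config = cfg)
  expect_equal(empty$summary$n, 0L)
  expect_true(is.na(empty$summary$percent_autovalidated))

  recs <- list(rec(5, sample_id = "S1"), rec(6, sample_id = "S2"),
               rec(7, sample_id = "S3"),
               rec(30, sample_id = "S4"))  # above AV range and critical
  res <- validate_batch(recs, config = cfg)
  expect_equal(res$summary$n_autovalidated, 3L)
  expect_equal(res$summary$percent_autovalidated, 75.0)
  expect_equal(nrow(res$table), 4L)
  expect_equal(res$table$decision[res$table$sample_id == "S4"], "HELD")
})

test_that("batch delta check sees earlier records of the same stream", {
  cfg <- small_config()
  r1 <- rec(5, sample_id = "S1", timestamp = TS0 - 24 * 3600)
  r2 <- rec(9, sample_id = "S2")  # 80% above prior, limit 30%
  res <- validate_batch(list(r1, r2), config = cfg)
  expect_equal(res$table$decision, c("AUTOVALIDATED", "HELD"))
  expect_match(res$table$reasons[2L], "delta_increase")
})

test_that("identical inputs give identical decisions (determinism)", {
  cfg <- small_config()
  r <- rec(5.5, flags = "INFO_ONLY")
  h <- list(rec(5.0, sample_id = "S0", timestamp = TS0 - 3600 * 20))
  d1 <- validate_record(r, h, config = cfg)
  d2 <- validate_record(r, h, config = cfg)
  expect_identical(d1, d2)
})
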