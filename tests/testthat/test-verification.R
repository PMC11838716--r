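test_that("generated cases cover every enabled rule in both directions", {
  cfg <- example_config()
  td <- cfg$tests$GLUC
  cases <- generate_phase1_cases(td, cfg)
  rules <- vapply(cases, `[[`, character(1), "rule")
  expected <- vapply(cases, `[[`, character(1), "expected")
  enabled <- c("demographics", "flags", "hil", "av_range", "critical",
               "delta", "qc")
  for (r in enabled) {
    expect_true(any(rules == r & expected == "NO"), label = paste(r, "NO"))
    expect_true(any(rules == r & expected == "YES"), label = paste(r, "YES"))
  }
  # boundary convention: at-limit AV cases expect YES, stepped-out NO
  d <- vapply(cases, `[[`, character(1), "description")
  expect_equal(expected[d == "result at low limit of AV range"], "YES")
  expect_equal(expected[d == "result at high limit of AV range"], "YES")
  expect_equal(expected[d == "result below AV range"], "NO")
  expect_equal(expected[d == "result above AV range"], "NO")
  expect_equal(expected[d == "result at critical high limit"], "NO")
  expect_equal(expected[d == "patient age absurd value (200 y)"], "NO")
  expect_equal(
    expected[d == "result out of delta check time interval (all other criteria met)"],
    "YES")
  expect_equal(expected[grepl("flag not affecting", d)], "YES")
})

test_that("consistency cases are generated for tests under a ratio rule", {
  cfg <- example_config()
  cases <- generate_phase1_cases(cfg$tests$AST, cfg)
  rules <- vapply(cases, `[[`, character(1), "rule")
  expected <- vapply(cases, `[[`, character(1), "expected")
  expect_true(any(rules == "consistency" & expected == "YES"))
  expect_true(any(rules == "consistency" & expected == "NO"))
})

test_that("a correct engine is 100% concordant on its own case set", {
  cfg <- example_config()
  for (code in names(cfg$tests)) {
    cases <- generate_phase1_cases(cfg$tests[[code]], cfg)
    rep <- run_phase1(cases, cfg)
    expect_equal(rep$n_concordant, rep$n_cases, label = code)
    expect_equal(rep$released_results, 0L)
  }
})

test_that("single-rule mutations each break concordance at their boundary", {
  cfg <- example_config()
  td <- cfg$tests$GLUC
  cases <- generate_phase1_cases(td, cfg)
  eps <- 10^(-td$decimals)

  mutate <- function(f) { m <- cfg; m$tests$GLUC <- f(m$tests$GLUC); m }
  mutants <- list(
    av_strict_boundary = mutate(function(t) {
      t$av_range <- interval(t$av_range$low + eps / 2,
                             t$av_range$high - eps / 2)
      t
    }),
    hil_tightened = mutate(function(t) {
      t$hil_thresholds$hemolysis <- t$hil_thresholds$hemolysis * 0.5
      t
    }),
    flag_unblocked = mutate(function(t) {
      t$flags_blocking <- setdiff(t$flags_blocking, "SAMPLE_CLOT")
      t
    }),
    delta_halved = mutate(function(t) {
      t$delta$limit <- t$delta$limit / 2
      t
    }),
    neonates_included = mutate(function(t) {
      t$age_groups_included <- list(c(0, 120))
      t
    }))

  for (nm in names(mutants)) {
    rep <- run_phase1(cases, mutants[[nm]])
    expect_gt(nrow(rep$discordances), 0L, label = nm)
  }
  # the inverted AV boundary discords exactly at the at-limit cases
  rep <- run_phase1(cases, mutants$av_strict_boundary)
  expect_setequal(rep$discordances$description,
                  c("result at low limit of AV range",
                    "result at high limit of AV range"))
})

test_that("a critical-boundary mutation is caught when critical limits bite", {
  # critical limits strictly inside the AV range, so the critical rule is
  # the deciding one at its boundary
  td <- test_definition("GLUC", av_range = interval(0, 30),
                        critical_limits = interval(2.5, 25),
                        decimals = 1L)
  cfg <- engine_config(tests = list(td))
  cases <- generate_phase1_cases(td, cfg)
  rep <- run_phase1(cases, cfg)
  expect_equal(rep$n_concordant, rep$n_cases)

  mut <- cfg
  mut$tests$GLUC$critical_limits <- interval(2.45, 25.05)  # exclusive-like
  rep <- run_phase1(cases, mut)
  expect_setequal(rep$discordances$description,
                  c("result at critical low limit",
                    "result at critical high limit"))
})

test_that("no result can be released while verification runs", {
  cfg <- small_config()
  cases <- generate_phase1_cases(cfg$tests$GLUC, cfg)
  n0 <- release_count()
  leaky_engine <- function(record, history, sample_context, config, now) {
    d <- validate_record(record, history, sample_context, config, now)
    release_decisions(list(d), tempfile())  # must fail hard
    d
  }
  expect_error(run_phase1(cases, cfg, engine = leaky_engine),
               class = "av_release_violation")
  rep <- run_phase1(cases, cfg)
  expect_equal(rep$released_results, 0L)
  # outside verification, releasing works and counts
  d <- validate_record(rec(5), config = cfg)
  f <- tempfile(fileext = ".csv")
  release_decisions(list(d), f)
  expect_true(file.exists(f))
  expect_equal(release_count(), n0 + 2L)  # 1 blocked attempt + 1 release
})

test_that("empty case list yields an empty report", {
  rep <- run_phase1(list(), small_config())
  expect_equal(rep$n_cases, 0L)
  expect_true(is.na(rep$percent_concordant))
})

test_that("phase II concordance, percentages and discordance flags", {
  mk_dec <- function(n, n_auto) {
    data.frame(sample_id = sprintf("S%02d", 1:n), test_code = "GLUC",
               decision = rep(c("AUTOVALIDATED", "HELD"),
                              c(n_auto, n - n_auto)))
  }
  labels <- function(dec, manual) data.frame(sample_id = dec$sample_id,
                                             test_code = dec$test_code,
                                             manual = manual)
  # all held, all rejected: 0% autovalidated, full concordance
  dec <- mk_dec(5, 0)
  rep <- run_phase2(dec, labels(dec, "reject"))
  expect_equal(rep$percent_autovalidated, 0)
  expect_equal(rep$n_concordant, 5L)

  # 10 records, 8 autovalidated, 1 of them manually rejected
  dec <- mk_dec(10, 8)
  man <- c("reject", rep("accept", 7), rep("reject", 2))
  rep <- run_phase2(dec, labels(dec, man))
  expect_equal(rep$percent_autovalidated, 80)
  expect_equal(sum(rep$discordances$flagged), 1L)
  expect_equal(rep$discordances$sample_id[rep$discordances$flagged], "S01")

  # held but manually accepted: benign discordance, reported unflagged
  dec <- mk_dec(4, 0)
  rep <- run_phase2(dec, labels(dec, c("accept", rep("reject", 3))))
  expect_equal(nrow(rep$discordances), 1L)
  expect_false(any(rep$discordances$flagged))

  # target percentage marking
  dec <- mk_dec(10, 8)
  rep <- run_phase2(dec, labels(dec, "accept"), target_percent = 90)
  expect_false(rep$target_met)
  rep <- run_phase2(dec, labels(dec, "accept"), target_percent = 75)
  expect_true(rep$target_met)

  # unmatched ids are an error listing them
  dec <- mk_dec(3, 3)
  short <- labels(dec, "accept")[1:2, ]
  expect_error(run_phase2(dec, short), "S03")
  expect_error(run_phase2(dec, labels(dec, "maybe")), "accept")
})

test_that("verification spreadsheets are written in both layouts", {
  cfg <- example_config()
  cases <- generate_phase1_cases(cfg$tests$GLUC, cfg)
  rep <- run_phase1(cases, cfg)
  fa <- tempfile(fileext = ".csv")
  fb <- tempfile(fileext = ".csv")
  export_table4(rep, fa, "A", meta = list(institution = "GH Test",
                                          lis_version = "9.1",
                                          verifier = "A. Verifier"))
  export_table4(rep, fb, "B", meta = list(test_name = "Glucose",
                                          instrument = "AN-1"))
  a <- readLines(fa)
  b <- readLines(fb)
  expect_true(any(grepl("Institution: GH Test", a)))
  expect_true(any(grepl("expected YES outcome", a)))
  expect_true(any(grepl("expected NO outcome", a)))
  expect_true(any(grepl("Test name: Glucose", b)))
  expect_true(any(grepl("hemolysis", b)))       # HIL boundary rows
  expect_true(any(grepl("delta check", b)))
  expect_true(any(grepl("low limit of AV range", b)))
  # one row per case across the two sections of layout B
  expect_equal(sum(grepl("^\"", b)), rep$n_cases)
})
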