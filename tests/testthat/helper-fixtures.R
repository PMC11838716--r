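# shared fixture builders: everything is generated in code, no stored data

TS0 <- as.POSIXct("2025-03-10 08:00:00", tz = "UTC")

adult <- function(id = "P1", age = 45, sex = "female") {
  patient_info(id, as.Date(TS0) - round(age * 365.25), sex)
}

rec <- function(value, test_code = "GLUC", sample_id = "S1",
                patient = adult(), timestamp = TS0, flags = character(),
                hil = hil_indices(0, 0, 0), analyzer = NA_character_) {
  result_record(sample_id, test_code, value = value, unit = "",
                timestamp = timestamp, patient = patient, flags = flags,
                hil = hil, analyzer = analyzer)
}

glucose_testdef <- function(...) {
  test_definition("GLUC", "Glucose", "mmol/L",
                  av_range = interval(3, 11),
                  critical_limits = interval(2.5, 25),
                  hil_thresholds = list(hemolysis = 100),
                  delta = delta_config("percent", limit = 30,
                                       window_days = 3),
                  age_groups_included = list(c(18, 120)),
                  flags_blocking = c("SAMPLE_CLOT", "SAMPLE_SHORT"),
                  decimals = 1L, ...)
}

small_config <- function(kill_switch = FALSE, qc = TRUE) {
  engine_config(
    tests = list(
      glucose_testdef(),
      test_definition("AST", av_range = interval(5, 200),
                      critical_limits = interval(high = 2000),
                      age_groups_included = list(c(18, 120)),
                      decimals = 0L),
      test_definition("ALT", av_range = interval(5, 250),
                      critical_limits = interval(high = 2000),
                      age_groups_included = list(c(18, 120)),
                      decimals = 0L)),
    consistency_rules = list(
      consistency_rule("ast_alt", "AST", "ALT", interval(0.25, 4))),
    qc_policies = if (qc) list(
      qc_policy("GLUC", TRUE, TS0 - 3600, 24)) else list(),
    kill_switch = kill_switch)
}

example_config <- function() {
  load_config(system.file("extdata", "example_config.yaml",
                          package = "autovalidr"))
}

biovar_fixture <- function() {
  read_biovar(system.file("extdata", "biological_variation.csv",
                          package = "autovalidr"))
}

# independent sort-and-interpolate percentile oracle (linear interpolation
# between order statistics), written directly from the documented formula
oracle_percentile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- 1 + (n - 1) * p / 100
  k <- floor(h)
  g <- h - k
  xs[k] + g * (xs[min(k + 1, n)] - xs[k])
}

# evaluate the delta rule for every patient's second draw against the
# first; a comparison is error-affected when either record carries a
# non-clean ground-truth label
delta_pair_outcomes <- function(sim, td) {
  recs <- autovalidr:::as_record_list(sim$records)
  labels <- sim$truth$label
  pid <- sim$records$patient_id
  ord <- order(pid, sim$records$timestamp)
  patient <- character(0)
  hold <- logical(0)
  affected <- logical(0)
  i <- 1L
  while (i < length(ord)) {
    a <- ord[i]; b <- ord[i + 1L]
    if (pid[a] == pid[b]) {
      out <- evaluate_delta(recs[[b]], list(recs[[a]]), td$delta, td)
      patient[length(patient) + 1L] <- pid[a]
      hold[length(hold) + 1L] <- out$status == "HOLD"
      affected[length(affected) + 1L] <-
        labels[a] != "clean" || labels[b] != "clean"
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  data.frame(patient = patient, hold = hold, affected = affected)
}

# random record generator used by the property suites: fields are drawn so
# every rule (demographics, flags, HIL, AV range, critical, delta, QC) gets
# exercised in both passing and failing regions
random_record <- function(i, config) {
  codes <- names(config$tests)
  code <- sample(codes, 1L)
  sexes <- c("male", "female", "unknown")
  has_dob <- stats::runif(1) > 0.1
  age <- stats::runif(1, 0, 130)
  value <- if (stats::runif(1) < 0.05) NA_real_ else
    stats::runif(1, -5, 40)
  flags <- character()
  if (stats::runif(1) < 0.2) flags <- c(flags, "SAMPLE_CLOT")
  if (stats::runif(1) < 0.2) flags <- c(flags, "INFO_ONLY")
  hem <- if (stats::runif(1) < 0.1) NA_real_ else stats::runif(1, 0, 200)
  p <- patient_info(sprintf("P%04d", sample.int(500, 1)),
                    if (has_dob) as.Date(TS0) - round(age * 365.25) else NA,
                    sample(sexes, 1L, prob = c(0.45, 0.45, 0.1)))
  result_record(sprintf("S%06d", i), code, value = value, unit = "",
                timestamp = TS0 - stats::runif(1, 0, 48) * 3600,
                patient = p, flags = flags,
                hil = hil_indices(hemolysis = hem, icterus = 0, lipemia = 0))
}
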