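#' Specification for a synthetic result stream
#'
#' Describes a stationary patient population: each patient owns a
#' homeostatic set-point drawn from the between-subject distribution
#' (spread `cvg`), and serial results vary about that set-point with the
#' combined within-subject and analytical spread `sqrt(cvi^2 + cva^2)`.
#' All distributions are log-normal (analyte concentrations are positive);
#' CVs are interpreted on the natural scale via
#' `sdlog = sqrt(log(1 + (cv/100)^2))`, so the generated between/within CVs
#' equal the specified ones exactly in expectation.
#'
#' @param n_patients Number of patients (>= 1).
#' @param tests Data frame with columns `test_code`, `mean`, `cvi`, `cvg`,
#'   `cva` (CVs in percent) and optionally `unit`.
#' @param draws_per_patient Serial samples per patient (>= 1).
#' @param interval_hours Length-2 numeric `c(min, max)`: time between
#'   consecutive draws of one patient is uniform on this range.
#' @param error_rates Named list of per-record injection probabilities:
#'   `swap`, `dilution`, `hemolysis`, `flag` (each in \[0, 1\]). Errors are
#'   mutually exclusive per record (a record carries at most one label).
#' @param seed Integer seed; a fixed spec yields byte-identical output.
#' @return A `sim_spec` object.
#' @export
sim_spec <- function(n_patients, tests, draws_per_patient = 2L,
                     interval_hours = c(12, 72),
                     error_rates = list(swap = 0, dilution = 0,
                                        hemolysis = 0, flag = 0),
                     seed = 1L) {
  stopifnot(is.data.frame(tests),
            all(c("test_code", "mean", "cvi", "cvg", "cva") %in%
                  names(tests)))
  if (!is.numeric(n_patients) || n_patients < 1) {
    stop("n_patients must be >= 1", call. = FALSE)
  }
  if (draws_per_patient < 1) stop("draws_per_patient must be >= 1",
                                  call. = FALSE)
  stopifnot(length(interval_hours) == 2L, interval_hours[1L] > 0,
            interval_hours[1L] <= interval_hours[2L])
  defaults <- list(swap = 0, dilution = 0, hemolysis = 0, flag = 0)
  defaults[names(error_rates)] <- error_rates
  for (nm in names(defaults)) {
    p <- defaults[[nm]]
    if (!is.numeric(p) || p < 0 || p > 1) {
      stop(sprintf("error rate '%s' must lie in [0, 1]", nm), call. = FALSE)
    }
  }
  if (any(tests$mean <= 0) || any(tests$cvg < 0) || any(tests$cvi < 0) ||
      any(tests$cva < 0)) {
    stop("test means must be > 0 and CVs >= 0", call. = FALSE)
  }
  if (is.null(tests$unit)) tests$unit <- ""
  structure(list(n_patients = as.integer(n_patients), tests = tests,
                 draws_per_patient = as.integer(draws_per_patient),
                 interval_hours = as.numeric(interval_hours),
                 error_rates = defaults, seed = as.integer(seed)),
            class = "sim_spec")
}

SIM_EPOCH <- as.POSIXct("2025-01-06 07:00:00", tz = "UTC")

#' Simulate an error-free result stream from a patient population
#'
#' Draws a homeostatic set-point per patient and test, then serial results
#' about the set-point, with strictly increasing per-patient timestamps.
#' One sample (barcode) per patient-draw carries all tests. Patients get
#' random adult demographics (ages 20-90, sex male/female). Output is
#' deterministic for a fixed spec (including its seed).
#'
#' @param spec A [sim_spec()].
#' @return List with `records` (data frame in the package record schema,
#'   see [read_records()]) and `truth` (one row per record: `sample_id`,
#'   `test_code`, `label = "clean"`, `swap_partner = NA`).
#' @export
simulate_population <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  np <- spec$n_patients
  nd <- spec$draws_per_patient
  pid <- sprintf("P%05d", seq_len(np))
  dob <- as.Date(SIM_EPOCH) - round(stats::runif(np, 20, 90) * 365.25)
  sex <- sample(c("male", "female"), np, replace = TRUE)

  # per-patient draw times: start offset + cumulative uniform gaps
  gaps <- matrix(stats::runif(np * nd, spec$interval_hours[1L],
                              spec$interval_hours[2L]), nrow = np)
  start <- stats::runif(np, 0, 24)
  times_h <- start + t(apply(gaps, 1L, cumsum))
  if (nd == 1L) times_h <- matrix(times_h, nrow = np)

  rows <- vector("list", nrow(spec$tests))
  for (j in seq_len(nrow(spec$tests))) {
    t <- spec$tests[j, ]
    sg <- sqrt(log(1 + (t$cvg / 100)^2))
    sw <- sqrt(log(1 + ((sqrt(t$cvi^2 + t$cva^2)) / 100)^2))
    mu_log <- log(t$mean) - sg^2 / 2 - sw^2 / 2
    setpt <- mu_log + sg * stats::rnorm(np)
    vals <- exp(setpt[rep(seq_len(np), each = nd)] +
                  sw * stats::rnorm(np * nd))
    idx_p <- rep(seq_len(np), each = nd)
    idx_d <- rep(seq_len(nd), times = np)
    rows[[j]] <- data.frame(
      sample_id = sprintf("S-%05d-%02d", idx_p, idx_d),
      patient_id = pid[idx_p],
      date_of_birth = dob[idx_p],
      sex = sex[idx_p],
      patient_class = "inpatient",
      location = "WARD-1",
      test_code = t$test_code,
      value = round(vals, 4L),
      unit = t$unit,
      timestamp = SIM_EPOCH + 3600 * times_h[cbind(idx_p, idx_d)],
      flags = "",
      hemolysis = 0, icterus = 0, lipemia = 0,
      analyzer = "AN-1",
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  records <- records[order(records$timestamp, records$sample_id,
                           records$test_code), , drop = FALSE]
  rownames(records) <- NULL
  truth <- data.frame(sample_id = records$sample_id,
                      test_code = records$test_code,
                      label = "clean", swap_partner = NA_character_,
                      stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

truth_key <- function(df) paste(df$sample_id, df$test_code, sep = "\r")

clean_idx <- function(sim, test_code = NULL) {
  ok <- sim$truth$label == "clean" & is.finite(sim$records$value)
  if (!is.null(test_code)) ok <- ok & sim$records$test_code == test_code
  which(ok)
}

#' Inject sample-swap errors (misidentification)
#'
#' Exchanges the values of pairs of same-test results belonging to
#' different patients — the classic sample misidentification the delta
#' check exists to catch. Timestamps, sample ids and all context stay with
#' the original record; only the measured values move. Both members of a
#' pair are labelled `swapped` with each other's sample id as
#' `swap_partner`. Only still-clean records are eligible (errors are
#' mutually exclusive per record).
#'
#' @param sim A `list(records, truth)` from [simulate_population()].
#' @param rate Fraction of eligible records to involve in swaps (pairs are
#'   formed, so the number of pairs is `floor(rate * n_eligible / 2)` per
#'   test).
#' @param seed Integer seed.
#' @return The modified `list(records, truth)`.
#' @export
inject_swap <- function(sim, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(sim)
  set.seed(seed)
  rec <- sim$records; tr <- sim$truth
  for (code in unique(rec$test_code)) {
    idx <- clean_idx(list(records = rec, truth = tr), code)
    if (length(idx) < 2L) next
    n_pairs <- floor(rate * length(idx) / 2)
    if (n_pairs < 1L) next
    perm <- sample(idx)
    pats <- rec$patient_id[perm]
    used <- 0L
    i <- 1L
    while (used < n_pairs && i < length(perm)) {
      # walk the shuffled list pairing adjacent entries from different
      # patients; skip same-patient adjacencies
      j <- i + 1L
      while (j <= length(perm) && pats[j] == pats[i]) j <- j + 1L
      if (j > length(perm)) break
      a <- perm[i]; b <- perm[j]
      tmp <- rec$value[a]
      rec$value[a] <- rec$value[b]
      rec$value[b] <- tmp
      tr$label[c(a, b)] <- "swapped"
      tr$swap_partner[a] <- rec$sample_id[b]
      tr$swap_partner[b] <- rec$sample_id[a]
      perm <- perm[-c(i, j)]
      pats <- rec$patient_id[perm]
      used <- used + 1L
    }
  }
  list(records = rec, truth = tr)
}

#' Inject intravenous-fluid dilution errors
#'
#' Multiplies selected clean values by a dilution factor in (0, 1),
#' emulating a sample drawn downstream of an intravenous infusion.
#'
#' @inheritParams inject_swap
#' @param rate Fraction of eligible records to dilute.
#' @param factor Dilution factor, strictly between 0 and 1.
#' @return The modified `list(records, truth)`.
#' @export
inject_dilution <- function(sim, rate, factor = 0.5, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  if (!(factor > 0 && factor < 1)) {
    stop("dilution factor must lie strictly in (0, 1)", call. = FALSE)
  }
  if (rate == 0) return(sim)
  set.seed(seed)
  idx <- clean_idx(sim)
  n <- round(rate * length(idx))
  if (n < 1L) return(sim)
  pick <- sample(idx, n)
  sim$records$value[pick] <- sim$records$value[pick] * factor
  sim$truth$label[pick] <- "diluted"
  sim
}

#' Inject hemolyzed samples
#'
#' Sets the hemolysis index of selected clean records to `index_value`
#' (which should exceed the paired configuration's hemolysis threshold so
#' the HIL rule fires on them).
#'
#' @inheritParams inject_swap
#' @param rate Fraction of eligible records to hemolyze.
#' @param index_value Hemolysis index assigned to the affected records.
#' @return The modified `list(records, truth)`.
#' @export
inject_hemolysis <- function(sim, rate, index_value = 500, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1, index_value >= 0)
  if (rate == 0) return(sim)
  set.seed(seed)
  idx <- clean_idx(sim)
  n <- round(rate * length(idx))
  if (n < 1L) return(sim)
  pick <- sample(idx, n)
  sim$records$hemolysis[pick] <- index_value
  sim$truth$label[pick] <- "hemolyzed"
  sim
}

#' Inject blocking analyzer flags
#'
#' @inheritParams inject_swap
#' @param rate Fraction of eligible records to flag.
#' @param flag Flag code to attach.
#' @return The modified `list(records, truth)`.
#' @export
inject_flag <- function(sim, rate, flag = "SAMPLE_CLOT", seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(sim)
  set.seed(seed)
  idx <- clean_idx(sim)
  n <- round(rate * length(idx))
  if (n < 1L) return(sim)
  pick <- sample(idx, n)
  sim$records$flags[pick] <- flag
  sim$truth$label[pick] <- "flagged"
  sim
}

#' Simulate a full stream with the spec's error injections applied
#'
#' Runs [simulate_population()] and then each injector whose rate in the
#' spec is positive (swap, dilution, hemolysis, flag), with sub-seeds
#' derived deterministically from the spec seed.
#'
#' @param spec A [sim_spec()].
#' @param dilution_factor,hemolysis_index,flag_code Injection parameters.
#' @return `list(records, truth)`.
#' @export
simulate_stream <- function(spec, dilution_factor = 0.5,
                            hemolysis_index = 500,
                            flag_code = "SAMPLE_CLOT") {
  sim <- simulate_population(spec)
  r <- spec$error_rates
  if (r$swap > 0) sim <- inject_swap(sim, r$swap, seed = spec$seed + 101L)
  if (r$dilution > 0) {
    sim <- inject_dilution(sim, r$dilution, dilution_factor,
                           seed = spec$seed + 202L)
  }
  if (r$hemolysis > 0) {
    sim <- inject_hemolysis(sim, r$hemolysis, hemolysis_index,
                            seed = spec$seed + 303L)
  }
  if (r$flag > 0) {
    sim <- inject_flag(sim, r$flag, flag_code, seed = spec$seed + 404L)
  }
  sim
}
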