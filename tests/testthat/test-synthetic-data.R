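sim_tests <- function(...) {
  data.frame(test_code = "GLUC", mean = 5.5, cvi = 4.6, cvg = 8.1,
             cva = 2, unit = "mmol/L", ...)
}

test_that("sim_spec validates rates, counts and tests", {
  expect_s3_class(sim_spec(10, sim_tests()), "sim_spec")
  expect_error(sim_spec(0, sim_tests()), "n_patients")
  expect_error(sim_spec(10, sim_tests(), draws_per_patient = 0), "draws")
  expect_error(sim_spec(10, sim_tests(),
                        error_rates = list(swap = 1.5)), "\\[0, 1\\]")
  bad <- sim_tests(); bad$mean <- -1
  expect_error(sim_spec(10, bad), "> 0")
})

test_that("simulation is byte-identical under a fixed seed", {
  spec <- sim_spec(30, sim_tests(), draws_per_patient = 3, seed = 7,
                   error_rates = list(swap = 0.1, dilution = 0.05,
                                      hemolysis = 0.05, flag = 0.05))
  a <- simulate_stream(spec)
  b <- simulate_stream(spec)
  expect_identical(a, b)
  c <- simulate_stream(sim_spec(30, sim_tests(), draws_per_patient = 3,
                                seed = 8,
                                error_rates = list(swap = 0.1)))
  expect_false(identical(a$records$value, c$records$value))
})

test_that("degenerate spreads collapse as expected", {
  # no between-subject spread: every patient shares the set-point
  t0 <- sim_tests(); t0$cvg <- 0; t0$cvi <- 0; t0$cva <- 0
  sim <- simulate_population(sim_spec(20, t0, draws_per_patient = 3,
                                      seed = 1))
  expect_equal(length(unique(sim$records$value)), 1L)
  # within-subject spread only kills serial variation per patient
  t1 <- sim_tests(); t1$cvi <- 0; t1$cva <- 0
  sim <- simulate_population(sim_spec(20, t1, draws_per_patient = 3,
                                      seed = 2))
  per_patient <- tapply(sim$records$value, sim$records$patient_id,
                        function(v) length(unique(v)))
  expect_true(all(per_patient == 1L))
  expect_gt(length(unique(sim$records$value)), 1L)
})

test_that("generated data recover the specified moments", {
  spec <- sim_spec(4000, sim_tests(), draws_per_patient = 3, seed = 99)
  sim <- simulate_population(spec)
  v <- sim$records$value
  n <- length(v)
  expect_equal(n, 12000L)
  expect_equal(mean(v), 5.5, tolerance = 0.02)
  # log-scale decomposition: between-patient sd of patient means and pooled
  # within-patient sd, against the transformed target CVs
  lv <- log(v)
  pm <- tapply(lv, sim$records$patient_id, mean)
  wsd <- sqrt(mean(tapply(lv, sim$records$patient_id, stats::var)))
  sw_target <- sqrt(log(1 + (sqrt(4.6^2 + 2^2) / 100)^2))
  sg_target <- sqrt(log(1 + (8.1 / 100)^2))
  expect_equal(wsd, sw_target, tolerance = 0.03)
  # patient means carry within-noise/3; compare against its expectation
  expect_equal(stats::sd(pm), sqrt(sg_target^2 + sw_target^2 / 3),
               tolerance = 0.1)
  # timestamps strictly increase within each patient
  by_p <- split(sim$records$timestamp, sim$records$patient_id)
  expect_true(all(vapply(by_p, function(x) all(diff(sort(unique(x))) > 0),
                         logical(1))))
})

test_that("swap injection exchanges values across patients only", {
  spec <- sim_spec(40, sim_tests(), draws_per_patient = 2, seed = 5)
  sim <- simulate_population(spec)
  swapped <- inject_swap(sim, rate = 0.5, seed = 6)
  expect_identical(inject_swap(sim, rate = 0, seed = 6), sim)
  idx <- which(swapped$truth$label == "swapped")
  expect_gt(length(idx), 0L)
  # context (ids, timestamps) untouched; only values moved
  expect_identical(swapped$records$sample_id, sim$records$sample_id)
  expect_identical(swapped$records$timestamp, sim$records$timestamp)
  key <- paste(sim$records$sample_id, sim$records$test_code)
  for (i in idx) {
    partner <- which(key == paste(swapped$truth$swap_partner[i],
                                  swapped$truth$test_code[i]))
    expect_length(partner, 1L)
    # values exchanged pairwise, between different patients
    expect_equal(swapped$records$value[i], sim$records$value[partner])
    expect_false(sim$records$patient_id[i] ==
                   sim$records$patient_id[partner])
  }
  # rate 1 with 2 patients: every pairable value exchanged
  two <- simulate_population(sim_spec(2, sim_tests(),
                                      draws_per_patient = 2, seed = 3))
  all_sw <- inject_swap(two, rate = 1, seed = 4)
  expect_true(all(all_sw$truth$label == "swapped"))
})

test_that("dilution and hemolysis injections label exactly what they touch", {
  spec <- sim_spec(50, sim_tests(), draws_per_patient = 2, seed = 12)
  sim <- simulate_population(spec)
  dil <- inject_dilution(sim, rate = 0.2, factor = 0.5, seed = 13)
  idx <- which(dil$truth$label == "diluted")
  expect_equal(length(idx), round(0.2 * nrow(sim$records)))
  expect_equal(dil$records$value[idx], sim$records$value[idx] * 0.5)
  untouched <- setdiff(seq_len(nrow(sim$records)), idx)
  expect_equal(dil$records$value[untouched], sim$records$value[untouched])
  expect_error(inject_dilution(sim, 0.1, factor = 1.2), "\\(0, 1\\)")

  hem <- inject_hemolysis(sim, rate = 0.1, index_value = 500, seed = 14)
  h_idx <- which(hem$truth$label == "hemolyzed")
  expect_true(all(hem$records$hemolysis[h_idx] == 500))
  # injected records HOLD under the HIL rule of a paired config
  td <- glucose_testdef()
  recs <- as.data.frame(hem$records[h_idx[1:min(5, length(h_idx))], ])
  for (r in autovalidr:::as_record_list(recs)) {
    expect_equal(evaluate_hil(r, td)$reason_code, "hemolysis_exceeded")
  }
})

test_that("errors are mutually exclusive per record", {
  spec <- sim_spec(60, sim_tests(), draws_per_patient = 2, seed = 21,
                   error_rates = list(swap = 0.3, dilution = 0.3,
                                      hemolysis = 0.3, flag = 0.3))
  sim <- simulate_stream(spec)
  expect_true(all(sim$truth$label %in%
                    c("clean", "swapped", "diluted", "hemolyzed",
                      "flagged")))
  # each record carries exactly one label; injectors only touched cleans
  expect_equal(nrow(sim$truth), nrow(sim$records))
  flagged <- sim$truth$label == "flagged"
  expect_true(all(sim$records$flags[flagged] == "SAMPLE_CLOT"))
  expect_true(all(sim$records$flags[!flagged] == ""))
})
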