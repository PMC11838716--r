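#' Load an engine configuration from a YAML document
#'
#' The configuration format is a single, versioned YAML schema
#' (`schema_version: 1`); see `system.file("extdata", "example_config.yaml",
#' package = "autovalidr")` for a complete annotated example. All structural
#' invariants are checked and every violation is reported with the path to
#' the offending field before the loader fails, so a rule-change review sees
#' the full list at once.
#'
#' @param source Path to a YAML file, or a literal YAML string.
#' @return An [engine_config()].
#' @export
load_config <- function(source) {
  doc <- tryCatch({
    if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
      yaml::read_yaml(source)
    } else {
      yaml::yaml.load(paste(source, collapse = "\n"))
    }
  }, error = function(e) {
    stop("config parse error: ", conditionMessage(e), call. = FALSE)
  })
  if (!is.list(doc)) stop("config parse error: not a mapping", call. = FALSE)
  if (is.null(doc$schema_version) || doc$schema_version != 1) {
    stop("config validation error: schema_version must be 1", call. = FALSE)
  }

  errs <- character()
  note <- function(path, msg) errs[[length(errs) + 1L]] <<- paste0(path, ": ", msg)

  parse_interval <- function(x, path) {
    lo <- if (is.null(x$low)) -Inf else as.numeric(x$low)
    hi <- if (is.null(x$high)) Inf else as.numeric(x$high)
    tryCatch(interval(lo, hi),
             error = function(e) { note(path, conditionMessage(e)); interval() })
  }

  tests <- list()
  for (i in seq_along(doc$tests)) {
    t <- doc$tests[[i]]
    path <- sprintf("tests[%d]", i)
    td <- tryCatch({
      delta <- NULL
      if (!is.null(t$delta)) {
        d <- t$delta
        delta <- delta_config(
          mode = d$mode %||% "percent",
          limit = as.numeric(d$limit %||% NA_real_),
          window_days = as.numeric(d$window_days %||% NA_real_),
          z_value = as.numeric(d$z_value %||% 1.96),
          cv_analytical = as.numeric(d$cv_analytical %||% NA_real_))
      }
      biovar <- NULL
      if (!is.null(t$biovar)) {
        biovar <- biological_variation(as.numeric(t$biovar$cvi),
                                       as.numeric(t$biovar$cvg))
      }
      test_definition(
        test_code = as.character(t$test_code %||% ""),
        name = as.character(t$name %||% t$test_code %||% ""),
        unit = as.character(t$unit %||% ""),
        av_range = parse_interval(t$av_range, paste0(path, ".av_range")),
        critical_limits = parse_interval(t$critical_limits,
                                         paste0(path, ".critical_limits")),
        hil_thresholds = lapply(t$hil_thresholds %||% list(), as.numeric),
        delta = delta, biovar = biovar,
        age_groups_included = t$age_groups_included %||% list(),
        flags_blocking = unlist(t$flags_blocking %||% character()),
        analyzers_included = unlist(t$analyzers_included %||% character()),
        decimals = as.integer(t$decimals %||% 1L))
    }, error = function(e) { note(path, conditionMessage(e)); NULL })
    if (!is.null(td)) tests[[length(tests) + 1L]] <- td
  }
  if (!length(tests) && !length(errs)) {
    note("tests", "at least one test definition is required")
  }

  crules <- list()
  known <- vapply(tests, `[[`, character(1), "test_code")
  for (i in seq_along(doc$consistency_rules)) {
    cr <- doc$consistency_rules[[i]]
    path <- sprintf("consistency_rules[%d]", i)
    out <- tryCatch({
      rule <- consistency_rule(
        rule_id = as.character(cr$rule_id %||% sprintf("rule_%d", i)),
        numerator_test = as.character(cr$numerator_test),
        denominator_test = as.character(cr$denominator_test),
        limits = parse_interval(cr$limits, paste0(path, ".limits")))
      missing_ref <- setdiff(c(rule$numerator_test, rule$denominator_test),
                             known)
      if (length(missing_ref)) {
        note(path, paste0("references undefined test(s): ",
                          paste(missing_ref, collapse = ", ")))
        NULL
      } else rule
    }, error = function(e) { note(path, conditionMessage(e)); NULL })
    if (!is.null(out)) crules[[length(crules) + 1L]] <- out
  }

  qps <- list()
  for (i in seq_along(doc$qc_policies)) {
    q <- doc$qc_policies[[i]]
    path <- sprintf("qc_policies[%d]", i)
    out <- tryCatch(
      qc_policy(as.character(q$test_code),
                in_control = isTRUE(q$in_control),
                last_pass_time = parse_timestamp(
                  gsub("[TZ]", " ", as.character(q$last_pass_time))),
                max_age_hours = as.numeric(q$max_age_hours)),
      error = function(e) { note(path, conditionMessage(e)); NULL })
    if (!is.null(out)) qps[[length(qps) + 1L]] <- out
  }

  if (length(errs)) {
    stop("config validation error:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  }
  engine_config(tests = tests, consistency_rules = crules,
                qc_policies = qps,
                mode = doc$mode %||% "manual_trigger",
                kill_switch = isTRUE(doc$kill_switch))
}

#' Serialize an engine configuration back to YAML
#'
#' `load_config(write_config(cfg, tempfile()))` yields a structurally
#' identical configuration (round-trip property).
#'
#' @param config An [engine_config()].
#' @param path Output file path; when `NULL` the YAML text is returned.
#' @return `path` (invisibly), or the YAML string when `path` is `NULL`.
#' @export
write_config <- function(config, path = NULL) {
  stopifnot(inherits(config, "engine_config"))
  iv2l <- function(iv) {
    out <- list()
    if (is_bounded(iv$low)) out$low <- iv$low
    if (is_bounded(iv$high)) out$high <- iv$high
    out
  }
  doc <- list(
    schema_version = 1L,
    mode = config$mode,
    kill_switch = config$kill_switch,
    tests = lapply(unname(config$tests), function(t) {
      out <- list(test_code = t$test_code, name = t$name, unit = t$unit,
                  decimals = t$decimals,
                  av_range = iv2l(t$av_range),
                  critical_limits = iv2l(t$critical_limits))
      if (length(t$hil_thresholds)) out$hil_thresholds <- t$hil_thresholds
      if (!is.null(t$delta)) {
        d <- t$delta[!vapply(t$delta, function(x) is.na(x[1L]), logical(1))]
        out$delta <- d
      }
      if (!is.null(t$biovar)) out$biovar <- unclass(t$biovar)
      if (length(t$age_groups_included)) {
        out$age_groups_included <- lapply(t$age_groups_included, as.list)
      }
      if (length(t$flags_blocking)) out$flags_blocking <- as.list(t$flags_blocking)
      if (length(t$analyzers_included)) {
        out$analyzers_included <- as.list(t$analyzers_included)
      }
      out
    }),
    consistency_rules = lapply(config$consistency_rules, function(cr) {
      list(rule_id = cr$rule_id, numerator_test = cr$numerator_test,
           denominator_test = cr$denominator_test, limits = iv2l(cr$limits))
    }),
    qc_policies = lapply(unname(config$qc_policies), function(q) {
      list(test_code = q$test_code, in_control = q$in_control,
           last_pass_time = format(q$last_pass_time, "%Y-%m-%dT%H:%M:%SZ",
                                   tz = "UTC"),
           max_age_hours = q$max_age_hours)
    }))
  txt <- yaml::as.yaml(doc, precision = 15L)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
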