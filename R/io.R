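# canonical delimited dialect: UTF-8, comma-separated, ISO-8601 UTC
# timestamps, dot decimal separator
RECORD_COLUMNS <- c("sample_id", "patient_id", "date_of_birth", "sex",
                    "patient_class", "location", "test_code", "value",
                    "unit", "timestamp", "flags", "hemolysis", "icterus",
                    "lipemia", "analyzer")

parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) return(lubridate::with_tz(x, "UTC"))
  out <- lubridate::parse_date_time(as.character(x),
                                    orders = c("Ymd HMS", "Ymd HM", "Ymd"),
                                    tz = "UTC", quiet = TRUE)
  if (any(is.na(out) & !is.na(x) & nzchar(as.character(x)))) {
    bad <- which(is.na(out) & !is.na(x))[1L]
    stop(sprintf("unparseable timestamp '%s'", as.character(x)[bad]),
         call. = FALSE)
  }
  out
}

#' Read a result-record file
#'
#' The record schema is a comma-separated UTF-8 file with columns
#' `sample_id, patient_id, date_of_birth, sex, patient_class, location,
#' test_code, value, unit, timestamp, flags, hemolysis, icterus, lipemia,
#' analyzer`. Timestamps are ISO-8601 (UTC assumed); `flags` is a
#' `;`-separated list; empty cells mean missing. Rows that fail to parse
#' are reported with their line number.
#'
#' @param path CSV file path.
#' @return A data frame with typed columns (`timestamp` as `POSIXct`,
#'   `date_of_birth` as `Date`).
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(RECORD_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("record file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- function(col, line_offset = 1L) {
    x <- df[[col]]
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & nzchar(x) & is.na(out))
    if (length(bad)) {
      stop(sprintf("line %d: non-numeric %s '%s'", bad[1L] + line_offset,
                   col, x[bad[1L]]), call. = FALSE)
    }
    out
  }
  df$value <- num("value")
  df$hemolysis <- num("hemolysis")
  df$icterus <- num("icterus")
  df$lipemia <- num("lipemia")
  df$timestamp <- parse_timestamp(df$timestamp)
  df$date_of_birth <- as.Date(ifelse(nzchar(df$date_of_birth),
                                     df$date_of_birth, NA))
  if (anyNA(df$timestamp)) {
    stop(sprintf("line %d: missing timestamp",
                 which(is.na(df$timestamp))[1L] + 1L), call. = FALSE)
  }
  df[RECORD_COLUMNS]
}

#' Write result records in the canonical dialect
#' @param records Data frame in the record schema.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  out <- records
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  out$date_of_birth <- format(out$date_of_birth, "%Y-%m-%d")
  out$date_of_birth[is.na(out$date_of_birth)] <- ""
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

as_record_list <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    for (r in x) stopifnot(inherits(r, "result_record"))
    return(x)
  }
  stopifnot(is.data.frame(x))
  if (!nrow(x)) return(list())
  ts <- parse_timestamp(x$timestamp)
  dob <- as.Date(x$date_of_birth)
  lapply(seq_len(nrow(x)), function(i) {
    flags <- x$flags[i]
    flags <- if (is.na(flags) || !nzchar(flags)) character() else
      strsplit(flags, ";", fixed = TRUE)[[1L]]
    result_record(
      sample_id = x$sample_id[i], test_code = x$test_code[i],
      value = x$value[i], unit = x$unit[i] %||% "", timestamp = ts[i],
      patient = patient_info(
        x$patient_id[i], date_of_birth = dob[i],
        sex = if (x$sex[i] %in% c("male", "female")) x$sex[i] else "unknown",
        location = x$location[i] %||% NA_character_,
        patient_class = if (x$patient_class[i] %in%
                              c("inpatient", "outpatient")) {
          x$patient_class[i]
        } else "unknown"),
      flags = flags,
      hil = hil_indices(x$hemolysis[i], x$icterus[i], x$lipemia[i]),
      analyzer = if (is.na(x$analyzer[i]) || !nzchar(x$analyzer[i]))
        NA_character_ else x$analyzer[i])
  })
}

#' Read a biological-variation table
#'
#' A delimited table with columns `measurand`, `cvi`, `cvg` (percent) and
#' optionally a published `ii` column. The packaged fixture covering 21
#' common chemistry, coagulation and hematology measurands is at
#' `system.file("extdata", "biological_variation.csv",
#' package = "autovalidr")`.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return A data frame.
#' @export
read_biovar <- function(path = system.file("extdata",
                                           "biological_variation.csv",
                                           package = "autovalidr")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("measurand", "cvi", "cvg") %in% names(df)))
  df
}

#' Read Phase II manual validation labels
#'
#' @param path CSV with columns `sample_id`, `test_code`, `manual`
#'   (`accept`/`reject`).
#' @return A data frame.
#' @export
read_manual_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "test_code", "manual") %in% names(df)))
  df
}

#' Digest of an engine configuration
#'
#' MD5 of the canonical YAML serialization; recorded in run manifests so an
#' audit trail can tie every decision file to the exact rule set in force.
#'
#' @param config An [engine_config()].
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Write a run manifest
#'
#' Every CLI run emits exactly one manifest: the command, the configuration
#' digest, the names and digests of all input files, the seed (when the run
#' is stochastic), timestamps and the tool version. Reruns with equal
#' manifests produce equal outputs.
#'
#' @param path Output JSON path.
#' @param command Command name.
#' @param config Optional [engine_config()] (hashed into the manifest).
#' @param inputs Character vector of input file paths.
#' @param seed Optional integer seed.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config = NULL,
                           inputs = character(), seed = NULL) {
  m <- list(
    command = command,
    tool = "autovalidr",
    version = as.character(utils::packageVersion("autovalidr")),
    config_hash = if (!is.null(config)) config_hash(config) else NULL,
    inputs = if (length(inputs)) {
      lapply(inputs, function(f) {
        list(file = basename(f), md5 = unname(tools::md5sum(f)))
      })
    } else list(),
    seed = seed,
    written_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  jsonlite::write_json(m, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}
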