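# Data model and delimited-text IO for the seven passive sensor streams and
# participant metadata. All timestamps are local wall-clock time carried as
# POSIXct in UTC: the pipeline never performs timezone arithmetic because every
# analysis window (6 AM feature day, 8 PM-4 AM night, ...) is anchored in the
# participant's local time.

#' Supported sensor modalities
#'
#' @return Character vector of modality names understood by [read_stream()]
#'   and [write_stream()].
#' @export
modalities <- function() {
  names(.modality_schemas)
}

.modality_schemas <- list(
  gps        = list(cols = c(t = "T", lat = "d", lon = "d")),
  bluetooth  = list(cols = c(t = "T", n_nearby = "i")),
  steps      = list(cols = c(t = "T", steps = "i")),
  heart_rate = list(cols = c(t = "T", bpm = "d")),
  sleep      = list(cols = c(t = "T", stage = "c", epoch_len = "d")),
  phone      = list(cols = c(t = "T", state = "c")),
  app        = list(cols = c(t = "T", duration = "d", category = "c"))
)

.sleep_stages <- c("light", "deep", "rem", "wake")
.phone_states <- c("unlock", "standby")

.check_modality <- function(modality) {
  if (!is.character(modality) || length(modality) != 1L ||
      !modality %in% names(.modality_schemas)) {
    stop("unknown modality: ", paste(modality, collapse = ", "),
         " (expected one of ", paste(names(.modality_schemas), collapse = ", "),
         ")", call. = FALSE)
  }
  modality
}

#' Conventional file name for a participant's stream
#'
#' Streams are laid out one file per participant per modality, named
#' `<pid>.<modality>.csv`.
#'
#' @param dir Dataset directory.
#' @param pid Participant identifier.
#' @param modality One of [modalities()].
#' @return File path.
#' @export
stream_path <- function(dir, pid, modality) {
  .check_modality(modality)
  file.path(dir, sprintf("%s.%s.csv", pid, modality))
}

.fail_rows <- function(bad, what) {
  if (any(bad)) {
    # +1 for the header row so the message names physical file lines
    lines <- which(bad) + 1L
    stop(what, " at line", if (length(lines) > 1L) "s" else "", " ",
         paste(utils::head(lines, 5L), collapse = ", "),
         if (length(lines) > 5L) ", ..." else "", call. = FALSE)
  }
  invisible(NULL)
}

#' Validate a sensor stream against its modality's invariants
#'
#' Checks ranges (latitude/longitude bounds, positive heart rate, nonnegative
#' counts and durations) and label sets. Unknown sleep-stage labels are
#' conservatively mapped to `"wake"` (excluded from sleep totals) with a
#' warning; unknown phone states are an error.
#'
#' @param records Tibble with the modality's columns.
#' @param modality One of [modalities()].
#' @return The validated (possibly relabelled) tibble, input order preserved.
#' @export
validate_stream <- function(records, modality) {
  .check_modality(modality)
  want <- names(.modality_schemas[[modality]]$cols)
  if (!all(want %in% names(records))) {
    stop("stream is missing columns: ",
         paste(setdiff(want, names(records)), collapse = ", "), call. = FALSE)
  }
  records <- records[want]
  .fail_rows(is.na(records$t), "missing or unparseable timestamp")
  switch(modality,
    gps = {
      .fail_rows(!is.finite(records$lat) | records$lat < -90 | records$lat > 90,
                 "latitude outside [-90, 90]")
      .fail_rows(!is.finite(records$lon) | records$lon < -180 | records$lon > 180,
                 "longitude outside [-180, 180]")
    },
    bluetooth = .fail_rows(is.na(records$n_nearby) | records$n_nearby < 0L,
                           "negative or missing nearby-device count"),
    steps = .fail_rows(is.na(records$steps) | records$steps < 0L,
                       "negative or missing step count"),
    heart_rate = .fail_rows(!is.finite(records$bpm) |
                              records$bpm <= 20 | records$bpm >= 250,
                            "heart rate outside (20, 250) bpm"),
    sleep = {
      unknown <- !records$stage %in% .sleep_stages
      if (any(unknown)) {
        warning(sum(unknown), " unknown sleep stage label(s) mapped to 'wake'",
                call. = FALSE)
        records$stage[unknown] <- "wake"
      }
      .fail_rows(is.na(records$epoch_len) | records$epoch_len <= 0,
                 "nonpositive epoch length")
    },
    phone = .fail_rows(!records$state %in% .phone_states,
                       "phone state not in {unlock, standby}"),
    app = .fail_rows(is.na(records$duration) | records$duration < 0,
                     "negative or missing app-use duration")
  )
  records
}

#' Read a sensor stream from a delimited text file
#'
#' Parses a comma-separated file with a header row matching the modality's
#' schema, enforces the modality's invariants, and returns records sorted by
#' timestamp. Timestamps must be ISO-8601; parsing is locale independent.
#'
#' @param path Path to the CSV file.
#' @param modality One of [modalities()].
#' @return Tibble of typed records sorted by `t`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("t,n_nearby", "2020-03-01T10:00:00Z,4"), f)
#' read_stream(f, "bluetooth")
read_stream <- function(path, modality) {
  .check_modality(modality)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  schema <- .modality_schemas[[modality]]
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                                  progress = FALSE))
  if (!identical(header, names(schema$cols))) {
    stop("header of ", path, " does not match the '", modality, "' schema: ",
         "expected ", paste(names(schema$cols), collapse = ","),
         " but found ", paste(header, collapse = ","), call. = FALSE)
  }
  types <- do.call(readr::cols, as.list(schema$cols))
  x <- suppressWarnings(
    readr::read_csv(path, col_types = types, progress = FALSE,
                    locale = readr::locale(tz = "UTC")))
  probs <- readr::problems(x)
  if (nrow(probs) > 0L) {
    # problems() rows are physical file lines (the header included)
    stop("malformed row in ", path, " at line ", probs$row[1L], ": ",
         probs$expected[1L], " expected, got '", probs$actual[1L], "'",
         call. = FALSE)
  }
  x <- validate_stream(x, modality)
  dplyr::arrange(x, .data$t)
}

#' Write a sensor stream to a delimited text file
#'
#' Records are validated and written sorted by timestamp so that
#' `read_stream(write_stream(x))` round-trips exactly. An empty record set
#' produces a header-only file.
#'
#' @param records Tibble of records for the modality.
#' @param path Output path.
#' @param modality One of [modalities()].
#' @return `path`, invisibly.
#' @export
write_stream <- function(records, path, modality) {
  records <- validate_stream(tibble::as_tibble(records), modality)
  records <- dplyr::arrange(records, .data$t)
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Read the participant metadata table
#'
#' Columns: `pid`, `age` (years), `gender` (`male`/`female`/`other`), `bmi`
#' (kg/m^2), `degree` (logical, bachelor's degree or above), `cohort`
#' (country/site label).
#'
#' @param path Path to the metadata CSV.
#' @return Tibble, one row per participant.
#' @export
read_metadata <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    pid = "c", age = "d", gender = "c", bmi = "d", degree = "l", cohort = "c"
  ), progress = FALSE)
  bad <- is.na(x$age) | x$age <= 0 | is.na(x$bmi) | x$bmi <= 0
  .fail_rows(bad, "nonpositive age or BMI")
  x
}

#' Write the participant metadata table
#'
#' @param metadata Tibble as returned by [read_metadata()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  readr::write_csv(metadata, path, progress = FALSE)
  invisible(path)
}
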