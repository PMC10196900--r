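# Stream schemas and tabular IO.
#
# All inputs are long-format CSV, one file per stream type, with mandatory
# headers.  Timestamps (column `t`) are epoch seconds on the participant's
# local clock; `participants.csv` may carry a `tz_offset` (seconds) which is
# added to every stream timestamp on read so that downstream time-of-day
# logic can ignore timezones.

STREAM_TYPES <- c("gps", "accel", "comm", "device", "wifi")

#' Column schemas for every stream and table the pipeline reads
#'
#' @return named list: for each stream/table, a character vector of required
#'   column names.
#' @export
stream_schemas <- function() {
  list(
    gps          = c("participant_id", "t", "lat", "lon", "accuracy"),
    accel        = c("participant_id", "t", "x", "y", "z"),
    comm         = c("participant_id", "t", "kind", "duration", "contact_id"),
    device       = c("participant_id", "t", "kind", "app_id", "battery_pct", "charging"),
    wifi         = c("participant_id", "t", "n_unique_hotspots"),
    ema          = c("participant_id", "date", "drank", "n_drinks", "onset_t", "end_t"),
    participants = c("participant_id", "sex", "enrolled_days", "tz_offset")
  )
}

COMM_KINDS <- c("call_in", "call_out", "sms")
DEVICE_KINDS <- c("screen_on", "screen_off", "app_foreground", "battery")

stop_schema <- function(file, line, msg) {
  stop(sprintf("%s: line %d: %s", file, line, msg), call. = FALSE)
}

check_stream_invariants <- function(dt, type, file) {
  bad <- switch(type,
    gps = which(!is.finite(dt$lat) | !is.finite(dt$lon) |
                  dt$lat < -90 | dt$lat > 90 | dt$lon < -180 | dt$lon > 180),
    accel = which(!is.finite(dt$x) | !is.finite(dt$y) | !is.finite(dt$z)),
    comm = which(!(dt$kind %in% COMM_KINDS) | dt$duration < 0),
    device = which(!(dt$kind %in% DEVICE_KINDS) |
                     (dt$kind == "battery" & (is.na(dt$battery_pct) |
                        dt$battery_pct < 0 | dt$battery_pct > 100)) |
                     (dt$kind == "app_foreground" & is.na(dt$app_id))),
    wifi = which(is.na(dt$n_unique_hotspots) | dt$n_unique_hotspots < 0),
    integer(0)
  )
  if (length(bad)) {
    stop_schema(file, bad[1] + 1L, # +1 for the header row
                sprintf("invalid %s record (field out of range or bad kind)", type))
  }
  invisible(dt)
}

#' Read sensor streams from a fixture directory
#'
#' Reads whichever of `gps.csv`, `accel.csv`, `comm.csv`, `device.csv`,
#' `wifi.csv` exist under `path`, checks schema invariants (latitude/longitude
#' ranges, enumerated kinds, non-negative durations) and returns each stream
#' sorted by participant and timestamp.  Row counts are preserved.
#'
#' @param path directory containing per-stream CSV files
#' @param participants optional participants table (used for `tz_offset`)
#' @return an object of class `sensor_streams`: a named list of data.tables
#' @export
read_streams <- function(path, participants = NULL) {
  if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
  schemas <- stream_schemas()
  out <- list()
  found <- FALSE
  for (type in STREAM_TYPES) {
    file <- file.path(path, paste0(type, ".csv"))
    if (!file.exists(file)) next
    found <- TRUE
    dt <- data.table::fread(file, colClasses = list(character = "participant_id"),
                            na.strings = c("", "NA"))
    need <- schemas[[type]]
    if (!all(need %in% names(dt))) {
      stop(sprintf("%s: missing column(s): %s", file,
                   paste(setdiff(need, names(dt)), collapse = ", ")), call. = FALSE)
    }
    check_stream_invariants(dt, type, file)
    if (!is.null(participants) && "tz_offset" %in% names(participants)) {
      off <- setNames(participants$tz_offset, participants$participant_id)
      shift <- off[dt$participant_id]
      shift[is.na(shift)] <- 0
      dt[, t := t + shift]
    }
    data.table::setorder(dt, participant_id, t)
    out[[type]] <- dt
  }
  if (!found) warning("no stream files found under ", path)
  structure(out, class = "sensor_streams")
}

#' Read self-report (EMA) and participant tables
#'
#' @param path fixture directory containing `ema.csv` / `participants.csv`
#' @return data.table
#' @export
read_ema <- function(path) {
  dt <- data.table::fread(file.path(path, "ema.csv"),
                          colClasses = list(character = "participant_id"),
                          na.strings = c("", "NA"))
  bad <- which(!dt$drank & dt$n_drinks != 0)
  if (length(bad)) stop_schema("ema.csv", bad[1] + 1L, "drank=FALSE requires n_drinks=0")
  bad <- which(dt$drank & !is.na(dt$onset_t) & !is.na(dt$end_t) & dt$onset_t >= dt$end_t)
  if (length(bad)) stop_schema("ema.csv", bad[1] + 1L, "onset_t must precede end_t")
  data.table::setorder(dt, participant_id, date)
  dt[]
}

#' @rdname read_ema
#' @export
read_participants <- function(path) {
  dt <- data.table::fread(file.path(path, "participants.csv"),
                          colClasses = list(character = "participant_id"))
  if (!all(dt$sex %in% c("female", "male"))) {
    bad <- which(!(dt$sex %in% c("female", "male")))
    stop_schema("participants.csv", bad[1] + 1L, "sex must be 'female' or 'male'")
  }
  if (!"tz_offset" %in% names(dt)) dt[, tz_offset := 0]
  dt[]
}

#' Validate sensor streams and report gaps
#'
#' Report-only quality control: per-participant record counts, contiguous
#' gaps longer than `gap_threshold` seconds, and invariant violations
#' (duplicate or non-increasing timestamps).  Default threshold is 30
#' minutes, the sync cadence of the collection app being emulated.
#'
#' @param streams a `sensor_streams` object
#' @param gap_threshold seconds; gaps longer than this are listed
#' @return list with elements `counts`, `gaps`, `violations` (data.tables)
#' @export
validate_streams <- function(streams, gap_threshold = 1800) {
  counts <- data.table::rbindlist(lapply(names(streams), function(type) {
    streams[[type]][, .(stream = type, n = .N), by = participant_id]
  }))
  gaps <- data.table::rbindlist(lapply(names(streams), function(type) {
    streams[[type]][, {
      dt_gap <- diff(t)
      idx <- which(dt_gap > gap_threshold)
      .(stream = type, gap_start = t[idx], gap_len = dt_gap[idx])
    }, by = participant_id]
  }))
  violations <- data.table::rbindlist(lapply(names(streams), function(type) {
    streams[[type]][, {
      dup <- anyDuplicated(t)
      if (dup > 0) .(stream = type, issue = "duplicate_timestamp", at = t[dup])
      else NULL
    }, by = participant_id]
  }))
  list(counts = counts, gaps = gaps, violations = violations)
}

#' Write a cohort fixture to disk
#'
#' Serializes streams (and optionally EMA reports / participants) as the
#' per-stream CSV layout read back by [read_streams()]; the round trip
#' reproduces the input at field level.
#'
#' @param streams `sensor_streams` object
#' @param path output directory (created if absent)
#' @param ema,participants optional tables written as `ema.csv` /
#'   `participants.csv`
#' @return `path`, invisibly
#' @export
write_fixture <- function(streams, path, ema = NULL, participants = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory: ", path, call. = FALSE)
  for (type in names(streams)) {
    dt <- streams[[type]]
    if (is.null(dt) || !nrow(dt)) next
    data.table::fwrite(dt, file.path(path, paste0(type, ".csv")))
  }
  if (!is.null(ema)) data.table::fwrite(ema, file.path(path, "ema.csv"))
  if (!is.null(participants)) {
    data.table::fwrite(participants, file.path(path, "participants.csv"))
  }
  invisible(path)
}
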