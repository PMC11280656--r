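#' Read an EDA trace from CSV
#'
#' Expects the interchange format written by \code{\link{write_eda_csv}}: a
#' header \code{time_s,eda_us}, comma separators, dot decimals, times in
#' seconds from recording start. The sampling rate is inferred from the median
#' sample spacing. Malformed files (missing columns, non-monotone times, gaps
#' larger than two sample periods) are rejected, never repaired.
#'
#' @param path Path to the CSV file.
#' @return An \code{\link{eda_ts}}.
#' @export
read_eda_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("time_s", "eda_us") %in% names(df))) {
    stop("EDA CSV must have columns `time_s` and `eda_us`", call. = FALSE)
  }
  if (!is.numeric(df$time_s) || !is.numeric(df$eda_us) ||
      anyNA(df$time_s) || anyNA(df$eda_us)) {
    stop("EDA CSV columns must be numeric with no missing values",
         call. = FALSE)
  }
  eda_ts(df$time_s, df$eda_us)
}

#' Write an EDA trace to CSV
#'
#' @param series An \code{\link{eda_ts}}.
#' @param path Output path.
#' @return \code{path}, invisibly. Values are written with 12 significant
#'   digits so a write/read round trip reproduces them to well below 1e-9.
#' @export
write_eda_csv <- function(series, path) {
  stopifnot(inherits(series, "eda_ts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_s,eda_us", con)
  writeLines(paste(sprintf("%.12g", series$time),
                   sprintf("%.12g", series$values), sep = ","), con)
  invisible(path)
}

crossover_event_cols <- function() {
  c("time_s", "direction", "triage", "sma_short", "sma_long", "warmup")
}

# validate an events data frame (as produced by detect/triage)
validate_events <- function(events, triaged = FALSE) {
  stopifnot(is.data.frame(events))
  need <- c("time_s", "direction")
  if (triaged) need <- c(need, "triage")
  miss <- setdiff(need, names(events))
  if (length(miss)) {
    stop(sprintf("event table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(events) > 1L && any(diff(events$time_s) <= 0)) {
    stop("events must be strictly increasing in time", call. = FALSE)
  }
  bad <- setdiff(unique(events$direction),
                 c("engagement", "disengagement"))
  if (length(bad)) stop("unknown event direction(s)", call. = FALSE)
  invisible(events)
}

#' Write crossover events to CSV
#'
#' Columns: \code{time_s, direction, triage, sma_short, sma_long, warmup}.
#' An empty event list produces a header-only file. The writer/reader pair is
#' a lossless round trip.
#'
#' @param events Data frame of crossover events, time-sorted.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_events <- function(events, path) {
  validate_events(events)
  cols <- crossover_event_cols()
  for (col in setdiff(cols, names(events))) {
    events[[col]] <- if (col == "triage") NA_character_
                     else if (col == "warmup") FALSE else NA_real_
  }
  events <- events[, cols, drop = FALSE]
  num <- vapply(events, is.numeric, logical(1))
  for (col in names(events)[num]) {
    events[[col]] <- sprintf("%.12g", events[[col]])
  }
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read crossover events written by \code{\link{write_events}}
#'
#' @param path Path to the events CSV.
#' @return Data frame with the crossover event columns.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(time_s = "numeric",
                                       direction = "character",
                                       triage = "character",
                                       sma_short = "numeric",
                                       sma_long = "numeric",
                                       warmup = "logical"))
  validate_events(df)
  df
}

#' Read / write a session protocol as a YAML config
#'
#' @param protocol An \code{\link{eda_protocol}}.
#' @param path File path.
#' @return \code{read_protocol} returns an \code{eda_protocol};
#'   \code{write_protocol} returns \code{path} invisibly.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "eda_protocol"))
  yaml::write_yaml(unclass(protocol), path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  p <- yaml::read_yaml(path)
  need <- c("baseline_start", "baseline_end", "stim_start", "stim_end")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    stop(sprintf("protocol file lacks field(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  eda_protocol(p$baseline_start, p$baseline_end, p$stim_start, p$stim_end,
               participant_id = if (is.null(p$participant_id)) NA
                                else p$participant_id,
               video_id = if (is.null(p$video_id)) NA else p$video_id)
}

#' Write the ground-truth annotation of a synthetic session as JSON
#'
#' Stores the engagement-state intervals and injected SCR events of an
#' \code{"eda_session"} so downstream validation can run from files alone.
#'
#' @param session An \code{"eda_session"} from \code{\link{generate_profile}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_truth_json <- function(session, path) {
  stopifnot(inherits(session, "eda_session"))
  jsonlite::write_json(list(morphology = session$morphology,
                            seed = session$seed,
                            truth_states = session$truth_states,
                            scr_events = session$scr_events),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
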