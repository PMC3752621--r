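#' Construct a patient record from traces
#'
#' @param patientId patient identifier.
#' @param duration record length in seconds.
#' @param traces list of [VitalTrace-class] objects (names optional; taken
#'   from each trace's channel).
#' @return A [PatientRecord-class].
#' @export
patientRecord <- function(patientId, duration, traces = list()) {
  names(traces) <- vapply(traces, function(tr) tr@channel, "")
  new("PatientRecord", patientId = as.character(patientId),
      duration = as.numeric(duration), traces = traces)
}

#' Read and write patient-record CSVs
#'
#' One CSV per patient record, long format with columns
#' `t_seconds,channel,value`; an empty `value` field is a missing sample.
#' Values are printed with 6 significant digits, so
#' `writeRecordCSV(readRecordCSV(f))` reproduces `f` byte for byte.
#'
#' @param record a [PatientRecord-class].
#' @param path CSV file path.
#' @param patientId patient id to attach on read (default: file name).
#' @param duration record duration; default: largest timestamp in the file.
#' @return `readRecordCSV` returns a [PatientRecord-class];
#'   `writeRecordCSV` returns `path` invisibly.
#' @export
writeRecordCSV <- function(record, path) {
  stopifnot(is(record, "PatientRecord"))
  rows <- lapply(record@traces, function(tr)
    data.frame(t_seconds = tr@t, channel = tr@channel,
               value = .fmtValue(tr@value), stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(t_seconds = numeric(0),
                                    channel = character(0),
                                    value = character(0))
  df <- df[order(df$channel, df$t_seconds), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeRecordCSV
#' @export
readRecordCSV <- function(path, patientId = NULL, duration = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(t_seconds = "numeric",
                                       channel = "character",
                                       value = "character"))
  if (is.null(patientId))
    patientId <- sub("\\.csv$", "", basename(path))
  if (is.null(duration))
    duration <- if (nrow(df)) max(df$t_seconds) else 1
  traces <- lapply(split(df, df$channel), function(d) {
    d <- d[order(d$t_seconds), , drop = FALSE]
    v <- suppressWarnings(as.numeric(d$value))
    v[d$value == ""] <- NA_real_
    makeTrace(d$channel[1], d$t_seconds, v)
  })
  patientRecord(patientId, duration, unname(traces))
}
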