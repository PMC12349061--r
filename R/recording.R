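#' Multichannel plate recording
#'
#' Container for the raw vertical-force time series of one forceplate:
#' a uniform time base and one column of forces (N) per uniaxial sensor
#' (four per plate on the device this package models).
#'
#' @param time numeric vector of sample times in seconds, uniformly spaced.
#' @param channels numeric matrix of vertical forces in Newtons, one column
#'   per sensor, `length(time)` rows.
#' @param rate sampling rate in Hz. Must agree with the time step.
#' @param labels sensor identifiers (column names).
#' @param plate plate identifier, e.g. `"lower"`, `"upper_left"`,
#'   `"upper_right"`.
#'
#' @return An object of class `plate_recording`: a list with elements
#'   `time`, `channels`, `rate`, `labels`, `plate`.
#' @export
plate_recording <- function(time, channels, rate,
                            labels = paste0("S", seq_len(ncol(channels))),
                            plate = "lower") {
  channels <- as.matrix(channels)
  if (length(time) != nrow(channels)) {
    stop_invalid("`time` length must match rows of `channels`",
                 "copsplit_invalid_input")
  }
  check_number(rate, "rate", positive = TRUE)
  if (length(time) >= 2L) {
    dt <- diff(time)
    if (any(dt <= 0) || max(abs(dt - 1 / rate)) >= 1e-6 / rate) {
      stop_invalid("`time` must increase uniformly at 1/rate",
                   "copsplit_invalid_input")
    }
  }
  if (length(labels) != ncol(channels)) {
    stop_invalid("one label per channel required", "copsplit_invalid_input")
  }
  colnames(channels) <- labels
  structure(
    list(time = as.numeric(time), channels = channels, rate = rate,
         labels = labels, plate = plate),
    class = "plate_recording"
  )
}

#' @export
print.plate_recording <- function(x, ...) {
  cat(sprintf("<plate_recording> plate=%s  %d samples x %d channels  %g Hz  (%.2f s)\n",
              x$plate, length(x$time), ncol(x$channels), x$rate,
              length(x$time) / x$rate))
  invisible(x)
}

n_samples <- function(rec) length(rec$time)

# replace channels (and optionally time) keeping metadata
rec_update <- function(rec, channels = rec$channels, time = rec$time) {
  plate_recording(time, channels, rec$rate, rec$labels, rec$plate)
}

#' Read / write plate recordings as delimited text
#'
#' Canonical dialect: UTF-8 CSV with `.` decimal separator, two comment
#' header lines `# rate_hz=<float>` and `# plate=<id>`, then a header row
#' `time,<label1>,...` followed by one row per sample (time in s, forces in
#' N). Values are written with 17 significant digits so a write/read
#' round-trip is bit-identical.
#'
#' @param path file path.
#' @param rec a [plate_recording()].
#' @return `read_plate_recording()` returns a [plate_recording()];
#'   `write_plate_recording()` returns `path` invisibly.
#' @export
read_plate_recording <- function(path) {
  lines <- readLines(path, n = 10L)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    m <- grep(paste0("^#\\s*", key, "="), hdr, value = TRUE)
    if (length(m) != 1L) {
      stop_invalid(sprintf("header line '# %s=' missing in %s", key, path),
                   "copsplit_invalid_input")
    }
    sub(paste0("^#\\s*", key, "="), "", m)
  }
  rate <- as.numeric(get_field("rate_hz"))
  plate <- get_field("plate")
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  plate_recording(df[[1L]], as.matrix(df[-1L]), rate,
                  labels = names(df)[-1L], plate = plate)
}

#' @rdname read_plate_recording
#' @export
write_plate_recording <- function(rec, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# rate_hz=%s", fmt_num(rec$rate)),
               sprintf("# plate=%s", rec$plate),
               paste(c("time", rec$labels), collapse = ",")), con)
  body <- cbind(fmt_num(rec$time),
                matrix(fmt_num(rec$channels), nrow = n_samples(rec)))
  writeLines(apply(body, 1L, paste, collapse = ","), con)
  invisible(path)
}
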