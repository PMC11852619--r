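#' @name logformat
#' @title Device CSV log dialect
#'
#' @description
#' The logger writes one comma-separated line per averaged differential
#' sample: `tick,diff_accel,heart_rate,spo2`. `tick` is an interrupt-counter
#' timestamp (milliseconds by default, `tick_rate = 1000` ticks/s),
#' `diff_accel` the block-averaged xiphoid-minus-sternum acceleration, and
#' the auxiliary pulse-oximeter columns are present only around their 1 Hz
#' update instants — missing values are empty fields, never zeros. Files
#' may carry a one-line header naming the columns; [read_log()] detects it
#' by its non-numeric first field.
NULL

LOG_COLUMNS <- c("tick", "diff_accel", "heart_rate", "spo2")

#' Construct a device log
#'
#' @param records data frame with columns `tick` (integer-valued, strictly
#'   increasing), `diff_accel` (numeric), `heart_rate` (numeric or NA),
#'   `spo2` (numeric in \[0, 100\] or NA).
#' @param tick_rate ticks per second (default 1000: millisecond ticks).
#' @param sample_rate nominal logging rate in Hz (default 100).
#' @param source_name free-text provenance label.
#' @return An object of class `device_log`.
#' @export
device_log <- function(records, tick_rate = 1000, sample_rate = 100,
                       source_name = "memory") {
  records <- as.data.frame(records)
  if (nrow(records) == 0L && ncol(records) == 0L)
    records <- data.frame(tick = numeric(0), diff_accel = numeric(0),
                          heart_rate = numeric(0), spo2 = numeric(0))
  if (!identical(names(records), LOG_COLUMNS))
    stop("records must have columns ", paste(LOG_COLUMNS, collapse = ", "))
  if (nrow(records) > 1L && any(diff(records$tick) <= 0))
    stop("ticks must be strictly increasing")
  hr <- records$heart_rate
  if (any(!is.na(hr) & hr <= 0)) stop("heart_rate must be > 0 when present")
  sp <- records$spo2
  if (any(!is.na(sp) & (sp < 0 | sp > 100)))
    stop("spo2 must lie in [0, 100] when present")
  structure(
    list(records = records, tick_rate = tick_rate, sample_rate = sample_rate,
         source_name = source_name),
    class = "device_log"
  )
}

#' @export
print.device_log <- function(x, ...) {
  cat(sprintf(
    "<device_log> %d records @ %g Hz nominal (ticks at %g/s) from %s\n",
    nrow(x$records), x$sample_rate, x$tick_rate, x$source_name))
  invisible(x)
}

parse_log_field <- function(s, what, line_no) {
  s <- trimws(s)
  if (s == "" || toupper(s) == "NA") return(NA_real_)
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v))
    stop("malformed log line ", line_no, ": non-numeric ", what, " '", s, "'")
  v
}

#' Read a device CSV log
#'
#' @param source path to a CSV file, or a character vector of lines.
#' @param tick_rate,sample_rate,... passed to [device_log()].
#' @return A [device_log()]. Malformed lines (wrong column count,
#'   non-numeric required fields) and non-monotone timestamps raise errors
#'   naming the offending line.
#' @export
read_log <- function(source, tick_rate = 1000, sample_rate = 100, ...) {
  if (length(source) == 1L && !grepl("[,\n]", source)) {
    if (!file.exists(source)) stop("log file not found: ", source)
    lines <- readLines(source, warn = FALSE)
    name <- basename(source)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
    name <- "text"
  }
  lines_keep <- which(nzchar(trimws(lines)))
  start <- 1L
  if (length(lines_keep)) {
    first <- strsplit(lines[lines_keep[1L]], ",", fixed = TRUE)[[1L]]
    if (is.na(suppressWarnings(as.numeric(trimws(first[1L])))))
      start <- 2L  # header line
  }
  data_idx <- if (start == 2L) lines_keep[-1L] else lines_keep
  n <- length(data_idx)
  tick <- accel <- hr <- sp <- numeric(n)
  for (i in seq_len(n)) {
    ln <- data_idx[i]
    f <- strsplit(lines[ln], ",", fixed = TRUE)[[1L]]
    # a trailing missing field is dropped by strsplit; restore it
    if (length(f) == 3L && grepl(",$", lines[ln])) f <- c(f, "")
    if (length(f) != 4L)
      stop("malformed log line ", ln, ": expected 4 comma-separated ",
           "columns, found ", length(f))
    tick[i] <- parse_log_field(f[1L], "tick", ln)
    accel[i] <- parse_log_field(f[2L], "diff_accel", ln)
    if (is.na(tick[i]) || is.na(accel[i]))
      stop("malformed log line ", ln, ": tick and diff_accel are required")
    hr[i] <- parse_log_field(f[3L], "heart_rate", ln)
    sp[i] <- parse_log_field(f[4L], "spo2", ln)
  }
  if (n > 1L && any(diff(tick) <= 0)) {
    bad <- data_idx[which(diff(tick) <= 0)[1L] + 1L]
    stop("non-monotone timestamps at line ", bad)
  }
  device_log(data.frame(tick = tick, diff_accel = accel, heart_rate = hr,
                        spo2 = sp),
             tick_rate = tick_rate, sample_rate = sample_rate,
             source_name = name, ...)
}

# Shortest decimal representation that parses back to the same double.
format_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    for (d in c(10L, 15L, 16L, 17L)) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

#' Write a device CSV log
#'
#' Serialization twin of [read_log()]: a header line naming the four
#' columns, then one line per record with missing auxiliary values as
#' empty fields. Writing, re-reading and writing again produces a
#' byte-identical file.
#'
#' @param log a [device_log()].
#' @param dest file path.
#' @return `dest`, invisibly.
#' @export
write_log <- function(log, dest) {
  stopifnot(inherits(log, "device_log"))
  r <- log$records
  lines <- c(paste(LOG_COLUMNS, collapse = ","),
             if (nrow(r)) paste(format_num(r$tick), format_num(r$diff_accel),
                                format_num(r$heart_rate), format_num(r$spo2),
                                sep = ","))
  con <- tryCatch(file(dest, "wb"), error = function(e)
    stop("cannot open '", dest, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(dest)
}

#' Convert a device log to a uniform time series
#'
#' Checks that inter-record intervals match the nominal sampling period
#' within `tolerance`; a single dropped sample (an interval of about twice
#' the period) is repaired by linear interpolation, while any larger gap is
#' an error listing the gap positions. The time origin is the first
#' record's tick converted to seconds.
#'
#' @param log a non-empty [device_log()].
#' @param tolerance allowed relative deviation of each interval from the
#'   nominal period (default 0.05).
#' @return A [uniform_series()] of the differential acceleration at
#'   `log$sample_rate`.
#' @export
to_uniform_series <- function(log, tolerance = 0.05) {
  stopifnot(inherits(log, "device_log"))
  r <- log$records
  if (nrow(r) == 0L) stop("cannot convert an empty log")
  t_s <- r$tick / log$tick_rate
  if (nrow(r) == 1L)
    return(uniform_series(r$diff_accel, log$sample_rate, t0 = t_s))
  period <- 1 / log$sample_rate
  dt <- diff(t_s)
  ok <- abs(dt - period) <= tolerance * period
  dropped <- abs(dt - 2 * period) <= tolerance * 2 * period
  bad <- which(!ok & !dropped)
  if (length(bad))
    stop("log gaps exceed tolerance after record(s) at t = ",
         paste(sprintf("%.4f", t_s[bad]), collapse = ", "), " s")
  step <- ifelse(dropped, 2L, 1L)
  pos <- c(1L, 1L + cumsum(step))          # output index of each record
  vals <- numeric(pos[length(pos)])
  vals[pos] <- r$diff_accel
  gap_pos <- pos[which(dropped)] + 1L      # one interpolated sample per gap
  if (length(gap_pos))
    vals[gap_pos] <- (r$diff_accel[which(dropped)] +
                        r$diff_accel[which(dropped) + 1L]) / 2
  uniform_series(vals, log$sample_rate, t0 = t_s[1L])
}
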