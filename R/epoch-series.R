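#' Epoch-level accelerometer count series
#'
#' An `epoch_series` holds the vertical-axis activity counts recorded by a
#' hip-worn accelerometer for one subject and placement, at a fixed epoch
#' length (typically 10 s or 60 s). The series is gap-free by construction:
#' the timestamp of epoch `i` (0-based) is `start_time + i * epoch_length`,
#' matching the ActiLife CSV convention of one count value per row with no
#' per-row timestamps.
#'
#' @param counts Numeric vector of non-negative, whole-valued epoch counts.
#' @param epoch_length Epoch duration in seconds; must divide 60 or be a
#'   multiple of 60 (e.g. 10, 15, 30, 60, 120).
#' @param start_time `POSIXct` timestamp of the first epoch's start.
#' @param subject_id Subject identifier (opaque string).
#' @param placement Sensor placement, `"right_hip"` or `"left_hip"`.
#' @return An object of class `epoch_series`.
#' @examples
#' es <- epoch_series(c(0, 120, 0), epoch_length = 10)
#' length(es$counts)
#' @export
epoch_series <- function(counts, epoch_length = 10,
                         start_time = as.POSIXct("2010-01-01 00:00:00", tz = "UTC"),
                         subject_id = "S01", placement = c("right_hip", "left_hip")) {
  placement <- match.arg(placement)
  if (!is.numeric(counts) || length(counts) == 0) {
    stop("`counts` must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(counts)) stop("`counts` must not contain NA", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be whole numbers", call. = FALSE)
  }
  epoch_length <- as.integer(epoch_length)
  if (is.na(epoch_length) || epoch_length <= 0) {
    stop("`epoch_length` must be a positive integer number of seconds", call. = FALSE)
  }
  if (!(60L %% epoch_length == 0L || epoch_length %% 60L == 0L)) {
    stop("`epoch_length` must divide 60 or be a multiple of 60 seconds", call. = FALSE)
  }
  if (!inherits(start_time, "POSIXct") || length(start_time) != 1L || is.na(start_time)) {
    stop("`start_time` must be a single POSIXct timestamp", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), placement = placement,
         epoch_length = epoch_length, start_time = start_time,
         counts = as.numeric(round(counts))),
    class = "epoch_series"
  )
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> subject %s, %s, %d-s epochs\n",
              x$subject_id, x$placement, x$epoch_length))
  cat(sprintf("  %d epochs from %s (%.1f h), total counts %.0f\n",
              length(x$counts), format(x$start_time, "%Y-%m-%d %H:%M:%S"),
              length(x$counts) * x$epoch_length / 3600, sum(x$counts)))
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$counts)

#' Epoch start timestamps
#'
#' @param series An [epoch_series()].
#' @return `POSIXct` vector of per-epoch start times.
#' @export
epoch_timestamps <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  series$start_time + (seq_along(series$counts) - 1L) * series$epoch_length
}

#' Describe the layout of an epoch count file
#'
#' Epoch CSV files come in three layouts: `"actigraph"` (a 10-line ActiLife
#' metadata header followed by one or more count columns), `"none"`
#' (headerless, one count value per line), and `"tidy"` (a tidy CSV with
#' columns `subject_id, placement, epoch_index, timestamp, counts` as
#' written by [write_epoch_csv()]). For layouts that do not carry metadata,
#' the dialect supplies it; for `"actigraph"` files the header metadata
#' (start time, epoch length) overrides the dialect defaults.
#'
#' @param header One of `"actigraph"`, `"none"`, `"tidy"`.
#' @param epoch_length Epoch length in seconds; required when the file
#'   carries no epoch metadata. When both the dialect and an ActiLife header
#'   specify an epoch length they must agree.
#' @param start_time Default start time (`POSIXct`) when the file carries none.
#' @param subject_id,placement Metadata applied to the resulting series.
#' @return A list of class `epoch_dialect`.
#' @export
epoch_dialect <- function(header = c("none", "actigraph", "tidy"),
                          epoch_length = NULL, start_time = NULL,
                          subject_id = "S01",
                          placement = c("right_hip", "left_hip")) {
  header <- match.arg(header)
  placement <- match.arg(placement)
  structure(list(header = header, epoch_length = epoch_length,
                 start_time = start_time, subject_id = subject_id,
                 placement = placement),
            class = "epoch_dialect")
}

# Parse "hh:mm:ss" to seconds.
.hms_to_seconds <- function(x) {
  p <- as.numeric(strsplit(trimws(x), ":", fixed = TRUE)[[1]])
  if (length(p) != 3L || anyNA(p)) return(NA_real_)
  p[1] * 3600 + p[2] * 60 + p[3]
}

# Extract ActiLife-style header metadata from its first 10 lines.
.parse_actigraph_header <- function(lines, path) {
  hdr <- list(epoch_length = NULL, start_date = NULL, start_clock = NULL)
  for (ln in lines) {
    if (grepl("Epoch Period", ln, ignore.case = TRUE)) {
      val <- regmatches(ln, regexpr("[0-9]{1,2}:[0-9]{2}:[0-9]{2}", ln))
      if (length(val)) hdr$epoch_length <- .hms_to_seconds(val)
    } else if (grepl("Start Time", ln, ignore.case = TRUE)) {
      val <- regmatches(ln, regexpr("[0-9]{1,2}:[0-9]{2}:[0-9]{2}", ln))
      if (length(val)) hdr$start_clock <- val
    } else if (grepl("Start Date", ln, ignore.case = TRUE)) {
      val <- regmatches(ln, regexpr("[0-9]{1,4}[/-][0-9]{1,2}[/-][0-9]{2,4}", ln))
      if (length(val)) hdr$start_date <- val
    }
  }
  hdr
}

#' Read an epoch-level count file
#'
#' Reads ActiLife-exported or plain epoch count CSV files into a validated
#' [epoch_series()]. Only the vertical axis is modeled; when a file carries
#' several count columns the first is used and the others are dropped with
#' a warning.
#'
#' @param path Path to the file.
#' @param dialect An [epoch_dialect()] describing the file layout.
#' @return An [epoch_series()].
#' @export
read_epoch_csv <- function(path, dialect = epoch_dialect()) {
  if (!inherits(dialect, "epoch_dialect")) stop("`dialect` must be an epoch_dialect", call. = FALSE)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!(seq_along(lines) > suppressWarnings(max(which(nzchar(trimws(lines))), -Inf)))]
  if (length(lines) == 0L || !any(nzchar(trimws(lines)))) {
    stop(sprintf("parse error: %s is empty", path), call. = FALSE)
  }

  epoch_length <- dialect$epoch_length
  start_time <- dialect$start_time
  subject_id <- dialect$subject_id
  placement <- dialect$placement

  if (dialect$header == "tidy") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("subject_id", "placement", "epoch_index", "timestamp", "counts")
    if (!all(need %in% names(df))) {
      stop("parse error: tidy epoch file lacks required columns", call. = FALSE)
    }
    df <- df[order(df$epoch_index), , drop = FALSE]
    ts <- as.POSIXct(df$timestamp, tz = "UTC")
    if (nrow(df) >= 2L) {
      epoch_length <- as.numeric(difftime(ts[2], ts[1], units = "secs"))
    } else if (is.null(epoch_length)) {
      stop("configuration error: epoch length unknown for single-row tidy file", call. = FALSE)
    }
    return(epoch_series(df$counts, epoch_length = epoch_length, start_time = ts[1],
                        subject_id = df$subject_id[1], placement = df$placement[1]))
  }

  data_lines <- lines
  if (dialect$header == "actigraph") {
    if (length(lines) <= 10L) stop(sprintf("parse error: %s has no data rows after header", path), call. = FALSE)
    hdr <- .parse_actigraph_header(lines[1:10], path)
    data_lines <- lines[-(1:10)]
    if (!is.null(hdr$epoch_length)) {
      if (!is.null(epoch_length) && hdr$epoch_length != epoch_length) {
        stop(sprintf(
          "configuration error: header declares %d-s epochs but dialect specifies %d s",
          as.integer(hdr$epoch_length), as.integer(epoch_length)), call. = FALSE)
      }
      epoch_length <- hdr$epoch_length
    }
    if (!is.null(hdr$start_date) && !is.null(hdr$start_clock)) {
      st <- as.POSIXct(paste(hdr$start_date, hdr$start_clock),
                       tryFormats = c("%m/%d/%Y %H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                      "%d/%m/%Y %H:%M:%S"),
                       tz = "UTC")
      if (!is.na(st)) start_time <- st
    }
  }
  if (is.null(epoch_length)) {
    stop("configuration error: epoch length given neither in file header nor dialect", call. = FALSE)
  }
  if (is.null(start_time)) start_time <- as.POSIXct("2010-01-01 00:00:00", tz = "UTC")

  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) == 0L) stop(sprintf("parse error: %s has no data rows", path), call. = FALSE)
  fields <- strsplit(data_lines, ",", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols > 1L)) {
    warning("multiple count columns found; using the first (vertical axis) only",
            call. = FALSE)
  }
  first <- vapply(fields, `[[`, character(1), 1L)
  counts <- suppressWarnings(as.numeric(first))
  if (anyNA(counts)) {
    bad <- which(is.na(counts))[1]
    offset <- length(lines) - length(data_lines)
    stop(sprintf("parse error at line %d of %s: %s", bad + offset, path,
                 dQuote(trimws(data_lines[bad]))), call. = FALSE)
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0)[1]
    stop(sprintf("validation error: negative count at data row %d of %s", bad, path),
         call. = FALSE)
  }
  epoch_series(counts, epoch_length = epoch_length, start_time = start_time,
               subject_id = subject_id, placement = placement)
}

#' Write an epoch series as a tidy CSV
#'
#' Writes columns `subject_id, placement, epoch_index, timestamp, counts`
#' (0-based epoch index). The file can be read back with
#' `epoch_dialect(header = "tidy")`.
#'
#' @param series An [epoch_series()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_epoch_csv <- function(series, path) {
  stopifnot(inherits(series, "epoch_series"))
  df <- data.frame(
    subject_id = series$subject_id,
    placement = series$placement,
    epoch_index = seq_along(series$counts) - 1L,
    timestamp = format(epoch_timestamps(series), "%Y-%m-%d %H:%M:%S"),
    counts = series$counts
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Re-integrate an epoch series to a longer epoch
#'
#' Sums consecutive blocks of epochs into a coarser epoch length, e.g. 10-s
#' epochs into 60-s epochs before minute-level scoring. A trailing block
#' that is not complete is dropped (padding it with zeros would fabricate
#' wear time) and reported via a message. Total counts over the complete
#' blocks are conserved.
#'
#' @param series An [epoch_series()].
#' @param target_epoch Target epoch length in seconds; must be a positive
#'   multiple of `series$epoch_length`.
#' @return An [epoch_series()] at the target epoch length.
#' @examples
#' es <- epoch_series(c(10, 20, 30, 40, 50, 60), epoch_length = 10)
#' reintegrate(es, 60)$counts  # 210
#' @export
reintegrate <- function(series, target_epoch) {
  stopifnot(inherits(series, "epoch_series"))
  target_epoch <- as.integer(target_epoch)
  if (is.na(target_epoch) || target_epoch <= 0 ||
      target_epoch %% series$epoch_length != 0L) {
    stop("`target_epoch` must be a positive multiple of the source epoch length",
         call. = FALSE)
  }
  k <- target_epoch %/% series$epoch_length
  if (k == 1L) return(series)
  n <- length(series$counts)
  n_blocks <- n %/% k
  dropped <- n - n_blocks * k
  if (dropped > 0L) {
    message(sprintf("reintegrate: dropped %d trailing partial epoch(s)", dropped))
  }
  if (n_blocks == 0L) {
    stop("series shorter than one target epoch; nothing to reintegrate", call. = FALSE)
  }
  sums <- colSums(matrix(series$counts[seq_len(n_blocks * k)], nrow = k))
  epoch_series(sums, epoch_length = target_epoch, start_time = series$start_time,
               subject_id = series$subject_id, placement = series$placement)
}

#' Mean counts per minute over a steady-state window
#'
#' Computes the mean counts/min over a time window, as done for the last
#' two minutes of rest and of each treadmill stage during calibration:
#' the epoch counts falling in the window are summed and divided by the
#' window duration in minutes.
#'
#' @param series An [epoch_series()].
#' @param window_start,window_end Window offsets in seconds from the start
#'   of the series (half-open, `[start, end)`); must align with epoch
#'   boundaries and lie inside the series.
#' @return Mean counts per minute (scalar).
#' @export
steady_state_counts <- function(series, window_start, window_end) {
  stopifnot(inherits(series, "epoch_series"))
  len <- series$epoch_length
  total <- length(series$counts) * len
  if (window_start < 0 || window_end > total || window_end <= window_start) {
    stop(sprintf("window [%s, %s) s outside series of %d s", window_start,
                 window_end, total), call. = FALSE)
  }
  if (window_start %% len != 0 || window_end %% len != 0) {
    stop("window boundaries must align with epoch boundaries", call. = FALSE)
  }
  idx <- seq.int(window_start %/% len + 1L, window_end %/% len)
  sum(series$counts[idx]) / ((window_end - window_start) / 60)
}
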