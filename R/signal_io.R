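#' Construct a two-channel physiological recording
#'
#' A `signal_record` holds simultaneously acquired arterial blood pressure
#' (ABP, mmHg) and cerebral blood-flow velocity (CBFV, cm/s) waveforms with
#' their common sampling rate. It is the raw-data container consumed by all
#' downstream preprocessing and analysis.
#'
#' @param abp Numeric vector, arterial blood pressure waveform (mmHg).
#' @param cbfv Numeric vector, cerebral blood-flow velocity waveform (cm/s),
#'   same length as `abp`.
#' @param fs Sampling rate in Hz (> 0).
#' @param time_s Optional numeric vector of sample times in seconds from
#'   record start. Reconstructed as `(0:(n-1))/fs` when omitted; when given it
#'   must be monotone and consistent with `fs` to within 1 ppm.
#' @param meta Named list of free-form metadata (e.g. `subject`, `timepoint`,
#'   `condition`). A `condition` entry, when present, must be `"baseline"` or
#'   `"intervention"`.
#' @return An object of class `signal_record` with fields `time_s`, `abp`,
#'   `cbfv`, `fs`, `meta`.
#' @examples
#' rec <- signal_record(abp = 90 + sin(2 * pi * 0.1 * (0:999) / 10),
#'                      cbfv = rep(40, 1000), fs = 10)
#' duration(rec)
#' @export
signal_record <- function(abp, cbfv, fs, time_s = NULL, meta = list()) {
  if (length(abp) != length(cbfv)) {
    stop("channel length mismatch: abp has ", length(abp),
         " samples, cbfv has ", length(cbfv))
  }
  if (length(abp) == 0L) stop("empty record")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number (Hz)")
  }
  if (is.null(time_s)) {
    time_s <- (seq_along(abp) - 1) / fs
  } else {
    if (length(time_s) != length(abp)) {
      stop("channel length mismatch: time has ", length(time_s),
           " samples, abp has ", length(abp))
    }
    if (length(time_s) > 1L) {
      dt <- diff(time_s)
      if (any(dt <= 0)) stop("time_s must be strictly increasing")
      # spacing must agree with fs to 1 ppm
      if (any(abs(dt * fs - 1) > 1e-6)) {
        stop("time spacing inconsistent with fs (tolerance 1 ppm)")
      }
    }
  }
  if (!is.null(meta$condition) &&
      !meta$condition %in% c("baseline", "intervention")) {
    stop("condition label must be 'baseline' or 'intervention', got '",
         meta$condition, "'")
  }
  structure(
    list(time_s = as.numeric(time_s), abp = as.numeric(abp),
         cbfv = as.numeric(cbfv), fs = as.numeric(fs), meta = meta),
    class = "signal_record"
  )
}

#' Record duration in seconds
#'
#' @param record A [signal_record()].
#' @return Duration in seconds (`n / fs`).
#' @export
duration <- function(record) {
  stopifnot(inherits(record, "signal_record"))
  length(record$abp) / record$fs
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> %d samples @ %g Hz (%.1f s)\n",
              length(x$abp), x$fs, duration(x)))
  cat(sprintf("  ABP  [mmHg]: mean %.2f, range [%.2f, %.2f]\n",
              mean(x$abp), min(x$abp), max(x$abp)))
  cat(sprintf("  CBFV [cm/s]: mean %.2f, range [%.2f, %.2f]\n",
              mean(x$cbfv), min(x$cbfv), max(x$cbfv)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta),
                         vapply(x$meta, function(v) paste(format(v), collapse = ","),
                                character(1)),
                         sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Select an analysis window within a recording
#'
#' Marks a (by default) 5-minute window of a recording for analysis; windows
#' are chosen to avoid artefacts, so the selection carries a free-text quality
#' note.
#'
#' @param start_s Offset of the window start from record start (s, >= 0).
#' @param duration_s Window length in seconds (default 300, the conventional
#'   5-minute analysis window).
#' @param quality_note Free text describing the selection rationale.
#' @return An object of class `segment_selection`.
#' @export
segment_selection <- function(start_s = 0, duration_s = 300, quality_note = "") {
  if (start_s < 0) stop("start_s must be >= 0")
  if (duration_s <= 0) stop("duration_s must be > 0")
  structure(list(start_s = start_s, duration_s = duration_s,
                 quality_note = quality_note),
            class = "segment_selection")
}

# meta values are written as "# key=value" header lines; only scalars survive
# the round trip (numbers re-read as numeric, everything else as character)
format_meta_value <- function(v) {
  if (is.numeric(v)) format(v, digits = 17, scientific = FALSE) else as.character(v)
}

parse_meta_value <- function(s) {
  num <- suppressWarnings(as.numeric(s))
  if (!is.na(num) && grepl("^[-+0-9.eE]+$", s)) num else s
}

#' Read a two-channel recording from delimited text
#'
#' Reads the package's plain-text recording format: optional `# key=value`
#' metadata lines, then a comma-separated table with a header naming columns
#' `time`, `abp`, `cbfv` (the `time` column may be absent when a sampling rate
#' is available from metadata or `fs_override`).
#'
#' @param path Path to the file.
#' @param fs_override Optional sampling rate in Hz; overrides any `fs`
#'   metadata in the file and permits files without a time column.
#' @return A validated [signal_record()].
#' @seealso [write_record()]
#' @export
read_record <- function(path, fs_override = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      key <- trimws(substr(kv, 1, eq - 1))
      val <- trimws(substr(kv, eq + 1, nchar(kv)))
      meta[[key]] <- parse_meta_value(val)
    }
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("no data rows in ", path)
  header <- tolower(trimws(strsplit(body[[1]], ",", fixed = TRUE)[[1]]))
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        header = TRUE, col.names = header,
                        colClasses = "character", check.names = FALSE)
  need <- c("abp", "cbfv")
  missing_cols <- setdiff(need, header)
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  to_num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad) || anyNA(v)) {
      stop("non-numeric cell in column '", col, "' (first at data row ",
           if (length(bad)) bad[1] else which(is.na(v))[1], ")")
    }
    v
  }
  abp <- to_num("abp")
  cbfv <- to_num("cbfv")
  fs <- fs_override
  if (is.null(fs) && !is.null(meta$fs)) fs <- as.numeric(meta$fs)
  time_s <- NULL
  if ("time" %in% header) {
    time_s <- to_num("time")
    if (is.null(fs)) {
      if (length(time_s) < 2L) stop("cannot infer fs from a single-row time column")
      fs <- 1 / stats::median(diff(time_s))
    }
  } else if (is.null(fs)) {
    stop("file has no time column and no sampling rate: supply fs_override ",
         "or an 'fs' metadata line")
  }
  meta$fs <- NULL
  signal_record(abp = abp, cbfv = cbfv, fs = fs, time_s = time_s, meta = meta)
}

#' Write a recording as delimited text
#'
#' Inverse of [read_record()]: metadata as `# key=value` lines (including the
#' sampling rate), then a `time,abp,cbfv` table at full numeric precision
#' (>= 15 significant digits), so that a read/write round trip is lossless to
#' well below 1e-9.
#'
#' @param record A [signal_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "signal_record"))
  if (length(record$abp) == 0L) stop("empty record")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# fs=%s", format(record$fs, digits = 17, scientific = FALSE)),
             con)
  for (key in names(record$meta)) {
    v <- record$meta[[key]]
    # only scalar metadata survives the text header; nested objects (e.g.
    # generator ground truth) are serialized separately as JSON by the CLI
    if (is.atomic(v) && length(v) == 1L) {
      writeLines(sprintf("# %s=%s", key, format_meta_value(v)), con)
    }
  }
  writeLines("time,abp,cbfv", con)
  fmt <- function(v) formatC(v, digits = 15, format = "g")
  writeLines(paste(fmt(record$time_s), fmt(record$abp), fmt(record$cbfv), sep = ","),
             con)
  invisible(path)
}

#' Write per-segment analysis results as JSON
#'
#' Serializes the nested result of [analyze_record()] (variability, Mx and
#' transfer-function results for one analyzed segment pair) to a JSON
#' document.
#'
#' @param result A list as returned by [analyze_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, path) {
  jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
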