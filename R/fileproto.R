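# Text-file exchange protocol between the optimizer process and the
# instrument side. Plain key=value ASCII with a monotone sequence number so
# the reader can tell a fresh result from a stale file.

#' Write and read the parameter exchange file
#'
#' The parameter file carries one `name=value` line per tuning parameter,
#' preceded by a `seq=<n>` request sequence number. `read_param_file()`
#' parses it back; write-then-read is an identity on the values.
#'
#' @param params Named numeric vector of tuning parameters.
#' @param path File path.
#' @param seq Request sequence number (monotone increasing across requests).
#' @return `write_param_file()` returns `path` invisibly;
#'   `read_param_file()` returns a list with `seq` and the named numeric
#'   vector `params`.
#' @examples
#' f <- tempfile()
#' write_param_file(c(CUR = 20.229, GS1 = 15.573), f, seq = 1)
#' read_param_file(f)$params
#' @export
write_param_file <- function(params, path, seq = 1L) {
  stopifnot(is.numeric(params), !is.null(names(params)), all(names(params) != ""))
  lines <- c(sprintf("seq=%d", as.integer(seq)),
             sprintf("%s=%.15g", names(params), params))
  writeLines(lines, path)
  invisible(path)
}

parse_kv <- function(line, lineno, path) {
  m <- regmatches(line, regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(\\S+)\\s*$",
                                line))[[1L]]
  if (length(m) != 3L) {
    stop("malformed line ", lineno, " in '", path, "': \"", line, "\"",
         call. = FALSE)
  }
  val <- suppressWarnings(as.numeric(m[3L]))
  if (is.na(val)) {
    stop("non-numeric value on line ", lineno, " in '", path, "': \"",
         line, "\"", call. = FALSE)
  }
  stats::setNames(val, m[2L])
}

#' @rdname write_param_file
#' @export
read_param_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop("parameter file '", path, "' is empty or lacks parameter lines",
         call. = FALSE)
  }
  kv <- unlist(lapply(seq_along(lines),
                      function(i) parse_kv(lines[i], i, path)))
  if (names(kv)[1L] != "seq") {
    stop("first line of '", path, "' must be the sequence number",
         call. = FALSE)
  }
  list(seq = as.integer(kv[[1L]]), params = kv[-1L])
}

#' Write and read the intensity result file
#'
#' The instrument side reports one line per peak with comma-separated
#' `mass=`, `intensity=`, `fwhm=` and `mass_error=` fields, preceded by the
#' echoed `seq=<n>` line of the request it answers.
#'
#' @param measurements List of `peak_measurement` objects (or a data frame
#'   with columns `mass`, `intensity`, `fwhm`, `mass_error`).
#' @param path File path.
#' @param seq Echoed request sequence number.
#' @return `write_intensity_file()` returns `path` invisibly;
#'   `read_intensity_file()` returns a list with `seq` and a data frame
#'   `peaks`.
#' @export
write_intensity_file <- function(measurements, path, seq = 1L) {
  df <- if (is.data.frame(measurements)) measurements
        else peaks_table(measurements)
  lines <- c(sprintf("seq=%d", as.integer(seq)),
             sprintf("mass=%.15g, intensity=%.15g, fwhm=%.15g, mass_error=%.15g",
                     df$mass, df$intensity, df$fwhm, df$mass_error))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_intensity_file
#' @export
read_intensity_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop("intensity file '", path, "' is empty or lacks peak lines",
         call. = FALSE)
  }
  seq_kv <- parse_kv(lines[1L], 1L, path)
  if (names(seq_kv) != "seq") {
    stop("first line of '", path, "' must be the sequence number",
         call. = FALSE)
  }
  rows <- lapply(seq_along(lines[-1L]) + 1L, function(i) {
    fields <- strsplit(lines[i], ",")[[1L]]
    kv <- unlist(lapply(fields, parse_kv, lineno = i, path = path))
    need <- c("mass", "intensity", "fwhm", "mass_error")
    if (!all(need %in% names(kv))) {
      stop("line ", i, " in '", path, "' is missing field(s): ",
           paste(setdiff(need, names(kv)), collapse = ", "), call. = FALSE)
    }
    as.data.frame(as.list(kv[need]))
  })
  list(seq = as.integer(seq_kv[[1L]]), peaks = do.call(rbind, rows))
}

#' Poll an exchange file until its sequence number advances
#'
#' Re-reads `path` with `reader` every `poll` seconds until the parsed `seq`
#' exceeds `last_seq`, then returns the parsed structure. A missing or
#' not-yet-updated file within `timeout` seconds raises a condition of class
#' `qms_timeout`.
#'
#' @param path File path.
#' @param last_seq Last sequence number already consumed.
#' @param timeout Maximum wait (seconds).
#' @param poll Poll interval (seconds).
#' @param reader Parser, [read_intensity_file()] by default.
#' @return The parsed structure whose `seq > last_seq`.
#' @export
wait_for_update <- function(path, last_seq, timeout = 10, poll = 0.1,
                            reader = read_intensity_file) {
  deadline <- Sys.time() + timeout
  repeat {
    if (file.exists(path)) {
      parsed <- tryCatch(reader(path), error = function(e) NULL)
      if (!is.null(parsed) && parsed$seq > last_seq) return(parsed)
    }
    if (Sys.time() >= deadline) {
      stop(errorCondition(
        sprintf("timed out after %gs waiting for '%s' to advance past seq %d",
                timeout, path, last_seq),
        class = "qms_timeout"))
    }
    Sys.sleep(poll)
  }
}
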