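# Shared structured-CSV dialect for instrument trace files.
#
# Layout: a header section of `key,value` lines, terminated by a single
# blank line, followed by a column-header row and the numeric body.
# The header carries test metadata (identity, geometry, calibration,
# field notes); the body is the already-calibrated sample stream.

read_structured_csv <- function(path, required_cols) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  sep <- which(!nzchar(trimws(lines)))[1L]
  if (is.na(sep) || sep == length(lines)) {
    stop(sprintf("%s: no blank line separating header from body", path),
         call. = FALSE)
  }
  header_lines <- lines[seq_len(sep - 1L)]
  header <- list()
  for (ln in header_lines) {
    comma <- regexpr(",", ln, fixed = TRUE)
    if (comma < 0L) {
      stop(sprintf("%s: header line %s is not 'key,value'", path,
                   dQuote(ln, q = FALSE)), call. = FALSE)
    }
    key <- substr(ln, 1L, comma - 1L)
    header[[key]] <- substr(ln, comma + 1L, nchar(ln))
  }
  body <- utils::read.csv(text = lines[seq.int(sep + 1L, length(lines))],
                          stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(body))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(body) == 0L) stop(sprintf("%s: empty body", path), call. = FALSE)
  list(header = header, body = body)
}

# Deterministic body formatting: 10 significant digits survive a
# decimal -> double -> decimal round trip, so write -> read -> write is
# bit-identical on the body.
format_body_number <- function(x) {
  ifelse(x == floor(x) & abs(x) < 1e15, sprintf("%d", as.integer(round(x))),
         sprintf("%.10g", x))
}

write_structured_csv <- function(path, header, body) {
  head_lines <- vapply(names(header), function(k) {
    paste0(k, ",", as.character(header[[k]]))
  }, character(1L))
  body_cols <- lapply(body, function(col) {
    if (is.numeric(col)) format_body_number(col) else as.character(col)
  })
  body_lines <- do.call(paste, c(body_cols, sep = ","))
  writeLines(c(head_lines, "", paste(names(body), collapse = ","), body_lines),
             path)
  invisible(path)
}

header_numeric <- function(header, key, path = "<file>", required = FALSE) {
  if (is.null(header[[key]])) {
    if (required) {
      stop(sprintf("%s: missing mandatory header key '%s'", path, key),
           call. = FALSE)
    }
    return(NULL)
  }
  as.numeric(header[[key]])
}

# Sensor calibration pairs are stored as "raw:ref;raw:ref;..." strings
# under header keys prefixed "calib_". They are parsed and reported but
# never re-applied: the device calibrates on board.
parse_calibration_pairs <- function(header) {
  keys <- grep("^calib_", names(header), value = TRUE)
  out <- lapply(keys, function(k) {
    pairs <- strsplit(strsplit(header[[k]], ";", fixed = TRUE)[[1L]], ":",
                      fixed = TRUE)
    data.frame(sensor = sub("^calib_", "", k),
               raw = vapply(pairs, function(p) as.numeric(p[[1L]]), numeric(1L)),
               reference = vapply(pairs, function(p) as.numeric(p[[2L]]),
                                  numeric(1L)))
  })
  if (length(out)) do.call(rbind, out) else NULL
}

# R^2 without summary.lm (which warns on numerically perfect fits).
fit_r_squared <- function(fit) {
  y <- fit$model[[1L]]
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) return(1)
  max(0, 1 - sum(stats::residuals(fit)^2) / ss_tot)
}

check_time_monotone <- function(time_s, path = "<trace>") {
  if (any(diff(time_s) <= 0)) {
    stop(sprintf("%s: time is not strictly increasing", path), call. = FALSE)
  }
  invisible(TRUE)
}
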