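# Universal-testing-machine (Instron-style) trace I/O, shared by the
# rind-puncture, long-span bending and micro-bending analyses.

INSTRON_COLUMNS <- c("time_s", "displacement_mm", "force_N")
TEST_KINDS <- c("puncture", "bending3pt", "micro_bending")

#' Read an Instron-style force-displacement CSV
#'
#' Files use the same structured dialect as the field-device files: a
#' `key,value` metadata header (stalk identity, internode index, test
#' kind, sampling rate, fixture geometry), a blank line, then the body
#' with columns \code{time_s,displacement_mm,force_N}. Puncture tests are
#' collected at 1000 Hz with monotone crosshead displacement; structural
#' bending tests sample every 100 ms.
#'
#' @param path Path to the CSV file.
#' @param column_names Optional named character vector remapping
#'   nonstandard body column names, e.g.
#'   \code{c(time_s = "Time", displacement_mm = "Extension", force_N = "Load")}.
#' @return A \code{force_displacement_trace}: list with \code{samples}
#'   (data.frame \code{time_s}, \code{displacement_mm}, \code{force_N})
#'   and \code{metadata} (list: \code{stalk_id}, \code{internode_index},
#'   \code{test_kind}, \code{sampling_rate_hz}, geometry keys if present,
#'   \code{extra}).
#' @export
read_instron_csv <- function(path, column_names = NULL) {
  raw <- read_structured_csv(
    path, if (is.null(column_names)) INSTRON_COLUMNS else unname(column_names))
  body <- raw$body
  if (!is.null(column_names)) {
    names(body)[match(column_names, names(body))] <- names(column_names)
  }
  check_time_monotone(body$time_s, path)
  kind <- raw$header[["test_kind"]] %||% "puncture"
  if (!kind %in% TEST_KINDS) {
    stop(sprintf("%s: test_kind '%s' not one of %s", path, kind,
                 paste(TEST_KINDS, collapse = ", ")), call. = FALSE)
  }
  if (kind == "puncture" && any(diff(body$displacement_mm) < 0)) {
    stop(sprintf("%s: displacement must be monotone non-decreasing for a puncture test",
                 path), call. = FALSE)
  }
  rate <- header_numeric(raw$header, "sampling_rate_hz", path)
  if (is.null(rate)) {
    rate <- 1 / stats::median(diff(body$time_s))
  }
  if (rate <= 0) stop(sprintf("%s: sampling rate must be positive", path),
                      call. = FALSE)
  known <- c("stalk_id", "internode_index", "test_kind", "sampling_rate_hz",
             "zero_plane_mm", "span_mm", "a_mm", "b_mm", "width_mm",
             "thickness_mm")
  meta <- list(
    stalk_id = raw$header[["stalk_id"]],
    internode_index = header_numeric(raw$header, "internode_index", path),
    test_kind = kind,
    sampling_rate_hz = rate,
    zero_plane_mm = header_numeric(raw$header, "zero_plane_mm", path),
    span_mm = header_numeric(raw$header, "span_mm", path),
    a_mm = header_numeric(raw$header, "a_mm", path),
    b_mm = header_numeric(raw$header, "b_mm", path),
    width_mm = header_numeric(raw$header, "width_mm", path),
    thickness_mm = header_numeric(raw$header, "thickness_mm", path),
    extra = raw$header[setdiff(names(raw$header), known)]
  )
  force_displacement_trace(body, meta)
}

#' Construct a force-displacement trace object
#'
#' @param samples data.frame with \code{time_s}, \code{displacement_mm},
#'   \code{force_N}; time strictly increasing.
#' @param metadata list; \code{test_kind} defaults to \code{"puncture"}.
#' @return A \code{force_displacement_trace}.
#' @export
force_displacement_trace <- function(samples, metadata = list()) {
  stopifnot(all(INSTRON_COLUMNS %in% names(samples)))
  check_time_monotone(samples$time_s)
  if (is.null(metadata$test_kind)) metadata$test_kind <- "puncture"
  if (is.null(metadata$sampling_rate_hz)) {
    metadata$sampling_rate_hz <- 1 / stats::median(diff(samples$time_s))
  }
  structure(list(samples = samples[INSTRON_COLUMNS], metadata = metadata),
            class = "force_displacement_trace")
}

#' @export
print.force_displacement_trace <- function(x, ...) {
  cat(sprintf("%s trace: %s internode %s | %d samples @ %.0f Hz | peak %.2f N\n",
              x$metadata$test_kind, x$metadata$stalk_id %||% "<no id>",
              x$metadata$internode_index %||% "?", nrow(x$samples),
              x$metadata$sampling_rate_hz, max(x$samples$force_N)))
  invisible(x)
}

#' Write a force-displacement trace to the structured CSV dialect
#'
#' @param trace A \code{force_displacement_trace}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_instron_csv <- function(trace, path) {
  m <- trace$metadata
  out <- list()
  for (k in c("stalk_id", "internode_index", "test_kind", "sampling_rate_hz",
              "zero_plane_mm", "span_mm", "a_mm", "b_mm", "width_mm",
              "thickness_mm")) {
    if (!is.null(m[[k]]) && !anyNA(m[[k]])) {
      out[[k]] <- if (is.numeric(m[[k]])) format_body_number(m[[k]]) else m[[k]]
    }
  }
  for (k in names(m$extra)) out[[k]] <- m$extra[[k]]
  write_structured_csv(path, out, trace$samples)
}
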