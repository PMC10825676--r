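#' Parse a StalkID plant identifier
#'
#' Field labels carry a unique plant identifier with the syntax
#' \code{"LocationYear_Plot-Stalk"}: a leading alphabetic location code,
#' a 4-digit year, an underscore, a plot number, a hyphen, and a stalk
#' number (e.g. \code{"ID2021_101-3"}). Because the identifier doubles as a
#' filename for per-plant data files, characters that are illegal or
#' hazardous in filenames (period, slash, backslash, asterisk, colon,
#' question mark, quotes, angle brackets, pipe) are rejected outright.
#'
#' @param text A single non-empty identifier string.
#' @return An object of class \code{stalk_id}: a list with elements
#'   \code{location} (character), \code{year} (integer), \code{plot}
#'   (integer), \code{stalk} (integer) and \code{raw_text} (the verbatim
#'   input, which always round-trips).
#' @examples
#' parse_stalk_id("ID2021_101-3")
#' @export
parse_stalk_id <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("StalkID must be a single character string", call. = FALSE)
  }
  if (!nzchar(text)) {
    stop("malformed StalkID: empty input", call. = FALSE)
  }
  bad <- prohibited_id_characters(text)
  if (length(bad)) {
    stop(sprintf("malformed StalkID %s: prohibited filename character '%s'",
                 dQuote(text, q = FALSE), bad[[1L]]), call. = FALSE)
  }
  m <- regexec("^([A-Za-z]+)([0-9]{4})_([0-9]+)-([0-9]+)$", text)
  parts <- regmatches(text, m)[[1L]]
  if (!length(parts)) {
    stop(sprintf(paste("malformed StalkID %s: expected syntax",
                       "'LocationYear_Plot-Stalk' (%s)"),
                 dQuote(text, q = FALSE), describe_syntax_failure(text)),
         call. = FALSE)
  }
  plot <- as.integer(parts[[4L]])
  stalk <- as.integer(parts[[5L]])
  if (plot <= 0L || stalk <= 0L) {
    stop(sprintf("malformed StalkID %s: plot and stalk numbers must be positive",
                 dQuote(text, q = FALSE)), call. = FALSE)
  }
  structure(
    list(location = parts[[2L]], year = as.integer(parts[[3L]]),
         plot = plot, stalk = stalk, raw_text = text),
    class = "stalk_id"
  )
}

#' @export
print.stalk_id <- function(x, ...) {
  cat(sprintf("StalkID %s (location %s, year %d, plot %d, stalk %d)\n",
              x$raw_text, x$location, x$year, x$plot, x$stalk))
  invisible(x)
}

#' @export
format.stalk_id <- function(x, ...) x$raw_text

#' @export
as.character.stalk_id <- function(x, ...) x$raw_text

# Characters that must never appear in an identifier used as a filename.
PROHIBITED_ID_CHARS <- c(".", "/", "\\", "*", ":", "?", "\"", "'", "<", ">", "|")

prohibited_id_characters <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  chars[chars %in% PROHIBITED_ID_CHARS]
}

# Name the first missing token so the error message is actionable.
describe_syntax_failure <- function(text) {
  if (!grepl("^[A-Za-z]", text)) return("missing leading alphabetic location code")
  if (!grepl("^[A-Za-z]+[0-9]{4}", text)) return("missing 4-digit year after location")
  if (!grepl("_", text, fixed = TRUE)) return("missing '_' before plot token")
  if (!grepl("-", text, fixed = TRUE)) return("missing '-' before stalk token")
  "unexpected characters"
}

#' Error-correct a triple-redundant scanned QR payload
#'
#' QR plant labels encode the StalkID three times, joined by a delimiter
#' (\code{"StalkID__StalkID__StalkID"}). Scans occasionally misread single
#' characters; because the three copies are redundant, a per-character
#' majority vote recovers the true identifier and flags exactly where the
#' scan went wrong. Copies of unequal length (insertion/deletion errors)
#' and positions where all three copies disagree are unrecoverable: no safe
#' tiebreak exists, so the function stops rather than fabricate an ID.
#'
#' @param payload The raw decoded string from one QR scan.
#' @param delimiter Joiner between the three copies (default \code{"__"};
#'   a double underscore is required because a single underscore is legal
#'   inside a StalkID).
#' @param parse If \code{TRUE} (default), also parse the corrected text via
#'   [parse_stalk_id()]; set \code{FALSE} to accept identifiers that do not
#'   follow the standard syntax.
#' @return A list of class \code{scan_correction} with elements
#'   \code{id_text} (the corrected identifier string), \code{stalk_id}
#'   (parsed [parse_stalk_id()] result, or \code{NULL} when
#'   \code{parse = FALSE}), and \code{corrections}, a data.frame with one
#'   row per corrected character: \code{position} (1-based within the ID),
#'   \code{copy} (which of the three copies was wrong), \code{observed} and
#'   \code{corrected} characters. Zero rows when all copies agree.
#' @examples
#' correct_scanned_payload("ID2021_101-3__ID2021_101-3__ID2021_101-3")
#' @export
correct_scanned_payload <- function(payload, delimiter = "__", parse = TRUE) {
  if (!is.character(payload) || length(payload) != 1L || !nzchar(payload)) {
    stop("payload must be a single non-empty string", call. = FALSE)
  }
  copies <- strsplit(payload, delimiter, fixed = TRUE)[[1L]]
  if (length(copies) != 3L) {
    stop(sprintf("unrecoverable payload: expected 3 copies separated by %s, found %d",
                 dQuote(delimiter, q = FALSE), length(copies)), call. = FALSE)
  }
  lens <- nchar(copies)
  if (length(unique(lens)) != 1L) {
    stop(sprintf(paste("unrecoverable payload: copies have unequal lengths (%s);",
                       "insertion/deletion scan errors cannot be aligned safely"),
                 paste(lens, collapse = ", ")), call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(copies, "", fixed = TRUE))
  out <- character(ncol(mat))
  corr <- list()
  for (p in seq_len(ncol(mat))) {
    col <- mat[, p]
    tab <- table(col)
    if (length(tab) == 1L) {
      out[p] <- col[[1L]]
    } else if (max(tab) == 2L) {
      winner <- names(tab)[which.max(tab)]
      out[p] <- winner
      bad_copy <- which(col != winner)
      corr[[length(corr) + 1L]] <- data.frame(
        position = p, copy = bad_copy,
        observed = col[[bad_copy]], corrected = winner,
        stringsAsFactors = FALSE
      )
    } else {
      stop(sprintf(paste("unrecoverable payload: all three copies disagree at",
                         "position %d ('%s', '%s', '%s')"),
                   p, col[[1L]], col[[2L]], col[[3L]]), call. = FALSE)
    }
  }
  corrections <- if (length(corr)) {
    do.call(rbind, corr)
  } else {
    data.frame(position = integer(), copy = integer(),
               observed = character(), corrected = character(),
               stringsAsFactors = FALSE)
  }
  id_text <- paste(out, collapse = "")
  structure(
    list(id_text = id_text,
         stalk_id = if (parse) parse_stalk_id(id_text) else NULL,
         corrections = corrections),
    class = "scan_correction"
  )
}

#' @export
print.scan_correction <- function(x, ...) {
  cat(sprintf("corrected StalkID: %s (%d correction%s)\n", x$id_text,
              nrow(x$corrections), if (nrow(x$corrections) == 1L) "" else "s"))
  if (nrow(x$corrections)) print(x$corrections, row.names = FALSE)
  invisible(x)
}

#' Build the triple-redundant payload for a StalkID
#'
#' Inverse of [correct_scanned_payload()] for a clean scan: repeats the
#' identifier three times with the delimiter, as encoded in QR labels.
#'
#' @param id_text Identifier string (or a \code{stalk_id} object).
#' @param delimiter Joiner between copies.
#' @return The payload string.
#' @export
triple_payload <- function(id_text, delimiter = "__") {
  if (inherits(id_text, "stalk_id")) id_text <- id_text$raw_text
  paste(rep(id_text, 3L), collapse = delimiter)
}
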