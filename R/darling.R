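# Field lodging-device (DARLING) test analysis.
#
# A test records force at the load cell and rotation of the device arm
# while the operator deflects a standing stalk: three preload cycles to
# 5-10 degrees, then a fourth push to structural failure. Structural
# bending strength is the peak applied moment M = F*h; flexural
# stiffness comes from the cantilever deflection model EI = phi*h^3/3
# with phi the slope of the force-deflection curve and deflection
# delta = h*sin(theta). Forces are in newtons and lengths in metres:
# the equations are unit-coherent only in SI.

DARLING_COLUMNS <- c("time_s", "force_N", "rotation_deg")
FAILURE_NOTES <- c("root_lodged", "stalk_lodged", "bent_no_break", "unspecified")

#' Read a structured DARLING field-test CSV
#'
#' A test file has a `key,value` metadata header (stalk identity, load
#' height, timestamp, GPS, sensor calibration values, failure note,
#' optional humidity/temperature), a blank line, then the sample body with
#' columns \code{time_s,force_N,rotation_deg}. The body stores the raw
#' device rotation (the sensors are calibrated over 80-180 degrees);
#' deflection angle from vertical is \code{rotation_vertical_ref_deg -
#' rotation_deg}. Calibration pairs are parsed into a table but never
#' re-applied -- the device applies them on board. Unknown header keys are
#' preserved verbatim.
#'
#' @param path Path to the CSV file.
#' @return A \code{force_rotation_trace}: list with \code{samples}
#'   (data.frame of \code{time_s}, \code{force_N}, \code{rotation_deg}),
#'   \code{header} (typed metadata list incl. \code{stalk_id},
#'   \code{load_height_m}, \code{failure_note}, \code{calibration},
#'   \code{extra}).
#' @seealso [write_darling_csv()], [analyze_darling()]
#' @export
read_darling_csv <- function(path) {
  raw <- read_structured_csv(path, DARLING_COLUMNS)
  h <- header_numeric(raw$header, "load_height_m", path, required = TRUE)
  if (is.na(h) || h <= 0) {
    stop(sprintf("%s: load_height_m must be a positive number", path),
         call. = FALSE)
  }
  if (is.null(raw$header[["stalk_id"]])) {
    stop(sprintf("%s: missing mandatory header key 'stalk_id'", path),
         call. = FALSE)
  }
  check_time_monotone(raw$body$time_s, path)
  note <- raw$header[["failure_note"]]
  if (is.null(note)) note <- "unspecified"
  if (!note %in% FAILURE_NOTES) {
    stop(sprintf("%s: failure_note '%s' not one of %s", path, note,
                 paste(FAILURE_NOTES, collapse = ", ")), call. = FALSE)
  }
  known <- c("stalk_id", "load_height_m", "failure_note", "timestamp",
             "gps_lat", "gps_lon", "rotation_vertical_ref_deg",
             "humidity_pct", "temperature_c",
             grep("^calib_", names(raw$header), value = TRUE))
  ref <- header_numeric(raw$header, "rotation_vertical_ref_deg", path)
  header <- list(
    stalk_id = raw$header[["stalk_id"]],
    load_height_m = h,
    failure_note = note,
    timestamp = raw$header[["timestamp"]],
    gps_lat = header_numeric(raw$header, "gps_lat", path),
    gps_lon = header_numeric(raw$header, "gps_lon", path),
    rotation_vertical_ref_deg = if (is.null(ref)) 180 else ref,
    humidity_pct = header_numeric(raw$header, "humidity_pct", path),
    temperature_c = header_numeric(raw$header, "temperature_c", path),
    calibration = parse_calibration_pairs(raw$header),
    extra = raw$header[setdiff(names(raw$header), known)]
  )
  force_rotation_trace(raw$body, header)
}

#' Construct a force-rotation trace object
#'
#' @param samples data.frame with columns \code{time_s}, \code{force_N},
#'   \code{rotation_deg} (raw device angle), time strictly increasing.
#' @param header metadata list; must carry a positive \code{load_height_m}.
#' @return A \code{force_rotation_trace} object.
#' @export
force_rotation_trace <- function(samples, header) {
  stopifnot(all(DARLING_COLUMNS %in% names(samples)))
  check_time_monotone(samples$time_s)
  if (is.null(header$load_height_m) || header$load_height_m <= 0) {
    stop("header$load_height_m must be positive", call. = FALSE)
  }
  if (is.null(header$rotation_vertical_ref_deg)) {
    header$rotation_vertical_ref_deg <- 180
  }
  structure(list(samples = samples[DARLING_COLUMNS], header = header),
            class = "force_rotation_trace")
}

#' @export
print.force_rotation_trace <- function(x, ...) {
  cat(sprintf("DARLING trace: %s | h = %.3f m | %d samples | %.1f s | note: %s\n",
              x$header$stalk_id, x$header$load_height_m, nrow(x$samples),
              diff(range(x$samples$time_s)), x$header$failure_note))
  invisible(x)
}

#' Write a DARLING trace back to the structured CSV dialect
#'
#' Body numbers are written with 10 significant digits, so a
#' write/read/write cycle reproduces the body byte for byte.
#'
#' @param trace A \code{force_rotation_trace}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_darling_csv <- function(trace, path) {
  h <- trace$header
  out <- list(stalk_id = h$stalk_id,
              load_height_m = format_body_number(h$load_height_m))
  for (k in c("timestamp", "gps_lat", "gps_lon", "failure_note",
              "rotation_vertical_ref_deg", "humidity_pct", "temperature_c")) {
    if (!is.null(h[[k]])) out[[k]] <- h[[k]]
  }
  if (!is.null(h$calibration)) {
    for (s in unique(h$calibration$sensor)) {
      rows <- h$calibration[h$calibration$sensor == s, ]
      out[[paste0("calib_", s)]] <-
        paste(sprintf("%g:%g", rows$raw, rows$reference), collapse = ";")
    }
  }
  for (k in names(h$extra)) out[[k]] <- h$extra[[k]]
  write_structured_csv(path, out, trace$samples)
}

#' Deflection angle from vertical, in degrees
#'
#' The raw device angle spans 80-180 degrees over the arm's range of
#' motion; the header's vertical reference maps it to a deflection angle
#' from vertical: \code{theta = ref - raw}.
#'
#' @param trace A \code{force_rotation_trace}.
#' @return Numeric vector of deflection angles (degrees).
#' @export
deflection_angle_deg <- function(trace) {
  trace$header$rotation_vertical_ref_deg - trace$samples$rotation_deg
}

#' Horizontal deflection of the load point
#'
#' The load cell sits at height \code{h} on a stalk rotating about its
#' base, so the horizontal deflection at the load point is
#' \code{h * sin(theta)}.
#'
#' @param theta_deg Deflection angle(s) from vertical, degrees.
#' @param h Load-cell height (m), positive.
#' @return Deflection in metres (vectorised over \code{theta_deg}).
#' @examples
#' deflection_from_rotation(90, 0.8)  # 0.8 m
#' @export
deflection_from_rotation <- function(theta_deg, h) {
  if (!is.numeric(h) || any(h <= 0)) stop("h must be positive", call. = FALSE)
  if (any(theta_deg < 0 | theta_deg > 90, na.rm = TRUE)) {
    message("deflection_from_rotation: angle(s) outside [0, 90] degrees")
  }
  h * sin(theta_deg * pi / 180)
}

#' Cantilever flexural stiffness from a force-deflection slope
#'
#' The tip-loaded cantilever deflection relation \code{delta = F h^3 /
#' (3 EI)} inverted for stiffness: \code{EI = phi * h^3 / 3}, where
#' \code{phi} is the slope of the force-deflection curve.
#'
#' @param phi Slope of force vs deflection (N/m).
#' @param h Load height (m).
#' @return Flexural stiffness EI (N m^2), vectorised.
#' @export
cantilever_stiffness <- function(phi, h) {
  phi * h^3 / 3
}

#' Segment a field test into its preload cycles and failure push
#'
#' The protocol deflects the stalk by 5-10 degrees three times, then a
#' fourth push runs to structural failure. Detection uses hysteresis
#' thresholding on the deflection angle: a push starts when the angle
#' rises above \code{theta_on} and ends when it falls back below
#' \code{theta_off}. The push whose peak exceeds \code{failure_theta}, or
#' the push still in progress when the file ends, is the failure push
#' (the last such if several qualify); all others are preload cycles.
#'
#' @param trace A \code{force_rotation_trace}.
#' @param theta_on,theta_off Hysteresis thresholds, degrees.
#' @param failure_theta Peak deflection (degrees) above which a push is
#'   treated as the failure push.
#' @return data.frame with one row per push: \code{kind}
#'   (\code{"preload_cycle"}/\code{"failure_push"}), \code{start},
#'   \code{end} (inclusive sample indices), \code{peak_rotation} (peak
#'   deflection angle, degrees). Warns (protocol violation) when the
#'   number of pushes is not four; errors when no push is detected.
#' @export
segment_pushes <- function(trace, theta_on = 2, theta_off = 1,
                           failure_theta = 15) {
  stopifnot(theta_on > theta_off)
  theta <- deflection_angle_deg(trace)
  n <- length(theta)
  if (n == 0L) stop("empty trace", call. = FALSE)
  segs <- list()
  i <- 1L
  while (i <= n) {
    if (theta[[i]] >= theta_on) {
      j <- i
      while (j < n && theta[[j + 1L]] >= theta_off) j <- j + 1L
      segs[[length(segs) + 1L]] <- c(start = i, end = j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(segs)) {
    stop("no push detected: deflection never exceeds the onset threshold",
         call. = FALSE)
  }
  seg <- as.data.frame(do.call(rbind, segs))
  seg$peak_rotation <- vapply(seq_len(nrow(seg)), function(k) {
    max(theta[seg$start[[k]]:seg$end[[k]]])
  }, numeric(1L))
  is_failure_candidate <- seg$peak_rotation > failure_theta |
    (seq_len(nrow(seg)) == nrow(seg) & seg$end == n)
  failure_idx <- if (any(is_failure_candidate)) {
    max(which(is_failure_candidate))
  } else {
    nrow(seg)
  }
  seg$kind <- ifelse(seq_len(nrow(seg)) == failure_idx,
                     "failure_push", "preload_cycle")
  if (nrow(seg) != 4L) {
    warning(sprintf("protocol violation: %d push(es) detected, expected 4",
                    nrow(seg)), call. = FALSE)
  }
  seg[c("kind", "start", "end", "peak_rotation")]
}

#' Structural bending strength from a field test
#'
#' The maximum bending moment the stalk sustains: \code{M = F * h},
#' maximised over the failure push.
#'
#' @param trace A \code{force_rotation_trace}.
#' @param segments Optional precomputed [segment_pushes()] result.
#' @return Bending strength in newton-metres.
#' @export
bending_strength <- function(trace, segments = NULL) {
  if (is.null(segments)) segments <- segment_pushes(trace)
  fail <- segments[segments$kind == "failure_push", ]
  if (nrow(fail) == 0L) stop("no failure push in segmentation", call. = FALSE)
  idx <- fail$start[[1L]]:fail$end[[1L]]
  max(trace$samples$force_N[idx] * trace$header$load_height_m)
}

#' Flexural stiffness from the preload cycles of a field test
#'
#' For each preload cycle, the loading limb (push start to peak rotation)
#' is reduced to its 20-80\% force-quantile band and a straight line is
#' fitted to force versus deflection (\code{h*sin(theta)}); the slope
#' \code{phi} gives the cantilever stiffness \code{EI = phi * h^3 / 3}.
#' The reported \code{EI} is the arithmetic mean across cycles, with every
#' per-cycle fit retained.
#'
#' @param trace A \code{force_rotation_trace}.
#' @param segments Optional precomputed [segment_pushes()] result.
#' @param quantile_band Lower/upper force quantiles bounding the fit
#'   window on the loading limb.
#' @param min_points Minimum samples required in the fit window.
#' @return List with \code{EI} (N m^2), \code{slope_phi} (N/m),
#'   \code{r_squared} (mean across cycles), and \code{per_cycle}
#'   (data.frame: cycle, phi, EI, r_squared, n, deflection window).
#' @export
flexural_stiffness <- function(trace, segments = NULL,
                               quantile_band = c(0.2, 0.8), min_points = 5L) {
  if (is.null(segments)) segments <- segment_pushes(trace)
  pre <- segments[segments$kind == "preload_cycle", ]
  if (nrow(pre) == 0L) stop("no preload cycle in segmentation", call. = FALSE)
  h <- trace$header$load_height_m
  theta <- deflection_angle_deg(trace)
  cycles <- lapply(seq_len(nrow(pre)), function(k) {
    idx <- pre$start[[k]]:pre$end[[k]]
    peak_at <- idx[[which.max(theta[idx])]]
    limb <- pre$start[[k]]:peak_at
    f <- trace$samples$force_N[limb]
    d <- deflection_from_rotation(pmax(theta[limb], 0), h)
    # window on a smoothed copy of the force: selecting samples by their
    # own noisy values would truncate the noise and attenuate the slope
    f_sel <- centered_moving_average(f, 11L)
    qs <- stats::quantile(f_sel, quantile_band, names = FALSE)
    win <- f_sel >= qs[[1L]] & f_sel <= qs[[2L]]
    if (sum(win) < min_points || diff(range(d[win])) <= 0) {
      stop(sprintf(
        "degenerate fit in preload cycle %d: %d samples, deflection span %g m",
        k, sum(win), diff(range(d[win]))), call. = FALSE)
    }
    fit <- stats::lm(f[win] ~ d[win])
    phi <- unname(stats::coef(fit)[[2L]])
    r2 <- fit_r_squared(fit)
    data.frame(cycle = k, phi = phi, EI = cantilever_stiffness(phi, h),
               r_squared = r2,
               n = sum(win), deflection_min = min(d[win]),
               deflection_max = max(d[win]))
  })
  per_cycle <- do.call(rbind, cycles)
  list(EI = mean(per_cycle$EI), slope_phi = mean(per_cycle$phi),
       r_squared = mean(per_cycle$r_squared), per_cycle = per_cycle)
}

#' Full analysis of one field lodging test
#'
#' Segments the trace, then computes structural bending strength and
#' flexural stiffness.
#'
#' @inheritParams flexural_stiffness
#' @param failure_theta Passed to [segment_pushes()].
#' @return A \code{darling_result}: list with \code{stalk_id},
#'   \code{bending_strength_Nm}, \code{flexural_stiffness_Nm2},
#'   \code{slope_phi}, \code{r_squared}, \code{per_cycle},
#'   \code{failure_note}, \code{timestamp}, \code{gps_lat}, \code{gps_lon},
#'   \code{n_pushes}.
#' @export
analyze_darling <- function(trace, quantile_band = c(0.2, 0.8),
                            failure_theta = 15) {
  segments <- segment_pushes(trace, failure_theta = failure_theta)
  stiff <- flexural_stiffness(trace, segments, quantile_band = quantile_band)
  structure(list(
    stalk_id = trace$header$stalk_id,
    bending_strength_Nm = bending_strength(trace, segments),
    flexural_stiffness_Nm2 = stiff$EI,
    slope_phi = stiff$slope_phi,
    r_squared = stiff$r_squared,
    per_cycle = stiff$per_cycle,
    failure_note = trace$header$failure_note,
    timestamp = trace$header$timestamp,
    gps_lat = trace$header$gps_lat,
    gps_lon = trace$header$gps_lon,
    n_pushes = nrow(segments)
  ), class = "darling_result")
}

#' @export
print.darling_result <- function(x, ...) {
  cat(sprintf("%s: M = %.3f N m, EI = %.3f N m^2 (R^2 = %.4f), %s\n",
              x$stalk_id, x$bending_strength_Nm, x$flexural_stiffness_Nm2,
              x$r_squared, x$failure_note))
  invisible(x)
}

#' Batch-process DARLING files into a tidy phenotype table
#'
#' @param paths Character vector of DARLING CSV paths.
#' @return data.frame with one row per file: stalk_id, bending strength,
#'   flexural stiffness, R^2, failure note, timestamp, GPS.
#' @export
process_darling_files <- function(paths) {
  rows <- lapply(paths, function(p) {
    res <- analyze_darling(read_darling_csv(p))
    data.frame(stalk_id = res$stalk_id,
               bending_strength_Nm = res$bending_strength_Nm,
               flexural_stiffness_Nm2 = res$flexural_stiffness_Nm2,
               r_squared = res$r_squared,
               failure_note = res$failure_note,
               timestamp = res$timestamp %||% NA_character_,
               gps_lat = res$gps_lat %||% NA_real_,
               gps_lon = res$gps_lon %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
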