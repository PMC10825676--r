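# Rind puncture analysis.
#
# A 2 mm chamfered probe is driven through the minor axis of an
# internode resting on a platform. The probe is zeroed on the platform
# face, raised 35 mm, and driven at 25.4 mm/s to 5 mm below the surface
# while force is sampled at 1000 Hz. The force-displacement curve shows
# two rind-wall peaks separated by a soft pith plateau; four keypoints
# summarise the geometry:
#   A - initial contact with the proximal rind wall
#   B - mid-lumen force minimum ("midpoint")
#   C - reengagement with the distal rind wall
#   D - exit (zero) plane, where the probe tip is flush with the platform
# Minor diameter = D - A, rind thickness = D - C, rind penetration
# resistance (RPR) = peak force, integrated puncture score (IPS) =
# integral of force over displacement from A to D.

#' Is this trace a blank (empty) test?
#'
#' Damaged internodes are logged as blank instrument runs so the file
#' order keeps track of internode numbers. A blank never develops real
#' load: the test is blank when its peak force is strictly below the
#' threshold.
#'
#' @param trace A \code{force_displacement_trace}.
#' @param threshold_N Blank threshold (N); a peak exactly at the
#'   threshold is \emph{not} blank.
#' @return Logical scalar.
#' @export
detect_blank_test <- function(trace, threshold_N = 1) {
  max(trace$samples$force_N) < threshold_N
}

centered_moving_average <- function(x, window) {
  if (window <= 1L || length(x) < window) return(x)
  sm <- stats::filter(x, rep(1 / window, window), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

# Refine a threshold crossing to the true onset of a force rise: fit a
# line to the raw rising edge just past the crossing and extrapolate
# back to the local baseline level. Threshold crossings lag the onset by
# threshold/slope; back-projection removes that bias. Falls back to the
# crossing sample when the edge is not locally linear (e.g. an
# instantaneous step).
refine_onset <- function(d, f, j0, base_level, peak_idx, window = 10L,
                         max_back_mm = 0.75) {
  hi <- min(j0 + window - 1L, peak_idx)
  if (hi - j0 + 1L < 3L) return(d[j0])
  seg_d <- d[j0:hi]
  seg_f <- f[j0:hi]
  if (diff(range(seg_d)) <= 0) return(d[j0])
  fit <- stats::lm(seg_f ~ seg_d)
  slope <- stats::coef(fit)[[2L]]
  if (!is.finite(slope) || slope <= 0) return(d[j0])
  onset <- (base_level - stats::coef(fit)[[1L]]) / slope
  if (onset > d[j0] || onset < d[j0] - max_back_mm) return(d[j0])
  onset
}

#' Locate the four characteristic keypoints of a puncture trace
#'
#' Detection works on a centred moving-average of the force signal.
#' The contact threshold is the pre-contact baseline median plus
#' \code{max(contact_min_N, noise_mult * baseline sd)}; A is the first
#' displacement where force exceeds it (the crossing is refined on the
#' raw signal to avoid smoothing lag). D is the zero-plane displacement
#' -- a fixture property (probe tip flush with the platform), not a force
#' feature. The proximal and distal wall peaks are the force maxima of
#' the two halves of the span (A, D); B is the force minimum between the
#' peaks, and C is the last rising crossing, before the distal peak, of a
#' reengagement threshold set at the mid-lumen trough level plus the same
#' margin (the trough, not the free-air baseline, is the local baseline
#' for reengagement: pith resistance keeps mid-lumen force well above
#' zero).
#'
#' @param trace A non-blank puncture \code{force_displacement_trace}.
#' @param zero_plane_mm Displacement of the zero plane; defaults to the
#'   trace's \code{zero_plane_mm} metadata, then to 0 (the Instron
#'   zeroing origin).
#' @param contact_min_N Minimum force margin above baseline (N).
#' @param noise_mult Multiplier on the baseline noise s.d.
#' @param smooth_window Moving-average window, samples (21 at 1000 Hz).
#' @param baseline_n Number of leading samples defining the pre-contact
#'   baseline.
#' @return A \code{puncture_keypoints} list: \code{A}, \code{B},
#'   \code{C}, \code{D} (mm, in the probe-travel coordinate that
#'   increases toward the platform), plus the sample indices
#'   \code{A_idx}, \code{B_idx}, \code{C_idx}, \code{D_idx}.
#' @export
detect_keypoints <- function(trace, zero_plane_mm = NULL, contact_min_N = 0.5,
                             noise_mult = 5, smooth_window = 21L,
                             baseline_n = 200L) {
  d <- trace$samples$displacement_mm
  f <- trace$samples$force_N
  n <- length(f)
  if (is.null(zero_plane_mm)) {
    zero_plane_mm <- trace$metadata$zero_plane_mm %||% 0
  }
  D_idx <- max(which(d <= zero_plane_mm))
  if (!is.finite(D_idx) || D_idx < 3L) {
    stop("keypoint not found: trace does not reach the zero plane",
         call. = FALSE)
  }
  baseline_n <- min(baseline_n, floor(n / 4))
  baseline <- stats::median(f[seq_len(baseline_n)])
  noise_sd <- stats::sd(f[seq_len(baseline_n)])
  threshold <- baseline + max(contact_min_N, noise_mult * noise_sd)
  sm <- centered_moving_average(f, smooth_window)

  cross <- which(sm[seq_len(D_idx)] > threshold)[1L]
  if (is.na(cross)) {
    stop("keypoint not found: no contact (force never exceeds the contact threshold)",
         call. = FALSE)
  }
  scan_from <- max(1L, cross - smooth_window)
  A_idx <- scan_from + which(f[scan_from:D_idx] > threshold)[1L] - 1L
  if (is.na(A_idx)) A_idx <- cross

  # Wall peaks: maxima of the two halves of the (A, D) span. Thin-walled
  # stalks always place the proximal wall in the first half and the
  # distal wall in the second.
  half_idx <- max(which(d <= d[A_idx] + 0.5 * (d[D_idx] - d[A_idx])))
  half_idx <- min(max(half_idx, A_idx + 1L), D_idx - 1L)
  p1 <- A_idx - 1L + which.max(sm[A_idx:half_idx])
  p2 <- half_idx + which.max(sm[(half_idx + 1L):D_idx])
  if (sm[p2] <= threshold) {
    stop("keypoint not found: no reengagement (no distal force rise before the zero plane)",
         call. = FALSE)
  }
  trough_idx <- p1 - 1L + which.min(sm[p1:p2])
  thr_re <- sm[trough_idx] + max(contact_min_N, noise_mult * noise_sd)
  if (thr_re >= sm[p2]) {
    stop("keypoint not found: distal force rise not separable from the mid-lumen trough",
         call. = FALSE)
  }
  seg <- (trough_idx + 1L):p2
  rising <- seg[sm[seg] > thr_re & sm[seg - 1L] <= thr_re]
  if (!length(rising)) {
    stop("keypoint not found: no reengagement crossing after the mid-lumen trough",
         call. = FALSE)
  }
  c_cross <- rising[[length(rising)]]
  scan_from <- max(trough_idx, c_cross - smooth_window)
  C_idx <- scan_from + which(f[scan_from:p2] > thr_re)[1L] - 1L
  if (is.na(C_idx)) C_idx <- c_cross
  B_idx <- trough_idx

  A <- refine_onset(d, f, A_idx, baseline, p1, window = smooth_window %/% 2L)
  C <- refine_onset(d, f, C_idx, sm[trough_idx], p2,
                    window = smooth_window %/% 2L)
  # D is the known zero-plane coordinate (a fixture property), not a
  # sampled force feature; D_idx is the last sample at or before it.
  kp <- list(A = A, B = d[B_idx], C = C, D = zero_plane_mm,
             A_idx = A_idx, B_idx = B_idx, C_idx = C_idx, D_idx = D_idx)
  if (!(kp$A < kp$B && kp$B < kp$C && kp$C <= kp$D)) {
    stop(sprintf(
      "degenerate geometry: keypoints not ordered (A=%.3f, B=%.3f, C=%.3f, D=%.3f mm)",
      kp$A, kp$B, kp$C, kp$D), call. = FALSE)
  }
  structure(kp, class = "puncture_keypoints")
}

#' @export
print.puncture_keypoints <- function(x, ...) {
  cat(sprintf("puncture keypoints (mm): A=%.3f B=%.3f C=%.3f D=%.3f\n",
              x$A, x$B, x$C, x$D))
  invisible(x)
}

#' Integrated puncture score
#'
#' Force integrated over displacement from contact (A) to the exit plane
#' (D) by the trapezoid rule. An optional weighting hook supports
#' force-displacement weighted variants: \code{weight} is called with the
#' relative depth \code{(d - A)/(D - A)} in [0, 1] and its value
#' multiplies the force pointwise before integration.
#'
#' @param trace A \code{force_displacement_trace}.
#' @param keypoints A [detect_keypoints()] result.
#' @param weight Optional weighting function of relative depth; the
#'   default (NULL) integrates unweighted force.
#' @return Score in N mm.
#' @export
integrated_puncture_score <- function(trace, keypoints, weight = NULL) {
  idx <- keypoints$A_idx:keypoints$D_idx
  d <- trace$samples$displacement_mm[idx]
  f <- trace$samples$force_N[idx]
  if (!is.null(weight)) {
    f <- f * weight((d - keypoints$A) / (keypoints$D - keypoints$A))
  }
  pracma::trapz(d, f)
}

#' All puncture phenotypes for one internode trace
#'
#' Blanks are flagged and get NA phenotypes (they are retained for
#' internode bookkeeping, never silently dropped). Otherwise keypoints
#' are detected and the phenotypes follow by identity: minor diameter =
#' D - A, rind thickness = D - C, rind penetration resistance = peak
#' force, integrated puncture score = force integral A..D.
#'
#' @param trace A puncture \code{force_displacement_trace}.
#' @param blank_threshold_N Passed to [detect_blank_test()].
#' @param weight Optional IPS weighting hook.
#' @param ... Passed to [detect_keypoints()].
#' @return A \code{puncture_result} list: \code{minor_diameter_mm},
#'   \code{rind_thickness_mm}, \code{rind_penetration_resistance_N},
#'   \code{integrated_puncture_score_Nmm}, \code{keypoints},
#'   \code{is_blank}.
#' @export
puncture_phenotypes <- function(trace, blank_threshold_N = 1, weight = NULL,
                                ...) {
  if (detect_blank_test(trace, blank_threshold_N)) {
    return(structure(list(
      minor_diameter_mm = NA_real_, rind_thickness_mm = NA_real_,
      rind_penetration_resistance_N = NA_real_,
      integrated_puncture_score_Nmm = NA_real_,
      keypoints = NULL, is_blank = TRUE), class = "puncture_result"))
  }
  kp <- detect_keypoints(trace, ...)
  structure(list(
    minor_diameter_mm = kp$D - kp$A,
    rind_thickness_mm = kp$D - kp$C,
    rind_penetration_resistance_N = max(trace$samples$force_N),
    integrated_puncture_score_Nmm = integrated_puncture_score(trace, kp, weight),
    keypoints = kp,
    is_blank = FALSE), class = "puncture_result")
}

#' @export
print.puncture_result <- function(x, ...) {
  if (x$is_blank) {
    cat("blank puncture test\n")
  } else {
    cat(sprintf(
      "diameter %.2f mm | rind %.3f mm | RPR %.1f N | IPS %.1f N mm\n",
      x$minor_diameter_mm, x$rind_thickness_mm,
      x$rind_penetration_resistance_N, x$integrated_puncture_score_Nmm))
  }
  invisible(x)
}

#' Batch-process puncture files into a tidy phenotype table
#'
#' Files are processed in the given order; internode indices follow the
#' testing protocol (ear internode first, then successively basal ones),
#' counting blanks, unless a file's metadata carries an explicit
#' \code{internode_index}.
#'
#' @param paths Puncture CSV paths in testing order.
#' @param ... Passed to [puncture_phenotypes()].
#' @return data.frame: one row per file with stalk_id, internode_index,
#'   phenotypes and the blank flag.
#' @export
process_puncture_files <- function(paths, ...) {
  counters <- new.env(parent = emptyenv())
  rows <- lapply(paths, function(p) {
    trace <- read_instron_csv(p)
    id <- trace$metadata$stalk_id %||% NA_character_
    idx <- trace$metadata$internode_index
    if (is.null(idx)) {
      key <- if (is.na(id)) "<none>" else id
      idx <- (if (is.null(counters[[key]])) 0L else counters[[key]]) + 1L
      counters[[key]] <- idx
    }
    res <- puncture_phenotypes(trace, ...)
    data.frame(stalk_id = id, internode_index = idx,
               minor_diameter_mm = res$minor_diameter_mm,
               rind_thickness_mm = res$rind_thickness_mm,
               rind_penetration_resistance_N = res$rind_penetration_resistance_N,
               integrated_puncture_score_Nmm = res$integrated_puncture_score_Nmm,
               is_blank = res$is_blank,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
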