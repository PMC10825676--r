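# Three-point bending: long-span structural tests on whole stalks and
# micro-bending tests on excised rind strips.
#
# Structural tests load the stalk at its central node and support it at
# the most apical and basal nodes; spans at least 10x the stalk diameter
# give natural failure modes. For a load F applied at distance a from
# the left support (b from the right, span L = a + b) the internal
# moment is M(x) = F*b*x/L left of the load and F*a*(L-x)/L right of it;
# strength is the peak moment at the load point, M = F_max*a*b/L, and
# stiffness comes from the load-point deflection relation
# EI = phi*a^2*b^2/(3L), with phi the force-deflection slope below 6 mm
# of deflection (no permanent damage). Units are N and mm throughout
# this module (instrument-native).

#' Span geometry of a three-point bending test
#'
#' @param a Distance from the left support to the load point (mm).
#' @param b Distance from the right support to the load point (mm);
#'   default \code{L - a}.
#' @param L Span between supports (mm); default \code{a + b}.
#' @return A \code{span_geometry} list (\code{a}, \code{b}, \code{L}).
#' @export
span_geometry <- function(a, b = NULL, L = NULL) {
  if (is.null(b) && is.null(L)) stop("supply b or L", call. = FALSE)
  if (is.null(b)) b <- L - a
  if (is.null(L)) L <- a + b
  if (a <= 0 || b <= 0) {
    stop("degenerate geometry: a and b must be positive", call. = FALSE)
  }
  if (abs(a + b - L) > 1e-9 * L) {
    stop(sprintf("inconsistent geometry: a + b = %g but L = %g", a + b, L),
         call. = FALSE)
  }
  if (min(a, b) < 0.05 * L) {
    warning("degenerate geometry: load point within 5% of a support",
            call. = FALSE)
  }
  structure(list(a = a, b = b, L = L), class = "span_geometry")
}

#' Internal bending moment along a three-point-bending specimen
#'
#' Non-symmetric three-point bending: \code{M(x) = F*b*x/L} for
#' \code{0 <= x <= a} and \code{M(x) = F*a*(L-x)/L} for
#' \code{a < x <= L}. Both branches agree at the load point; the moment
#' vanishes at the supports.
#'
#' @param F Applied load (N).
#' @param geom A [span_geometry()].
#' @param x Position(s) along the span, measured from the left support (mm).
#' @return Moment(s) in N mm (vectorised over \code{x}).
#' @export
moment_profile <- function(F, geom, x) {
  if (any(x < 0 | x > geom$L)) {
    stop(sprintf("x outside [0, %g] mm", geom$L), call. = FALSE)
  }
  ifelse(x <= geom$a, F * geom$b * x / geom$L,
         F * geom$a * (geom$L - x) / geom$L)
}

#' Structural bending strength from a long-span bending trace
#'
#' The maximum moment at the load point: \code{M = F_max * a * b / L}.
#' Long-span validity (span at least 10x the specimen diameter) is
#' checked when a diameter is supplied; violations warn but do not stop.
#'
#' @param trace A bending \code{force_displacement_trace}.
#' @param geom A [span_geometry()].
#' @param diameter_mm Optional specimen diameter for the long-span check.
#' @return Bending strength in N mm.
#' @export
structural_bending_strength <- function(trace, geom, diameter_mm = NULL) {
  f_max <- max(trace$samples$force_N)
  if (f_max <= 0) {
    warning("invalid test: no positive force recorded", call. = FALSE)
  }
  if (!is.null(diameter_mm) && geom$L < 10 * diameter_mm) {
    warning(sprintf(
      "short span: L = %g mm < 10 x diameter (%g mm); failure mode may be unnatural",
      geom$L, diameter_mm), call. = FALSE)
  }
  max(f_max, 0) * geom$a * geom$b / geom$L
}

#' Three-point-bending flexural stiffness from a force-deflection slope
#'
#' Load-point deflection of a simply supported beam loaded at distance
#' \code{a} from one support: \code{delta = F a^2 b^2 / (3 L EI)},
#' inverted for stiffness: \code{EI = phi * a^2 * b^2 / (3 L)}. With
#' \code{a = b = L/2} this reduces to the classical \code{phi L^3 / 48}.
#'
#' @param phi Slope of force vs deflection (N/mm).
#' @param geom A [span_geometry()].
#' @return Flexural stiffness EI (N mm^2), vectorised over \code{phi}.
#' @export
bend3pt_stiffness <- function(phi, geom) {
  phi * geom$a^2 * geom$b^2 / (3 * geom$L)
}

#' Structural flexural stiffness from a long-span bending trace
#'
#' Fits the slope \code{phi} of force versus crosshead displacement over
#' the loading limb restricted to deflections at or below
#' \code{max_deflection_mm} (6 mm by default: small enough to leave no
#' permanent damage), then \code{EI = phi * a^2 * b^2 / (3 L)}.
#'
#' @param trace A bending \code{force_displacement_trace}.
#' @param geom A [span_geometry()].
#' @param max_deflection_mm Upper bound of the fit window (mm).
#' @param min_points Minimum samples required in the window.
#' @return List: \code{EI} (N mm^2), \code{slope_phi} (N/mm),
#'   \code{r_squared}, \code{n} (samples in window).
#' @export
structural_flexural_stiffness <- function(trace, geom, max_deflection_mm = 6,
                                          min_points = 5L) {
  f <- trace$samples$force_N
  d <- trace$samples$displacement_mm
  limb <- seq_len(which.max(f))
  win <- limb[d[limb] <= max_deflection_mm & d[limb] >= 0]
  if (length(win) < min_points || diff(range(d[win])) <= 0) {
    stop(sprintf(
      "degenerate fit: %d samples with deflection in [0, %g] mm on the loading limb",
      length(win), max_deflection_mm), call. = FALSE)
  }
  fit <- stats::lm(f[win] ~ d[win])
  phi <- unname(stats::coef(fit)[[2L]])
  list(EI = bend3pt_stiffness(phi, geom), slope_phi = phi,
       r_squared = fit_r_squared(fit), n = length(win))
}

# Roll/twist heuristic: a force drop of more than 20% of the running
# maximum before 80% of peak force is reached suggests the specimen
# rolled on the supports. Tests are flagged, never auto-deleted: the
# discard decision stays with the operator.
detect_roll_flag <- function(trace, drop_frac = 0.2, peak_frac = 0.8) {
  f <- trace$samples$force_N
  ipk <- which.max(f)
  if (ipk <= 2L) return(FALSE)
  pre <- f[seq_len(ipk)]
  run_max <- cummax(pre)
  any(run_max - pre > drop_frac * run_max & run_max < peak_frac * max(f))
}

#' Full analysis of one long-span structural bending test
#'
#' @inheritParams structural_flexural_stiffness
#' @param diameter_mm Optional specimen diameter for the long-span check.
#' @return A \code{bending_result} list: \code{bending_strength_Nmm},
#'   \code{flexural_stiffness_Nmm2}, \code{slope_phi}, \code{r_squared},
#'   \code{discard_recommended}, \code{long_span_ok} (NA when no diameter
#'   supplied), plus identity metadata.
#' @export
analyze_bending3pt <- function(trace, geom, diameter_mm = NULL,
                               max_deflection_mm = 6) {
  stiff <- structural_flexural_stiffness(trace, geom, max_deflection_mm)
  structure(list(
    stalk_id = trace$metadata$stalk_id,
    bending_strength_Nmm = structural_bending_strength(trace, geom, diameter_mm),
    flexural_stiffness_Nmm2 = stiff$EI,
    slope_phi = stiff$slope_phi,
    r_squared = stiff$r_squared,
    discard_recommended = detect_roll_flag(trace),
    long_span_ok = if (is.null(diameter_mm)) NA else geom$L >= 10 * diameter_mm
  ), class = "bending_result")
}

#' @export
print.bending_result <- function(x, ...) {
  cat(sprintf("%s: M = %.1f N mm, EI = %.3g N mm^2 (R^2 = %.4f)%s\n",
              x$stalk_id %||% "<no id>", x$bending_strength_Nmm,
              x$flexural_stiffness_Nmm2, x$r_squared,
              if (isTRUE(x$discard_recommended)) " [discard recommended]" else ""))
  invisible(x)
}

#' Rind strip geometry for micro-bending tests
#'
#' Defaults are the nominal strip dimensions (18 x 2.8 x 0.7 mm,
#' length x width x thickness) tested over a 10 mm span.
#'
#' @param length_mm,width_mm,thickness_mm Strip dimensions (mm).
#' @param span_mm Support span (mm).
#' @return A \code{rind_strip_geometry} list.
#' @export
rind_strip_geometry <- function(length_mm = 18, width_mm = 2.8,
                                thickness_mm = 0.7, span_mm = 10) {
  stopifnot(length_mm > 0, width_mm > 0, thickness_mm > 0, span_mm > 0)
  structure(list(length_mm = length_mm, width_mm = width_mm,
                 thickness_mm = thickness_mm, span_mm = span_mm),
            class = "rind_strip_geometry")
}

#' Flexural stress at the midspan surface of a strip in 3-point bending
#'
#' \code{sigma = 3 F L / (2 w t^2)}; with F in N and lengths in mm the
#' result is in MPa.
#'
#' @param F Force(s), N.
#' @param strip A [rind_strip_geometry()].
#' @return Stress(es), MPa.
#' @export
flexural_stress <- function(F, strip) {
  3 * F * strip$span_mm / (2 * strip$width_mm * strip$thickness_mm^2)
}

#' Flexural strain at the midspan surface of a strip in 3-point bending
#'
#' The classical midspan relation \code{epsilon = 6 delta t / L^2}
#' (dimensionless). Note for readers comparing with the source
#' literature: the strain expression is sometimes misprinted with the
#' strip width in place of the span; only the span-based form is
#' dimensionally consistent and satisfies \code{E = sigma/epsilon}
#' against beam theory, so it is the one implemented.
#'
#' @param delta Midspan deflection(s), mm.
#' @param strip A [rind_strip_geometry()].
#' @return Strain(s), dimensionless.
#' @export
flexural_strain <- function(delta, strip) {
  6 * delta * strip$thickness_mm / strip$span_mm^2
}

#' Tissue-level stress-strain analysis of a micro-bending trace
#'
#' Converts the force-displacement record to a flexural stress-strain
#' curve, then takes Young's modulus as the slope of stress versus
#' strain over the 20-80\% force band of the final (failure) loading
#' limb; stress and strain at failure are read at peak force. The three
#' preload cycles preceding failure are identified from direction
#' reversals of the crosshead displacement; when none are found the
#' analysis proceeds on the full trace with a warning.
#'
#' @param trace A micro-bending \code{force_displacement_trace}.
#' @param strip A [rind_strip_geometry()]; defaults to the trace's
#'   metadata geometry when present, else the nominal strip.
#' @param quantile_band Force fraction band (of limb peak force) for the
#'   modulus fit.
#' @param min_points Minimum samples in the fit window.
#' @return A \code{tissue_result} list: \code{youngs_modulus_MPa},
#'   \code{flexural_stress_at_failure_MPa}, \code{strain_at_failure},
#'   \code{r_squared}, \code{n_preload_cycles}, and
#'   \code{stress_strain_curve} (data.frame \code{strain},
#'   \code{stress_MPa} over the whole trace).
#' @export
tissue_flexural_curve <- function(trace, strip = NULL,
                                  quantile_band = c(0.2, 0.8),
                                  min_points = 5L) {
  if (is.null(strip)) {
    m <- trace$metadata
    strip <- if (!is.null(m$span_mm) && !is.null(m$width_mm) &&
                 !is.null(m$thickness_mm)) {
      rind_strip_geometry(width_mm = m$width_mm, thickness_mm = m$thickness_mm,
                          span_mm = m$span_mm)
    } else {
      rind_strip_geometry()
    }
  }
  d <- trace$samples$displacement_mm
  f <- trace$samples$force_N
  sigma <- flexural_stress(f, strip)
  eps <- flexural_strain(d, strip)
  ipk <- which.max(f)

  # Direction reversals of the crosshead locate the preload cycles; the
  # failure limb starts at the last displacement minimum before peak force.
  dd <- diff(d[seq_len(ipk)])
  reversals_down <- which(dd < 0)
  if (length(reversals_down)) {
    start <- max(reversals_down) + 1L
    n_cycles <- sum(rle(sign(dd))$values < 0)
  } else {
    warning("preload cycles not detected; analysing the full trace",
            call. = FALSE)
    start <- 1L
    n_cycles <- 0L
  }
  limb <- start:ipk
  # select the fit window on a smoothed copy of the force so the band
  # edges do not truncate the noise and attenuate the fitted modulus
  f_sel <- centered_moving_average(f[limb], 11L)
  band <- range(quantile_band) * max(f_sel)
  win <- limb[f_sel >= band[[1L]] & f_sel <= band[[2L]]]
  if (length(win) < min_points || diff(range(eps[win])) <= 0) {
    stop(sprintf("degenerate fit: %d samples in the modulus window",
                 length(win)), call. = FALSE)
  }
  fit <- stats::lm(sigma[win] ~ eps[win])
  structure(list(
    stalk_id = trace$metadata$stalk_id,
    youngs_modulus_MPa = unname(stats::coef(fit)[[2L]]),
    flexural_stress_at_failure_MPa = sigma[[ipk]],
    strain_at_failure = eps[[ipk]],
    r_squared = fit_r_squared(fit),
    n_preload_cycles = n_cycles,
    stress_strain_curve = data.frame(strain = eps, stress_MPa = sigma)
  ), class = "tissue_result")
}

#' @export
print.tissue_result <- function(x, ...) {
  cat(sprintf(
    "%s: E = %.0f MPa, sigma_f = %.1f MPa, eps_f = %.4f (R^2 = %.4f)\n",
    x$stalk_id %||% "<no id>", x$youngs_modulus_MPa,
    x$flexural_stress_at_failure_MPa, x$strain_at_failure, x$r_squared))
  invisible(x)
}
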