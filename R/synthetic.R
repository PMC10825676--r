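# Seeded forward simulators for every instrument trace and annotation
# format the analysis modules consume. Each simulator starts from an
# explicit ground-truth phenotype set and inverts the same mechanical
# relations the analyses use, so end-to-end recovery can be tested
# without any instrument: analysis(simulate(truth)) must return truth
# within the stated tolerances. Noise is additive Gaussian on force
# (fractional s.d. of peak force); all draws come from one seeded
# stream per file, and the seed is recorded in the file header.

with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Ground-truth phenotypes of one simulated stalk
#'
#' The parameters mirror the phenotypes each analysis must recover,
#' with defaults in the range typical of mature maize: flexural
#' stiffness of order tens of N m^2, bending strength of order tens of
#' N m, a 15-25 mm minor diameter with a 1-3 mm rind, peak puncture
#' forces of tens of newtons and rind tissue moduli of a few GPa.
#'
#' @param stalk_id Identifier string.
#' @param EI_true_Nm2 Flexural stiffness (N m^2).
#' @param strength_true_Nm Bending strength (N m).
#' @param failure_mode One of \code{"stalk_lodged"}, \code{"root_lodged"},
#'   \code{"bent_no_break"}.
#' @param diameter_true_mm Minor diameter (mm).
#' @param rind_thickness_true_mm Rind thickness (mm); twice the thickness
#'   must be below the diameter.
#' @param peak_puncture_force_N Peak puncture force / RPR (N).
#' @param E_tissue_true_MPa Rind tissue Young's modulus (MPa).
#' @param node_positions_cm Node positions along the stalk from the base (cm).
#' @param noise_frac Force noise s.d. as a fraction of peak force.
#' @return A \code{stalk_ground_truth} list.
#' @export
stalk_ground_truth <- function(stalk_id = "ID2021_101-1",
                               EI_true_Nm2 = 25,
                               strength_true_Nm = 15,
                               failure_mode = "stalk_lodged",
                               diameter_true_mm = 20,
                               rind_thickness_true_mm = 2,
                               peak_puncture_force_N = 60,
                               E_tissue_true_MPa = 5000,
                               node_positions_cm = cumsum(c(8, 12, 14, 15, 16, 16, 15, 14)),
                               noise_frac = 0.02) {
  stopifnot(EI_true_Nm2 > 0, strength_true_Nm > 0, diameter_true_mm > 0,
            rind_thickness_true_mm > 0, peak_puncture_force_N > 0,
            E_tissue_true_MPa > 0, noise_frac >= 0)
  if (2 * rind_thickness_true_mm >= diameter_true_mm) {
    stop("rind walls thicker than the diameter allows", call. = FALSE)
  }
  failure_mode <- match.arg(failure_mode,
                            c("stalk_lodged", "root_lodged", "bent_no_break"))
  structure(list(stalk_id = stalk_id, EI_true_Nm2 = EI_true_Nm2,
                 strength_true_Nm = strength_true_Nm,
                 failure_mode = failure_mode,
                 diameter_true_mm = diameter_true_mm,
                 rind_thickness_true_mm = rind_thickness_true_mm,
                 peak_puncture_force_N = peak_puncture_force_N,
                 E_tissue_true_MPa = E_tissue_true_MPa,
                 node_positions_cm = node_positions_cm,
                 noise_frac = noise_frac),
            class = "stalk_ground_truth")
}

#' Draw randomized ground truths over realistic phenotype ranges
#'
#' @param n Number of stalks.
#' @param seed RNG seed.
#' @param noise_frac Force noise fraction shared by all stalks.
#' @param failure_mode Failure mode for all stalks (default cycles
#'   through the taxonomy).
#' @return List of [stalk_ground_truth()] objects with ids
#'   \code{ID2021_<plot>-<stalk>}.
#' @export
random_ground_truths <- function(n, seed = 1, noise_frac = 0.02,
                                 failure_mode = NULL) {
  modes <- c("stalk_lodged", "root_lodged", "bent_no_break")
  with_seed(seed, lapply(seq_len(n), function(i) {
    thick <- stats::runif(1, 1, 3)
    stalk_ground_truth(
      stalk_id = sprintf("ID2021_%d-%d", 100 + (i - 1) %/% 4, (i - 1) %% 4 + 1),
      EI_true_Nm2 = stats::runif(1, 10, 40),
      strength_true_Nm = stats::runif(1, 8, 25),
      failure_mode = failure_mode %||% modes[(i - 1) %% 3 + 1],
      diameter_true_mm = stats::runif(1, max(15, 2 * thick + 10), 25),
      rind_thickness_true_mm = thick,
      peak_puncture_force_N = stats::runif(1, 30, 90),
      E_tissue_true_MPa = stats::runif(1, 3000, 15000),
      node_positions_cm = cumsum(stats::runif(8, 8, 18)),
      noise_frac = noise_frac)
  }))
}

#' Simulate one field lodging-device test
#'
#' Three preload cycles to peaks drawn in 5-10 degrees, then a failure
#' push. On every loading limb force follows the cantilever line
#' \code{F = 3 EI sin(theta) / h^2}; the failure push runs up the
#' elastic line until the moment \code{F h} reaches the programmed
#' strength, after which the force follows the failure mode: a sharp
#' drop to near zero (stalk lodged), a plateau then gradual decline
#' (root lodged), or truncation at peak without a drop (bent, no break).
#' Gaussian noise (s.d. = \code{noise_frac} x peak force) is added to
#' force only; the rotation channel is clean.
#'
#' @param gt A [stalk_ground_truth()].
#' @param h Load-cell height (m).
#' @param seed RNG seed (recorded in the header).
#' @param sample_rate_hz Sampling rate.
#' @param n_preload Number of preload cycles (3 in the standard
#'   protocol; reduce to simulate protocol violations).
#' @return A \code{force_rotation_trace} with attribute \code{"truth"}:
#'   list with \code{EI_Nm2}, \code{strength_Nm}, \code{failure_force_N},
#'   \code{push_bounds} (data.frame of true start/end sample of each
#'   push) and \code{theta_deg} (the clean deflection-angle signal).
#' @export
simulate_darling_test <- function(gt, h = 0.75, seed = 1,
                                  sample_rate_hz = 100, n_preload = 3L) {
  with_seed(seed, {
    dt <- 1 / sample_rate_hz
    ref <- 180
    elastic_force <- function(theta_deg) {
      3 * gt$EI_true_Nm2 * sin(theta_deg * pi / 180) / h^2
    }
    f_fail <- gt$strength_true_Nm / h
    sin_fail <- f_fail * h^2 / (3 * gt$EI_true_Nm2)
    if (sin_fail >= sin(60 * pi / 180)) {
      stop("strength/stiffness combination requires deflection beyond 60 degrees",
           call. = FALSE)
    }
    theta_fail <- asin(sin_fail) * 180 / pi

    gap <- function(n = round(0.5 / dt)) list(theta = rep(0, n),
                                              force = rep(0, n))
    pieces <- list(gap())
    bounds <- list()
    peaks <- stats::runif(n_preload, 5, 10)
    for (p in peaks) {
      n_up <- round(1.5 / dt)
      th <- c(seq(0, p, length.out = n_up), seq(p, 0, length.out = n_up)[-1L])
      pieces[[length(pieces) + 1L]] <- list(theta = th,
                                            force = elastic_force(th))
      pieces[[length(pieces) + 1L]] <- gap()
    }
    n_up <- round(2.5 / dt)
    th_load <- seq(0, theta_fail, length.out = n_up)
    f_load <- elastic_force(th_load)
    f_load[[n_up]] <- f_fail   # peak exactly representable
    n_post <- round(1 / dt)
    th_post <- seq(theta_fail, theta_fail + 10, length.out = n_post)
    f_post <- switch(gt$failure_mode,
      stalk_lodged = {
        n_drop <- round(0.2 / dt)
        c(seq(f_fail, 0.02 * f_fail, length.out = n_drop),
          rep(0.02 * f_fail, n_post - n_drop))
      },
      root_lodged = {
        n_plat <- round(0.3 / dt)
        c(rep(0.95 * f_fail, n_plat),
          seq(0.95 * f_fail, 0.4 * f_fail, length.out = n_post - n_plat))
      },
      bent_no_break = NULL)
    if (is.null(f_post)) {
      pieces[[length(pieces) + 1L]] <- list(theta = th_load, force = f_load)
    } else {
      pieces[[length(pieces) + 1L]] <- list(theta = c(th_load, th_post),
                                            force = c(f_load, f_post))
    }

    theta <- unlist(lapply(pieces, `[[`, "theta"))
    force <- unlist(lapply(pieces, `[[`, "force"))
    n <- length(theta)
    noise_sd <- gt$noise_frac * f_fail
    force_noisy <- force + stats::rnorm(n, 0, noise_sd)

    # true push bounds: contiguous runs with theta > 0
    active <- theta > 0
    r <- rle(active)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    push_bounds <- data.frame(start = starts[r$values], end = ends[r$values])

    samples <- data.frame(time_s = (seq_len(n) - 1L) * dt,
                          force_N = force_noisy,
                          rotation_deg = ref - theta)
    header <- list(stalk_id = gt$stalk_id, load_height_m = h,
                   failure_note = gt$failure_mode,
                   timestamp = sprintf("2021-08-20T%02d:%02d:00",
                                       8 + seed %% 10, seed %% 60),
                   rotation_vertical_ref_deg = ref,
                   calibration = data.frame(
                     sensor = "force",
                     raw = c(0, 112, 223, 334, 445),
                     reference = c(0, 27.8, 55.6, 83.4, 111.2)),
                   extra = list(seed = as.character(seed)))
    trace <- force_rotation_trace(samples, header)
    attr(trace, "truth") <- list(EI_Nm2 = gt$EI_true_Nm2,
                                 strength_Nm = gt$strength_true_Nm,
                                 failure_force_N = f_fail,
                                 push_bounds = push_bounds,
                                 theta_deg = theta)
    trace
  })
}

# Piecewise-linear force profile of a puncture: steep rise on contact
# with each rind wall, post-penetration drop, soft pith plateau between
# the walls, sharp exit drop at the zero plane. x is displacement in the
# probe coordinate (zero plane at 0, start at -35 mm).
puncture_signal <- function(x, diameter, thickness, peak,
                            pith_frac = 0.05, distal_frac = 0.85,
                            rise = 0.5, fall = 0.3, peak_dwell = 0.08) {
  A <- -diameter
  C <- -thickness
  pith <- pith_frac * peak
  rise2 <- min(rise, 0.6 * thickness)
  prox_end <- A + thickness
  # brief dwell at peak force so the sampled maximum equals the peak
  xs <- c(A, A + rise, A + rise + peak_dwell,
          min(A + rise + peak_dwell + fall, prox_end), prox_end,
          C, C + rise2, -0.05, 0)
  ys <- c(0, peak, peak, pith, pith,
          pith, distal_frac * peak, distal_frac * peak, 0)
  keep <- !duplicated(xs)
  stats::approx(xs[keep], ys[keep], xout = x, method = "linear",
                yleft = 0, yright = 0)$y
}

#' Simulate one rind puncture test
#'
#' The probe starts 35 mm above the zero plane (the platform face) and
#' travels at 25.4 mm/s to 5 mm below it, sampled at 1000 Hz. The force
#' profile has a steep rise at contact with the proximal rind wall up to
#' the programmed peak force, a drop to a soft pith plateau after
#' penetration, a second rise at the distal wall, and a sharp exit drop
#' at the zero plane; wall positions are placed so that D - A equals the
#' true diameter and D - C the true rind thickness (D = 0). Blanks carry
#' only baseline noise.
#'
#' @param gt A [stalk_ground_truth()].
#' @param seed RNG seed.
#' @param internode_index Recorded internode number.
#' @param blank Simulate a blank (empty platform) run.
#' @param sample_rate_hz Sampling rate.
#' @param speed_mm_s Probe speed.
#' @return A \code{force_displacement_trace} (metadata
#'   \code{zero_plane_mm = 0}) with attribute \code{"truth"}: list with
#'   \code{A}, \code{C}, \code{D} (mm), \code{diameter_mm},
#'   \code{rind_thickness_mm}, \code{rpr_N}, \code{ips_Nmm} (noise-free
#'   integral), \code{is_blank}.
#' @export
simulate_puncture_test <- function(gt, seed = 1, internode_index = 1L,
                                   blank = FALSE, sample_rate_hz = 1000,
                                   speed_mm_s = 25.4) {
  with_seed(seed, {
    step <- speed_mm_s / sample_rate_hz
    x <- seq(-35, 5, by = step)
    n <- length(x)
    signal <- if (blank) rep(0, n) else {
      puncture_signal(x, gt$diameter_true_mm, gt$rind_thickness_true_mm,
                      gt$peak_puncture_force_N)
    }
    noise_sd <- if (blank) 0.02 else gt$noise_frac * gt$peak_puncture_force_N
    force <- signal + stats::rnorm(n, 0, noise_sd)
    samples <- data.frame(time_s = (seq_len(n) - 1L) / sample_rate_hz,
                          displacement_mm = x, force_N = force)
    meta <- list(stalk_id = gt$stalk_id, internode_index = internode_index,
                 test_kind = "puncture", sampling_rate_hz = sample_rate_hz,
                 zero_plane_mm = 0,
                 extra = list(seed = as.character(seed)))
    trace <- force_displacement_trace(samples, meta)
    in_span <- x >= -gt$diameter_true_mm & x <= 0
    attr(trace, "truth") <- list(
      A = -gt$diameter_true_mm, C = -gt$rind_thickness_true_mm, D = 0,
      diameter_mm = gt$diameter_true_mm,
      rind_thickness_mm = gt$rind_thickness_true_mm,
      rpr_N = if (blank) 0 else max(signal),
      ips_Nmm = if (blank) 0 else pracma::trapz(x[in_span], signal[in_span]),
      is_blank = blank)
    trace
  })
}

#' Simulate one long-span structural bending test
#'
#' Force-deflection follows the three-point-bending line of slope
#' \code{3 L EI / (a^2 b^2)} up to failure at \code{F = M L / (a b)},
#' then drops to 20\% of peak. Crosshead speed 10 cm/min, one sample
#' every 100 ms, noise on force only.
#'
#' @param gt A [stalk_ground_truth()].
#' @param geom A [span_geometry()] (mm).
#' @param seed RNG seed.
#' @param internode_index Recorded internode number (NULL: whole stalk).
#' @return A \code{force_displacement_trace} (geometry in metadata) with
#'   attribute \code{"truth"}: \code{EI_Nmm2}, \code{strength_Nmm},
#'   \code{failure_force_N}, \code{slope_N_mm}.
#' @export
simulate_bending_test <- function(gt, geom = span_geometry(a = 250, b = 250),
                                  seed = 1, internode_index = NULL) {
  with_seed(seed, {
    EI <- gt$EI_true_Nm2 * 1e6          # N m^2 -> N mm^2
    strength <- gt$strength_true_Nm * 1e3  # N m -> N mm
    k <- 3 * geom$L * EI / (geom$a^2 * geom$b^2)
    f_fail <- strength * geom$L / (geom$a * geom$b)
    step <- 100 / 60 * 0.1              # 10 cm/min, 100 ms -> mm/sample
    d_fail <- f_fail / k
    d_load <- seq(0, d_fail, by = step)
    if (d_load[[length(d_load)]] < d_fail) d_load <- c(d_load, d_fail)
    f_load <- k * d_load
    n_post <- 20L
    d_post <- d_fail + step * seq_len(n_post)
    f_post <- seq(f_fail, 0.2 * f_fail, length.out = n_post)
    d <- c(d_load, d_post)
    f <- c(f_load, f_post)
    f <- f + stats::rnorm(length(f), 0, gt$noise_frac * f_fail)
    samples <- data.frame(time_s = (seq_along(d) - 1L) * 0.1,
                          displacement_mm = d, force_N = f)
    meta <- list(stalk_id = gt$stalk_id, internode_index = internode_index,
                 test_kind = "bending3pt", sampling_rate_hz = 10,
                 span_mm = geom$L, a_mm = geom$a, b_mm = geom$b,
                 extra = list(seed = as.character(seed)))
    trace <- force_displacement_trace(samples, meta)
    attr(trace, "truth") <- list(EI_Nmm2 = EI, strength_Nmm = strength,
                                 failure_force_N = f_fail, slope_N_mm = k)
    trace
  })
}

#' Simulate one micro-bending test on a rind strip
#'
#' A linear-elastic strip of modulus \code{E_tissue_true_MPa}: force
#' follows \code{F = 48 E I delta / L^3} (I = w t^3 / 12). Three preload
#' cycles sweep the midspan strain between 0.3\% and 1.4\%, then the
#' final push runs to the failure strain and the force drops sharply.
#'
#' @param gt A [stalk_ground_truth()].
#' @param strip A [rind_strip_geometry()].
#' @param seed RNG seed.
#' @param internode_index Recorded internode number.
#' @param failure_strain Midspan strain at failure.
#' @param sample_rate_hz Sampling rate.
#' @param speed_mm_s Crosshead speed.
#' @return A \code{force_displacement_trace} (strip geometry in
#'   metadata) with attribute \code{"truth"}: \code{E_MPa},
#'   \code{sigma_f_MPa}, \code{eps_f}, \code{failure_force_N}.
#' @export
simulate_micro_bending_test <- function(gt, strip = rind_strip_geometry(),
                                        seed = 1, internode_index = 1L,
                                        failure_strain = 0.025,
                                        sample_rate_hz = 10,
                                        speed_mm_s = 1 / 60) {
  with_seed(seed, {
    E <- gt$E_tissue_true_MPa
    I <- strip$width_mm * strip$thickness_mm^3 / 12
    L <- strip$span_mm
    k <- 48 * E * I / L^3
    strain_to_delta <- L^2 / (6 * strip$thickness_mm)
    d_lo <- 0.003 * strain_to_delta
    d_hi <- 0.014 * strain_to_delta
    d_f <- failure_strain * strain_to_delta
    step <- speed_mm_s / sample_rate_hz
    ramp <- function(from, to) {
      n <- max(2L, ceiling(abs(to - from) / step))
      seq(from, to, length.out = n)
    }
    d <- c(ramp(0, d_hi))
    for (i in 1:2) d <- c(d, ramp(d_hi, d_lo)[-1L], ramp(d_lo, d_hi)[-1L])
    d <- c(d, ramp(d_hi, d_lo)[-1L], ramp(d_lo, d_f)[-1L])
    f <- k * d
    f_fail <- k * d_f
    f[[length(f)]] <- f_fail
    n_post <- 10L
    d <- c(d, d_f + step * seq_len(n_post))
    f <- c(f, seq(0.3 * f_fail, 0.05 * f_fail, length.out = n_post))
    f <- f + stats::rnorm(length(f), 0, gt$noise_frac * f_fail)
    samples <- data.frame(time_s = (seq_along(d) - 1L) / sample_rate_hz,
                          displacement_mm = d, force_N = f)
    meta <- list(stalk_id = gt$stalk_id, internode_index = internode_index,
                 test_kind = "micro_bending", sampling_rate_hz = sample_rate_hz,
                 span_mm = L, width_mm = strip$width_mm,
                 thickness_mm = strip$thickness_mm,
                 extra = list(seed = as.character(seed)))
    trace <- force_displacement_trace(samples, meta)
    attr(trace, "truth") <- list(
      E_MPa = E,
      sigma_f_MPa = 3 * f_fail * L / (2 * strip$width_mm * strip$thickness_mm^2),
      eps_f = failure_strain, failure_force_N = f_fail)
    trace
  })
}

#' Simulate a node annotation set for one imaged stalk
#'
#' Nodes are placed down the image (stalk base at the top) at the
#' ground-truth positions times the pixel scale, with uniform +/- jitter
#' on the box centres emulating detector localisation error.
#'
#' @param gt A [stalk_ground_truth()].
#' @param scale_px_per_cm Pixel scale of the calibrated image.
#' @param image_width_px Image width; height defaults to fit the stalk.
#' @param image_height_px Optional image height.
#' @param seed RNG seed.
#' @param jitter_px Uniform jitter half-width on box centres (px).
#' @return A \code{node_annotation_set} with attribute \code{"truth"}:
#'   \code{internode_lengths_cm} (consecutive differences of the node
#'   positions) and \code{jitter_px}.
#' @export
simulate_annotation_set <- function(gt, scale_px_per_cm = 10,
                                    image_width_px = 800,
                                    image_height_px = NULL, seed = 1,
                                    jitter_px = 2) {
  with_seed(seed, {
    pos <- gt$node_positions_cm
    margin <- 40
    if (is.null(image_height_px)) {
      image_height_px <- ceiling(max(pos) * scale_px_per_cm + 2 * margin)
    }
    n <- length(pos)
    y <- margin + pos * scale_px_per_cm + stats::runif(n, -jitter_px, jitter_px)
    x <- image_width_px / 2 + stats::runif(n, -jitter_px, jitter_px)
    w <- gt$diameter_true_mm / 10 * scale_px_per_cm * 1.4
    h <- 2 * scale_px_per_cm
    ann <- data.frame(x_center = x / image_width_px,
                      y_center = y / image_height_px,
                      width = w / image_width_px,
                      height = h / image_height_px,
                      confidence = stats::runif(n, 0.85, 0.99))
    set <- node_annotation_set(ann, image_width_px, image_height_px,
                               scale_px_per_cm, stalk_id = gt$stalk_id)
    attr(set, "truth") <- list(internode_lengths_cm = diff(pos),
                               jitter_px = jitter_px)
    set
  })
}

#' Write a complete synthetic test-file set for a list of stalks
#'
#' For each ground truth, writes one field-device CSV, puncture CSVs for
#' three internodes, one structural bending CSV and one micro-bending
#' CSV into \code{dir}, in the exact dialects the readers consume.
#'
#' @param truths List of [stalk_ground_truth()] objects.
#' @param dir Output directory (created if needed).
#' @param seed Base seed; file seeds are derived deterministically.
#' @param n_internodes Puncture internodes per stalk.
#' @param blank_internodes Internode indices written as blanks.
#' @return Manifest data.frame (\code{path}, \code{kind}), invisibly
#'   usable with [run_batch()].
#' @export
write_synthetic_stalk_files <- function(truths, dir, seed = 1,
                                        n_internodes = 3L,
                                        blank_internodes = integer()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  add <- function(path, kind) {
    rows[[length(rows) + 1L]] <<- data.frame(path = path, kind = kind,
                                             stringsAsFactors = FALSE)
  }
  for (i in seq_along(truths)) {
    gt <- truths[[i]]
    base <- file.path(dir, gsub("[^A-Za-z0-9_-]", "_", gt$stalk_id))
    s <- seed * 1000L + i * 10L
    p <- paste0(base, "_darling.csv")
    write_darling_csv(simulate_darling_test(gt, seed = s), p)
    add(p, "darling")
    for (k in seq_len(n_internodes)) {
      p <- sprintf("%s_puncture_%d.csv", base, k)
      write_instron_csv(simulate_puncture_test(gt, seed = s + k,
                                               internode_index = k,
                                               blank = k %in% blank_internodes),
                        p)
      add(p, "puncture")
    }
    p <- paste0(base, "_bend3pt.csv")
    write_instron_csv(simulate_bending_test(gt, seed = s + 7L), p)
    add(p, "bending3pt")
    p <- paste0(base, "_microbend.csv")
    write_instron_csv(simulate_micro_bending_test(gt, seed = s + 8L,
                                                  internode_index = 1L), p)
    add(p, "micro_bending")
  }
  invisible(do.call(rbind, rows))
}
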