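# Shared fixture builders for the test suite. Everything is generated
# in code; no binary or stored fixtures.

rel_err <- function(x, truth) abs(x / truth - 1)

# A minimal hand-written DARLING file: header, blank line, body.
write_tiny_darling <- function(path, body_rows = 5L, drop_key = NULL) {
  header <- c("stalk_id,ID2021_101-3",
              "load_height_m,0.6",
              "failure_note,stalk_lodged")
  if (!is.null(drop_key)) {
    header <- header[!startsWith(header, paste0(drop_key, ","))]
  }
  t <- seq_len(body_rows)
  body <- sprintf("%g,%g,%g", t / 10, t * 2, 180 - t)
  writeLines(c(header, "", "time_s,force_N,rotation_deg", body), path)
  path
}

# Build a force-rotation trace directly from a deflection-angle signal.
make_fr_trace <- function(theta_deg, force_N, h = 0.6, ref = 180,
                          dt = 0.01, ...) {
  force_rotation_trace(
    data.frame(time_s = (seq_along(theta_deg) - 1) * dt,
               force_N = force_N,
               rotation_deg = ref - theta_deg),
    header = list(stalk_id = "ID2021_101-3", load_height_m = h,
                  failure_note = "stalk_lodged",
                  rotation_vertical_ref_deg = ref, ...))
}

# Step-walled toy puncture trace with force corners exactly on samples.
make_toy_puncture <- function(step = 0.1, a = 10, c = 26, d_zero = 28,
                              peak = 60, distal = 52, pith = 3) {
  x <- seq(0, 30, by = step)
  f <- numeric(length(x))
  f[x >= a & x < a + 2] <- peak
  f[x >= a + 2 & x < c] <- pith
  f[x >= c & x < d_zero] <- distal
  force_displacement_trace(
    data.frame(time_s = (seq_along(x) - 1) * 1e-3, displacement_mm = x,
               force_N = f),
    metadata = list(test_kind = "puncture", zero_plane_mm = d_zero,
                    sampling_rate_hz = 1000))
}

# Annotation set from explicit pixel midpoints.
make_annotation_set <- function(mid_px, img = c(1000, 1000), cal = 10,
                                box_px = 60, id = "ID2021_101-3") {
  node_annotation_set(
    data.frame(x_center = mid_px[, 1] / img[1],
               y_center = mid_px[, 2] / img[2],
               width = box_px / img[1], height = box_px / img[2]),
    image_width_px = img[1], image_height_px = img[2],
    calibration_px_per_cm = cal, stalk_id = id)
}
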