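# Linear density of internode sections and structural-carbohydrate
# composition from standard forage fiber assays.

#' Linear density of an internode section
#'
#' Mass per unit length, \code{m / L}, of a sectioned internode
#' (node tissue removed). Implausibly light sections (below
#' \code{mass_floor_g}) are accepted with a warning: they usually signal
#' a data-entry slip rather than a real specimen.
#'
#' @param mass_g Section mass, grams (> 0).
#' @param length_cm Section length, centimetres (> 0).
#' @param mass_floor_g Plausibility floor for the mass warning.
#' @return Linear density in g/cm (vectorised).
#' @export
linear_density <- function(mass_g, length_cm, mass_floor_g = 0.5) {
  if (any(mass_g <= 0) || any(length_cm <= 0)) {
    stop("mass and length must be positive", call. = FALSE)
  }
  if (any(mass_g < mass_floor_g)) {
    warning(sprintf("%d section mass(es) below the %g g plausibility floor",
                    sum(mass_g < mass_floor_g), mass_floor_g), call. = FALSE)
  }
  mass_g / length_cm
}

#' Derive cellulose and hemicellulose from fiber assay proportions
#'
#' Standard forage assays report acid detergent fiber (ADF), ash-free
#' neutral detergent fiber (aNDF) and lignin proportions. Cellulose is
#' the difference between ADF and lignin; hemicellulose the difference
#' between aNDF and ADF. Valid inputs satisfy
#' \code{0 <= lignin <= ADF <= aNDF <= 1}; ordering violations are
#' rejected naming the inverted pair. Consequently
#' \code{cellulose + hemicellulose + lignin == aNDF} exactly.
#'
#' @param adf,andf,lignin Proportions, either as fractions (default) or
#'   percentages.
#' @param unit \code{"fraction"} or \code{"percent"}; percent inputs are
#'   divided by 100 and results are returned as fractions either way.
#' @return data.frame with columns \code{cellulose} and
#'   \code{hemicellulose} (fractions), one row per input.
#' @examples
#' derive_composition(adf = 0.45, andf = 0.65, lignin = 0.05)
#' @export
derive_composition <- function(adf, andf, lignin,
                               unit = c("fraction", "percent")) {
  unit <- match.arg(unit)
  if (unit == "percent") {
    adf <- adf / 100; andf <- andf / 100; lignin <- lignin / 100
  }
  if (any(lignin < 0)) stop("lignin must be non-negative", call. = FALSE)
  if (any(lignin > adf)) {
    stop("ordering violation: lignin exceeds ADF", call. = FALSE)
  }
  if (any(adf > andf)) {
    stop("ordering violation: ADF exceeds aNDF", call. = FALSE)
  }
  if (any(andf > 1)) {
    stop("ordering violation: aNDF exceeds 1", call. = FALSE)
  }
  data.frame(cellulose = adf - lignin, hemicellulose = andf - adf)
}
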