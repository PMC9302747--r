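#' @title Downed dead wood carbon from planar-intercept transects
#' @description Volume and carbon of downed wood from line-transect piece
#'   tallies using the Van Wagner planar-intercept estimator
#'   V = pi^2 * sum(d^2) / (8 L), with d in cm, L in m and V in m^3 ha^-1.
#' @name necromass
NULL

DWC_CLASSES <- c("fine", "small", "large_sound", "large_rotten")

#' Construct and validate a transect tally
#'
#' Fine (< 2.5 cm) and small (2.5-7.6 cm) pieces are tallied as counts
#' with a class quadratic mean diameter (QMD); large pieces (> 7.6 cm)
#' are measured individually and carry a soundness class.
#'
#' @param plot_id,transect_id identifiers.
#' @param length_m sampled transect length in m; either a scalar used for
#'   every size class or a named vector with entries `fine`, `small`,
#'   `large`.
#' @param fine_count,small_count tally counts (>= 0).
#' @param fine_qmd_cm,small_qmd_cm class quadratic mean diameters (cm).
#' @param large_pieces data.frame with `diameter_cm` (> 0) and `soundness`
#'   in `SOUND`/`ROTTEN`; may be empty.
#' @return object of class `transect_tally`.
#' @export
transect_tally <- function(plot_id, transect_id, length_m,
                           fine_count = 0, small_count = 0,
                           fine_qmd_cm = 1.24, small_qmd_cm = 4.52,
                           large_pieces = data.frame(
                             diameter_cm = numeric(0),
                             soundness = character(0))) {
  if (any(!is.finite(length_m)) || any(length_m <= 0))
    stop("transect length must be > 0")
  if (length(length_m) == 1L)
    length_m <- c(fine = length_m, small = length_m, large = length_m)
  stopifnot(all(c("fine", "small", "large") %in% names(length_m)))
  if (fine_count < 0 || small_count < 0) stop("piece counts must be >= 0")
  if (fine_qmd_cm <= 0 || small_qmd_cm <= 0) stop("QMDs must be > 0")
  if (nrow(large_pieces)) {
    stopifnot(all(c("diameter_cm", "soundness") %in% names(large_pieces)))
    if (any(large_pieces$diameter_cm <= 0))
      stop("large piece diameters must be > 0")
    if (any(!large_pieces$soundness %in% c("SOUND", "ROTTEN")))
      stop("soundness must be SOUND or ROTTEN")
  }
  structure(list(plot_id = plot_id, transect_id = transect_id,
                 length_m = length_m, fine_count = fine_count,
                 small_count = small_count, fine_qmd_cm = fine_qmd_cm,
                 small_qmd_cm = small_qmd_cm, large_pieces = large_pieces),
            class = "transect_tally")
}

#' Downed wood volume per hectare by size class
#'
#' Applies V = pi^2 * sum(d_i^2) / (8 L) per class. Tally classes use
#' count x QMD^2; large pieces use individual diameters, split by
#' soundness.
#'
#' @param tally a [transect_tally()].
#' @return named numeric (m^3 ha^-1) with entries `fine`, `small`,
#'   `large_sound`, `large_rotten`.
#' @export
transect_volume <- function(tally) {
  stopifnot(inherits(tally, "transect_tally"))
  vw <- function(sum_d2, L) pi^2 * sum_d2 / (8 * L)
  lp <- tally$large_pieces
  sound <- lp$diameter_cm[lp$soundness == "SOUND"]
  rotten <- lp$diameter_cm[lp$soundness == "ROTTEN"]
  c(fine = vw(tally$fine_count * tally$fine_qmd_cm^2,
              tally$length_m[["fine"]]),
    small = vw(tally$small_count * tally$small_qmd_cm^2,
               tally$length_m[["small"]]),
    large_sound = vw(sum(sound^2), tally$length_m[["large"]]),
    large_rotten = vw(sum(rotten^2), tally$length_m[["large"]]))
}

#' Default downed-wood specific gravities
#'
#' Per-class wood densities (g cm^-3) in the range reported for
#' Micronesian mangrove downed wood; rotten large pieces are lighter than
#' sound ones. Values are configuration, overridable per analysis.
#'
#' @return named numeric vector over the four size classes.
#' @export
default_necromass_density <- function() {
  c(fine = 0.48, small = 0.64, large_sound = 0.69, large_rotten = 0.29)
}

#' Downed wood carbon of one transect
#'
#' Biomass = volume x specific gravity (g cm^-3 = Mg m^-3); carbon uses
#' the dead-wood fraction 0.50.
#'
#' @param volumes named m^3 ha^-1 by class, from [transect_volume()].
#' @param densities named specific gravities (g cm^-3) covering every
#'   class present in `volumes`.
#' @param carbon_fraction carbon fraction of dead wood biomass.
#' @return MgC ha^-1 (scalar).
#' @export
transect_carbon <- function(volumes, densities = default_necromass_density(),
                            carbon_fraction = 0.50) {
  cls <- names(volumes)[volumes > 0]
  missing_cls <- setdiff(cls, names(densities))
  if (length(missing_cls))
    stop("no specific gravity for class(es): ",
         paste(missing_cls, collapse = ", "))
  if (any(densities < 0 | densities >= 1.5))
    stop("specific gravities must be in [0, 1.5)")
  sum(volumes * densities[names(volumes)] * carbon_fraction, na.rm = TRUE)
}

#' Downed wood carbon of a plot
#'
#' Each transect is an unbiased per-hectare estimate; the plot value is
#' their arithmetic mean (pooled sum(d^2)/sum(L) available via
#' `aggregate = "pooled"`).
#'
#' @param tallies list of [transect_tally()] for one plot (>= 1).
#' @param densities,carbon_fraction see [transect_carbon()].
#' @param aggregate `"mean"` (default) or `"pooled"`.
#' @return MgC ha^-1 (scalar).
#' @export
plot_dwc <- function(tallies, densities = default_necromass_density(),
                     carbon_fraction = 0.50, aggregate = c("mean", "pooled")) {
  aggregate <- match.arg(aggregate)
  if (!length(tallies)) stop("plot has no transects")
  if (inherits(tallies, "transect_tally")) tallies <- list(tallies)
  per <- vapply(tallies, function(t)
    transect_carbon(transect_volume(t), densities, carbon_fraction),
    numeric(1))
  if (aggregate == "mean") return(mean(per))
  # pooled: treat all transects as one long line per class
  tot_d2 <- c(fine = 0, small = 0, large_sound = 0, large_rotten = 0)
  tot_L <- c(fine = 0, small = 0, large_sound = 0, large_rotten = 0)
  for (t in tallies) {
    lp <- t$large_pieces
    tot_d2 <- tot_d2 + c(
      fine = t$fine_count * t$fine_qmd_cm^2,
      small = t$small_count * t$small_qmd_cm^2,
      large_sound = sum(lp$diameter_cm[lp$soundness == "SOUND"]^2),
      large_rotten = sum(lp$diameter_cm[lp$soundness == "ROTTEN"]^2))
    tot_L <- tot_L + c(fine = t$length_m[["fine"]],
                       small = t$length_m[["small"]],
                       large_sound = t$length_m[["large"]],
                       large_rotten = t$length_m[["large"]])
  }
  vols <- pi^2 * tot_d2 / (8 * tot_L)
  transect_carbon(vols, densities, carbon_fraction)
}
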