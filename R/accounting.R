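#' @title Island-scale carbon stock and change accounting
#' @description Strata-based upscaling: plot-mean aboveground carbon times
#'   mapped mangrove area, with loss/gain carbon from two-date extent maps
#'   and per-species carbon-density mapping.
#' @name carbon_accounting
NULL

#' Round half away from zero
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric (ties go away from zero, matching common
#'   report presentation rather than IEEE banker's rounding).
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Total aboveground carbon stock
#'
#' Strata product: mean carbon density times mapped area, reported to
#' whole MgC.
#'
#' @param mean_agc_MgC_ha mean aboveground carbon density (MgC ha^-1).
#' @param area_ha mapped mangrove area (ha).
#' @return total stock in MgC (whole number).
#' @export
total_stock <- function(mean_agc_MgC_ha, area_ha) {
  stopifnot(mean_agc_MgC_ha >= 0, area_ha >= 0)
  round_half_up(mean_agc_MgC_ha * area_ha)
}

#' Area and carbon change ledger between two dates
#'
#' Carbon in lost and gained area is the mean aboveground carbon density
#' times the respective area. Percent change uses the later-date area as
#' denominator. Carbon totals are reported to whole MgC, areas to the
#' precision given, percent to two decimals (half-up).
#'
#' @param area_t0_ha mangrove area at the first date (ha).
#' @param loss_ha,gain_ha gross area lost and gained between the dates.
#' @param mean_agc_MgC_ha mean aboveground carbon density (MgC ha^-1).
#' @return object of class `change_ledger`: `area_t0_ha`, `area_t1_ha`,
#'   `loss_ha`, `gain_ha`, `net_ha`, `mean_agc_MgC_ha`,
#'   `carbon_loss_MgC`, `carbon_gain_MgC`, `carbon_net_MgC`,
#'   `total_stock_MgC`, `percent_change`.
#' @export
change_ledger <- function(area_t0_ha, loss_ha, gain_ha, mean_agc_MgC_ha) {
  stopifnot(area_t0_ha >= 0, loss_ha >= 0, gain_ha >= 0,
            mean_agc_MgC_ha >= 0)
  if (loss_ha > area_t0_ha)
    stop("loss (", loss_ha, " ha) exceeds initial area (", area_t0_ha,
         " ha)")
  net <- gain_ha - loss_ha
  area_t1 <- area_t0_ha + net
  closs <- round_half_up(mean_agc_MgC_ha * loss_ha)
  cgain <- round_half_up(mean_agc_MgC_ha * gain_ha)
  structure(list(
    area_t0_ha = area_t0_ha, area_t1_ha = area_t1,
    loss_ha = loss_ha, gain_ha = gain_ha, net_ha = net,
    mean_agc_MgC_ha = mean_agc_MgC_ha,
    carbon_loss_MgC = closs, carbon_gain_MgC = cgain,
    carbon_net_MgC = cgain - closs,
    total_stock_MgC = total_stock(mean_agc_MgC_ha, area_t1),
    percent_change = if (area_t1 > 0)
      round_half_up(100 * net / area_t1, 2) else NA_real_),
    class = "change_ledger")
}

#' @export
print.change_ledger <- function(x, ...) {
  cat(sprintf(
    paste0("change_ledger: %g -> %g ha (loss %g, gain %g, net %+g ha,",
           " %+.2f%%)\n  carbon: loss %g, gain %g, net %+g MgC;",
           " total stock %g MgC at %g MgC/ha\n"),
    x$area_t0_ha, x$area_t1_ha, x$loss_ha, x$gain_ha, x$net_ha,
    x$percent_change, x$carbon_loss_MgC, x$carbon_gain_MgC,
    x$carbon_net_MgC, x$total_stock_MgC, x$mean_agc_MgC_ha))
  invisible(x)
}

#' Areas and change from two binary extent maps
#'
#' Counts cells in each map for the date areas; loss cells are mangrove
#' at t0 only, gain cells at t1 only. Change strips narrower than
#' `min_change_m` (e.g. shoreline digitizing jitter) are discounted by
#' morphological opening of each change mask with a square element of
#' that width.
#'
#' @param map_t0,map_t1 co-registered binary (0/1) `grid_raster` maps.
#' @param min_change_m minimum credible change width in metres
#'   (default 10); strips narrower than this are discounted.
#' @return list with `area_t0_ha`, `area_t1_ha`, `loss_ha`, `gain_ha`
#'   (after discounting), `raw_loss_ha`, `raw_gain_ha`, and a
#'   `cell_counts` breakdown (`unchanged`, `loss`, `gain`, `never`,
#'   before discounting).
#' @export
area_from_extent_maps <- function(map_t0, map_t1, min_change_m = 10) {
  stopifnot(inherits(map_t0, "grid_raster"), inherits(map_t1, "grid_raster"))
  if (!grids_aligned(map_t0, map_t1))
    stop("extent maps are not co-registered (shape/georeference mismatch)")
  a <- map_t0$values; b <- map_t1$values
  if (!all(a %in% c(0, 1), b %in% c(0, 1)))
    stop("extent maps must be binary 0/1")
  ca <- cell_area_ha(map_t0)
  loss_mask <- (a == 1) * (b == 0)
  gain_mask <- (a == 0) * (b == 1)
  width <- max(1L, ceiling(min_change_m / map_t0$cell_size_m))
  loss_open <- binary_open(loss_mask, width)
  gain_open <- binary_open(gain_mask, width)
  list(
    area_t0_ha = sum(a) * ca,
    area_t1_ha = sum(b) * ca,
    loss_ha = sum(loss_open) * ca,
    gain_ha = sum(gain_open) * ca,
    raw_loss_ha = sum(loss_mask) * ca,
    raw_gain_ha = sum(gain_mask) * ca,
    cell_counts = c(unchanged = sum(a == 1 & b == 1),
                    loss = sum(loss_mask), gain = sum(gain_mask),
                    never = sum(a == 0 & b == 0)))
}

#' Carbon density by dominant species
#'
#' For each species, the mean carbon per qualifying tree (DBH >= 5 cm)
#' multiplied by the all-species mean stem density, giving the expected
#' standing carbon per hectare where that species dominates. Species
#' with no qualifying trees are omitted with a message.
#'
#' @param trees tree table including `carbon_kg` (see
#'   [tree_carbon_table()]).
#' @param mean_density_trees_ha all-species mean stem density
#'   (default 890 trees ha^-1).
#' @param min_dbh_cm qualifying-tree DBH threshold (default 5 cm).
#' @return data.frame with `species`, `n_trees`, `mean_tree_carbon_MgC`,
#'   `carbon_MgC_ha`.
#' @export
species_carbon_density <- function(trees, mean_density_trees_ha = 890,
                                   min_dbh_cm = 5) {
  stopifnot("carbon_kg" %in% names(trees), mean_density_trees_ha >= 0)
  all_sp <- sort(unique(trees$species))
  q <- trees[trees$dbh_cm >= min_dbh_cm, , drop = FALSE]
  dropped <- setdiff(all_sp, unique(q$species))
  if (length(dropped))
    message("species with no trees >= ", min_dbh_cm, " cm omitted: ",
            paste(dropped, collapse = ", "))
  if (!nrow(q)) stop("no qualifying trees at DBH >= ", min_dbh_cm, " cm")
  sp <- sort(unique(q$species))
  mc <- vapply(sp, function(s)
    mean(q$carbon_kg[q$species == s]) / 1000, numeric(1))
  data.frame(species = sp,
             n_trees = vapply(sp, function(s) sum(q$species == s),
                              integer(1)),
             mean_tree_carbon_MgC = mc,
             carbon_MgC_ha = mc * mean_density_trees_ha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Carbon-density map from a dominance map
#'
#' Assigns each cell the carbon density of its predicted dominant
#' species; no-data cells stay no-data.
#'
#' @param dominance a `grid_raster` of integer species codes with a
#'   `legend` attribute (as from [predict_dominance_grid()]).
#' @param density_table data.frame from [species_carbon_density()] (or
#'   any with `species` and `carbon_MgC_ha`).
#' @return a `grid_raster` of MgC ha^-1.
#' @export
carbon_map <- function(dominance, density_table) {
  stopifnot(inherits(dominance, "grid_raster"))
  legend <- attr(dominance, "legend")
  if (is.null(legend)) stop("dominance grid has no species legend")
  mapped <- unique(legend[as.character(
    dominance$values[!is.na(dominance$values)])])
  miss <- setdiff(mapped, density_table$species)
  if (length(miss))
    stop("no carbon density for mapped species: ",
         paste(miss, collapse = ", "))
  dens <- stats::setNames(density_table$carbon_MgC_ha,
                          density_table$species)
  v <- matrix(dens[legend[as.character(dominance$values)]],
              nrow(dominance$values), ncol(dominance$values))
  grid_raster(v, cell_size_m = dominance$cell_size_m,
              origin = dominance$origin)
}
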