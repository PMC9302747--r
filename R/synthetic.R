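#' @title Synthetic survey and imagery generator
#' @description Generates plot inventories, downed-wood transect tallies,
#'   spatially autocorrelated predictor rasters with a recoverable
#'   dominance signal, and paired extent maps with known change, so every
#'   downstream stage is testable with known ground truth.
#' @name synthetic_data
NULL

#' Default species mix of the emulated survey
#'
#' Relative stem densities matching the observed community composition
#' (dense *B. gymnorhiza* and *R. apiculata*, sparse *L. littorea*, a
#' trace unidentified-*Rhizophora* class), normalized to sum to one.
#'
#' @return named numeric vector over the eight species codes.
#' @export
default_species_mix <- function() {
  d <- c(BRGY = 346, LULI = 17, RHAP = 260, RHST_MU = 97, RHLA = 63,
         SOAL = 53, XYGR = 52, RH_UNK = 2)
  d / sum(d)
}

#' Default per-species DBH log-normal parameters
#'
#' (meanlog, sdlog) on the log-cm scale, chosen so truncated-at-5-cm
#' means sit near the observed per-species mean DBH (about 16 cm for
#' *B. gymnorhiza*, 41 cm for *S. alba*) with heavy enough tails to
#' produce rare very large stems.
#'
#' @return named list of length-2 numeric vectors.
#' @export
default_dbh_params <- function() {
  list(BRGY = c(2.60, 0.55), LULI = c(3.30, 0.50), RHAP = c(2.55, 0.50),
       RHST_MU = c(2.70, 0.60), RHLA = c(2.20, 0.35), SOAL = c(3.55, 0.60),
       XYGR = c(3.20, 0.60), RH_UNK = c(2.70, 0.50))
}

#' Synthetic survey configuration
#'
#' Defaults emulate the study conditions: 273 circular 10 m plots with
#' 3 m subplots, 890 stems ha^-1 mean density, the observed species mix
#' and DBH scales, four 12 m planar-intercept transects per plot with
#' piece intensities calibrated so the expected downed-wood carbon is
#' about 46 MgC ha^-1, and a 200 x 200 grid of 5 m cells for predictor
#' rasters.
#'
#' @param n_plots number of circular plots.
#' @param plot_radius_m,subplot_radius_m plot geometry (m).
#' @param species_mix named relative stem densities summing to 1.
#' @param dbh_lognormal_params named list of (meanlog, sdlog) per
#'   species, log-cm scale.
#' @param dead_fraction named proportions of stems in `DEAD1`, `DEAD2`,
#'   `DEAD3`; the remainder is live.
#' @param target_mean_density_per_ha full-plot stem density (trees
#'   ha^-1, stems >= 5 cm DBH).
#' @param sapling_density_per_ha density of small stems (< 5 cm)
#'   censused in the subplot only.
#' @param n_transects,transect_length_m downed-wood transect layout per
#'   plot.
#' @param dwc_intensity expected pieces per metre of transect by size
#'   class (`fine`, `small`, `large`).
#' @param large_diam_lognormal (meanlog, sdlog) of large piece
#'   diameters (truncated at the 7.6 cm class boundary).
#' @param rotten_fraction fraction of large pieces in the rotten class.
#' @param fine_qmd_cm,small_qmd_cm tally-class quadratic mean diameters.
#' @param grid_shape (rows, cols) of generated rasters.
#' @param cell_size_m raster cell size (m).
#' @param spatial_corr_length_m correlation length of the Gaussian
#'   random fields (m).
#' @param dominance_noise weight of imagery variation in the latent
#'   seaward-to-landward score that sorts species dominance; 0 gives a
#'   truth perfectly determined by distance to water within each island
#'   side, larger values blur the sorting (default 0.3).
#' @param loss_cells,gain_cells planted change patch sizes for
#'   [gen_extent_pair()], in cells.
#' @param seed integer master seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_plots = 273,
                       plot_radius_m = 10, subplot_radius_m = 3,
                       species_mix = default_species_mix(),
                       dbh_lognormal_params = default_dbh_params(),
                       dead_fraction = c(DEAD1 = 0.04, DEAD2 = 0.03,
                                         DEAD3 = 0.03),
                       target_mean_density_per_ha = 890,
                       sapling_density_per_ha = 2000,
                       n_transects = 4, transect_length_m = 12,
                       dwc_intensity = c(fine = 1.0, small = 0.5,
                                         large = 0.504),
                       large_diam_lognormal = c(2.565, 0.4),
                       rotten_fraction = 0.4,
                       fine_qmd_cm = 1.24, small_qmd_cm = 4.52,
                       grid_shape = c(200, 200), cell_size_m = 5,
                       spatial_corr_length_m = 50,
                       dominance_noise = 0.3,
                       loss_cells = 16, gain_cells = 65,
                       seed = 1) {
  if (abs(sum(species_mix) - 1) > 1e-9)
    stop("species_mix must sum to 1 (got ", format(sum(species_mix)), ")")
  if (any(species_mix < 0)) stop("species_mix entries must be >= 0")
  stopifnot(n_plots >= 1, plot_radius_m > 0, subplot_radius_m > 0,
            target_mean_density_per_ha > 0, sapling_density_per_ha >= 0,
            n_transects >= 1, transect_length_m > 0,
            all(grid_shape >= 1), cell_size_m > 0)
  if (spatial_corr_length_m <= 0)
    stop("spatial correlation length must be > 0")
  stopifnot(dominance_noise >= 0)
  if (any(dwc_intensity < 0)) stop("dwc_intensity must be >= 0")
  if (any(dead_fraction < 0) || any(dead_fraction > 1) ||
      sum(dead_fraction) > 1)
    stop("dead_fraction entries must be in [0,1] and sum to <= 1")
  miss <- setdiff(names(species_mix), names(dbh_lognormal_params))
  if (length(miss))
    stop("no DBH parameters for species: ", paste(miss, collapse = ", "))
  for (p in dbh_lognormal_params)
    if (p[2] <= 0) stop("DBH sdlog must be > 0")
  structure(as.list(environment()), class = "sim_config")
}

# truncated lognormal sampler: d >= lower ------------------------------

rlnorm_trunc <- function(n, meanlog, sdlog, lower) {
  p0 <- stats::plnorm(lower, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, p0, 1), meanlog, sdlog)
}

#' Generate a synthetic plot inventory
#'
#' Plots are placed on distinct raster cell centres. Full-plot stem
#' counts are Poisson at the target density times plot area; species
#' are multinomial draws from the mix; DBH is per-species log-normal
#' truncated at 5 cm for full-plot stems; mortality status follows the
#' configured fractions. Saplings (< 5 cm DBH) are generated only in
#' the 3 m subplot and flagged `in_subplot`. Deterministic for a fixed
#' config seed.
#'
#' @param config a [sim_config()].
#' @param registry optional [allometric_registry()] used to record the
#'   per-plot true standing carbon in the returned truth (defaults to
#'   the packaged registry).
#' @return list with `plots`, `trees` (data.frames) and `truth` (list
#'   with `per_plot_true_stc`, `expected_dwc_MgC_ha`, `true_mean_agc`).
#' @export
gen_plot_inventory <- function(config, registry = default_registry()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  cs <- config$cell_size_m
  cells <- sample.int(nr * nc, config$n_plots,
                      replace = config$n_plots > nr * nc)
  row <- (cells - 1L) %/% nc + 1L
  col <- (cells - 1L) %% nc + 1L
  x <- (col - 0.5) * cs
  y <- (nr - row + 0.5) * cs
  plot_area_ha <- pi * config$plot_radius_m^2 / 1e4
  sub_area_ha <- pi * config$subplot_radius_m^2 / 1e4
  munis <- c("Madolenihmw", "Kitti", "Sokehs", "Nett", "U")
  plots <- data.frame(
    plot_id = sprintf("P%03d", seq_len(config$n_plots)),
    x = x, y = y,
    radius_m = config$plot_radius_m,
    subplot_radius_m = config$subplot_radius_m,
    municipality = sample(munis, config$n_plots, replace = TRUE),
    side = ifelse(x > nc * cs / 2, "WINDWARD", "LEEWARD"),
    dist_to_coast_m = round(stats::runif(config$n_plots, 0, 500), 1),
    dist_to_upland_m = round(stats::runif(config$n_plots, 0, 500), 1),
    stringsAsFactors = FALSE)
  plots$zone <- classify_zone(plots$dist_to_coast_m, plots$dist_to_upland_m)

  sp_codes <- names(config$species_mix)
  statuses <- c("LIVE", names(config$dead_fraction))
  p_status <- c(1 - sum(config$dead_fraction), config$dead_fraction)
  tree_rows <- vector("list", config$n_plots)
  for (i in seq_len(config$n_plots)) {
    n_full <- stats::rpois(1, config$target_mean_density_per_ha *
                                plot_area_ha)
    n_sap <- stats::rpois(1, config$sapling_density_per_ha * sub_area_ha)
    sp <- sample(sp_codes, n_full + n_sap, replace = TRUE,
                 prob = config$species_mix)
    dbh <- numeric(n_full + n_sap)
    for (s in unique(sp)) {
      pars <- config$dbh_lognormal_params[[s]]
      isp <- which(sp == s)
      full_s <- isp[isp <= n_full]
      sap_s <- isp[isp > n_full]
      dbh[full_s] <- rlnorm_trunc(length(full_s), pars[1], pars[2], 5)
      # saplings: below the 5 cm census threshold
      if (length(sap_s)) {
        p5 <- stats::plnorm(5, pars[1], pars[2])
        p1 <- stats::plnorm(1, pars[1], pars[2])
        dbh[sap_s] <- stats::qlnorm(
          stats::runif(length(sap_s), p1, p5), pars[1], pars[2])
      }
    }
    status <- sample(statuses, n_full + n_sap, replace = TRUE,
                     prob = p_status)
    if (n_full + n_sap == 0) next
    tree_rows[[i]] <- data.frame(
      plot_id = plots$plot_id[i], species = sp,
      dbh_cm = round(dbh, 2), status = status,
      in_subplot = seq_len(n_full + n_sap) > n_full,
      stringsAsFactors = FALSE)
  }
  trees <- do.call(rbind, tree_rows)
  rownames(trees) <- NULL

  truth <- list()
  if (!is.null(registry)) {
    tc <- tree_carbon_table(trees, registry)
    truth$per_plot_true_stc <- vapply(seq_len(nrow(plots)), function(i)
      plot_standing_carbon(plots[i, ],
                           tc[tc$plot_id == plots$plot_id[i], ,
                              drop = FALSE]),
      numeric(1))
    truth$expected_dwc_MgC_ha <- expected_dwc(config)
    truth$true_mean_agc <- mean(truth$per_plot_true_stc) +
      truth$expected_dwc_MgC_ha
  }
  list(plots = plots, trees = trees, truth = truth)
}

#' Expected downed-wood carbon of the generator (closed form)
#'
#' Planar-intercept expectation under the configured Poisson piece
#' intensities: tally classes contribute
#' pi^2 * lambda * QMD^2 / 8 per metre sampled, large pieces
#' pi^2 * lambda * E[d^2] / 8 with E[d^2] from the truncated
#' log-normal; volumes times class specific gravity times the 0.50
#' dead-wood carbon fraction.
#'
#' @param config a [sim_config()].
#' @param densities class specific gravities.
#' @return expected plot DWC in MgC ha^-1.
#' @export
expected_dwc <- function(config, densities = default_necromass_density()) {
  lam <- config$dwc_intensity
  v_fine <- pi^2 * lam[["fine"]] * config$fine_qmd_cm^2 / 8
  v_small <- pi^2 * lam[["small"]] * config$small_qmd_cm^2 / 8
  ml <- config$large_diam_lognormal[1]; sl <- config$large_diam_lognormal[2]
  lower <- 7.6
  # E[d^2 | d > lower] for lognormal
  ed2 <- exp(2 * ml + 2 * sl^2) *
    stats::pnorm((ml + 2 * sl^2 - log(lower)) / sl) /
    (1 - stats::plnorm(lower, ml, sl))
  v_large <- pi^2 * lam[["large"]] * ed2 / 8
  rho_large <- (1 - config$rotten_fraction) * densities[["large_sound"]] +
    config$rotten_fraction * densities[["large_rotten"]]
  0.5 * (v_fine * densities[["fine"]] + v_small * densities[["small"]] +
           v_large * rho_large)
}

#' Generate downed-wood transect tallies for a plot set
#'
#' Per plot, `n_transects` fixed-length transects; tally-class counts
#' are Poisson at the configured intensity times sampled length; large
#' piece diameters are truncated log-normal with a Bernoulli rotten
#' class. Reproducible for a fixed config seed.
#'
#' @param config a [sim_config()].
#' @param plots plot table from [gen_plot_inventory()].
#' @return named list (by plot id) of lists of [transect_tally()].
#' @export
gen_downed_wood <- function(config, plots) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  lam <- config$dwc_intensity
  L <- config$transect_length_m
  out <- vector("list", nrow(plots))
  names(out) <- plots$plot_id
  for (i in seq_len(nrow(plots))) {
    tl <- vector("list", config$n_transects)
    for (t in seq_len(config$n_transects)) {
      n_large <- stats::rpois(1, lam[["large"]] * L)
      lp <- data.frame(
        diameter_cm = round(rlnorm_trunc(n_large,
                                         config$large_diam_lognormal[1],
                                         config$large_diam_lognormal[2],
                                         7.6), 1),
        soundness = ifelse(
          stats::runif(n_large) < config$rotten_fraction,
          "ROTTEN", "SOUND"),
        stringsAsFactors = FALSE)
      tl[[t]] <- transect_tally(
        plot_id = plots$plot_id[i], transect_id = sprintf("T%d", t),
        length_m = L,
        fine_count = stats::rpois(1, lam[["fine"]] * L),
        small_count = stats::rpois(1, lam[["small"]] * L),
        fine_qmd_cm = config$fine_qmd_cm,
        small_qmd_cm = config$small_qmd_cm,
        large_pieces = lp)
    }
    out[[i]] <- tl
  }
  out
}

# Gaussian random field: FFT convolution of white noise with a wrapped
# Gaussian kernel; standardized to mean 0, sd 1 ------------------------

gaussian_random_field <- function(nr, nc, corr_cells) {
  noise <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (corr_cells <= 0.5) return((noise - mean(noise)) / stats::sd(noise))
  dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  kern <- exp(-outer(dr^2, dc^2, "+") / (2 * corr_cells^2))
  sm <- Re(stats::fft(stats::fft(noise) * stats::fft(kern),
                      inverse = TRUE)) / (nr * nc)
  (sm - mean(sm)) / stats::sd(sm)
}

#' Generate predictor rasters with a recoverable dominance truth
#'
#' Feature bands: three smooth Gaussian-random-field imagery
#' principal-component surrogates, distance to water (distance to the
#' nearer west/east coast plus spatial noise), an elevation surface
#' rising away from the water, and a binary island-side indicator
#' splitting the grid at mid-longitude. The true dominant species
#' emulates the field pattern of communities sorting by island side and
#' tidal position: species are split into a windward and a leeward pool,
#' and within each side the cells are banded along a seaward-to-landward
#' latent score (standardized distance-to-water plus
#' `dominance_noise` times imagery variation) with band widths
#' proportional to the species mix. Labels are therefore spatially
#' coherent and recoverable from the features, with `dominance_noise`
#' controlling how sharply the sorting is expressed.
#'
#' @param config a [sim_config()].
#' @return list with `features` (named list of `grid_raster`:
#'   `pc1..pc3`, `dist_to_water_m`, `elevation_m`, `side`) and `truth`
#'   (list with `true_dominance_grid`, a coded `grid_raster` carrying a
#'   `legend` attribute).
#' @export
gen_predictor_raster <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  cs <- config$cell_size_m
  corr <- config$spatial_corr_length_m / cs
  g <- function() gaussian_random_field(nr, nc, corr)
  pcs <- list(pc1 = g(), pc2 = g(), pc3 = g())
  xc <- matrix(rep((seq_len(nc) - 0.5) * cs, each = nr), nr, nc)
  extent_x <- nc * cs
  # water to the west and east; upland ridge in the middle
  dist_to_water <- pmax(pmin(xc, extent_x - xc) + 20 * g(), 0)
  elevation <- pmax(0.5 + 0.004 * dist_to_water + 0.8 * g(), 0)
  side <- matrix(as.numeric(xc > extent_x / 2), nr, nc)

  sp <- names(config$species_mix)
  zs <- function(m) (m - mean(m)) / stats::sd(m)
  z <- zs(zs(dist_to_water) +
            config$dominance_noise * (pcs$pc1 + 0.5 * pcs$pc2))
  lab <- matrix(1L, nr, nc)
  if (length(sp) > 1) {
    ord <- names(sort(config$species_mix, decreasing = TRUE))
    pools <- list(ord[seq(2, length(ord), by = 2)],   # side 0 (leeward)
                  ord[seq(1, length(ord), by = 2)])   # side 1 (windward)
    for (s in 0:1) {
      pool <- pools[[s + 1]]
      if (!length(pool)) pool <- pools[[2 - s]]
      pm <- config$species_mix[pool] / sum(config$species_mix[pool])
      sel <- side == s
      qs <- stats::quantile(z[sel], cumsum(pm)[-length(pm)])
      lab[sel] <- match(pool, sp)[findInterval(z[sel], qs) + 1L]
    }
  }
  mk <- function(m) grid_raster(m, cell_size_m = cs, origin = c(0, 0))
  dom <- mk(lab)
  attr(dom, "legend") <- stats::setNames(sp, seq_along(sp))
  list(features = list(pc1 = mk(pcs$pc1), pc2 = mk(pcs$pc2),
                       pc3 = mk(pcs$pc3),
                       dist_to_water_m = mk(dist_to_water),
                       elevation_m = mk(elevation), side = mk(side)),
       truth = list(true_dominance_grid = dom))
}

# place an h x w rectangle of 1s; returns the modified mask ------------

plant_patch <- function(mask, n_cells, inside) {
  # near-square rectangle with exactly n_cells cells
  h <- floor(sqrt(n_cells))
  while (n_cells %% h != 0) h <- h - 1
  w <- n_cells / h
  cand <- which(inside, arr.ind = TRUE)
  nr <- nrow(mask); nc <- ncol(mask)
  for (i in sample(nrow(cand))) {
    r0 <- cand[i, 1]; c0 <- cand[i, 2]
    if (r0 + h - 1 > nr || c0 + w - 1 > nc) next
    block <- inside[r0:(r0 + h - 1), c0:(c0 + w - 1)]
    if (all(block)) {
      mask[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- 1
      return(mask)
    }
  }
  stop("could not place a ", n_cells, "-cell patch; grid too small")
}

#' Generate a pair of extent maps with planted change
#'
#' The first-date extent is a solid block; the second date removes a
#' rectangular loss patch of `loss_cells` cells from its interior and
#' adds a rectangular gain patch of `gain_cells` cells outside it, so
#' the change truth is exact in cell counts.
#'
#' @param config a [sim_config()].
#' @return list with `map_t0`, `map_t1` (binary `grid_raster`) and
#'   `truth` (list `loss_ha`, `gain_ha` from planted cell counts).
#' @export
gen_extent_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  cs <- config$cell_size_m
  t0 <- matrix(0, nr, nc)
  r_in <- floor(nr * 0.2):ceiling(nr * 0.8)
  c_in <- floor(nc * 0.2):ceiling(nc * 0.8)
  t0[r_in, c_in] <- 1
  loss <- plant_patch(matrix(0, nr, nc), config$loss_cells,
                      inside = t0 == 1)
  t1 <- t0 * (1 - loss)
  gain <- plant_patch(matrix(0, nr, nc), config$gain_cells,
                      inside = t0 == 0)
  t1 <- pmax(t1, gain)
  ca <- cs^2 / 1e4
  mk <- function(m) grid_raster(m, cell_size_m = cs, origin = c(0, 0))
  list(map_t0 = mk(t0), map_t1 = mk(t1),
       truth = list(loss_ha = config$loss_cells * ca,
                    gain_ha = config$gain_cells * ca))
}
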