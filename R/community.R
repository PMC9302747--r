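#' @title Community structure statistics
#' @description Per-species density, basal area, importance value and DBH
#'   summaries from plot inventories, plot zonation, stratified means and
#'   the two-group comparisons used for island sides and tidal zones.
#' @name community_structure
NULL

#' Classify a plot into a tidal zone
#'
#' Seaward: within 30 m of the coast; landward: within 30 m of the upland
#' forest ecotone; interior: everything in between. Coast proximity wins
#' when a plot satisfies both.
#'
#' @param dist_to_coast_m,dist_to_upland_m distances in metres
#'   (vectorized, >= 0, no missing values).
#' @param cutoff_m zone cutoff distance (default 30 m).
#' @return character vector in `SEAWARD`/`INTERIOR`/`LANDWARD`.
#' @export
classify_zone <- function(dist_to_coast_m, dist_to_upland_m, cutoff_m = 30) {
  if (length(dist_to_coast_m) != length(dist_to_upland_m))
    stop("distance vectors differ in length")
  if (anyNA(dist_to_coast_m) || anyNA(dist_to_upland_m))
    stop("missing distance: both distances are required for zonation")
  if (any(dist_to_coast_m < 0) || any(dist_to_upland_m < 0))
    stop("distances must be >= 0")
  ifelse(dist_to_coast_m <= cutoff_m, "SEAWARD",
         ifelse(dist_to_upland_m <= cutoff_m, "LANDWARD", "INTERIOR"))
}

#' Basal area of a stem
#' @param dbh_cm diameter at breast height in cm (vectorized, > 0).
#' @return cross-sectional area in m^2.
#' @export
basal_area <- function(dbh_cm) {
  if (any(dbh_cm <= 0)) stop("dbh must be > 0")
  pi * (dbh_cm / 200)^2
}

#' Importance value index
#'
#' Composite of relative density, relative basal area and relative
#' frequency, scaled so the species column totals 100.
#'
#' @param rel_density,rel_basal_area,rel_frequency per-species relative
#'   measures; each must lie in `[0, 1]` and sum to 1.
#' @param tol tolerance on the sum-to-one checks.
#' @return numeric vector of IVI percentages summing to 100.
#' @export
importance_value <- function(rel_density, rel_basal_area, rel_frequency,
                             tol = 1e-6) {
  for (v in list(rel_density, rel_basal_area, rel_frequency)) {
    if (any(v < 0) || any(v > 1)) stop("relative measures must be in [0,1]")
    if (abs(sum(v) - 1) > tol)
      stop("relative measures must sum to 1 over species (got ",
           format(sum(v)), ")")
  }
  100 * (rel_density + rel_basal_area + rel_frequency) / 3
}

#' Mean and standard error by stratum
#'
#' @param values numeric per-plot values.
#' @param strata stratum label per value.
#' @return data.frame with `stratum`, `n`, `mean`, `se`
#'   (SE = sd / sqrt(n), n-1 denominator; `NA` for n < 2). Declared
#'   strata (factor levels) with no plots are kept with `n = 0` and a
#'   warning rather than dropped.
#' @export
stratified_means <- function(values, strata) {
  stopifnot(length(values) == length(strata))
  strata <- as.factor(strata)
  lev <- levels(strata)
  out <- data.frame(stratum = lev, n = NA_integer_, mean = NA_real_,
                    se = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(lev)) {
    v <- values[strata == lev[i]]
    out$n[i] <- length(v)
    if (length(v)) out$mean[i] <- mean(v)
    if (length(v) >= 2) out$se[i] <- stats::sd(v) / sqrt(length(v))
    if (length(v) == 1) out$se[i] <- 0
  }
  if (any(out$n == 0))
    warning("empty stratum: ", paste(out$stratum[out$n == 0],
                                     collapse = ", "))
  out
}

#' Two-sided unpaired Student's t-test
#'
#' Pooled-variance Student's t by default (a Welch option is available).
#' Degenerate inputs follow the convention: zero pooled variance with
#' equal means gives t = 0, p = 1; zero variance with unequal means is an
#' error.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param welch use Welch's unequal-variance form instead.
#' @return list with `t`, `df`, `p`.
#' @export
students_t_test <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs n >= 2")
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, df = length(group_a) + length(group_b) - 2, p = 1))
    }
    stop("zero variance in both groups with unequal means: t undefined")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = !welch,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

# per-plot x per-species matrix of a per-area quantity ------------------

per_plot_species <- function(plots, trees, quantity) {
  sp <- sort(unique(trees$species))
  m <- matrix(0, nrow = nrow(plots), ncol = length(sp),
              dimnames = list(plots$plot_id, sp))
  if (!nrow(trees)) return(m)
  agg <- tapply(quantity, list(trees$plot_id, trees$species), sum)
  rows <- intersect(rownames(agg), rownames(m))
  agg <- agg[rows, , drop = FALSE]
  agg[is.na(agg)] <- 0
  m[rows, colnames(agg)] <- agg
  m
}

#' Species community-structure table
#'
#' Per-area statistics are computed plot by plot with the circular-plot
#' expansion factors, then averaged over all plots (plots lacking a
#' species contribute zero), with SE = sd / sqrt(n plots). Counts and DBH
#' summaries are over measured stems. The returned table carries one row
#' per species plus a `TOTAL` row (totals include the
#' unidentified-Rhizophora category).
#'
#' @param plots plot table with `plot_id`, `radius_m`,
#'   `subplot_radius_m`.
#' @param trees tree table (`plot_id`, `species`, `dbh_cm`, `status`,
#'   `in_subplot`); if `biomass_kg`/`carbon_kg` are absent and `registry`
#'   is given they are computed.
#' @param registry optional [allometric_registry()].
#' @param min_dbh_cm stems below this DBH are excluded from structure
#'   statistics (default 5 cm, the tall/medium mangrove census
#'   threshold).
#' @param factors carbon fractions, see [tree_carbon()].
#' @return data.frame with columns `species`, `count`,
#'   `basal_area_m2_ha`, `basal_area_se`, `density_trees_ha`,
#'   `density_se`, `ivi_percent`, `mean_dbh_cm`, `dbh_se`, `max_dbh_cm`,
#'   `biomass_Mg_ha`, `biomass_se`, `carbon_MgC_ha`, `carbon_se`.
#' @export
species_structure_table <- function(plots, trees, registry = NULL,
                                    min_dbh_cm = 5,
                                    factors = c(live = 0.48, dead = 0.50)) {
  stopifnot(nrow(plots) >= 1)
  if (!"radius_m" %in% names(plots)) plots$radius_m <- 10
  if (!"subplot_radius_m" %in% names(plots)) plots$subplot_radius_m <- 3
  if (!"in_subplot" %in% names(trees)) trees$in_subplot <- FALSE
  trees <- trees[trees$dbh_cm >= min_dbh_cm, , drop = FALSE]
  has_mass <- all(c("biomass_kg", "carbon_kg") %in% names(trees))
  if (!has_mass && !is.null(registry)) {
    trees <- tree_carbon_table(trees, registry, factors)
    has_mass <- TRUE
  }
  n_plots <- nrow(plots)
  radii <- stats::setNames(plots$radius_m, plots$plot_id)
  sub_radii <- stats::setNames(plots$subplot_radius_m, plots$plot_id)
  unknown <- setdiff(unique(trees$plot_id), plots$plot_id)
  if (length(unknown))
    stop("trees reference unknown plot(s): ",
         paste(unknown, collapse = ", "))
  r_tree <- ifelse(as.logical(trees$in_subplot),
                   sub_radii[trees$plot_id], radii[trees$plot_id])
  ef <- plot_expansion_factor(r_tree)

  dens_m <- per_plot_species(plots, trees, ef)
  ba_m <- per_plot_species(plots, trees, basal_area(trees$dbh_cm) * ef)
  sp <- colnames(dens_m)
  mse <- function(m) list(mean = colMeans(m),
                          se = apply(m, 2, stats::sd) / sqrt(n_plots))
  dens <- mse(dens_m); ba <- mse(ba_m)
  freq <- colMeans(dens_m > 0)

  if (length(sp)) {
    rel <- function(x) if (sum(x) > 0) x / sum(x) else rep(0, length(x))
    ivi <- importance_value(rel(dens$mean), rel(ba$mean), rel(freq))
  } else ivi <- numeric(0)

  count <- vapply(sp, function(s) sum(trees$species == s), integer(1))
  mean_dbh <- vapply(sp, function(s) mean(trees$dbh_cm[trees$species == s]),
                     numeric(1))
  dbh_se <- vapply(sp, function(s) {
    d <- trees$dbh_cm[trees$species == s]
    if (length(d) >= 2) stats::sd(d) / sqrt(length(d)) else 0
  }, numeric(1))
  max_dbh <- vapply(sp, function(s) max(trees$dbh_cm[trees$species == s]),
                    numeric(1))

  if (has_mass) {
    bio_m <- per_plot_species(plots, trees, trees$biomass_kg / 1000 * ef)
    car_m <- per_plot_species(plots, trees, trees$carbon_kg / 1000 * ef)
    bio <- mse(bio_m); car <- mse(car_m)
  } else {
    z <- stats::setNames(rep(NA_real_, length(sp)), sp)
    bio <- car <- list(mean = z, se = z)
  }

  tab <- data.frame(
    species = sp, count = count,
    basal_area_m2_ha = ba$mean, basal_area_se = ba$se,
    density_trees_ha = dens$mean, density_se = dens$se,
    ivi_percent = ivi,
    mean_dbh_cm = mean_dbh, dbh_se = dbh_se, max_dbh_cm = max_dbh,
    biomass_Mg_ha = bio$mean, biomass_se = bio$se,
    carbon_MgC_ha = car$mean, carbon_se = car$se,
    row.names = NULL, stringsAsFactors = FALSE)

  # TOTAL row over all species together (per-plot totals, then mean/SE)
  tot_of <- function(m) {
    v <- rowSums(m)
    c(mean(v), stats::sd(v) / sqrt(n_plots))
  }
  if (nrow(trees)) {
    td <- tot_of(dens_m); tb <- tot_of(ba_m)
    tbio <- if (has_mass) tot_of(per_plot_species(
      plots, trees, trees$biomass_kg / 1000 * ef)) else c(NA, NA)
    tcar <- if (has_mass) tot_of(per_plot_species(
      plots, trees, trees$carbon_kg / 1000 * ef)) else c(NA, NA)
    total <- data.frame(
      species = "TOTAL", count = nrow(trees),
      basal_area_m2_ha = tb[1], basal_area_se = tb[2],
      density_trees_ha = td[1], density_se = td[2],
      ivi_percent = sum(ivi),
      mean_dbh_cm = mean(trees$dbh_cm),
      dbh_se = if (nrow(trees) >= 2)
        stats::sd(trees$dbh_cm) / sqrt(nrow(trees)) else 0,
      max_dbh_cm = max(trees$dbh_cm),
      biomass_Mg_ha = tbio[1], biomass_se = tbio[2],
      carbon_MgC_ha = tcar[1], carbon_se = tcar[2],
      stringsAsFactors = FALSE)
    tab <- rbind(tab, total)
  }
  tab
}

#' Pairwise two-group comparisons of a per-plot metric
#'
#' Runs a Student's t-test for every unordered pair of strata, producing
#' the tidy comparison table used for island sides and tidal zones. No
#' multiple-testing correction is applied (none is applied in the survey
#' protocol this mirrors); note the test count when interpreting p
#' values.
#'
#' @param values per-plot metric values.
#' @param strata stratum label per plot.
#' @param metric metric name recorded in the output.
#' @param welch see [students_t_test()].
#' @return data.frame with `stratum_a`, `stratum_b`, `metric`, `n_a`,
#'   `n_b`, `t`, `df`, `p`.
#' @export
pairwise_t_table <- function(values, strata, metric = "value",
                             welch = FALSE) {
  lev <- sort(unique(as.character(strata)))
  out <- list()
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    if (j <= i) next
    a <- values[strata == lev[i]]; b <- values[strata == lev[j]]
    if (length(a) < 2 || length(b) < 2) next
    tt <- students_t_test(a, b, welch = welch)
    out[[length(out) + 1L]] <- data.frame(
      stratum_a = lev[i], stratum_b = lev[j], metric = metric,
      n_a = length(a), n_b = length(b),
      t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(stratum_a = character(0), stratum_b = character(0),
                      metric = character(0), n_a = integer(0),
                      n_b = integer(0), t = numeric(0), df = numeric(0),
                      p = numeric(0)))
  do.call(rbind, out)
}
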