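#' @title Table and configuration I/O, and the full pipeline
#' @description CSV schemas for plots, trees and transects, YAML
#'   serialization of the allometric registry, and [run_pipeline()] tying
#'   inventory, structure, dominance mapping and upscaling together.
#' @name io_pipeline
NULL

# 32-bit FNV-1a over a string; provenance stamp for report bundles -----

fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Packaged default allometric registry
#'
#' Loads the registry shipped with the package: common-form power-law
#' whole-tree equations (biomass = a * DBH^b with a proportional to
#' wood specific gravity) assembled from the published mangrove
#' allometry literature, plus leaf and main-stem components used by the
#' dead-tree deduction rules. See the registry YAML for per-species
#' coefficients and sources.
#'
#' @return an [allometric_registry()].
#' @export
default_registry <- function() {
  if (!is.null(.mc_cache$registry)) return(.mc_cache$registry)
  path <- system.file("extdata", "allometry_registry.yaml",
                      package = "mangroveCarbon")
  if (path == "") stop("packaged registry not found")
  reg <- read_registry(path)
  .mc_cache$registry <- reg
  reg
}

.mc_cache <- new.env(parent = emptyenv())

#' Write an allometric registry to YAML
#' @param registry an [allometric_registry()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "allometric_registry"))
  tab <- registry$table
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    cf <- tab$coefficients[[i]]
    if (is.character(cf)) cf <- as.numeric(strsplit(cf, "[,;]\\s*")[[1]])
    list(species = tab$species[i], component = tab$component[i],
         form = tab$form[i], coefficients = as.numeric(cf),
         dbh_min = tab$dbh_min[i], dbh_max = tab$dbh_max[i],
         specific_gravity = tab$specific_gravity[i],
         source = tab$source[i])
  })
  yaml::write_yaml(list(models = rows), path)
  invisible(path)
}

#' Read an allometric registry from YAML
#' @param path YAML written by [write_registry()] (or hand-edited with
#'   the same fields).
#' @return an [allometric_registry()].
#' @export
read_registry <- function(path) {
  doc <- yaml::read_yaml(path)
  rows <- doc$models
  if (is.null(rows)) stop("registry YAML has no 'models' list")
  tab <- do.call(rbind, lapply(rows, function(r) {
    data.frame(species = r$species, component = r$component,
               form = r$form,
               coefficients = I(list(as.numeric(unlist(r$coefficients)))),
               dbh_min = if (is.null(r$dbh_min)) NA_real_ else r$dbh_min,
               dbh_max = if (is.null(r$dbh_max)) NA_real_ else r$dbh_max,
               specific_gravity = if (is.null(r$specific_gravity))
                 NA_real_ else r$specific_gravity,
               source = if (is.null(r$source)) NA_character_ else r$source,
               stringsAsFactors = FALSE)
  }))
  allometric_registry(tab)
}

#' Flatten transect tallies to CSV-ready tables
#' @param tallies list (possibly nested per plot) of [transect_tally()].
#' @return list of data.frames `transects` and `large_pieces`.
#' @export
tallies_to_tables <- function(tallies) {
  flat <- list()
  collect <- function(x) {
    if (inherits(x, "transect_tally")) flat[[length(flat) + 1L]] <<- x
    else lapply(x, collect)
    invisible(NULL)
  }
  collect(tallies)
  tr <- do.call(rbind, lapply(flat, function(t) data.frame(
    plot_id = t$plot_id, transect_id = t$transect_id,
    length_fine_m = t$length_m[["fine"]],
    length_small_m = t$length_m[["small"]],
    length_large_m = t$length_m[["large"]],
    fine_count = t$fine_count, small_count = t$small_count,
    fine_qmd_cm = t$fine_qmd_cm, small_qmd_cm = t$small_qmd_cm,
    stringsAsFactors = FALSE)))
  lp <- do.call(rbind, lapply(flat, function(t) {
    if (!nrow(t$large_pieces)) return(NULL)
    cbind(data.frame(plot_id = t$plot_id, transect_id = t$transect_id,
                     stringsAsFactors = FALSE), t$large_pieces)
  }))
  if (is.null(lp))
    lp <- data.frame(plot_id = character(0), transect_id = character(0),
                     diameter_cm = numeric(0), soundness = character(0))
  list(transects = tr, large_pieces = lp)
}

#' Rebuild transect tallies from flat tables
#' @param transects,large_pieces data.frames in the
#'   [tallies_to_tables()] schema.
#' @return named list (by plot id) of lists of [transect_tally()].
#' @export
tables_to_tallies <- function(transects, large_pieces) {
  out <- list()
  for (i in seq_len(nrow(transects))) {
    r <- transects[i, ]
    lp <- large_pieces[large_pieces$plot_id == r$plot_id &
                         large_pieces$transect_id == r$transect_id,
                       c("diameter_cm", "soundness"), drop = FALSE]
    t <- transect_tally(
      plot_id = r$plot_id, transect_id = r$transect_id,
      length_m = c(fine = r$length_fine_m, small = r$length_small_m,
                   large = r$length_large_m),
      fine_count = r$fine_count, small_count = r$small_count,
      fine_qmd_cm = r$fine_qmd_cm, small_qmd_cm = r$small_qmd_cm,
      large_pieces = lp)
    out[[r$plot_id]] <- c(out[[r$plot_id]], list(t))
  }
  out
}

validate_trees <- function(trees, plots = NULL, permissive = TRUE) {
  errs <- character(0)
  bad <- rep(FALSE, nrow(trees))
  chk <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx)) {
      errs <<- c(errs, sprintf("row %d: %s", idx, msg))
      bad[idx] <<- TRUE
    }
  }
  chk(!is.finite(trees$dbh_cm) | trees$dbh_cm <= 0, "non-positive DBH")
  chk(!trees$species %in% c(mangrove_species_codes(), "RHST"),
      "unknown species code")
  chk(!trees$status %in% mortality_status_codes(),
      "unknown mortality status")
  if (!is.null(plots))
    chk(!trees$plot_id %in% plots$plot_id, "unknown plot_id")
  if (length(errs) && !permissive)
    stop("tree table validation failed:\n", paste(errs, collapse = "\n"))
  if (length(errs))
    warning(length(errs), " tree row(s) dropped:\n",
            paste(errs, collapse = "\n"))
  out <- trees[!bad, , drop = FALSE]
  attr(out, "validation_errors") <- errs
  out
}

#' Read plot, tree and transect tables from CSV
#'
#' CSVs are UTF-8, comma-separated, with a mandatory header row.
#' Row-level problems (non-positive DBH, unknown species or status,
#' trees referencing unknown plots, duplicated plot ids) are itemized
#' with row numbers; in permissive mode (default) offending rows are
#' dropped with a warning and listed in the `validation_errors`
#' attribute of the tree table.
#'
#' @param plots_csv,trees_csv paths to the plot and tree tables.
#' @param transects_csv,pieces_csv optional downed-wood tables.
#' @param permissive drop bad rows instead of failing.
#' @return list with `plots`, `trees`, and `tallies` (NULL when no
#'   transect files are given).
#' @export
read_plot_tables <- function(plots_csv, trees_csv, transects_csv = NULL,
                             pieces_csv = NULL, permissive = TRUE) {
  plots <- utils::read.csv(plots_csv, stringsAsFactors = FALSE)
  if (anyDuplicated(plots$plot_id))
    stop("duplicate plot_id in ", plots_csv, ": ",
         paste(unique(plots$plot_id[duplicated(plots$plot_id)]),
               collapse = ", "))
  trees <- utils::read.csv(trees_csv, stringsAsFactors = FALSE)
  if ("in_subplot" %in% names(trees))
    trees$in_subplot <- as.logical(trees$in_subplot)
  trees <- validate_trees(trees, plots, permissive = permissive)
  tallies <- NULL
  if (!is.null(transects_csv)) {
    tr <- utils::read.csv(transects_csv, stringsAsFactors = FALSE)
    lp <- if (!is.null(pieces_csv))
      utils::read.csv(pieces_csv, stringsAsFactors = FALSE)
    else data.frame(plot_id = character(0), transect_id = character(0),
                    diameter_cm = numeric(0), soundness = character(0))
    tallies <- tables_to_tallies(tr, lp)
  }
  list(plots = plots, trees = trees, tallies = tallies)
}

#' Write plot/tree/transect tables as CSV
#' @param inventory list with `plots`, `trees` and optional `tallies`.
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_plot_tables <- function(inventory, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(plots = file.path(dir, "plots.csv"),
             trees = file.path(dir, "trees.csv"))
  utils::write.csv(inventory$plots, paths["plots"], row.names = FALSE)
  utils::write.csv(inventory$trees, paths["trees"], row.names = FALSE)
  if (!is.null(inventory$tallies)) {
    tb <- tallies_to_tables(inventory$tallies)
    paths["transects"] <- file.path(dir, "transects.csv")
    paths["large_pieces"] <- file.path(dir, "large_pieces.csv")
    utils::write.csv(tb$transects, paths["transects"], row.names = FALSE)
    utils::write.csv(tb$large_pieces, paths["large_pieces"],
                     row.names = FALSE)
  }
  invisible(paths)
}

#' Run the full assessment pipeline on synthetic or loaded data
#'
#' Stages: inventory (generate or load) -> tree carbon -> plot standing
#' and downed-wood carbon -> community structure table and stratified
#' comparisons -> dominance labelling, KNN cross-validation and
#' dominance/carbon maps -> extent change ledger. Every stage failure
#' aborts with the stage name; the returned bundle carries the seed and
#' a config hash for provenance.
#'
#' @param config a [sim_config()] driving synthetic generation, or a
#'   list with `plots`, `trees`, `tallies` (and optionally `features`,
#'   `extent`) for pre-loaded data plus a `sim` entry for raster
#'   generation parameters.
#' @param registry an [allometric_registry()].
#' @param k KNN neighbour count.
#' @param cv_folds KNN cross-validation folds.
#' @param include_change compute the extent-change ledger (skipped with
#'   a notice otherwise).
#' @param out_dir optional directory; when given, tables (CSV), grids
#'   (.asc + JSON legend), the ledger (JSON) and a run log are written.
#' @return report bundle (list), invisibly if `out_dir` is given.
#' @export
run_pipeline <- function(config, registry = default_registry(), k = 16,
                         cv_folds = 10, include_change = TRUE,
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (inherits(config, "sim_config")) {
    seed <- config$seed
    inv <- stage("inventory", gen_plot_inventory(config, registry))
    tallies <- stage("downed_wood", gen_downed_wood(config, inv$plots))
    rast <- stage("predictors", gen_predictor_raster(config))
    extent <- if (include_change)
      stage("extent", gen_extent_pair(config)) else NULL
    plots <- inv$plots; trees <- inv$trees
    truth <- inv$truth
  } else {
    seed <- if (!is.null(config$seed)) config$seed else 1
    plots <- config$plots; trees <- config$trees
    tallies <- config$tallies
    rast <- config$rasters
    extent <- if (include_change) config$extent else NULL
    truth <- NULL
  }

  trees_c <- stage("allometry", tree_carbon_table(trees, registry))
  stc <- stage("standing_carbon", vapply(seq_len(nrow(plots)), function(i)
    plot_standing_carbon(plots[i, ],
                         trees_c[trees_c$plot_id == plots$plot_id[i], ,
                                 drop = FALSE]),
    numeric(1)))
  dwc <- if (!is.null(tallies))
    stage("downed_wood_carbon", vapply(
      plots$plot_id, function(p) plot_dwc(tallies[[p]]), numeric(1)))
  else rep(0, nrow(plots))
  agc <- stc + dwc
  n <- length(agc)
  summary_carbon <- data.frame(
    pool = c("STC", "DWC", "AGC"),
    mean_MgC_ha = c(mean(stc), mean(dwc), mean(agc)),
    se = c(stats::sd(stc), stats::sd(dwc), stats::sd(agc)) / sqrt(n))

  structure_tab <- stage("structure",
                         species_structure_table(plots, trees_c))
  comparisons <- stage("comparisons", {
    cmp <- list()
    if ("side" %in% names(plots)) {
      cmp$stc_side <- pairwise_t_table(stc, plots$side, "STC")
      cmp$dwc_side <- pairwise_t_table(dwc, plots$side, "DWC")
    }
    if ("zone" %in% names(plots)) {
      cmp$stc_zone <- pairwise_t_table(stc, plots$zone, "STC")
      cmp$dwc_zone <- pairwise_t_table(dwc, plots$zone, "DWC")
    }
    do.call(rbind, unname(cmp))
  })

  labels <- stage("dominance_labels", dominance_labels(plots, trees_c))
  knn <- dom_grid <- carbon_grid <- density_tab <- NULL
  if (!is.null(rast)) {
    feat_names <- names(rast$features)
    X <- vapply(feat_names, function(f)
      grid_sample(rast$features[[f]], plots$x, plots$y),
      numeric(nrow(plots)))
    colnames(X) <- feat_names
    ok <- !is.na(labels$species) & stats::complete.cases(X)
    kk <- min(k, sum(ok) - 1L)
    knn <- stage("knn", {
      cv <- knn_cross_validate(X[ok, , drop = FALSE],
                               labels$species[ok], k = kk,
                               folds = cv_folds, seed = seed)
      model <- knn_fit(X[ok, , drop = FALSE], labels$species[ok], kk)
      list(model = model, cv_agreement = cv$agreement)
    })
    dom_grid <- stage("dominance_map",
                      predict_dominance_grid(knn$model, rast$features))
    density_tab <- stage("carbon_density", {
      dens_all <- mean(structure_tab$density_trees_ha[
        structure_tab$species == "TOTAL"])
      tab <- suppressMessages(
        species_carbon_density(trees_c, mean_density_trees_ha = dens_all))
      mapped <- unique(attr(dom_grid, "legend")[as.character(
        dom_grid$values[!is.na(dom_grid$values)])])
      gap <- setdiff(mapped, tab$species)
      if (length(gap)) {
        message("assigning all-species mean carbon density to mapped ",
                "species without qualifying trees: ",
                paste(gap, collapse = ", "))
        tab <- rbind(tab, data.frame(
          species = gap, n_trees = 0L,
          mean_tree_carbon_MgC = mean(tab$mean_tree_carbon_MgC),
          carbon_MgC_ha = mean(tab$carbon_MgC_ha)))
      }
      tab
    })
    carbon_grid <- stage("carbon_map", carbon_map(dom_grid, density_tab))
  }

  ledger <- NULL
  if (include_change && !is.null(extent)) {
    ledger <- stage("change_ledger", {
      ar <- area_from_extent_maps(extent$map_t0, extent$map_t1)
      change_ledger(ar$area_t0_ha, ar$loss_ha, ar$gain_ha, mean(agc))
    })
  } else if (include_change) {
    message("no extent maps provided: change ledger skipped")
  }

  bundle <- list(
    plots = plots, trees = trees_c, summary_carbon = summary_carbon,
    plot_carbon = data.frame(plot_id = plots$plot_id, stc_MgC_ha = stc,
                             dwc_MgC_ha = dwc, agc_MgC_ha = agc),
    structure_table = structure_tab, comparisons = comparisons,
    dominance_labels = labels,
    knn_agreement = if (!is.null(knn)) knn$cv_agreement else NA_real_,
    dominance_grid = dom_grid, carbon_density = density_tab,
    carbon_grid = carbon_grid, change_ledger = ledger, truth = truth,
    log = list(seed = seed,
               config_hash = fnv1a_hash(unclass(config)),
               package_version =
                 as.character(utils::packageVersion("mangroveCarbon")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))

  if (!is.null(out_dir)) {
    write_bundle(bundle, out_dir)
    return(invisible(bundle))
  }
  bundle
}

#' Write a pipeline report bundle to disk
#'
#' Tables as CSV, grids as ESRI ASCII with a JSON species legend, the
#' change ledger and run log as JSON (both stamped with seed and config
#' hash).
#'
#' @param bundle result of [run_pipeline()].
#' @param dir output directory.
#' @return vector of written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    w <<- c(w, p)
  }
  wcsv(bundle$plots, "plots.csv")
  wcsv(bundle$trees, "trees.csv")
  wcsv(bundle$plot_carbon, "plot_carbon.csv")
  wcsv(bundle$summary_carbon, "summary_carbon.csv")
  wcsv(bundle$structure_table, "structure_table.csv")
  if (!is.null(bundle$comparisons)) wcsv(bundle$comparisons,
                                         "comparisons.csv")
  wcsv(bundle$dominance_labels, "dominance_labels.csv")
  if (!is.null(bundle$dominance_grid)) {
    p <- file.path(dir, "dominance.asc")
    write_grid_asc(bundle$dominance_grid, p); w <- c(w, p)
    pl <- file.path(dir, "dominance_legend.json")
    jsonlite::write_json(as.list(attr(bundle$dominance_grid, "legend")),
                         pl, auto_unbox = TRUE)
    w <- c(w, pl)
  }
  if (!is.null(bundle$carbon_density)) wcsv(bundle$carbon_density,
                                            "carbon_density.csv")
  if (!is.null(bundle$carbon_grid)) {
    p <- file.path(dir, "carbon.asc")
    write_grid_asc(bundle$carbon_grid, p); w <- c(w, p)
  }
  if (!is.null(bundle$change_ledger)) {
    p <- file.path(dir, "change_ledger.json")
    jsonlite::write_json(
      c(unclass(bundle$change_ledger), bundle$log["config_hash"],
        bundle$log["seed"]),
      p, auto_unbox = TRUE, digits = NA)
    w <- c(w, p)
  }
  p <- file.path(dir, "run_log.json")
  jsonlite::write_json(
    c(bundle$log, list(knn_agreement = bundle$knn_agreement)),
    p, auto_unbox = TRUE, digits = NA)
  w <- c(w, p)
  invisible(w)
}
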