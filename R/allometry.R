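#' @title Species-indexed allometric registry and tree carbon
#' @description Converts individual stems to dry biomass and carbon using a
#'   registry of species allometric equations, with decay-status deductions
#'   for standing dead trees and fixed carbon conversion factors.
#' @name allometry
NULL

#' In-scope mangrove species codes
#'
#' `RHST_MU` pools *Rhizophora stylosa* and *R. mucronata* (not separable
#' without flowers); `RHLA` is the hybrid *R. x lamarckii*; `RH_UNK` is the
#' unidentified-*Rhizophora* category.
#'
#' @return character vector of species codes.
#' @export
mangrove_species_codes <- function() {
  c("BRGY", "LULI", "RHAP", "RHST_MU", "RHLA", "SOAL", "XYGR", "RH_UNK")
}

#' Mortality status codes
#'
#' `LIVE`; `DEAD1` recently dead, leaves lost only; `DEAD2` secondary
#' branches lost; `DEAD3` only the main stem remains.
#'
#' @return character vector of status codes.
#' @export
mortality_status_codes <- function() c("LIVE", "DEAD1", "DEAD2", "DEAD3")

ALLOM_COMPONENTS <- c("WHOLE_TREE", "LEAVES", "MAIN_STEM")

eval_allom <- function(model, dbh_cm) {
  cf <- model$coefficients
  switch(model$form,
    power = cf[1] * dbh_cm^cf[2],
    # log-linear with optional multiplicative bias-correction factor
    log10 = {
      corr <- if (length(cf) >= 3) cf[3] else 1
      corr * 10^(cf[1] + cf[2] * log10(dbh_cm))
    },
    stop("unknown equation form: ", model$form)
  )
}

#' Build an allometric registry
#'
#' The registry maps (species, component) to an equation; lookups apply the
#' field substitution rules: the pooled `RHST_MU` class falls back to an
#' explicit `RHST` (*R. stylosa*) entry, the hybrid `RHLA` falls back to
#' `RHAP` (*R. apiculata*, similar growth form), and `RH_UNK` is evaluated
#' as the unweighted mean of the three resolved *Rhizophora* models.
#'
#' @param table data.frame with columns `species`, `component` (one of
#'   WHOLE_TREE, LEAVES, MAIN_STEM), `form` ("power": B = a * DBH^b, or
#'   "log10": log10 B = a + b log10 DBH with optional third correction
#'   coefficient), `coefficients` (list column, or a string of
#'   comma/semicolon-separated numbers), `dbh_min`, `dbh_max` (cm),
#'   `specific_gravity` (g cm^-3), `source`.
#' @return object of class `allometric_registry`.
#' @export
allometric_registry <- function(table) {
  stopifnot(is.data.frame(table))
  if (!nrow(table)) {
    stop("empty registry: no model for species ",
         paste(setdiff(mangrove_species_codes(), "RH_UNK"), collapse = ", "))
  }
  need <- c("species", "component", "form", "coefficients")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("registry table lacks columns: ", paste(miss, collapse = ", "))
  if (!"dbh_min" %in% names(table)) table$dbh_min <- NA_real_
  if (!"dbh_max" %in% names(table)) table$dbh_max <- NA_real_
  if (!"specific_gravity" %in% names(table))
    table$specific_gravity <- NA_real_
  if (!"source" %in% names(table)) table$source <- NA_character_
  bad <- !table$component %in% ALLOM_COMPONENTS
  if (any(bad))
    stop("unknown component(s): ",
         paste(unique(table$component[bad]), collapse = ", "))
  models <- list()
  for (i in seq_len(nrow(table))) {
    cf <- table$coefficients[[i]]
    if (is.character(cf)) cf <- as.numeric(strsplit(cf, "[,;]\\s*")[[1]])
    cf <- as.numeric(cf)
    if (anyNA(cf)) stop("non-numeric coefficients in registry row ", i)
    key <- paste(table$species[i], table$component[i], sep = "|")
    models[[key]] <- list(
      species = table$species[i], component = table$component[i],
      form = table$form[i], coefficients = cf,
      dbh_range_cm = c(table$dbh_min[i], table$dbh_max[i]),
      wood_specific_gravity = table$specific_gravity[i],
      source = table$source[i])
    sg <- table$specific_gravity[i]
    if (!is.na(sg) && (sg <= 0.1 || sg >= 1.5))
      stop("specific gravity out of (0.1, 1.5) in registry row ", i)
  }
  reg <- structure(list(models = models, table = table),
                   class = "allometric_registry")
  # every in-scope species must resolve a whole-tree model
  unresolved <- Filter(
    function(sp) is.null(tryCatch(resolve_model(reg, sp, "WHOLE_TREE"),
                                  error = function(e) NULL)),
    mangrove_species_codes())
  if (length(unresolved))
    stop("no whole-tree model (after substitutions) for species: ",
         paste(unresolved, collapse = ", "))
  reg
}

#' @export
print.allometric_registry <- function(x, ...) {
  cat(sprintf("allometric_registry: %d models, species: %s\n",
              length(x$models),
              paste(sort(unique(x$table$species)), collapse = ", ")))
  invisible(x)
}

#' Resolve a (species, component) model with substitution rules
#'
#' @param registry an `allometric_registry`.
#' @param species species code.
#' @param component one of WHOLE_TREE, LEAVES, MAIN_STEM.
#' @return a model record, or for `RH_UNK` a composite averaging record.
#' @export
resolve_model <- function(registry, species, component = "WHOLE_TREE") {
  stopifnot(inherits(registry, "allometric_registry"),
            component %in% ALLOM_COMPONENTS)
  key <- function(sp) paste(sp, component, sep = "|")
  m <- registry$models[[key(species)]]
  if (!is.null(m)) return(m)
  if (species == "RHST_MU") {
    m <- registry$models[[key("RHST")]]
    if (!is.null(m)) return(m)
  }
  if (species == "RHLA") {
    m <- registry$models[[key("RHAP")]]
    if (!is.null(m)) return(m)
  }
  if (species == "RH_UNK") {
    parts <- lapply(c("RHAP", "RHST_MU", "RHLA"), function(sp)
      tryCatch(resolve_model(registry, sp, component),
               error = function(e) NULL))
    parts <- Filter(Negate(is.null), parts)
    if (length(parts))
      return(structure(list(species = "RH_UNK", component = component,
                            form = "composite_mean", parts = parts,
                            dbh_range_cm = c(NA_real_, NA_real_)),
                       class = "composite_allom"))
  }
  stop("no ", component, " model for species ", species,
       " and no substitution applies")
}

eval_resolved <- function(model, dbh_cm) {
  if (inherits(model, "composite_allom"))
    return(mean(vapply(model$parts, eval_resolved, numeric(1),
                       dbh_cm = dbh_cm)))
  eval_allom(model, dbh_cm)
}

check_tree <- function(tree) {
  stopifnot(is.list(tree) || is.data.frame(tree))
  if (is.data.frame(tree)) tree <- as.list(tree[1, ])
  if (is.null(tree$dbh_cm) || !is.finite(tree$dbh_cm) || tree$dbh_cm <= 0)
    stop("tree dbh_cm must be a positive number")
  if (!tree$species %in% c(mangrove_species_codes(), "RHST"))
    stop("unknown species code: ", tree$species)
  if (!tree$status %in% mortality_status_codes())
    stop("unknown mortality status: ", tree$status)
  tree
}

in_range <- function(model, dbh) {
  r <- model$dbh_range_cm
  is.na(r[1]) || is.na(r[2]) || (dbh >= r[1] && dbh <= r[2])
}

#' Biomass of a live tree
#'
#' Evaluates the whole-tree equation at the measured DBH. A DBH outside
#' the equation's published validity range is still evaluated (clamping
#' would bias the largest stems) but the result carries an
#' `extrapolated = TRUE` attribute.
#'
#' @param tree list or one-row data.frame with `species`, `dbh_cm`,
#'   `status` (must be `LIVE`).
#' @param registry an `allometric_registry`.
#' @return dry biomass in kg.
#' @export
live_tree_biomass <- function(tree, registry) {
  tree <- check_tree(tree)
  if (tree$status != "LIVE")
    stop("live_tree_biomass called on a ", tree$status, " tree")
  m <- resolve_model(registry, tree$species, "WHOLE_TREE")
  out <- eval_resolved(m, tree$dbh_cm)
  attr(out, "extrapolated") <- !in_range(m, tree$dbh_cm)
  out
}

#' Biomass of a standing dead tree
#'
#' Decay-class deductions: `DEAD1` = whole tree minus leaves; `DEAD2` =
#' 85% of the whole tree; `DEAD3` = the main-stem component only.
#'
#' @inheritParams live_tree_biomass
#' @return dry biomass in kg.
#' @export
dead_tree_biomass <- function(tree, registry) {
  tree <- check_tree(tree)
  if (!tree$status %in% c("DEAD1", "DEAD2", "DEAD3"))
    stop("dead_tree_biomass requires status DEAD1/DEAD2/DEAD3, got ",
         tree$status)
  whole <- resolve_model(registry, tree$species, "WHOLE_TREE")
  w <- eval_resolved(whole, tree$dbh_cm)
  out <- switch(tree$status,
    DEAD1 = {
      lv <- tryCatch(resolve_model(registry, tree$species, "LEAVES"),
                     error = function(e)
                       stop("DEAD1 deduction needs a LEAVES model for ",
                            tree$species, call. = FALSE))
      max(w - eval_resolved(lv, tree$dbh_cm), 0)
    },
    DEAD2 = 0.85 * w,
    DEAD3 = {
      ms <- tryCatch(resolve_model(registry, tree$species, "MAIN_STEM"),
                     error = function(e)
                       stop("DEAD3 needs a MAIN_STEM model for ",
                            tree$species, call. = FALSE))
      eval_resolved(ms, tree$dbh_cm)
    })
  attr(out, "extrapolated") <- !in_range(whole, tree$dbh_cm)
  out
}

#' Convert biomass to carbon mass
#'
#' Live stems use a 0.48 carbon fraction, dead stems (any decay class)
#' 0.50.
#'
#' @param biomass_kg dry biomass, kg (vectorized).
#' @param status mortality status code(s), recycled against `biomass_kg`.
#' @param factors named numeric, carbon fractions for `live` and `dead`.
#' @return carbon mass in kg.
#' @export
tree_carbon <- function(biomass_kg, status,
                        factors = c(live = 0.48, dead = 0.50)) {
  if (any(!is.finite(biomass_kg)) || any(biomass_kg < 0))
    stop("biomass must be finite and >= 0")
  bad <- !status %in% mortality_status_codes()
  if (any(bad)) stop("unknown status: ", paste(unique(status[bad]),
                                               collapse = ", "))
  f <- ifelse(status == "LIVE", factors[["live"]], factors[["dead"]])
  as.numeric(biomass_kg * f)
}

#' Per-tree biomass and carbon for a tree table
#'
#' Vectorized convenience over [live_tree_biomass()], [dead_tree_biomass()]
#' and [tree_carbon()].
#'
#' @param trees data.frame with `plot_id`, `species`, `dbh_cm`, `status`,
#'   and optionally `in_subplot`.
#' @param registry an `allometric_registry`.
#' @param factors carbon fractions, see [tree_carbon()].
#' @return `trees` with added columns `biomass_kg`, `carbon_kg`,
#'   `extrapolated`.
#' @export
tree_carbon_table <- function(trees, registry,
                              factors = c(live = 0.48, dead = 0.50)) {
  n <- nrow(trees)
  biomass <- numeric(n); extra <- logical(n)
  for (i in seq_len(n)) {
    tr <- as.list(trees[i, ])
    b <- if (tr$status == "LIVE") live_tree_biomass(tr, registry)
         else dead_tree_biomass(tr, registry)
    biomass[i] <- as.numeric(b)
    extra[i] <- isTRUE(attr(b, "extrapolated"))
  }
  trees$biomass_kg <- biomass
  trees$carbon_kg <- tree_carbon(biomass, trees$status, factors)
  trees$extrapolated <- extra
  trees
}

#' Per-area expansion factor for a circular plot
#' @param radius_m plot radius in metres.
#' @return trees-per-ha represented by one counted stem (10000 / pi r^2).
#' @export
plot_expansion_factor <- function(radius_m) {
  stopifnot(all(radius_m > 0))
  1e4 / (pi * radius_m^2)
}

#' Standing tree carbon of one plot, per hectare
#'
#' Each stem's carbon is scaled by its per-area expansion factor (full
#' plot radius for stems censused over the whole plot, subplot radius for
#' small stems censused in the nested subplot) and summed.
#'
#' @param plot list or one-row data.frame with `plot_id`, `radius_m`, and
#'   `subplot_radius_m` (defaults 10 m and 3 m).
#' @param trees tree table for this plot (see [tree_carbon_table()]); a
#'   `carbon_kg` column is used if present, otherwise computed.
#' @param registry an `allometric_registry` (needed when carbon must be
#'   computed).
#' @param factors carbon fractions, see [tree_carbon()].
#' @return standing tree carbon in MgC per hectare.
#' @export
plot_standing_carbon <- function(plot, trees, registry = NULL,
                                 factors = c(live = 0.48, dead = 0.50)) {
  if (is.data.frame(plot)) plot <- as.list(plot[1, ])
  r_full <- if (!is.null(plot$radius_m)) plot$radius_m else 10
  r_sub <- if (!is.null(plot$subplot_radius_m)) plot$subplot_radius_m else 3
  if (nrow(trees) == 0) return(0)
  if (!is.null(plot$plot_id) && "plot_id" %in% names(trees) &&
      !all(trees$plot_id == plot$plot_id))
    stop("trees reference a different plot than ", plot$plot_id)
  if (!"carbon_kg" %in% names(trees)) {
    if (is.null(registry)) stop("registry needed to compute tree carbon")
    trees <- tree_carbon_table(trees, registry, factors)
  }
  sub <- if ("in_subplot" %in% names(trees)) as.logical(trees$in_subplot)
         else rep(FALSE, nrow(trees))
  ef <- ifelse(sub, plot_expansion_factor(r_sub),
               plot_expansion_factor(r_full))
  sum(trees$carbon_kg / 1000 * ef)  # kg -> Mg, x trees/ha
}
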