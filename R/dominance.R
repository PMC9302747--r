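#' @title Dominant-species labelling and mapping
#' @description Labels each plot's dominant species (largest basal area),
#'   and maps dominance over a predictor grid with an exact k-nearest-
#'   neighbour classifier (primary) and per-species random-forest models,
#'   with the cross-validation protocols used for model assessment.
#' @name dominance_models
NULL

#' Dominant species of a plot
#'
#' The species with the largest summed live basal area per hectare.
#' Exact ties are broken by live stem count, then lexicographic species
#' code, so labelling is deterministic and invariant to tree row order.
#'
#' @param trees tree table for one plot (`species`, `dbh_cm`, `status`,
#'   optional `in_subplot`).
#' @param radius_m,subplot_radius_m plot geometry for the per-area
#'   expansion.
#' @return list with `species` (NA if the plot has no live tree),
#'   `basal_area_margin` (winner minus runner-up, m^2 ha^-1) and
#'   `ba_by_species`.
#' @export
dominant_species <- function(trees, radius_m = 10, subplot_radius_m = 3) {
  live <- trees[trees$status == "LIVE", , drop = FALSE]
  if (!nrow(live))
    return(list(species = NA_character_, basal_area_margin = NA_real_,
                ba_by_species = numeric(0)))
  sub <- if ("in_subplot" %in% names(live)) as.logical(live$in_subplot)
         else rep(FALSE, nrow(live))
  ef <- ifelse(sub, plot_expansion_factor(subplot_radius_m),
               plot_expansion_factor(radius_m))
  ba <- tapply(basal_area(live$dbh_cm) * ef, live$species, sum)
  cnt <- tapply(rep(1L, nrow(live)), live$species, sum)
  sp <- names(ba)
  ord <- order(-unname(ba), -unname(cnt), sp)
  ba_sorted <- ba[ord]
  margin <- if (length(ba_sorted) > 1)
    unname(ba_sorted[1] - ba_sorted[2]) else unname(ba_sorted[1])
  list(species = sp[ord][1], basal_area_margin = margin,
       ba_by_species = ba)
}

#' Dominance labels for a plot set
#'
#' @param plots plot table (`plot_id`, `radius_m`, `subplot_radius_m`).
#' @param trees tree table with `plot_id`.
#' @return data.frame `plot_id`, `species`, `basal_area_margin`; plots
#'   with no live trees get an `NA` species.
#' @export
dominance_labels <- function(plots, trees) {
  if (!"radius_m" %in% names(plots)) plots$radius_m <- 10
  if (!"subplot_radius_m" %in% names(plots)) plots$subplot_radius_m <- 3
  rows <- lapply(seq_len(nrow(plots)), function(i) {
    tr <- trees[trees$plot_id == plots$plot_id[i], , drop = FALSE]
    d <- dominant_species(tr, plots$radius_m[i], plots$subplot_radius_m[i])
    data.frame(plot_id = plots$plot_id[i], species = d$species,
               basal_area_margin = d$basal_area_margin,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Principal components of a band stack
#'
#' Centred, scaled PCA of co-registered feature bands; constant bands are
#' dropped with a warning. Components are retained up to a cumulative
#' explained-variance target.
#'
#' @param bands named list of `grid_raster` bands, or a numeric matrix
#'   (observations x bands).
#' @param var_target cumulative proportion of variance to retain
#'   (default 0.95); `NULL` keeps all components.
#' @param scale. scale bands to unit variance before rotation.
#' @return for matrix input, a list with `scores`, `rotation`, `center`,
#'   `scale`, `sdev`, `retained`; for raster input the scores are
#'   additionally returned as a named list of `grid_raster` components.
#' @export
pca_composite <- function(bands, var_target = 0.95, scale. = TRUE) {
  as_raster <- inherits(bands, "list") &&
    all(vapply(bands, inherits, logical(1), "grid_raster"))
  if (as_raster) {
    ref <- bands[[1]]
    for (b in bands) stopifnot(grids_aligned(ref, b))
    X <- vapply(bands, function(b) as.vector(b$values),
                numeric(length(ref$values)))
  } else {
    X <- as.matrix(bands)
  }
  if (ncol(X) < 2) stop("PCA needs at least two bands")
  if (any(!is.finite(X))) stop("PCA input must be finite")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant band(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    if (ncol(X) < 2) stop("fewer than two non-constant bands remain")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  prop <- pc$sdev^2 / sum(pc$sdev^2)
  retained <- if (is.null(var_target)) length(prop)
              else max(1L, which(cumsum(prop) >= var_target)[1])
  out <- list(scores = pc$x, rotation = pc$rotation, center = pc$center,
              scale = pc$scale, sdev = pc$sdev,
              prop_variance = prop, retained = retained)
  if (as_raster) {
    d <- dim(ref$values)
    out$score_rasters <- lapply(seq_len(retained), function(j)
      grid_raster(matrix(pc$x[, j], d[1], d[2]),
                  cell_size_m = ref$cell_size_m, origin = ref$origin))
    names(out$score_rasters) <- paste0("pc", seq_len(retained))
  }
  out
}

# standardize a feature matrix against stored (mean, sd) ---------------

zscore_apply <- function(X, center, scale) {
  sweep(sweep(X, 2, center, "-"), 2, scale, "/")
}

#' Fit an exact k-nearest-neighbour dominance classifier
#'
#' Features are z-score standardized (a feature's scale then cannot
#' drive the Euclidean metric); zero-variance features are dropped with a
#' warning. Prediction takes the majority species among the k nearest
#' training plots; vote ties go to the tied class of the nearest single
#' neighbour.
#'
#' @param features numeric matrix (plots x features), column names
#'   required.
#' @param labels species code per training row.
#' @param k neighbour count (default 16).
#' @return object of class `knn_dominance`.
#' @export
knn_fit <- function(features, labels, k = 16) {
  X <- as.matrix(features)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  keep <- !is.na(labels) & stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]; labels <- labels[keep]
  if (k > nrow(X)) stop("k (", k, ") exceeds training size (", nrow(X), ")")
  mu <- colMeans(X); sd <- apply(X, 2, stats::sd)
  if (any(sd == 0)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(X)[sd == 0], collapse = ", "))
    X <- X[, sd > 0, drop = FALSE]
    mu <- mu[sd > 0]; sd <- sd[sd > 0]
    if (!ncol(X)) stop("no non-constant features remain")
  }
  structure(list(k = as.integer(k), X = zscore_apply(X, mu, sd),
                 labels = labels, center = mu, scale = sd,
                 features = colnames(X)),
            class = "knn_dominance")
}

#' @export
print.knn_dominance <- function(x, ...) {
  cat(sprintf("knn_dominance: k = %d, n = %d, %d features (%s)\n",
              x$k, nrow(x$X), length(x$features),
              paste(x$features, collapse = ", ")))
  invisible(x)
}

#' Predict dominant species with a fitted KNN model
#'
#' @param object a `knn_dominance` model.
#' @param newdata matrix or data.frame of features; must contain the
#'   training feature columns. Rows with missing values predict `NA`.
#' @param ... unused.
#' @return character vector of species codes.
#' @export
predict.knn_dominance <- function(object, newdata, ...) {
  Q <- as.matrix(newdata)
  if (is.null(colnames(Q)) && ncol(Q) == length(object$features))
    colnames(Q) <- object$features
  miss <- setdiff(object$features, colnames(Q))
  if (length(miss))
    stop("newdata lacks feature(s): ", paste(miss, collapse = ", "))
  Q <- Q[, object$features, drop = FALSE]
  out <- rep(NA_character_, nrow(Q))
  ok <- stats::complete.cases(Q)
  if (!any(ok)) return(out)
  Qz <- zscore_apply(Q[ok, , drop = FALSE], object$center, object$scale)
  X <- object$X; lab <- object$labels; k <- object$k
  # squared Euclidean distances, chunked to bound memory
  n <- nrow(Qz)
  pred <- character(n)
  x2 <- rowSums(X^2)
  chunk <- max(1L, floor(4e6 / nrow(X)))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    D <- outer(rowSums(Qz[s:e, , drop = FALSE]^2), x2, "+") -
      2 * Qz[s:e, , drop = FALSE] %*% t(X)
    for (i in seq_len(e - s + 1L)) {
      ord <- order(D[i, ])[seq_len(k)]
      votes <- table(lab[ord])
      top <- names(votes)[votes == max(votes)]
      pred[s + i - 1L] <- if (length(top) == 1L) top else {
        # nearest neighbour belonging to a tied class decides
        lab[ord][lab[ord] %in% top][1]
      }
    }
  }
  out[ok] <- pred
  out
}

#' Cross-validated agreement of the KNN dominance model
#'
#' Random (seeded) assignment of plots to folds; per fold, the model is
#' fit on the remaining plots and agreement is the fraction of held-out
#' plots whose dominant species is predicted correctly; the reported
#' value averages the fold agreements.
#'
#' @param features,labels,k see [knn_fit()].
#' @param folds number of CV folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return list with `agreement` (mean over folds), `fold_agreement`,
#'   `predictions` (out-of-fold prediction per plot).
#' @export
knn_cross_validate <- function(features, labels, k = 16, folds = 10,
                               seed = 1) {
  X <- as.matrix(features)
  labels <- as.character(labels)
  n <- nrow(X)
  if (n < folds) stop("need at least as many plots as folds")
  set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = n))
  pred <- rep(NA_character_, n)
  fa <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    kf <- min(k, sum(tr))
    m <- suppressWarnings(knn_fit(X[tr, , drop = FALSE], labels[tr], kf))
    pred[!tr] <- predict(m, X[!tr, , drop = FALSE])
    fa[f] <- mean(pred[!tr] == labels[!tr])
  }
  list(agreement = mean(fa), fold_agreement = fa, predictions = pred)
}

#' Specification for a per-species random-forest model
#'
#' @param species species code the model targets.
#' @param n_trees ensemble size (default 1000).
#' @param balancing `"AUTO"` (class-balanced sampling when the dominant
#'   fraction falls below `imbalance_cutoff`), `"PLAIN"`, or
#'   `"CLASS_BALANCED"`.
#' @param imbalance_cutoff dominant-plot fraction below which AUTO
#'   switches to class-balanced sampling (default 0.2).
#' @return list of class `rf_spec`.
#' @export
rf_spec <- function(species, n_trees = 1000,
                    balancing = c("AUTO", "PLAIN", "CLASS_BALANCED"),
                    imbalance_cutoff = 0.2) {
  balancing <- match.arg(balancing)
  stopifnot(n_trees >= 1, imbalance_cutoff > 0, imbalance_cutoff < 1)
  structure(list(species = species, n_trees = as.integer(n_trees),
                 balancing = balancing,
                 imbalance_cutoff = imbalance_cutoff),
            class = "rf_spec")
}

#' Dominance threshold maximizing sensitivity + specificity
#'
#' Scans every achievable cut-point on predicted dominance
#' probabilities; a case is called dominant when its probability is >=
#' the threshold. Ties on the Youden criterion go to the highest (most
#' specific) threshold.
#'
#' @param prob predicted probabilities of dominance.
#' @param truth logical, actual dominance.
#' @return list with `threshold`, `sensitivity`, `specificity`.
#' @export
rf_best_threshold <- function(prob, truth) {
  stopifnot(length(prob) == length(truth), any(truth), any(!truth))
  cand <- sort(unique(c(0, prob)))
  best <- NULL
  for (th in cand) {
    call <- prob >= th
    sens <- sum(call & truth) / sum(truth)
    spec <- sum(!call & !truth) / sum(!truth)
    j <- sens + spec
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && th > best$threshold))
      best <- list(threshold = th, sensitivity = sens,
                   specificity = spec, j = j)
  }
  best[c("threshold", "sensitivity", "specificity")]
}

#' Train a per-species random-forest dominance model
#'
#' Binary classification (dominant vs not) with `n_trees` trees grown on
#' subsamples drawn without replacement (out-of-bag fraction then
#' emerges near 37%). When the species is dominant in fewer than
#' `imbalance_cutoff` of the plots (AUTO) or when requested, both
#' classes are subsampled to the minority class size (balanced
#' bootstrap). The dominance threshold maximizes sensitivity +
#' specificity on out-of-bag predictions.
#'
#' @param labels species code per plot (the plot's dominant species).
#' @param features numeric feature matrix (plots x features).
#' @param spec an [rf_spec()].
#' @param seed integer seed.
#' @return object of class `rf_dominance` (fields `forest`, `threshold`,
#'   `oob_sensitivity`, `oob_specificity`, `balancing_used`), or an
#'   object of class `rf_skip` with a message when the species is never
#'   (or always) dominant.
#' @export
rf_train_species <- function(labels, features, spec, seed = 1) {
  stopifnot(inherits(spec, "rf_spec"))
  y <- factor(ifelse(labels == spec$species, "dom", "other"),
              levels = c("other", "dom"))
  if (length(unique(y)) < 2) {
    return(structure(
      list(species = spec$species,
           reason = sprintf("species %s dominant in %d of %d plots",
                            spec$species, sum(y == "dom"), length(y))),
      class = "rf_skip"))
  }
  X <- as.matrix(features)
  frac_dom <- mean(y == "dom")
  balanced <- spec$balancing == "CLASS_BALANCED" ||
    (spec$balancing == "AUTO" && frac_dom < spec$imbalance_cutoff)
  set.seed(seed)
  if (balanced) {
    # equal per-class draws at the without-replacement bootstrap rate of
    # the minority class, so both classes retain out-of-bag coverage
    m <- max(1L, ceiling(0.632 * min(table(y))))
    fit <- randomForest::randomForest(
      x = X, y = y, ntree = spec$n_trees, replace = FALSE,
      sampsize = c(other = m, dom = m), strata = y)
  } else {
    fit <- randomForest::randomForest(
      x = X, y = y, ntree = spec$n_trees, replace = FALSE)
  }
  # rows that never landed out-of-bag have undefined vote fractions
  covered <- fit$oob.times > 0 & is.finite(fit$votes[, "dom"])
  thr <- rf_best_threshold(fit$votes[covered, "dom"],
                           (y == "dom")[covered])
  structure(list(species = spec$species, forest = fit,
                 threshold = thr$threshold,
                 oob_sensitivity = thr$sensitivity,
                 oob_specificity = thr$specificity,
                 balancing_used = if (balanced) "CLASS_BALANCED"
                                  else "PLAIN"),
            class = "rf_dominance")
}

#' @export
print.rf_skip <- function(x, ...) {
  cat("rf model skipped:", x$reason, "\n"); invisible(x)
}

#' @export
print.rf_dominance <- function(x, ...) {
  cat(sprintf(
    "rf_dominance[%s]: %s sampling, threshold %.3f (OOB sens %.2f, spec %.2f)\n",
    x$species, x$balancing_used, x$threshold, x$oob_sensitivity,
    x$oob_specificity))
  invisible(x)
}

#' Predict species dominance probability / call with a per-species RF
#' @param object an `rf_dominance` model.
#' @param newdata feature matrix.
#' @param type `"prob"` for dominance probability, `"call"` for the
#'   thresholded logical call.
#' @param ... unused.
#' @return numeric probabilities or logical calls.
#' @export
predict.rf_dominance <- function(object, newdata,
                                 type = c("prob", "call"), ...) {
  type <- match.arg(type)
  p <- stats::predict(object$forest, newdata = as.matrix(newdata),
                      type = "prob")[, "dom"]
  if (type == "prob") unname(p) else unname(p >= object$threshold)
}

#' Repeated split cross-validation of a per-species RF model
#'
#' Repeated random 90/10 train/test splits; each rep trains a forest on
#' the training split and scores sensitivity, specificity and accuracy
#' on the held-out split using the training-OOB threshold.
#'
#' @param labels,features,spec see [rf_train_species()].
#' @param reps number of random splits (protocol default 1000; scale
#'   down for quick checks).
#' @param test_fraction held-out fraction per rep (default 0.1).
#' @param seed integer seed.
#' @return data.frame with one row per evaluable rep: `rep`,
#'   `sensitivity`, `specificity`, `accuracy`.
#' @export
rf_cross_validate <- function(labels, features, spec, reps = 1000,
                              test_fraction = 0.1, seed = 1) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 10) stop("need at least 10 plots")
  truth_all <- labels == spec$species
  set.seed(seed)
  rows <- list()
  for (r in seq_len(reps)) {
    test <- sample.int(n, max(1L, round(test_fraction * n)))
    fit <- rf_train_species(labels[-test], X[-test, , drop = FALSE],
                            spec, seed = sample.int(2^30, 1))
    if (inherits(fit, "rf_skip")) next
    call <- predict(fit, X[test, , drop = FALSE], type = "call")
    truth <- truth_all[test]
    rows[[length(rows) + 1L]] <- data.frame(
      rep = r,
      sensitivity = if (any(truth)) mean(call[truth]) else NA_real_,
      specificity = if (any(!truth)) mean(!call[!truth]) else NA_real_,
      accuracy = mean(call == truth))
  }
  do.call(rbind, rows)
}

#' Map dominance over a predictor grid with a fitted KNN model
#'
#' @param model a `knn_dominance` model.
#' @param grid named list of `grid_raster` feature bands covering the
#'   model's training features; cells with any missing predictor map to
#'   no-data.
#' @return a `grid_raster` of integer species codes with a
#'   `legend` attribute (code -> species) and the input georeference.
#' @export
predict_dominance_grid <- function(model, grid) {
  stopifnot(inherits(model, "knn_dominance"), is.list(grid))
  miss <- setdiff(model$features, names(grid))
  if (length(miss))
    stop("predictor grid lacks band(s): ", paste(miss, collapse = ", "))
  ref <- grid[[model$features[1]]]
  for (f in model$features)
    if (!grids_aligned(ref, grid[[f]]))
      stop("band ", f, " is not co-registered with the other bands")
  X <- vapply(model$features, function(f) as.vector(grid[[f]]$values),
              numeric(length(ref$values)))
  colnames(X) <- model$features
  pred <- predict(model, X)
  legend <- sort(unique(model$labels))
  codes <- match(pred, legend)
  out <- grid_raster(matrix(as.numeric(codes), nrow(ref$values),
                            ncol(ref$values)),
                     cell_size_m = ref$cell_size_m, origin = ref$origin)
  attr(out, "legend") <- stats::setNames(legend, seq_along(legend))
  out
}
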