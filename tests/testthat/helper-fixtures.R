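# shared fixtures and independent oracles, built in code

# synthetic registry with stated test models: whole tree B = 0.2 D^2.4,
# leaves 4% and main stem 60% of that power law, for every species code
# (RHST_MU/RHLA resolve via substitution: only RHST and RHAP rows exist
# for Rhizophora)
syn_registry <- function(a = 0.2, b = 2.4) {
  sp <- c("BRGY", "LULI", "RHAP", "RHST", "SOAL", "XYGR")
  rows <- do.call(rbind, lapply(sp, function(s) data.frame(
    species = s,
    component = c("WHOLE_TREE", "LEAVES", "MAIN_STEM"),
    form = "power",
    coefficients = I(list(c(a, b), c(0.04 * a, b), c(0.6 * a, b))),
    dbh_min = 5, dbh_max = 50, specific_gravity = 0.7,
    source = "synthetic test model", stringsAsFactors = FALSE)))
  allometric_registry(rows)
}

# unit-coefficient registry where whole(10 cm) = 100 kg exactly
unit_registry <- function() {
  rows <- data.frame(
    species = rep("BRGY", 3),
    component = c("WHOLE_TREE", "LEAVES", "MAIN_STEM"),
    form = "power",
    coefficients = I(list(c(1, 2), c(0.04, 2), c(0.6, 2))),
    dbh_min = 5, dbh_max = 50, specific_gravity = 0.7,
    source = "unit test model", stringsAsFactors = FALSE)
  rows2 <- rows
  rows2$species <- "RHAP"
  reg <- rbind(rows, rows2)
  # remaining species resolve through RHAP-style duplicates
  for (s in c("LULI", "RHST", "SOAL", "XYGR")) {
    r <- rows; r$species <- s; reg <- rbind(reg, r)
  }
  allometric_registry(reg)
}

mk_tree <- function(species = "BRGY", dbh = 10, status = "LIVE",
                    plot_id = "P1", in_subplot = FALSE) {
  list(plot_id = plot_id, species = species, dbh_cm = dbh,
       status = status, in_subplot = in_subplot)
}

# Monte-Carlo line-intersect oracle: random horizontal cylinders on a
# plane, sampled by a transect line; returns mean planar-intercept
# volume estimate, its SE, and the true volume density (m^3/ha)
cylinder_field_oracle <- function(n_rep = 1e4, lambda_m2 = 0.02,
                                  diam_cm = 10, len_m = 1,
                                  transect_len = 50, domain = 100,
                                  seed = 99) {
  set.seed(seed)
  n_pieces <- stats::rpois(n_rep, lambda_m2 * domain^2)
  tot <- sum(n_pieces)
  rep_id <- rep.int(seq_len(n_rep), n_pieces)
  cx <- stats::runif(tot, 0, domain)
  cy <- stats::runif(tot, 0, domain)
  th <- stats::runif(tot, 0, pi)
  dx <- cos(th) * len_m / 2; dy <- sin(th) * len_m / 2
  y1 <- cy - dy; y2 <- cy + dy
  yline <- domain / 2
  crosses <- (y1 - yline) * (y2 - yline) < 0
  # x where the axis crosses the transect's y
  tfrac <- (yline - y1) / (y2 - y1)
  xc <- (cx - dx) + tfrac * 2 * dx
  x0 <- (domain - transect_len) / 2
  hit <- crosses & xc >= x0 & xc <= x0 + transect_len
  hits_per_rep <- tabulate(rep_id[hit], nbins = n_rep)
  est <- pi^2 * hits_per_rep * diam_cm^2 / (8 * transect_len)
  true_v <- lambda_m2 * (pi * (diam_cm / 100)^2 / 4 * len_m) * 1e4
  list(mean = mean(est), se = stats::sd(est) / sqrt(n_rep),
       true_volume_m3_ha = true_v)
}

# exhaustive-distance KNN oracle: per-query loops, z-scoring against
# training moments, majority vote, tie -> nearest tied-class neighbour
knn_oracle <- function(train_X, train_y, query_X, k) {
  mu <- colMeans(train_X)
  sd <- apply(train_X, 2, stats::sd)
  tz <- sweep(sweep(train_X, 2, mu), 2, sd, "/")
  qz <- sweep(sweep(query_X, 2, mu), 2, sd, "/")
  out <- character(nrow(qz))
  for (i in seq_len(nrow(qz))) {
    d <- numeric(nrow(tz))
    for (j in seq_len(nrow(tz)))
      d[j] <- sqrt(sum((qz[i, ] - tz[j, ])^2))
    ord <- order(d)[seq_len(k)]
    tab <- table(train_y[ord])
    top <- names(tab)[tab == max(tab)]
    out[i] <- if (length(top) == 1) top
              else train_y[ord][train_y[ord] %in% top][1]
  }
  out
}

# brute-force scan over a dense cut-point grid plus all achievable
# probabilities; returns the best achievable Youden operating point
threshold_oracle <- function(prob, truth) {
  cand <- sort(unique(c(0, seq(0, 1, by = 1e-3), prob)))
  best_j <- -Inf; best <- NULL
  for (th in cand) {
    call <- prob >= th
    sens <- sum(call & truth) / sum(truth)
    spec <- sum(!call & !truth) / sum(!truth)
    if (sens + spec > best_j + 1e-12) {
      best_j <- sens + spec
      best <- c(threshold = th, sensitivity = sens, specificity = spec)
    }
  }
  best
}

# small synthetic config for fast tests
small_config <- function(seed = 1, ...) {
  sim_config(n_plots = 40, grid_shape = c(60, 60), seed = seed, ...)
}

# strong-signal configuration: four balanced species, long correlation
# length, near-noiseless tidal sorting (the separability study condition)
strong_signal_config <- function(seed = 1, grid = c(120, 120)) {
  sim_config(
    seed = seed, grid_shape = grid,
    species_mix = c(BRGY = 0.25, RHAP = 0.25, SOAL = 0.25, XYGR = 0.25),
    spatial_corr_length_m = 100, dominance_noise = 0.05)
}
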