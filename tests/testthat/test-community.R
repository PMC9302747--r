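test_that("zone classification follows the 30 m rules", {
  expect_equal(classify_zone(20, 900), "SEAWARD")
  expect_equal(classify_zone(500, 25), "LANDWARD")
  expect_equal(classify_zone(31, 31), "INTERIOR")
  # boundary: exactly 30 m counts as inside the zone
  expect_equal(classify_zone(30, 900), "SEAWARD")
  expect_equal(classify_zone(40, 30), "LANDWARD")
  # coast wins when both distances are small
  expect_equal(classify_zone(10, 10), "SEAWARD")
  expect_error(classify_zone(NA, 10), "missing")
})

test_that("every plot receives exactly one zone", {
  set.seed(3)
  d1 <- runif(200, 0, 400); d2 <- runif(200, 0, 400)
  z <- classify_zone(d1, d2)
  expect_true(all(z %in% c("SEAWARD", "INTERIOR", "LANDWARD")))
  expect_length(z, 200)
})

test_that("basal area follows the quadratic closed form", {
  expect_equal(basal_area(20), pi * 0.01, tolerance = 1e-12)
  expect_equal(basal_area(20), 0.0314159, tolerance = 1e-6)
  expect_equal(basal_area(40) / basal_area(20), 4)
  expect_lt(basal_area(1e-6), 1e-12)
  expect_error(basal_area(0), "> 0")
})

test_that("importance value composes relative measures to percent", {
  expect_equal(importance_value(1, 1, 1), 100)
  expect_equal(importance_value(c(0.8, 0.2), c(0.6, 0.4), c(0.4, 0.6)),
               c(60, 40))
  expect_equal(sum(importance_value(c(0.8, 0.2), c(0.6, 0.4),
                                    c(0.4, 0.6))), 100)
  expect_error(importance_value(c(0.5, 0.4), c(0.5, 0.5), c(0.5, 0.5)),
               "sum to 1")
})

test_that("stratified means return mean and SE with n-1 denominator", {
  out <- stratified_means(c(1, 2, 3), rep("A", 3))
  expect_equal(out$mean, 2)
  expect_equal(out$se, 0.57735, tolerance = 1e-5)
  one <- stratified_means(5, "A")
  expect_equal(one$se, 0)
  expect_warning(
    stratified_means(c(1, 2), factor(c("A", "A"), levels = c("A", "B"))),
    "empty stratum")
})

test_that("weighted stratum means recompose the pooled mean", {
  set.seed(11)
  v <- rnorm(60)
  s <- sample(c("A", "B", "C"), 60, replace = TRUE)
  out <- stratified_means(v, s)
  expect_equal(sum(out$mean * out$n) / sum(out$n), mean(v),
               tolerance = 1e-12)
})

test_that("pooled Student's t matches the textbook case", {
  tt <- students_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t, -3.6742, tolerance = 1e-4)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 0.02131, tolerance = 1e-4)
  # swapping groups negates t, preserves p
  rev <- students_t_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rev$t, -tt$t)
  expect_equal(rev$p, tt$p)
  # degenerate contracts
  same <- students_t_test(c(2, 2), c(2, 2))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  expect_error(students_t_test(c(2, 2), c(3, 3)), "zero variance")
  # welch option changes df
  tw <- students_t_test(c(1, 2, 3), c(4, 5, 6, 7, 8), welch = TRUE)
  expect_false(isTRUE(all.equal(tw$df, 6)))
})

test_that("structure table matches an independent hand computation", {
  plots <- data.frame(plot_id = c("P1", "P2"), radius_m = 10,
                      subplot_radius_m = 3, stringsAsFactors = FALSE)
  trees <- data.frame(
    plot_id = c("P1", "P1", "P1", "P2"),
    species = c("A", "A", "B", "A"),
    dbh_cm = c(10, 20, 30, 15),
    status = "LIVE", in_subplot = FALSE, stringsAsFactors = FALSE)
  tab <- species_structure_table(plots, trees)
  ef <- 1e4 / (pi * 100)  # 31.83099 trees/ha per stem
  # spreadsheet arithmetic, written out independently
  dens_A <- c(2 * ef, 1 * ef); dens_B <- c(ef, 0)
  ba_A <- c((10^2 + 20^2) / 400, 15^2 / 400)  # BA/ha = d^2/400 here
  ba_B <- c(30^2 / 400, 0)
  a <- tab[tab$species == "A", ]; b <- tab[tab$species == "B", ]
  expect_equal(a$density_trees_ha, mean(dens_A), tolerance = 1e-10)
  expect_equal(a$density_se, sd(dens_A) / sqrt(2), tolerance = 1e-10)
  expect_equal(b$density_trees_ha, mean(dens_B), tolerance = 1e-10)
  expect_equal(a$basal_area_m2_ha, mean(ba_A), tolerance = 1e-10)
  expect_equal(b$basal_area_m2_ha, mean(ba_B), tolerance = 1e-10)
  expect_equal(a$count, 3); expect_equal(b$count, 1)
  expect_equal(a$mean_dbh_cm, 15); expect_equal(a$max_dbh_cm, 20)
  rd <- mean(dens_A) / (mean(dens_A) + mean(dens_B))
  rba <- mean(ba_A) / (mean(ba_A) + mean(ba_B))
  rf <- 1 / (1 + 0.5)
  expect_equal(a$ivi_percent, 100 * (rd + rba + rf) / 3,
               tolerance = 1e-10)
  tot <- tab[tab$species == "TOTAL", ]
  expect_equal(tot$ivi_percent, 100, tolerance = 1e-9)
  expect_equal(tot$density_trees_ha, mean(c(3 * ef, ef)),
               tolerance = 1e-10)
})

test_that("single-species plot takes the whole importance value", {
  plots <- data.frame(plot_id = "P1", radius_m = 10,
                      subplot_radius_m = 3)
  trees <- data.frame(plot_id = "P1", species = "SOAL", dbh_cm = 22,
                      status = "LIVE", in_subplot = FALSE)
  tab <- species_structure_table(plots, trees)
  expect_equal(tab$ivi_percent[tab$species == "SOAL"], 100)
})

test_that("total density equals the sum of species densities", {
  cfg <- small_config(seed = 8)
  inv <- gen_plot_inventory(cfg, registry = NULL)
  tab <- species_structure_table(inv$plots, inv$trees)
  sp_rows <- tab[tab$species != "TOTAL", ]
  tot <- tab[tab$species == "TOTAL", ]
  expect_equal(sum(sp_rows$density_trees_ha), tot$density_trees_ha,
               tolerance = 1e-9)
  expect_equal(sum(sp_rows$ivi_percent), 100, tolerance = 1e-9)
})

test_that("pairwise comparisons produce one row per stratum pair", {
  set.seed(4)
  v <- rnorm(30)
  z <- rep(c("SEAWARD", "INTERIOR", "LANDWARD"), each = 10)
  out <- pairwise_t_table(v, z, metric = "STC")
  expect_equal(nrow(out), 3)
  expect_true(all(out$metric == "STC"))
  expect_true(all(out$df == 18))
})
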