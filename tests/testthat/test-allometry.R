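test_that("power-law whole-tree biomass evaluates in closed form", {
  reg <- syn_registry(a = 0.2, b = 2.4)
  b <- live_tree_biomass(mk_tree("BRGY", 10), reg)
  expect_equal(as.numeric(b), 0.2 * 10^2.4, tolerance = 1e-12)
  expect_equal(as.numeric(b), 50.2377, tolerance = 1e-4)
  expect_false(attr(b, "extrapolated"))
})

test_that("out-of-range DBH is evaluated continuously and flagged", {
  reg <- syn_registry()
  at_max <- live_tree_biomass(mk_tree(dbh = 50), reg)
  eps <- 1e-4
  above <- live_tree_biomass(mk_tree(dbh = 50 + eps), reg)
  slope <- 0.2 * 2.4 * 50^1.4
  expect_lt(abs(as.numeric(above) - as.numeric(at_max)),
            slope * eps * 1.01)
  expect_false(attr(at_max, "extrapolated"))
  expect_true(attr(above, "extrapolated"))
})

test_that("biomass is increasing in DBH across the whole registry", {
  for (reg in list(syn_registry(), default_registry())) {
    for (sp in mangrove_species_codes()) {
      grid <- seq(5, 300, by = 5)
      vals <- vapply(grid, function(d)
        as.numeric(live_tree_biomass(mk_tree(sp, d), reg)), numeric(1))
      expect_true(all(diff(vals) > 0), label = paste("monotone", sp))
      expect_gt(as.numeric(live_tree_biomass(mk_tree(sp, 20), reg)),
                as.numeric(live_tree_biomass(mk_tree(sp, 10), reg)))
    }
  }
})

test_that("dead-tree deductions follow the decay-status rules", {
  reg <- unit_registry()  # whole(10) = 100, leaves = 4, main stem = 60
  expect_equal(as.numeric(dead_tree_biomass(mk_tree(dbh = 10,
                                                    status = "DEAD2"),
                                            reg)), 85)
  expect_equal(as.numeric(dead_tree_biomass(mk_tree(dbh = 10,
                                                    status = "DEAD1"),
                                            reg)), 96)
  expect_equal(as.numeric(dead_tree_biomass(mk_tree(dbh = 10,
                                                    status = "DEAD3"),
                                            reg)), 60)
  expect_error(dead_tree_biomass(mk_tree(dbh = 10, status = "LIVE"), reg),
               "DEAD")
})

test_that("dead statuses never exceed the live whole-tree biomass", {
  reg <- default_registry()
  for (sp in c("BRGY", "SOAL", "RHST_MU", "RH_UNK")) {
    for (d in c(6, 15, 40, 120)) {
      live <- as.numeric(live_tree_biomass(mk_tree(sp, d), reg))
      for (st in c("DEAD1", "DEAD2", "DEAD3")) {
        dead <- as.numeric(dead_tree_biomass(mk_tree(sp, d, st), reg))
        expect_lte(dead, live)
      }
    }
  }
})

test_that("carbon conversion uses 0.48 live and 0.50 dead", {
  expect_equal(tree_carbon(100, "LIVE"), 48)
  expect_equal(tree_carbon(100, "DEAD2"), 50)
  expect_equal(tree_carbon(0, "LIVE"), 0)
  expect_equal(tree_carbon(c(100, 100), c("LIVE", "DEAD3")), c(48, 50))
  expect_error(tree_carbon(-1, "LIVE"), ">= 0")
})

test_that("species substitution rules resolve pooled and hybrid codes", {
  reg <- syn_registry()  # has RHST and RHAP rows only
  m_st <- resolve_model(reg, "RHST_MU")
  expect_equal(m_st$species, "RHST")
  m_la <- resolve_model(reg, "RHLA")
  expect_equal(m_la$species, "RHAP")
  # substitution idempotence: pooled label gives the R. stylosa value
  b1 <- live_tree_biomass(mk_tree("RHST_MU", 17), reg)
  b2 <- live_tree_biomass(mk_tree("RHST", 17), reg)
  expect_equal(as.numeric(b1), as.numeric(b2))
  # unknown Rhizophora = unweighted mean of the resolved models
  b_unk <- as.numeric(live_tree_biomass(mk_tree("RH_UNK", 17), reg))
  parts <- c(as.numeric(live_tree_biomass(mk_tree("RHAP", 17), reg)),
             as.numeric(live_tree_biomass(mk_tree("RHST_MU", 17), reg)),
             as.numeric(live_tree_biomass(mk_tree("RHLA", 17), reg)))
  expect_equal(b_unk, mean(parts))
})

test_that("missing models raise informative errors", {
  tab <- data.frame(species = "BRGY", component = "WHOLE_TREE",
                    form = "power", coefficients = I(list(c(0.2, 2.4))),
                    stringsAsFactors = FALSE)
  expect_error(allometric_registry(tab), "no whole-tree model")
  expect_error(allometric_registry(data.frame()), "empty registry")
  reg <- allometric_registry(data.frame(
    species = c("BRGY", "LULI", "RHAP", "RHST", "SOAL", "XYGR"),
    component = "WHOLE_TREE", form = "power",
    coefficients = I(replicate(6, c(0.2, 2.4), simplify = FALSE)),
    stringsAsFactors = FALSE))
  expect_error(dead_tree_biomass(mk_tree(dbh = 10, status = "DEAD1"), reg),
               "LEAVES")
  expect_error(dead_tree_biomass(mk_tree(dbh = 10, status = "DEAD3"), reg),
               "MAIN_STEM")
})

test_that("plot standing carbon applies circular expansion factors", {
  plot <- list(plot_id = "P1", radius_m = 10, subplot_radius_m = 3)
  trees <- data.frame(plot_id = "P1", species = "BRGY", dbh_cm = 10,
                      status = "LIVE", in_subplot = FALSE,
                      carbon_kg = 100)
  expect_equal(plot_standing_carbon(plot, trees),
               0.100 * 1e4 / (pi * 100), tolerance = 1e-10)
  expect_equal(plot_standing_carbon(plot, trees), 3.1831,
               tolerance = 1e-4)
  trees$in_subplot <- TRUE
  expect_equal(plot_standing_carbon(plot, trees), 35.368,
               tolerance = 1e-4)
  empty <- trees[0, ]
  expect_equal(plot_standing_carbon(plot, empty), 0)
})

test_that("plot standing carbon is additive over disjoint tree subsets", {
  reg <- syn_registry()
  set.seed(5)
  trees <- data.frame(
    plot_id = "P1",
    species = sample(c("BRGY", "SOAL", "RHAP"), 20, replace = TRUE),
    dbh_cm = runif(20, 5, 60),
    status = sample(mortality_status_codes(), 20, replace = TRUE),
    in_subplot = FALSE, stringsAsFactors = FALSE)
  plot <- list(plot_id = "P1", radius_m = 10, subplot_radius_m = 3)
  whole <- plot_standing_carbon(plot, trees, reg)
  split <- plot_standing_carbon(plot, trees[1:7, ], reg) +
    plot_standing_carbon(plot, trees[8:20, ], reg)
  expect_equal(whole, split, tolerance = 1e-12)
})
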