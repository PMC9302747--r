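test_that("dominant species takes the largest live basal area", {
  one <- data.frame(plot_id = "P", species = "SOAL", dbh_cm = 20,
                    status = "LIVE", in_subplot = FALSE)
  d <- dominant_species(one)
  expect_equal(d$species, "SOAL")
  expect_equal(d$basal_area_margin, basal_area(20) * 1e4 / (pi * 100))
  two <- data.frame(plot_id = "P", species = c("SOAL", "RHAP"),
                    dbh_cm = c(40, 30), status = "LIVE",
                    in_subplot = FALSE)
  d2 <- dominant_species(two)
  expect_equal(d2$species, "SOAL")
  expect_equal(d2$basal_area_margin,
               (basal_area(40) - basal_area(30)) * 1e4 / (pi * 100))
})

test_that("dominance ties break by stem count then species code", {
  # A: one 20 cm stem; B: two stems with the same total basal area
  db <- sqrt(200)  # 2 * (sqrt(200))^2 = 400 = 20^2
  trees <- data.frame(plot_id = "P",
                      species = c("A", "B", "B"),
                      dbh_cm = c(20, db, db), status = "LIVE",
                      in_subplot = FALSE)
  expect_equal(dominant_species(trees)$species, "B")
  # full tie (same BA, same count) -> lexicographic
  tie <- data.frame(plot_id = "P", species = c("B", "A"),
                    dbh_cm = c(20, 20), status = "LIVE",
                    in_subplot = FALSE)
  expect_equal(dominant_species(tie)$species, "A")
  # permutation invariance
  set.seed(2)
  trees2 <- trees[sample(nrow(trees)), ]
  expect_equal(dominant_species(trees2)$species,
               dominant_species(trees)$species)
  # dead trees do not count; no live tree -> sentinel
  dead <- data.frame(plot_id = "P", species = "A", dbh_cm = 50,
                     status = "DEAD2", in_subplot = FALSE)
  expect_true(is.na(dominant_species(dead)$species))
})

test_that("PCA of correlated bands concentrates variance and round-trips", {
  set.seed(9)
  b1 <- rnorm(300)
  X <- cbind(a = b1, b = 2 * b1)
  pc <- pca_composite(X, var_target = NULL, scale. = TRUE)
  expect_equal(pc$prop_variance[1], 1, tolerance = 1e-12)
  # orthogonal unit-variance bands share the variance
  Y <- cbind(a = rep(c(1, -1), 150), b = rep(c(1, 1, -1, -1), 75))
  pcy <- pca_composite(Y, var_target = NULL, scale. = TRUE)
  expect_equal(pcy$prop_variance, c(0.5, 0.5), tolerance = 1e-12)
  # reconstruction from all components recovers the input
  set.seed(10)
  Z <- matrix(rnorm(400), 100, 4,
              dimnames = list(NULL, paste0("b", 1:4)))
  pz <- pca_composite(Z, var_target = NULL, scale. = FALSE)
  rec <- pz$scores %*% t(pz$rotation)
  rec <- sweep(rec, 2, pz$center, "+")
  expect_equal(unname(rec), unname(Z), tolerance = 1e-8)
  expect_warning(pca_composite(cbind(c = rep(1, 100), Z)), "constant")
})

test_that("KNN predictions equal an exhaustive-distance oracle", {
  set.seed(42)
  X <- matrix(rnorm(20 * 3), 20, 3,
              dimnames = list(NULL, c("f1", "f2", "f3")))
  y <- sample(c("BRGY", "RHAP", "SOAL"), 20, replace = TRUE)
  Q <- matrix(rnorm(15 * 3), 15, 3,
              dimnames = list(NULL, c("f1", "f2", "f3")))
  for (k in c(1, 3, 5)) {
    m <- knn_fit(X, y, k = k)
    expect_equal(predict(m, Q), knn_oracle(X, y, Q, k),
                 label = paste("k =", k))
  }
  # k = 1 at a training point returns that point's label
  m1 <- knn_fit(X, y, k = 1)
  expect_equal(predict(m1, X[4, , drop = FALSE]), y[4])
  # all labels identical -> constant prediction
  mc <- knn_fit(X, rep("SOAL", 20), k = 5)
  expect_true(all(predict(mc, Q) == "SOAL"))
  expect_error(knn_fit(X, y, k = 21), "exceeds")
})

test_that("KNN agrees with class::knn on a tie-free fixture", {
  set.seed(7)
  X <- matrix(rnorm(40 * 2), 40, 2, dimnames = list(NULL, c("a", "b")))
  y <- ifelse(X[, 1] + X[, 2] > 0, "POS", "NEG")
  Q <- matrix(rnorm(25 * 2), 25, 2, dimnames = list(NULL, c("a", "b")))
  m <- knn_fit(X, y, k = 5)  # odd k, two classes: no vote ties
  Xz <- scale(X); Qz <- scale(Q, center = attr(Xz, "scaled:center"),
                              scale = attr(Xz, "scaled:scale"))
  ref <- as.character(class::knn(Xz, Qz, factor(y), k = 5))
  expect_equal(predict(m, Q), ref)
})

test_that("KNN is invariant to raw feature scaling", {
  set.seed(3)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- sample(c("X", "Y", "Z"), 30, replace = TRUE)
  Q <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  m1 <- knn_fit(X, y, k = 4)
  X2 <- X; X2[, 1] <- X2[, 1] * 10
  Q2 <- Q; Q2[, 1] <- Q2[, 1] * 10
  m2 <- knn_fit(X2, y, k = 4)
  expect_equal(predict(m1, Q), predict(m2, Q2))
})

test_that("KNN cross-validation is seeded and near chance on shuffled
           balanced labels", {
  set.seed(31)
  n <- 400
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- sample(rep(mangrove_species_codes(), length.out = n))
  cv1 <- knn_cross_validate(X, y, k = 16, folds = 10, seed = 5)
  cv2 <- knn_cross_validate(X, y, k = 16, folds = 10, seed = 5)
  expect_identical(cv1$agreement, cv2$agreement)
  expect_lt(abs(cv1$agreement - 1 / 8), 0.06)
})

test_that("RF threshold equals a brute-force scan on a 10-point table", {
  prob <- c(0.05, 0.15, 0.22, 0.35, 0.41, 0.55, 0.60, 0.72, 0.88, 0.95)
  truth <- c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE,
             TRUE)
  got <- rf_best_threshold(prob, truth)
  oracle <- threshold_oracle(prob, truth)
  # the maximized criterion must match the oracle exactly; several
  # cut-points can tie on it, so the operating point is checked against
  # the threshold itself below
  expect_equal(got$sensitivity + got$specificity,
               unname(oracle["sensitivity"] + oracle["specificity"]),
               tolerance = 1e-12)
  call <- prob >= got$threshold
  expect_equal(sum(call & truth) / sum(truth), got$sensitivity)
  expect_equal(sum(!call & !truth) / sum(!truth), got$specificity)
})

test_that("per-species RF separates a linearly separable toy problem", {
  set.seed(12)
  n <- 80
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- ifelse(X[, 1] > 0.2, "SOAL", "BRGY")
  fit <- rf_train_species(y, X, rf_spec("SOAL", n_trees = 300), seed = 4)
  expect_s3_class(fit, "rf_dominance")
  expect_gt(fit$oob_sensitivity, 0.95)
  expect_gt(fit$oob_specificity, 0.95)
  # degenerate label set -> skip notice
  skip_fit <- rf_train_species(rep("BRGY", n), X, rf_spec("SOAL"))
  expect_s3_class(skip_fit, "rf_skip")
})

test_that("class-balanced sampling engages for rare dominants", {
  set.seed(13)
  n <- 100
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- c(rep("XYGR", 10), rep("BRGY", 90))
  X[y == "XYGR", 1] <- X[y == "XYGR", 1] + 3
  fit <- rf_train_species(y, X, rf_spec("XYGR", n_trees = 300), seed = 4)
  expect_equal(fit$balancing_used, "CLASS_BALANCED")
  plain <- rf_train_species(y, X,
                            rf_spec("XYGR", n_trees = 300,
                                    balancing = "PLAIN"), seed = 4)
  expect_equal(plain$balancing_used, "PLAIN")
})

test_that("repeated-split RF cross-validation is reproducible and
           accurate on separable data", {
  set.seed(14)
  n <- 60
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- ifelse(X[, 1] > 0, "SOAL", "BRGY")
  sp <- rf_spec("SOAL", n_trees = 200)
  m1 <- rf_cross_validate(y, X, sp, reps = 2, seed = 9)
  m2 <- rf_cross_validate(y, X, sp, reps = 2, seed = 9)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 2)
  m3 <- rf_cross_validate(y, X, sp, reps = 10, seed = 9)
  expect_gt(median(m3$accuracy), 0.95)
  # metric invariance to feature order
  Xr <- X[, c("b", "a")]
  m4 <- rf_cross_validate(y, Xr, sp, reps = 2, seed = 9)
  expect_equal(m1$accuracy, m4$accuracy)
})

test_that("dominance grid prediction preserves georeference and
           propagates no-data", {
  set.seed(15)
  X <- matrix(rnorm(30 * 2), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- sample(c("BRGY", "SOAL"), 30, replace = TRUE)
  m <- knn_fit(X, y, k = 3)
  mk <- function(v) grid_raster(matrix(v, 4, 5), cell_size_m = 5,
                                origin = c(100, 200))
  ga <- mk(rnorm(20)); gb <- mk(rnorm(20))
  ga$values[2, 3] <- NA
  out <- predict_dominance_grid(m, list(a = ga, b = gb))
  expect_equal(out$cell_size_m, 5)
  expect_equal(out$origin, c(100, 200))
  expect_true(is.na(out$values[2, 3]))
  leg <- attr(out, "legend")
  expect_true(all(leg[as.character(out$values[!is.na(out$values)])] %in%
                    c("BRGY", "SOAL")))
  # constant grid equal to a training point -> that point's label
  gc1 <- mk(rep(X[7, "a"], 20)); gc2 <- mk(rep(X[7, "b"], 20))
  m1 <- knn_fit(X, y, k = 1)
  u <- predict_dominance_grid(m1, list(a = gc1, b = gc2))
  expect_true(all(attr(u, "legend")[as.character(u$values)] == y[7]))
  expect_error(predict_dominance_grid(m, list(a = ga)), "lacks band")
})
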