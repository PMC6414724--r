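sep_data <- function(n = 60) {
  # linearly separable toy data on one predictor
  tibble::tibble(z = c(seq(-2, -0.5, length.out = n / 2),
                       seq(0.5, 2, length.out = n / 2)),
                 detected = rep(c(0L, 1L), each = n / 2))
}

test_that("split-sample partitions are stratified, disjoint and deterministic", {
  detected <- rep(c(1L, 0L), c(30, 70))
  parts <- split_sample(detected, n_replicates = 10, train_fraction = 0.7,
                        seed = 1)
  for (p in parts) {
    expect_length(intersect(p$train, p$test), 0)
    expect_setequal(c(p$train, p$test), 1:100)
    expect_length(p$test, 30)
    expect_equal(sum(detected[p$test]), 9)  # round(0.3 * 30) presences
  }
  parts2 <- split_sample(detected, n_replicates = 10, train_fraction = 0.7,
                         seed = 1)
  expect_identical(parts, parts2)
  expect_error(split_sample(rep(1L, 20), 5), "stratify")
})

test_that("single fits separate separable data and are reproducible", {
  d <- sep_data()
  part <- split_sample(d$detected, 1, 0.7, seed = 2)[[1]]
  train <- d[part$train, ]
  for (alg in c("glm", "rf", "gbm")) {
    f1 <- fit_single(d, part, "z", alg, seed = 5)
    train_pred <- f1$predict_fn(f1$model, train)
    expect_equal(auc(train_pred[train$detected == 1],
                     train_pred[train$detected == 0]), 1, info = alg)
    expect_gte(f1$holdout_auc, 0.8)
    f2 <- fit_single(d, part, "z", alg, seed = 5)
    expect_equal(f1$holdout_auc, f2$holdout_auc, info = alg)
  }
  expect_error(fit_single(d, part, "z", "maxent"), "unregistered")
  expect_error(fit_single(d, part, c("a", "b", "c", "d"), "glm"),
               "three predictors")
})

test_that("a pure-noise predictor yields null-band holdout AUC", {
  withr::with_seed(8, {
    d <- tibble::tibble(z = rnorm(200), detected = rep(c(0L, 1L), 100))
  })
  parts <- split_sample(d$detected, 30, 0.7, seed = 8)
  aucs <- vapply(seq_along(parts), function(r) {
    fit_single(d, parts[[r]], "z", "glm", replicate = r, seed = r)$holdout_auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("single-class training folds raise the fold-skip signal", {
  d <- sep_data(20)
  part <- list(train = which(d$detected == 1), test = which(d$detected == 0))
  expect_error(fit_single(d, part, "z", "glm"),
               class = "nichetransfer_fold_skip")
})

fake_member <- function(auc_value, pred_value, replicate = 1L) {
  structure(list(algorithm = "fake", replicate = replicate,
                 model = pred_value,
                 predict_fn = function(model, newdata) {
                   rep(model, nrow(newdata))
                 },
                 holdout_auc = auc_value, train = 1:7, test = 8:10,
                 test_pred = rep(pred_value, 3)),
            class = "single_model_fit")
}

test_that("ensemble membership follows the AUC threshold with fallback", {
  ens <- build_ensemble(list(fake_member(0.9, 0.5), fake_member(0.6, 0.9)),
                        threshold = 0.65)
  expect_equal(sum(ens$member_table$included), 1)
  expect_equal(ens$member_table$weight, c(0.9, 0))

  equal <- build_ensemble(list(fake_member(0.8, 0.2), fake_member(0.8, 0.6)),
                          threshold = 0.65)
  p <- predict_ensemble(equal, tibble::tibble(z = 1))
  expect_equal(p, 0.4)  # equal weights -> arithmetic mean

  expect_warning(
    fb <- build_ensemble(list(fake_member(0.5, 0.3), fake_member(0.45, 0.8)),
                         threshold = 0.65),
    "falling back")
  expect_true(fb$fallback)
  expect_equal(which(fb$member_table$included), 1)  # argmax member

  expect_error(build_ensemble(list()), "no fitted members")
})

test_that("consensus predictions are the AUC-weighted mean and convex", {
  ens <- build_ensemble(list(fake_member(0.8, 0.5), fake_member(0.7, 0.65)),
                        threshold = 0.65)
  p <- predict_ensemble(ens, tibble::tibble(z = 0))
  expect_equal(p, (0.8 * 0.5 + 0.7 * 0.65) / 1.5, tolerance = 1e-12)
  # convexity: within the members' prediction range
  expect_gte(p, 0.5)
  expect_lte(p, 0.65)
})

test_that("an ensemble of one member reproduces that member's map", {
  d <- sep_data()
  part <- split_sample(d$detected, 1, 0.7, seed = 3)[[1]]
  fit <- fit_single(d, part, "z", "glm", seed = 3)
  ens <- build_ensemble(list(fit), threshold = 0.65, predictors = "z")
  stack <- list(z = grid_of(matrix(seq(-2, 2, length.out = 16), 4, 4)))
  m_member <- predict_map(fit, stack)
  m_ens <- predict_map(ens, stack)
  expect_equal(max(abs(m_ens$values - m_member$values)), 0)
})

test_that("ensemble fitting accounts for every replicate x algorithm", {
  d <- sep_data(40)
  ens <- fit_ensemble_model(d, "z", algorithms = c("glm", "rf"),
                            n_replicates = 5, seed = 9)
  expect_equal(nrow(ens$member_table), 5 * 2 - nrow(ens$skips))
  expect_equal(nrow(ens$skips), 0)
  counts <- table(ens$member_table$algorithm)
  expect_equal(as.vector(counts[c("glm", "rf")]), c(5L, 5L))
})

test_that("predict_map propagates nodata and validates layers", {
  d <- sep_data()
  ens <- fit_ensemble_model(d, "z", algorithms = "glm", n_replicates = 2,
                            seed = 1)
  z <- grid_of(matrix(0.3, 3, 3))
  z$values[2, 2] <- NA
  z$nodata_mask[2, 2] <- TRUE
  m <- predict_map(ens, list(z = z))
  expect_true(is.na(m$values[2, 2]))
  expect_true(all(!is.na(m$values[-5])))
  expect_error(predict_map(ens, list(other = z)), "missing")
})

test_that("combined models inherit the predictor arity rule", {
  occ <- tibble::tibble(x = runif(30, 0, 4), y = runif(30, 0, 4),
                        detected = rep(c(0L, 1L), 15))
  maps <- list(a = const_grid(0.4), b = const_grid(0.6),
               c = const_grid(0.5), d = const_grid(0.7))
  expect_error(build_combined(maps, occ), "2 or 3")
  expect_error(build_combined(maps[1], occ), "2 or 3")
})

test_that("combined models track a dominant input map", {
  # occurrences generated from map `a` alone: its coefficient dominates in
  # the linear learner, and the combined prediction rank-follows the input
  withr::with_seed(13, {
    vals <- matrix(runif(400), 20, 20)
    map_a <- grid_of(vals)
    map_b <- grid_of(matrix(runif(400), 20, 20))
    cells <- cell_centres(map_a)
    idx <- sample(nrow(cells), 150)
    p <- vals[cbind(cells$row[idx], cells$col[idx])]
    occ <- tibble::tibble(x = cells$x[idx], y = cells$y[idx],
                          detected = rbinom(150, 1, p))
  })
  comb <- suppressWarnings(
    build_combined(list(a = map_a, b = map_b), occ, algorithms = "glm",
                   n_replicates = 5, seed = 13))
  coefs <- vapply(comb$members, function(m) stats::coef(m$model)[-1],
                  numeric(2))
  expect_true(all(abs(coefs["a", ]) > abs(coefs["b", ])))

  comb_map <- predict_map(comb, list(a = map_a, b = map_b))
  expect_gt(cor(as.numeric(comb_map$values), as.numeric(map_a$values),
                method = "spearman"), 0.9)
})

test_that("two identical inputs give a rank-equal combined prediction", {
  withr::with_seed(14, {
    vals <- matrix(runif(100), 10, 10)
    map <- grid_of(vals)
    cells <- cell_centres(map)
    idx <- sample(100, 80)
    occ <- tibble::tibble(x = cells$x[idx], y = cells$y[idx],
                          detected = rbinom(80, 1,
                                            vals[cbind(cells$row[idx],
                                                       cells$col[idx])]))
  })
  comb <- suppressWarnings(
    build_combined(list(a = map, b = map), occ, algorithms = "glmnet",
                   n_replicates = 3, seed = 14))
  m <- predict_map(comb, list(a = map, b = map))
  expect_equal(cor(as.numeric(m$values), as.numeric(map$values),
                   method = "spearman"), 1, tolerance = 1e-6)
})

test_that("regional models project onto their own grid exactly (round trip)", {
  w <- tiny_world()
  cb <- derive_regional_bioclim(w, "t0")
  sp <- make_virtual_species(1, seed = 21)
  reg_occ <- sample_regional_occurrences(sp[1, ], cb, 200, seed = 21)
  reg <- suppressWarnings(
    fit_regional_climate(reg_occ, cb, algorithms = "glm", n_replicates = 3,
                         seed = 21))
  direct <- project_direct(reg, cb)
  std <- standardize_stack(cb, reference_stats = reg$standardize_stats)
  expected <- predict_map(reg, std$layers)
  expect_equal(direct$values, expected$values)

  # constant fine climate -> constant projected suitability
  flat <- list(bio5 = const_grid(20, 8), bio12 = const_grid(900, 8),
               bio15 = const_grid(40, 8))
  proj <- project_direct(reg, flat)
  expect_equal(diff(range(proj$values)), 0)
})
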