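test_that("AUC matches its closed-form cases", {
  expect_equal(auc(c(0.8, 0.9), c(0.1, 0.2)), 1)
  expect_equal(auc(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  expect_equal(auc(rep(0.5, 5), rep(0.5, 7)), 0.5)
  expect_error(auc(numeric(0), c(0.1)), "both classes")
})

test_that("rank-based AUC equals the brute-force pairwise loop exactly", {
  withr::with_seed(31, {
    for (i in 1:25) {
      n_p <- sample(1:120, 1)
      n_a <- sample(1:80, 1)
      # discretized scores force ties between and within classes
      pres <- round(runif(n_p), 2)
      abs_ <- round(runif(n_a), 2)
      expect_identical(auc(pres, abs_), auc_bruteforce(pres, abs_))
    }
  })
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(32, {
    pres <- rnorm(40, 1)
    abs_ <- rnorm(60)
  })
  base <- auc(pres, abs_)
  expect_equal(auc(exp(pres), exp(abs_)), base)
  all_r <- rank(c(pres, abs_))
  expect_equal(auc(all_r[1:40], all_r[41:100]), base)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(33, {
    scores <- runif(150)
    labels <- rbinom(150, 1, scores)
  })
  ours <- auc(scores[labels == 1], scores[labels == 0])
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("confusion metrics reproduce the 2x2 arithmetic", {
  perfect <- confusion_metrics(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0), 0.5)
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "tss", "kappa")]),
               c(sensitivity = 1, specificity = 1, tss = 1, kappa = 1))

  # TP=8 FN=2 TN=7 FP=3: sens 0.8, spec 0.7, TSS 0.5, kappa 0.5 (p_e = 0.5)
  scores <- c(rep(0.9, 8), rep(0.1, 2), rep(0.2, 7), rep(0.8, 3))
  observed <- rep(c(1, 0), c(10, 10))
  cm <- confusion_metrics(scores, observed, 0.5)
  expect_equal(cm$sensitivity, 0.8)
  expect_equal(cm$specificity, 0.7)
  expect_equal(cm$tss, 0.5)
  expect_equal(cm$kappa, 0.5)

  all_present <- confusion_metrics(scores, observed, 0)
  expect_equal(all_present$sensitivity, 1)
  expect_equal(all_present$specificity, 0)
  expect_equal(all_present$tss, 0)

  expect_error(confusion_metrics(scores, rep(1, 20), 0.5), "both")
})

test_that("max-TSS threshold equals the exhaustive scan on random instances", {
  withr::with_seed(34, {
    for (i in 1:100) {
      n <- sample(10:60, 1)
      scores <- round(runif(n), 2)
      observed <- rbinom(n, 1, pmin(scores + 0.1, 1))
      if (length(unique(observed)) < 2) next
      expect_identical(max_tss_threshold(scores, observed),
                       max_tss_oracle(scores, observed))
    }
  })
})

test_that("max-TSS threshold handles separable and degenerate scores", {
  th <- max_tss_threshold(c(0.9, 0.8, 0.2), c(1, 1, 0))
  expect_equal(th, 0.8)  # smallest candidate attaining TSS 1
  expect_equal(confusion_metrics(c(0.9, 0.8, 0.2), c(1, 1, 0), th)$tss, 1)

  single <- max_tss_threshold(rep(0.4, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(single, 0.4)
  expect_equal(confusion_metrics(rep(0.4, 6), c(1, 1, 1, 0, 0, 0),
                                 single)$tss, 0)
})

test_that("Schoener's D matches its closed forms and invariances", {
  a <- grid_of(matrix(c(1, 2, 3, 4), 2, 2))
  expect_equal(schoener_d(a, a), 1)

  disjoint_a <- grid_of(matrix(c(1, 0, 0, 0), 2, 2))
  disjoint_b <- grid_of(matrix(c(0, 0, 0, 1), 2, 2))
  expect_equal(schoener_d(disjoint_a, disjoint_b), 0)

  two_a <- grid_of(matrix(c(1, 0), 1, 2))
  two_b <- grid_of(matrix(c(0.5, 0.5), 1, 2))
  expect_equal(schoener_d(two_a, two_b), 0.5)

  withr::with_seed(35, {
    u <- grid_of(matrix(runif(36), 6, 6))
    v <- grid_of(matrix(runif(36), 6, 6))
  })
  expect_equal(schoener_d(u, v), schoener_d(v, u))
  scaled <- grid_of(u$values * 7.3)
  expect_equal(schoener_d(u, scaled), 1, tolerance = 1e-12)

  expect_error(schoener_d(u, grid_of(matrix(0, 6, 6))), "all-zero")
  expect_error(schoener_d(u, grid_of(matrix(1, 3, 3))), "co-registered")
})

test_that("transferability counting uses a strict cut", {
  recs <- tibble::tibble(species_id = c("a", "b", "c"),
                         auc = c(0.71, 0.70, 0.69))
  expect_equal(count_transferable(recs), 1L)
  expect_equal(count_transferable(recs[0, ]), 0L)
  expect_equal(count_transferable(tibble::tibble(auc = rep(1, 4))), 4L)
})

test_that("evaluation regimes enforce protocol consistency and freeze thresholds", {
  d <- tibble::tibble(z = c(seq(-2, -0.3, length.out = 30),
                            seq(0.3, 2, length.out = 30)),
                      detected = rep(c(0L, 1L), each = 30))
  ens <- fit_ensemble_model(d, "z", algorithms = "glm", n_replicates = 3,
                            seed = 41)
  stack <- list(z = grid_of(matrix(seq(-2, 2, length.out = 64), 8, 8)))
  map <- predict_map(ens, stack)
  cells <- cell_centres(stack$z)
  # deterministic detections: present on the top-scoring half of the cells,
  # ordered so every subset mixes both classes
  s_all <- extract_at(map, cells$x, cells$y)
  ord <- order(s_all)
  pick <- ord[seq(1, 64, length.out = 40)]
  occ_cal <- tibble::tibble(x = cells$x[pick], y = cells$y[pick],
                            detected = as.integer(s_all[pick] >
                                                    stats::median(s_all)),
                            epoch = "t0", protocol = "calibration")
  occ_int <- dplyr::mutate(occ_cal[seq(1, 40, by = 2), ], epoch = "t1",
                           protocol = "internal_tt")

  rec_cv <- evaluate_model(ens, map, occ_cal, "crossvalidation")
  expect_true(rec_cv$auc >= 0 && rec_cv$auc <= 1)

  rec_int <- evaluate_model(ens, map, occ_int, "internal_tt",
                            threshold = rec_cv$threshold)
  expect_identical(rec_int$threshold, rec_cv$threshold)  # frozen at t0

  expect_error(evaluate_model(ens, map, occ_cal, "internal_tt",
                              threshold = 0.5), "protocol")
  expect_error(evaluate_model(ens, map, occ_int, "internal_tt"),
               "frozen")
  occ_t0_int <- dplyr::mutate(occ_int, epoch = "t0")
  expect_error(evaluate_model(ens, map, occ_t0_int, "internal_tt",
                              threshold = 0.5), "t1")
})

test_that("scoring the truth against its own draws hits the noise ceiling", {
  withr::with_seed(42, {
    p <- stats::rbeta(2000, 2.5, 2.5)  # suitability SD ~ 0.2
    y <- rbinom(2000, 1, p)
  })
  a <- auc(p[y == 1], p[y == 0])
  expect_gt(a, 0.70)
  expect_lt(a, 0.95)
})

test_that("training-data evaluation is optimistic relative to holdout", {
  withr::with_seed(43, {
    d <- tibble::tibble(z = rnorm(120),
                        detected = rbinom(120, 1, plogis(0.8 * rnorm(120))))
  })
  parts <- split_sample(d$detected, 30, 0.7, seed = 43)
  diffs <- vapply(seq_along(parts), function(r) {
    f <- fit_single(d, parts[[r]], "z", "glm", replicate = r, seed = r)
    train <- d[parts[[r]]$train, ]
    train_pred <- f$predict_fn(f$model, train)
    train_auc <- auc(train_pred[train$detected == 1],
                     train_pred[train$detected == 0])
    train_auc - f$holdout_auc
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
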