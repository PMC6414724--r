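test_that("the Gaussian GLM reports the ML likelihood convention", {
  d <- tibble::tibble(y = c(0.6, 0.8))
  fit <- gaussian_glm(d, "y")
  # sigma2 = RSS/n = 0.01; loglik = -(n/2)(ln(2 pi sigma2) + 1); k = 2
  expect_equal(fit$loglik, -(2 / 2) * (log(2 * pi * 0.01) + 1),
               tolerance = 1e-12)
  expect_equal(fit$k, 2)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * 2, tolerance = 1e-12)
  # identical to the stats::logLik/AIC conventions on lm
  expect_equal(fit$loglik, as.numeric(stats::logLik(stats::lm(y ~ 1, d))),
               tolerance = 1e-12)
  expect_equal(fit$aic, stats::AIC(stats::lm(y ~ 1, d)), tolerance = 1e-12)
})

test_that("perfect fits are flagged degenerate, noise factors never hurt loglik", {
  d <- tibble::tibble(y = c(1, 2, 3, 4), g = c("a", "a", "b", "b"))
  d$y <- ifelse(d$g == "a", 0.6, 0.9)
  fit <- gaussian_glm(d, "y", "g")
  expect_true(fit$degenerate)

  withr::with_seed(51, {
    d2 <- tibble::tibble(y = rnorm(40),
                         f1 = sample(c("u", "v"), 40, replace = TRUE),
                         noise = sample(c("p", "q"), 40, replace = TRUE))
  })
  base <- gaussian_glm(d2, "y", "f1")
  bigger <- gaussian_glm(d2, "y", c("f1", "noise"))
  expect_gte(bigger$loglik, base$loglik - 1e-10)

  d3 <- tibble::tibble(y = rnorm(10), a = rep("x", 10))
  expect_error(gaussian_glm(d3, "y", "a"), "aliased|contrasts")
})

test_that("the dredge enumerates all subsets with coherent weights", {
  withr::with_seed(52, {
    d <- tibble::tibble(
      auc = runif(60, 0.6, 0.9),
      PRED = sample(c("CLI", "LULC", "EFA"), 60, replace = TRUE),
      APP = sample(c("h", "nh"), 60, replace = TRUE),
      TRAIT = sample(c("m", "e"), 60, replace = TRUE))
  })
  inf <- dredge_all_subsets(d, "auc")
  expect_s3_class(inf, "inference_table")
  expect_equal(nrow(inf$models), 8)  # 2^3
  expect_equal(sum(inf$models$weight), 1, tolerance = 1e-12)
  expect_equal(min(inf$models$delta), 0)
  # weights strictly decreasing in AIC
  expect_true(all(diff(inf$models$weight[order(inf$models$aic)]) <= 1e-12))
  expect_true(all(inf$importance$sum_weight >= 0 &
                    inf$importance$sum_weight <= 1))
  td <- tidy(inf)
  expect_true(all(c("formula", "aic", "delta", "weight") %in% names(td)))
  gl <- glance(inf)
  expect_true("sum_weight_PRED" %in% names(gl))
})

test_that("Akaike weights follow the closed-form ratios", {
  # two models at AIC 100 and 102
  w <- exp(-c(0, 2) / 2)
  w <- w / sum(w)
  expect_equal(w, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-12)
  expect_equal(w, c(0.731, 0.269), tolerance = 1e-3 / 0.269)

  # three-model set {PRED: 100}, {PRED+TRAIT: 102}, {TRAIT: 110}
  aic <- c(100, 102, 110)
  wts <- exp(-(aic - min(aic)) / 2)
  wts <- wts / sum(wts)
  expect_equal(sum(wts[1:2]), 0.995, tolerance = 1e-3 / 0.995)  # sum W, PRED
  expect_equal(sum(wts[2:3]), 0.273, tolerance = 1e-3 / 0.273)  # sum W, TRAIT
})

test_that("adding a constant to the response leaves deltas and weights fixed", {
  withr::with_seed(53, {
    d <- tibble::tibble(auc = runif(50, 0.5, 1),
                        PRED = sample(c("a", "b"), 50, replace = TRUE),
                        APP = sample(c("h", "nh"), 50, replace = TRUE))
  })
  i1 <- dredge_all_subsets(d, "auc", c("PRED", "APP"))
  d$auc <- d$auc + 5
  i2 <- dredge_all_subsets(d, "auc", c("PRED", "APP"))
  expect_equal(i1$models$delta, i2$models$delta, tolerance = 1e-9)
  expect_equal(i1$models$weight, i2$models$weight, tolerance = 1e-9)
})

test_that("Wilcoxon signed-rank matches its exact small-sample law", {
  res <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_equal(res$p_value, 2 / 32)
  expect_equal(res$statistic, 15)  # all ranks positive: V = 1+2+3+4+5

  expect_error(wilcoxon_signed_rank(1:6, 1:6), "zero")
  expect_error(wilcoxon_signed_rank(c(1, 2, 3), c(0, 1, 2)), "at least 5")

  withr::with_seed(54, {
    a <- rnorm(12)
    b <- rnorm(12)
  })
  expect_equal(wilcoxon_signed_rank(a, b)$p_value,
               wilcoxon_signed_rank(b, a)$p_value)
})

test_that("the exact path equals full sign enumeration for n <= 12", {
  withr::with_seed(55, {
    for (i in 1:20) {
      n <- sample(5:12, 1)
      a <- round(rnorm(n), 1)  # rounding forces tied absolute differences
      b <- round(rnorm(n), 1)
      if (all(a == b)) next
      d <- a - b
      if (sum(d != 0) < 5) next
      got <- wilcoxon_signed_rank(a, b)
      want <- wilcoxon_enum_oracle(a, b)
      expect_equal(got$statistic, want$statistic)
      expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
    }
  })
})

test_that("the exact path agrees with stats::wilcox.test on tie-free data", {
  withr::with_seed(56, {
    for (i in 1:10) {
      n <- sample(6:20, 1)
      a <- rnorm(n)
      b <- rnorm(n)
      got <- wilcoxon_signed_rank(a, b)
      ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
      expect_equal(got$statistic, unname(ref$statistic))
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("the large-sample path approximates the exact distribution", {
  withr::with_seed(57, {
    a <- rnorm(40, 0.1)
    b <- rnorm(40)
  })
  approx <- wilcoxon_signed_rank(a, b)
  expect_equal(approx$method, "normal-approximation")
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(approx$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("trait contrasts recover planted effects and only planted effects", {
  flagged <- vapply(1:10, function(s) {
    pa <- simulate_planted_auc(trait_effect = 0.2, seed = s)
    trait_contrast_table(pa, "origin")$significant[1]
  }, logical(1))
  expect_gte(sum(flagged), 9)

  null_sig <- vapply(1:10, function(s) {
    pa <- simulate_planted_auc(trait_effect = 0, seed = s)
    trait_contrast_table(pa, "origin")$significant[1]
  }, logical(1))
  expect_lte(sum(null_sig), 1)

  one_level <- simulate_planted_auc(seed = 1)
  one_level$origin <- "Eurosiberian"
  expect_warning(out <- trait_contrast_table(one_level, "origin"),
                 "fewer than two levels")
  expect_equal(nrow(out), 0)
})
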