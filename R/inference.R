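#' Gaussian-identity GLM with ML likelihood bookkeeping
#'
#' Ordinary least squares on treatment-coded factors; the log-likelihood uses
#' the maximum-likelihood variance `RSS/n` and the parameter count `k`
#' includes the variance parameter, so AIC is comparable across fixed-effect
#' structures (these are the conventions of `stats::logLik`/`stats::AIC` on an
#' `lm` fit, used directly). Near-perfect fits are flagged degenerate with the
#' variance floored at 1e-12.
#'
#' @param data Data frame with the response and factor columns.
#' @param response Response column name (an accuracy metric such as AUC).
#' @param factors Character vector of factor column names; may be empty
#'   (intercept-only model).
#' @return List with `model` (the `lm` fit), `coefficients`, `loglik`, `aic`,
#'   `k`, `degenerate`.
#' @export
gaussian_glm <- function(data, response, factors = character()) {
  rhs <- if (length(factors)) paste(factors, collapse = " + ") else "1"
  f <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(f, data = data)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("gaussian_glm: rank-deficient design; aliased terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- length(stats::resid(fit))
  sigma2 <- sum(stats::resid(fit)^2) / n
  degenerate <- sigma2 < 1e-12
  sigma2 <- max(sigma2, 1e-12)
  loglik <- -(n / 2) * (log(2 * pi * sigma2) + 1)
  k <- length(stats::coef(fit)) + 1L  # + variance parameter
  list(model = fit, coefficients = stats::coef(fit),
       loglik = loglik, aic = -2 * loglik + 2 * k, k = k,
       degenerate = degenerate)
}

#' All-subsets multimodel inference over main-effects factors
#'
#' Fits the Gaussian-identity GLM for every subset of the candidate factors
#' (including the intercept-only model; interactions excluded), ranks models
#' by AIC, and derives `delta` (AIC difference to the best model), Akaike
#' weights, the per-factor summed weight (importance, consequential when
#' above 0.5) and the support set (`delta < support_cut`, 7 by default).
#'
#' @param data Data frame with response and factor columns.
#' @param response Response column name.
#' @param candidate_factors Character vector of at most 10 factor names.
#' @param support_cut Delta-AIC support cutoff.
#' @return An object of class `inference_table` with elements `models`
#'   (tibble: `formula`, `k`, `loglik`, `aic`, `delta`, `weight`, `supported`),
#'   `importance` (tibble: `factor`, `sum_weight`, `consequential`),
#'   `support_cut`, `response`.
#' @export
dredge_all_subsets <- function(data, response,
                               candidate_factors = c("PRED", "APP", "TRAIT"),
                               support_cut = 7) {
  m <- length(candidate_factors)
  if (m > 10) stop("dredge_all_subsets: at most 10 candidate factors",
                   call. = FALSE)
  subsets <- purrr::map(0:(2^m - 1), function(mask) {
    candidate_factors[bitwAnd(mask, bitwShiftL(1, seq_len(m) - 1)) != 0]
  })
  fits <- purrr::map(subsets, function(fs) gaussian_glm(data, response, fs))
  models <- tibble::tibble(
    formula = vapply(subsets, function(fs) {
      if (length(fs)) paste(fs, collapse = " + ") else "(intercept)"
    }, character(1)),
    terms = subsets,
    k = vapply(fits, function(f) f$k, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1))
  )
  models <- models |>
    dplyr::mutate(delta = .data$aic - min(.data$aic)) |>
    dplyr::mutate(weight = exp(-.data$delta / 2) / sum(exp(-.data$delta / 2)),
                  supported = .data$delta < support_cut) |>
    dplyr::arrange(.data$aic)
  importance <- tibble::tibble(
    factor = candidate_factors,
    sum_weight = vapply(candidate_factors, function(f) {
      sum(models$weight[vapply(models$terms, function(t) f %in% t, logical(1))])
    }, numeric(1))
  ) |>
    dplyr::mutate(consequential = .data$sum_weight > 0.5)
  structure(list(models = models, importance = importance,
                 support_cut = support_cut, response = response),
            class = "inference_table")
}

#' @export
print.inference_table <- function(x, ...) {
  cat(sprintf("<inference_table> %d models on '%s'; support: delta < %g\n",
              nrow(x$models), x$response, x$support_cut))
  print(dplyr::select(dplyr::filter(x$models, .data$supported),
                      "formula", "aic", "delta", "weight"))
  cat("importance (sum of Akaike weights):\n")
  print(x$importance)
  invisible(x)
}

#' Model-ranking table of a multimodel inference run
#' @param x An `inference_table`.
#' @param ... Unused.
#' @return Tibble mirroring the AIC ranking (formula, k, loglik, AIC, delta,
#'   weight, support flag).
#' @export
tidy.inference_table <- function(x, ...) {
  dplyr::select(x$models, "formula", "k", "loglik", "aic", "delta",
                "weight", "supported")
}

#' One-row summary of a multimodel inference run
#' @param x An `inference_table`.
#' @param ... Unused.
#' @return One-row tibble with per-factor summed Akaike weights and model
#'   counts.
#' @export
glance.inference_table <- function(x, ...) {
  imp <- x$importance
  out <- tibble::as_tibble(as.list(stats::setNames(imp$sum_weight,
                                                   paste0("sum_weight_", imp$factor))))
  out$n_models <- nrow(x$models)
  out$n_supported <- sum(x$models$supported)
  out
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; tied absolute differences receive midranks.
#' The two-sided p-value is exact — full enumeration of the `2^n` sign
#' assignments — for `n <= 25` retained pairs, and uses the normal
#' approximation with continuity correction above that.
#'
#' @param paired_a,paired_b Equal-length numeric vectors.
#' @return List of class `wilcoxon_signed_rank`: `statistic` (V, the positive
#'   rank sum), `p_value` (two-sided), `n` (retained pairs), `method`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b)) {
    stop("wilcoxon_signed_rank: inputs must have equal length", call. = FALSE)
  }
  d <- paired_a - paired_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    stop("wilcoxon_signed_rank: all differences are zero", call. = FALSE)
  }
  if (n < 5) {
    stop("wilcoxon_signed_rank: need at least 5 nonzero differences",
         call. = FALSE)
  }
  r <- rank(abs(d), ties.method = "average")
  v <- sum(r[d > 0])
  total <- sum(r)
  if (n <= 25) {
    # exact distribution of the positive rank sum over all 2^n sign
    # assignments, by convolution; midranks doubled so every rank is integer
    r2 <- as.integer(round(2 * r))
    counts <- numeric(sum(r2) + 1L)  # index s+1 holds #assignments with sum s
    counts[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(length(counts) - ri)])
      counts <- counts + shifted
    }
    s_vals <- seq_along(counts) - 1L
    v2 <- round(2 * v)
    tail_ge <- sum(counts[s_vals >= v2]) / 2^n
    tail_le <- sum(counts[s_vals <= v2]) / 2^n
    p <- min(1, 2 * min(tail_ge, tail_le))
    method <- "exact"
  } else {
    mu <- total / 2
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  structure(list(statistic = v, p_value = p, n = n, method = method),
            class = "wilcoxon_signed_rank")
}

#' @export
print.wilcoxon_signed_rank <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: V = %g, n = %d, p = %.4g (%s)\n",
              x$statistic, x$n, x$p_value, x$method))
  invisible(x)
}

#' Tidy a Wilcoxon signed-rank result
#' @param x A `wilcoxon_signed_rank` result.
#' @param ... Unused.
#' @return One-row tibble (`statistic`, `p_value`, `n`, `method`).
#' @export
tidy.wilcoxon_signed_rank <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value, n = x$n,
                 method = x$method)
}

#' Trait-group contrasts of model accuracy
#'
#' Compares the two levels of one binary trait on an accuracy metric,
#' separately per evaluation regime. Because trait groups partition species,
#' the pairing unit is the model configuration: within each
#' `eval_type x predictor_set x approach` cell the metric is averaged per
#' trait level, and the paired Wilcoxon signed-rank test runs across those
#' cell pairs. Significance uses the conservative `p < 0.001` rule. An
#' unpaired rank-sum alternative is available via `paired = FALSE`.
#'
#' @param eval_records Eval-record tibble carrying `species_id`, `eval_type`,
#'   `predictor_set`, `approach`, the metric column, and the trait column
#'   (joined from the trait table).
#' @param trait_column Name of the binary trait column.
#' @param metric Metric column name (default `"auc"`).
#' @param paired Use the paired signed-rank test on configuration-cell means
#'   (default) or an unpaired rank-sum test on species means.
#' @param alpha Significance level (0.001).
#' @return Tibble: one row per eval_type with group means, test statistic,
#'   p-value and significance flag; empty (with a warning) if the trait has
#'   fewer than two levels.
#' @export
trait_contrast_table <- function(eval_records, trait_column, metric = "auc",
                                 paired = TRUE, alpha = 0.001) {
  lv <- sort(unique(eval_records[[trait_column]]))
  if (length(lv) < 2) {
    warning("trait_contrast_table: trait '", trait_column,
            "' has fewer than two levels; returning empty table", call. = FALSE)
    return(tibble::tibble())
  }
  purrr::map_dfr(sort(unique(eval_records$eval_type)), function(et) {
    sub <- dplyr::filter(eval_records, .data$eval_type == et)
    means <- sub |>
      dplyr::group_by(.data$predictor_set, .data$approach,
                      level = .data[[trait_column]]) |>
      dplyr::summarise(m = mean(.data[[metric]]), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "level", values_from = "m")
    res <- if (paired) {
      ok <- stats::complete.cases(means[lv])
      tryCatch(wilcoxon_signed_rank(means[[lv[1]]][ok], means[[lv[2]]][ok]),
               error = function(e) NULL)
    } else {
      a <- sub[[metric]][sub[[trait_column]] == lv[1]]
      b <- sub[[metric]][sub[[trait_column]] == lv[2]]
      wt <- suppressWarnings(stats::wilcox.test(a, b))
      list(statistic = unname(wt$statistic), p_value = wt$p.value,
           n = length(a) + length(b), method = "rank-sum")
    }
    tibble::tibble(
      eval_type = et, trait = trait_column,
      level_a = lv[1], level_b = lv[2],
      mean_a = mean(sub[[metric]][sub[[trait_column]] == lv[1]]),
      mean_b = mean(sub[[metric]][sub[[trait_column]] == lv[2]]),
      statistic = if (is.null(res)) NA_real_ else res$statistic,
      p_value = if (is.null(res)) NA_real_ else res$p_value,
      significant = if (is.null(res)) FALSE else res$p_value < alpha
    )
  })
}
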