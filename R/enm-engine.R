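#' Learner registry
#'
#' The single-model algorithms available to the ensemble, each a thin adapter
#' around an established implementation behind a common
#' fit/predict-probability interface: `glm` (binomial GLM), `glmnet`
#' (penalized ridge logistic), `gam` (thin-plate spline additive logistic,
#' mgcv), `rf` (random forest, ranger), `gbm` (gradient boosting, xgboost),
#' `fda` (linear discriminant posterior, MASS) and `ann` (single-hidden-layer
#' network, nnet). All fits are single-threaded and deterministic for a fixed
#' seed.
#'
#' @return Named list; each element has functions `fit(data, predictors,
#'   seed)` and `predict(model, newdata)` returning probabilities in `[0, 1]`.
#' @export
learner_registry <- function() {
  clamp01 <- function(p) pmin(pmax(as.numeric(p), 0), 1)
  list(
    glm = list(
      fit = function(data, predictors, seed) {
        f <- stats::reformulate(predictors, response = "detected")
        suppressWarnings(stats::glm(f, data = data, family = stats::binomial()))
      },
      predict = function(model, newdata) {
        clamp01(stats::predict(model, newdata = newdata, type = "response"))
      }
    ),
    glmnet = list(
      fit = function(data, predictors, seed) {
        x <- as.matrix(data[predictors])
        m <- glmnet::glmnet(x, data$detected, family = "binomial", alpha = 0,
                            nlambda = 30, lambda.min.ratio = 1e-4)
        list(model = m, lambda = min(m$lambda), predictors = predictors)
      },
      predict = function(model, newdata) {
        x <- as.matrix(newdata[model$predictors])
        clamp01(stats::predict(model$model, newx = x, s = model$lambda,
                               type = "response"))
      }
    ),
    gam = list(
      fit = function(data, predictors, seed) {
        k <- max(3, min(6, floor(nrow(data) / (3 * length(predictors)))))
        terms <- sprintf("s(%s, k = %d)", predictors, k)
        f <- stats::as.formula(paste("detected ~", paste(terms, collapse = " + ")))
        suppressWarnings(mgcv::gam(f, data = data, family = stats::binomial(),
                                   method = "REML"))
      },
      predict = function(model, newdata) {
        clamp01(stats::predict(model, newdata = newdata, type = "response"))
      }
    ),
    rf = list(
      fit = function(data, predictors, seed) {
        data$detected <- factor(data$detected, levels = c(0, 1))
        f <- stats::reformulate(predictors, response = "detected")
        ranger::ranger(f, data = data, probability = TRUE, num.trees = 200,
                       min.node.size = 5, seed = seed, num.threads = 1)
      },
      predict = function(model, newdata) {
        clamp01(stats::predict(model, data = newdata,
                               num.threads = 1)$predictions[, "1"])
      }
    ),
    gbm = list(
      fit = function(data, predictors, seed) {
        dtrain <- xgboost::xgb.DMatrix(as.matrix(data[predictors]),
                                       label = data$detected)
        m <- xgboost::xgb.train(
          params = list(objective = "binary:logistic", max_depth = 2,
                        eta = 0.1, nthread = 1, seed = seed),
          data = dtrain, nrounds = 60, verbose = 0)
        list(model = m, predictors = predictors)
      },
      predict = function(model, newdata) {
        clamp01(stats::predict(model$model,
                               xgboost::xgb.DMatrix(as.matrix(newdata[model$predictors]))))
      }
    ),
    fda = list(
      fit = function(data, predictors, seed) {
        f <- stats::reformulate(predictors, response = "detected")
        MASS::lda(f, data = dplyr::mutate(data, detected = factor(.data$detected,
                                                                  levels = c(0, 1))))
      },
      predict = function(model, newdata) {
        clamp01(stats::predict(model, newdata = newdata)$posterior[, "1"])
      }
    ),
    ann = list(
      fit = function(data, predictors, seed) {
        f <- stats::reformulate(predictors, response = "detected")
        with_seed(seed, nnet::nnet(f, data = data, size = 3, decay = 0.01,
                                   maxit = 200, trace = FALSE))
      },
      predict = function(model, newdata) {
        clamp01(stats::predict(model, newdata = newdata))
      }
    )
  )
}

#' Stratified split-sample partitions
#'
#' Random presence/absence-stratified partitions of the occurrence records into
#' a calibration (train) and evaluation (test) fraction, repeated
#' `n_replicates` times. The test fold takes `round((1 - train_fraction) * n)`
#' records of each class.
#'
#' @param detected Binary response vector (0/1).
#' @param n_replicates Number of replicate partitions.
#' @param train_fraction Fraction of each class used for calibration.
#' @param seed Integer seed.
#' @return List of `n_replicates` lists with integer index vectors `train`,
#'   `test`.
#' @export
split_sample <- function(detected, n_replicates = 30, train_fraction = 0.7,
                         seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  pres <- which(detected == 1)
  abs_ <- which(detected == 0)
  if (length(pres) < 2 || length(abs_) < 2) {
    stop("split_sample: need at least 2 presences and 2 absences to stratify",
         call. = FALSE)
  }
  n_test_p <- max(1L, round((1 - train_fraction) * length(pres)))
  n_test_a <- max(1L, round((1 - train_fraction) * length(abs_)))
  with_seed(child_seed(seed, 41L), {
    lapply(seq_len(n_replicates), function(r) {
      tp <- sample(pres, n_test_p)
      ta <- sample(abs_, n_test_a)
      test <- sort(c(tp, ta))
      list(train = setdiff(seq_along(detected), test), test = test)
    })
  })
}

fold_skip <- function(algorithm, replicate) {
  structure(class = c("nichetransfer_fold_skip", "error", "condition"),
            list(message = sprintf("single-class training fold: %s replicate %d",
                                   algorithm, replicate),
                 call = NULL))
}

#' Fit one single-algorithm model on one partition
#'
#' @param data Tibble with binary `detected` and the predictor columns.
#' @param partition List with `train`/`test` index vectors.
#' @param predictors Character vector of at most three predictor names.
#' @param algorithm Name in [learner_registry()].
#' @param replicate Replicate index (bookkeeping).
#' @param seed Integer seed.
#' @return List of class `single_model_fit` with the fitted handle, the
#'   holdout AUC and the partition; signals a `nichetransfer_fold_skip`
#'   condition when the training fold holds a single class.
#' @export
fit_single <- function(data, partition, predictors, algorithm,
                       replicate = 1L, seed = 1L) {
  if (length(predictors) > 3L) {
    stop("fit_single: at most three predictors per model", call. = FALSE)
  }
  reg <- learner_registry()
  if (!algorithm %in% names(reg)) {
    stop("fit_single: unregistered algorithm '", algorithm, "'", call. = FALSE)
  }
  train <- data[partition$train, , drop = FALSE]
  test <- data[partition$test, , drop = FALSE]
  if (length(unique(train$detected)) < 2L) {
    stop(fold_skip(algorithm, replicate))
  }
  learner <- reg[[algorithm]]
  model <- learner$fit(train, predictors, seed)
  test_pred <- learner$predict(model, test)
  holdout_auc <- if (length(unique(test$detected)) < 2L) NA_real_ else {
    auc(test_pred[test$detected == 1], test_pred[test$detected == 0])
  }
  structure(list(algorithm = algorithm, replicate = replicate,
                 model = model, predict_fn = learner$predict,
                 holdout_auc = holdout_auc,
                 train = partition$train, test = partition$test,
                 test_pred = test_pred),
            class = "single_model_fit")
}

#' Build an AUC-weighted consensus from fitted members
#'
#' Members with holdout AUC strictly above `threshold` enter the consensus
#' with weight equal to their raw AUC. When no member qualifies, the single
#' best member is used alone (with a warning), so every species obtains an
#' ensemble.
#'
#' @param members List of `single_model_fit` objects.
#' @param threshold AUC inclusion cutoff.
#' @param predictors Predictor names the members were trained on.
#' @return Object of class `ensemble_model`.
#' @export
build_ensemble <- function(members, threshold = 0.65, predictors = NULL) {
  members <- Filter(Negate(is.null), members)
  if (!length(members)) stop("build_ensemble: no fitted members", call. = FALSE)
  aucs <- vapply(members, function(m) m$holdout_auc, numeric(1))
  included <- !is.na(aucs) & aucs > threshold
  fallback <- FALSE
  if (!any(included)) {
    fallback <- TRUE
    warning("build_ensemble: no member exceeded AUC ", threshold,
            "; falling back to the single best member", call. = FALSE)
    included[which.max(ifelse(is.na(aucs), -Inf, aucs))] <- TRUE
  }
  member_table <- tibble::tibble(
    algorithm = vapply(members, function(m) m$algorithm, character(1)),
    replicate = vapply(members, function(m) m$replicate, integer(1)),
    holdout_auc = aucs,
    included = included,
    weight = ifelse(included, aucs, 0)
  )
  structure(list(members = members, member_table = member_table,
                 threshold = threshold, fallback = fallback,
                 predictors = predictors %||% NA_character_),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  mt <- x$member_table
  cat(sprintf("<ensemble_model> %d members (%d included, AUC > %.2f)%s\n",
              nrow(mt), sum(mt$included), x$threshold,
              if (x$fallback) " [fallback]" else ""))
  cat(sprintf("  predictors: %s; mean holdout AUC %.3f\n",
              paste(x$predictors, collapse = ", "),
              mean(mt$holdout_auc, na.rm = TRUE)))
  invisible(x)
}

#' Member table of an ensemble
#' @param x An `ensemble_model`.
#' @param ... Unused.
#' @return Tibble of members (`algorithm`, `replicate`, `holdout_auc`,
#'   `included`, `weight`).
#' @export
tidy.ensemble_model <- function(x, ...) x$member_table

#' One-row summary of an ensemble
#' @param x An `ensemble_model`.
#' @param ... Unused.
#' @return One-row tibble with member counts and mean holdout AUC.
#' @export
glance.ensemble_model <- function(x, ...) {
  mt <- x$member_table
  tibble::tibble(n_members = nrow(mt), n_included = sum(mt$included),
                 mean_holdout_auc = mean(mt$holdout_auc, na.rm = TRUE),
                 threshold = x$threshold, fallback = x$fallback)
}

#' Consensus prediction at new data points
#'
#' AUC-weighted convex combination of the included members' probabilities.
#'
#' @param ensemble An [build_ensemble()] result.
#' @param newdata Tibble holding the ensemble's predictor columns.
#' @return Numeric vector of suitabilities in `[0, 1]`.
#' @export
predict_ensemble <- function(ensemble, newdata) {
  mt <- ensemble$member_table
  idx <- which(mt$included)
  w <- mt$weight[idx]
  preds <- vapply(idx, function(i) {
    m <- ensemble$members[[i]]
    m$predict_fn(m$model, newdata)
  }, numeric(nrow(newdata)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
  as.numeric(preds %*% w / sum(w))
}

#' Fit the full split-sample ensemble for one species and predictor set
#'
#' Runs the stratified split-sample procedure, fits every algorithm on every
#' replicate (30 x algorithms candidate members by default), and pools all
#' algorithm-by-replicate members into the AUC-weighted consensus.
#' Single-class training folds are skipped and logged.
#'
#' @param data Tibble with binary `detected` and predictor columns.
#' @param predictors Character vector (max 3) of predictor names.
#' @param algorithms Names from [learner_registry()].
#' @param n_replicates Number of split-sample replicates.
#' @param train_fraction Calibration fraction per replicate.
#' @param threshold Ensemble AUC inclusion cutoff.
#' @param seed Integer seed.
#' @return An `ensemble_model`; `$skips` records dropped folds,
#'   `$partitions` the replicate partitions.
#' @export
fit_ensemble_model <- function(data, predictors, algorithms = c("glm", "rf", "gbm"),
                               n_replicates = 30, train_fraction = 0.7,
                               threshold = 0.65, seed = 1L) {
  partitions <- split_sample(data$detected, n_replicates, train_fraction, seed)
  members <- list()
  skips <- tibble::tibble(algorithm = character(), replicate = integer())
  k <- 0L
  for (r in seq_along(partitions)) {
    for (alg in algorithms) {
      k <- k + 1L
      fit <- tryCatch(
        fit_single(data, partitions[[r]], predictors, alg,
                   replicate = r, seed = child_seed(seed, 100L + k)),
        nichetransfer_fold_skip = function(e) NULL
      )
      if (is.null(fit)) {
        skips <- dplyr::bind_rows(skips,
                                  tibble::tibble(algorithm = alg, replicate = r))
      } else {
        members[[length(members) + 1L]] <- fit
      }
    }
  }
  ens <- build_ensemble(members, threshold, predictors)
  ens$partitions <- partitions
  ens$skips <- skips
  ens$data <- data
  ens
}

#' Predict a suitability map from an ensemble or single fit
#'
#' Evaluates the model cell-wise over a named predictor stack (standardized
#' with the calibration-epoch statistics). Nodata propagates.
#'
#' @param object An `ensemble_model` or `single_model_fit`.
#' @param predictor_stack Named list of co-registered [raster_grid()]s
#'   containing every predictor the model was trained on.
#' @return A [raster_grid()] of suitabilities in `[0, 1]`.
#' @export
predict_map <- function(object, predictor_stack) {
  predictors <- if (inherits(object, "ensemble_model")) object$predictors else {
    stop_if_not_fit <- inherits(object, "single_model_fit")
    if (!stop_if_not_fit) stop("predict_map: unsupported object", call. = FALSE)
    attr(object, "predictors") %||% names(predictor_stack)
  }
  missing <- setdiff(predictors, names(predictor_stack))
  if (length(missing)) {
    stop("predict_map: predictor(s) missing from stack: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  template <- predictor_stack[[predictors[1]]]
  mask <- Reduce(`|`, lapply(predictor_stack[predictors],
                             function(g) g$nodata_mask))
  newdata <- tibble::as_tibble(lapply(predictor_stack[predictors],
                                      function(g) as.numeric(g$values)))
  p <- if (inherits(object, "ensemble_model")) {
    predict_ensemble(object, newdata)
  } else {
    object$predict_fn(object$model, newdata)
  }
  v <- matrix(p, template$n_rows, template$n_cols)
  v[mask] <- NA_real_
  grid_like(template, v, mask)
}

#' Fit a combined (suitability-stacked) ensemble
#'
#' The combined models of the framework: the suitability surfaces predicted by
#' two or three individual ensembles become the predictor variables of a fresh
#' ensemble run, which keeps every model trivariate at most by construction.
#'
#' @param suitability_maps Named list of 2–3 co-registered suitability
#'   [raster_grid()]s.
#' @param occ Calibration occurrence tibble (`x`, `y`, `detected`).
#' @param ... Passed on to [fit_ensemble_model()].
#' @param seed Integer seed.
#' @return An `ensemble_model` whose predictors are the input map names.
#' @export
build_combined <- function(suitability_maps, occ, ..., seed = 1L) {
  n <- length(suitability_maps)
  if (n < 2 || n > 3) {
    stop("build_combined: needs 2 or 3 suitability maps", call. = FALSE)
  }
  data <- tibble::as_tibble(lapply(suitability_maps, function(g) {
    extract_at(g, occ$x, occ$y)
  }))
  data$detected <- occ$detected
  keep <- stats::complete.cases(data)
  fit_ensemble_model(data[keep, ], names(suitability_maps), ..., seed = seed)
}

#' Fit the regional climate ensemble at coarse resolution
#'
#' Standard ensemble fitted to coarse-grid occurrences on the three regional
#' bioclimatic predictors; the standardization statistics of the regional
#' calibration data are stored on the result so later projections reuse them.
#'
#' @param coarse_occ Tibble (`x`, `y`, `detected`) of regional occurrences.
#' @param coarse_bioclim Named list of coarse `bio5`, `bio12`, `bio15`
#'   [raster_grid()]s (unstandardized).
#' @param ... Passed on to [fit_ensemble_model()].
#' @param seed Integer seed.
#' @return An `ensemble_model` with `$standardize_stats`.
#' @export
fit_regional_climate <- function(coarse_occ, coarse_bioclim, ..., seed = 1L) {
  std <- standardize_stack(coarse_bioclim)
  data <- tibble::as_tibble(lapply(std$layers, function(g) {
    extract_at(g, coarse_occ$x, coarse_occ$y)
  }))
  data$detected <- coarse_occ$detected
  keep <- stats::complete.cases(data)
  ens <- fit_ensemble_model(data[keep, ], names(coarse_bioclim), ..., seed = seed)
  ens$standardize_stats <- std$stats
  ens
}

#' Direct downscaling of a regional climate model
#'
#' Evaluates the regional response surface cell-wise on fine-resolution
#' climate layers (the "direct" approach): the fine stack is standardized with
#' the regional model's own training statistics and the regional ensemble is
#' predicted on it. The result feeds combined models as the climate component
#' of the hierarchical approach.
#'
#' @param regional_model Result of [fit_regional_climate()].
#' @param fine_bioclim Named list of fine-resolution `bio5`, `bio12`, `bio15`
#'   [raster_grid()]s (unstandardized).
#' @return A fine-resolution suitability [raster_grid()].
#' @export
project_direct <- function(regional_model, fine_bioclim) {
  stopifnot(inherits(regional_model, "ensemble_model"))
  if (is.null(regional_model$standardize_stats)) {
    stop("project_direct: regional model carries no standardization statistics",
         call. = FALSE)
  }
  std <- standardize_stack(fine_bioclim,
                           reference_stats = regional_model$standardize_stats)
  predict_map(regional_model, std$layers)
}
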