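#' Area under the ROC curve (Mann–Whitney formulation)
#'
#' The probability that a randomly chosen presence outscores a randomly chosen
#' absence, ties counting one half — computed from midranks, which is exactly
#' the pairwise fraction.
#'
#' @param presence_scores,absence_scores Numeric score vectors (each
#'   non-empty).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(presence_scores, absence_scores) {
  n_p <- length(presence_scores)
  n_a <- length(absence_scores)
  if (n_p < 1 || n_a < 1) {
    stop("auc: both classes need at least one score", call. = FALSE)
  }
  r <- rank(c(presence_scores, absence_scores), ties.method = "average")
  (sum(r[seq_len(n_p)]) - n_p * (n_p + 1) / 2) / (n_p * n_a)
}

#' Threshold-dependent accuracy metrics from a 2x2 confusion table
#'
#' Predicted presence is `score >= threshold`. Sensitivity is the proportion
#' of observed presences predicted present, specificity its absence
#' counterpart, TSS their sum minus one, and kappa the chance-corrected
#' agreement of the standard 2x2 table.
#'
#' @param scores Numeric suitability scores.
#' @param observed Binary observations (0/1).
#' @param threshold Binarization threshold in `[0, 1]`.
#' @return One-row tibble: `sensitivity`, `specificity`, `tss`, `kappa`,
#'   `threshold`.
#' @export
confusion_metrics <- function(scores, observed, threshold) {
  if (!any(observed == 1) || !any(observed == 0)) {
    stop("confusion_metrics: need both presences and absences", call. = FALSE)
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & observed == 1)
  fn <- sum(pred == 0 & observed == 1)
  tn <- sum(pred == 0 & observed == 0)
  fp <- sum(pred == 1 & observed == 0)
  n <- tp + fn + tn + fp
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  p_o <- (tp + tn) / n
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (abs(1 - p_e) < 1e-12) 0 else (p_o - p_e) / (1 - p_e)
  tibble::tibble(sensitivity = sens, specificity = spec,
                 tss = sens + spec - 1, kappa = kappa, threshold = threshold)
}

#' Threshold maximizing the true skill statistic
#'
#' Scans the observed unique scores as candidate thresholds and returns the
#' smallest one attaining the maximal TSS.
#'
#' @param scores Numeric suitability scores.
#' @param observed Binary observations (0/1).
#' @return A single threshold value.
#' @export
max_tss_threshold <- function(scores, observed) {
  if (!any(observed == 1) || !any(observed == 0)) {
    stop("max_tss_threshold: need both presences and absences", call. = FALSE)
  }
  cand <- sort(unique(scores))
  tss <- vapply(cand, function(th) {
    confusion_metrics(scores, observed, th)$tss
  }, numeric(1))
  cand[which.max(tss)]  # which.max takes the first (smallest) on ties
}

#' Schoener's D niche overlap between two suitability surfaces
#'
#' Both maps are normalized to sum one over their shared unmasked cells;
#' `D = 1 - 0.5 * sum |p_a - p_b|`, so identical surfaces score 1 and surfaces
#' with disjoint support score 0. Invariant to positive rescaling of either
#' map.
#'
#' @param map_a,map_b Co-registered nonnegative [raster_grid()]s.
#' @return Overlap in `[0, 1]`.
#' @export
schoener_d <- function(map_a, map_b) {
  if (!same_geometry(map_a, map_b)) {
    stop("schoener_d: maps are not co-registered", call. = FALSE)
  }
  ok <- !(map_a$nodata_mask | map_b$nodata_mask)
  a <- map_a$values[ok]
  b <- map_b$values[ok]
  if (any(a < 0) || any(b < 0)) {
    stop("schoener_d: maps must be nonnegative", call. = FALSE)
  }
  if (sum(a) <= 0 || sum(b) <= 0) {
    stop("schoener_d: cannot normalize an all-zero map", call. = FALSE)
  }
  1 - 0.5 * sum(abs(a / sum(a) - b / sum(b)))
}

#' Count species exceeding an AUC cut
#'
#' The complementary transferability indicator: how many species hold an AUC
#' strictly above `auc_cut` (0.7 by default) under a given evaluation regime.
#'
#' @param records Eval-record tibble with `species_id` and `auc` (one row per
#'   species, or several — the species' best row is not taken: rows are
#'   expected to be unique per species within one regime).
#' @param auc_cut Strict lower AUC bound.
#' @return Integer count.
#' @export
count_transferable <- function(records, auc_cut = 0.7) {
  if (!nrow(records)) return(0L)
  sum(records$auc > auc_cut)
}

#' Evaluate an ensemble under one evaluation regime
#'
#' Three regimes:
#' \describe{
#'   \item{crossvalidation}{AUC is the mean over split-sample replicates of
#'     the consensus prediction on that replicate's held-out fold (calibration
#'     epoch). Binary metrics come from the t0 suitability map scored at the
#'     calibration points.}
#'   \item{internal_tt}{the t1 suitability map scored at the revisited
#'     calibration locations against t1 detections.}
#'   \item{external_tt}{the t1 map scored at the spatially distinct t1
#'     locations.}
#' }
#' Binary metrics always use the calibration-data max-TSS threshold, frozen at
#' t0 and passed in for the transferability regimes.
#'
#' @param ensemble An `ensemble_model` from [fit_ensemble_model()].
#' @param suit_map Suitability [raster_grid()] at the regime's epoch.
#' @param occ Occurrence tibble subset matching the regime's protocol
#'   (`x`, `y`, `detected`, `epoch`, `protocol`).
#' @param eval_type `"crossvalidation"`, `"internal_tt"` or `"external_tt"`.
#' @param threshold Frozen t0 threshold; required for the transferability
#'   regimes, computed from `suit_map` + `occ` when `NULL` under
#'   crossvalidation.
#' @return One-row EvalRecord tibble: `eval_type`, `auc`, `sensitivity`,
#'   `specificity`, `tss`, `kappa`, `threshold`, `n`.
#' @export
evaluate_model <- function(ensemble, suit_map, occ,
                           eval_type = c("crossvalidation", "internal_tt",
                                         "external_tt"),
                           threshold = NULL) {
  eval_type <- match.arg(eval_type)
  expected_protocol <- switch(eval_type,
                              crossvalidation = "calibration",
                              internal_tt = "internal_tt",
                              external_tt = "external_tt")
  if (!all(occ$protocol == expected_protocol)) {
    stop("evaluate_model: occurrence protocol does not match eval_type '",
         eval_type, "'", call. = FALSE)
  }
  if (eval_type != "crossvalidation" && !all(occ$epoch == "t1")) {
    stop("evaluate_model: transferability regimes need t1 occurrences",
         call. = FALSE)
  }

  scores <- extract_at(suit_map, occ$x, occ$y)
  ok <- !is.na(scores)
  scores <- scores[ok]
  observed <- occ$detected[ok]

  if (eval_type == "crossvalidation") {
    if (is.null(threshold)) threshold <- max_tss_threshold(scores, observed)
    # per-replicate consensus over that replicate's own members, so the
    # held-out fold is never seen by any contributing fit
    mt <- ensemble$member_table
    reps <- vapply(seq_along(ensemble$partitions), function(r) {
      p <- ensemble$partitions[[r]]
      y <- ensemble$data$detected[p$test]
      if (length(unique(y)) < 2L) return(NA_real_)
      idx <- which(mt$replicate == r & mt$included)
      if (!length(idx)) {
        idx <- which(mt$replicate == r)
        if (!length(idx)) return(NA_real_)
        best <- idx[which.max(mt$holdout_auc[idx])]
        idx <- best
      }
      w <- pmax(mt$holdout_auc[idx], 1e-6)
      preds <- vapply(idx, function(i) ensemble$members[[i]]$test_pred,
                      numeric(length(p$test)))
      if (is.null(dim(preds))) preds <- matrix(preds, nrow = length(p$test))
      s <- as.numeric(preds %*% w / sum(w))
      auc(s[y == 1], s[y == 0])
    }, numeric(1))
    auc_value <- mean(reps, na.rm = TRUE)
  } else {
    if (is.null(threshold)) {
      stop("evaluate_model: transferability regimes need the frozen t0 threshold",
           call. = FALSE)
    }
    auc_value <- auc(scores[observed == 1], scores[observed == 0])
  }

  cm <- confusion_metrics(scores, observed, threshold)
  tibble::tibble(eval_type = eval_type, auc = auc_value,
                 sensitivity = cm$sensitivity, specificity = cm$specificity,
                 tss = cm$tss, kappa = cm$kappa, threshold = threshold,
                 n = length(scores))
}

#' Mean niche-overlap matrix between predictor sets
#'
#' Pairwise Schoener's D between the suitability maps of different predictor
#' sets, averaged across species, one matrix per epoch.
#'
#' @param maps Nested named list: `maps[[species_id]][[predictor_set]]` is a
#'   suitability [raster_grid()].
#' @return Tibble with `set_a`, `set_b`, `mean_d`, `n_species`.
#' @export
overlap_matrix <- function(maps) {
  sets <- names(maps[[1]])
  pairs <- expand.grid(set_a = sets, set_b = sets, stringsAsFactors = FALSE)
  purrr::pmap_dfr(pairs, function(set_a, set_b) {
    d <- vapply(maps, function(by_set) {
      schoener_d(by_set[[set_a]], by_set[[set_b]])
    }, numeric(1))
    tibble::tibble(set_a = set_a, set_b = set_b,
                   mean_d = mean(d), n_species = length(d))
  })
}
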