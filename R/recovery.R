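#' Reduced-scale transferability trial
#'
#' A light version of the full experiment used to validate the framework's
#' central transferability contrast: simulate a world with (or without)
#' environmental change, fit the three individual predictor-family ensembles
#' per species, and return the cross-validation and internal-transferability
#' AUC per species and family. With nonzero change the cross-validation AUC
#' should exceed the internal-transferability AUC on average; with
#' [no_change()] the two regimes should be statistically indistinguishable.
#'
#' @param seed Integer seed.
#' @param change A [change_scenario()].
#' @param n_species Number of virtual species.
#' @param world A [world_config()] (default: a 30 x 30 fine grid).
#' @param design A [survey_design()] scaled to the grid.
#' @param algorithms,n_replicates Ensemble settings.
#' @return Tibble: `species_id`, `predictor_set`, `cv_auc`, `internal_auc`.
#' @export
run_transfer_trial <- function(seed, change = change_scenario(),
                               n_species = 3,
                               world = world_config(n_rows = 30, n_cols = 30),
                               design = survey_design(150, 90, 150),
                               algorithms = "glm", n_replicates = 5) {
  w <- make_world(world, seed = child_seed(seed, 1L))
  w <- apply_change(w, change, seed = child_seed(seed, 2L))
  species <- make_virtual_species(n_species, seed = child_seed(seed, 3L))
  p0 <- derive_local_predictors(w, "t0")
  p1 <- derive_local_predictors(w, "t1")
  std0 <- standardize_stack(p0)
  std1 <- standardize_stack(p1, reference_stats = std0$stats)
  suit0 <- purrr::map(seq_len(n_species),
                      function(i) true_suitability(species[i, ], std0$layers))
  suit1 <- purrr::map(seq_len(n_species), function(i) {
    true_suitability(species[i, ], std1$layers,
                     logit_offset = disturbance_field(w, i,
                                                      seed = child_seed(seed, 5L)))
  })
  names(suit0) <- names(suit1) <- species$species_id
  occ <- sample_surveys(suit0, suit1, design, seed = child_seed(seed, 4L))
  retained <- prevalence_filter(occ)
  fam <- predictor_families()

  purrr::map_dfr(retained$species_id[retained$retained], function(sid) {
    cal <- dplyr::filter(occ, .data$species_id == sid,
                         .data$protocol == "calibration")
    int <- dplyr::filter(occ, .data$species_id == sid,
                         .data$protocol == "internal_tt")
    purrr::imap_dfr(fam, function(preds, f) {
      data <- extract_stack(std0$layers[preds], cal)
      ens <- suppressWarnings(
        fit_ensemble_model(data, preds, algorithms, n_replicates,
                           seed = child_seed(seed, 100L + match(sid, names(suit0)) * 10L +
                                               match(f, names(fam)))))
      map0 <- predict_map(ens, std0$layers[preds])
      map1 <- predict_map(ens, std1$layers[preds])
      s0 <- extract_at(map0, cal$x, cal$y)
      th <- max_tss_threshold(s0, cal$detected)
      cv <- evaluate_model(ens, map0, cal, "crossvalidation", threshold = th)
      it <- evaluate_model(ens, map1, int, "internal_tt", threshold = th)
      tibble::tibble(species_id = sid, predictor_set = f,
                     cv_auc = cv$auc, internal_auc = it$auc)
    })
  })
}

#' Reduced-scale predictor-combination trial
#'
#' Validates the combined-model gain: for species whose true suitability uses
#' all three driver families, fit the three individual ensembles and the
#' three-way combined (suitability-stacked) ensemble, returning each model's
#' cross-validation AUC. The combined model's mean AUC is expected to reach at
#' least every individual model's in most trials.
#'
#' @inheritParams run_transfer_trial
#' @return Tibble: `species_id`, `predictor_set` (the three families and
#'   `combined`), `cv_auc`.
#' @export
run_combination_trial <- function(seed, n_species = 2,
                                  world = world_config(n_rows = 30, n_cols = 30),
                                  design = survey_design(150, 90, 150),
                                  algorithms = "glm", n_replicates = 5) {
  w <- make_world(world, seed = child_seed(seed, 1L))
  w <- apply_change(w, no_change(), seed = child_seed(seed, 2L))
  species <- make_virtual_species(n_species, families = "all",
                                  seed = child_seed(seed, 3L))
  p0 <- derive_local_predictors(w, "t0")
  std0 <- standardize_stack(p0)
  suit0 <- purrr::map(seq_len(n_species),
                      function(i) true_suitability(species[i, ], std0$layers))
  names(suit0) <- species$species_id
  occ <- sample_surveys(suit0, suit0, design, seed = child_seed(seed, 4L))
  fam <- predictor_families()

  purrr::map_dfr(species$species_id, function(sid) {
    cal <- dplyr::filter(occ, .data$species_id == sid,
                         .data$protocol == "calibration")
    ind <- purrr::imap(fam, function(preds, f) {
      data <- extract_stack(std0$layers[preds], cal)
      suppressWarnings(
        fit_ensemble_model(data, preds, algorithms, n_replicates,
                           seed = child_seed(seed, 200L + match(f, names(fam)))))
    })
    maps <- purrr::map(ind, function(e) predict_map(e, std0$layers[e$predictors]))
    comb <- suppressWarnings(
      build_combined(maps, cal, algorithms = algorithms,
                     n_replicates = n_replicates,
                     seed = child_seed(seed, 250L)))
    comb_map <- predict_map(comb, maps)
    rows <- purrr::imap_dfr(ind, function(e, f) {
      m <- maps[[f]]
      s0 <- extract_at(m, cal$x, cal$y)
      th <- max_tss_threshold(s0, cal$detected)
      tibble::tibble(species_id = sid, predictor_set = f,
                     cv_auc = evaluate_model(e, m, cal, "crossvalidation",
                                             threshold = th)$auc)
    })
    s0 <- extract_at(comb_map, cal$x, cal$y)
    th <- max_tss_threshold(s0, cal$detected)
    dplyr::bind_rows(rows, tibble::tibble(
      species_id = sid, predictor_set = "combined",
      cv_auc = evaluate_model(comb, comb_map, cal, "crossvalidation",
                              threshold = th)$auc))
  })
}

#' Simulate an accuracy table with planted factor effects
#'
#' Generates a species x predictor-set x approach AUC table from a known
#' additive model plus Gaussian noise — the ground-truth harness for
#' validating the multimodel-inference machinery: a planted predictor-set
#' effect with no approach effect should yield a summed Akaike weight near 1
#' for PRED and below 0.5 for APP, and a planted trait effect should be
#' flagged by the trait contrast at p < 0.001.
#'
#' @param n_species Number of simulated species.
#' @param pred_effect AUC increment per predictor-set rank (0 = none).
#' @param app_effect AUC increment of the hierarchical approach (0 = none).
#' @param trait_effect AUC increment for the second trait level (0 = none).
#' @param noise_sd Residual SD of the simulated AUC values.
#' @param seed Integer seed.
#' @return Tibble: `species_id`, `predictor_set`, `approach`, `origin`,
#'   `eval_type`, `auc`.
#' @export
simulate_planted_auc <- function(n_species = 16, pred_effect = 0.05,
                                 app_effect = 0, trait_effect = 0,
                                 noise_sd = 0.03, seed = 1L) {
  sets <- names(predictor_sets())
  with_seed(child_seed(seed, 61L), {
    origin <- sample(rep(c("Eurosiberian", "Mediterranean"),
                         length.out = n_species))
    grid <- tidyr::expand_grid(
      species_id = sprintf("sp%02d", seq_len(n_species)),
      predictor_set = sets,
      approach = c("non_hierarchical", "hierarchical"))
    grid |>
      dplyr::mutate(
        origin = origin[match(.data$species_id,
                              sprintf("sp%02d", seq_len(n_species)))],
        eval_type = "crossvalidation",
        auc = 0.7 +
          pred_effect * (match(.data$predictor_set, sets) - 1) / (length(sets) - 1) +
          app_effect * (.data$approach == "hierarchical") +
          trait_effect * (.data$origin == "Mediterranean") +
          rnorm(dplyr::n(), 0, noise_sd))
  })
}
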