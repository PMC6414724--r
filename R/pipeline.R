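#' Full experiment configuration
#'
#' Bundles every stage's parameters. The defaults are the study conditions the
#' framework emulates: 27 species, 344/204/384 survey points, 30-fold 70/30
#' split-sample, ensemble inclusion at AUC > 0.65, the more-than-15-presences
#' filter, transferability counted at AUC > 0.7, delta-AIC support below 7,
#' importance consequential above 0.5, and the conservative p < 0.001 rule.
#' Reduced settings (smaller grid, fewer species/replicates) are passed
#' explicitly where a faster run is wanted.
#'
#' @param world A [world_config()].
#' @param change A [change_scenario()].
#' @param n_species Number of virtual species.
#' @param trait_design,beta_ranges,families Passed to [make_virtual_species()].
#' @param design A [survey_design()].
#' @param algorithms Learner names from [learner_registry()].
#' @param n_replicates,train_fraction Split-sample settings.
#' @param ensemble_auc_threshold Consensus inclusion cutoff.
#' @param min_presences Strict prevalence filter bound.
#' @param n_regional Regional occurrence points for the hierarchical branch.
#' @param lulc_factor Fractional-cover block size (fine cells).
#' @param auc_cut Transferability count cutoff.
#' @param support_cut Delta-AIC support cutoff.
#' @param alpha Significance level for trait contrasts.
#' @param traits Trait columns to contrast and to cycle through the TRAIT term.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(world = world_config(),
                              change = change_scenario(),
                              n_species = 27,
                              trait_design = "balanced",
                              beta_ranges = c(0.6, 1.4),
                              families = "all",
                              design = survey_design(),
                              algorithms = c("glm", "rf", "gbm"),
                              n_replicates = 30,
                              train_fraction = 0.7,
                              ensemble_auc_threshold = 0.65,
                              min_presences = 15,
                              n_regional = 400,
                              lulc_factor = 2,
                              auc_cut = 0.7,
                              support_cut = 7,
                              alpha = 0.001,
                              traits = c("origin", "phenology",
                                         "specialization", "preference")) {
  structure(as.list(environment()), class = "experiment_config")
}

config_hash <- function(config) rlang::hash(unclass(config))

predictor_sets <- function() {
  list(CLI = "CLI", LULC = "LULC", EFA = "EFA",
       `CLI+LULC` = c("CLI", "LULC"), `CLI+EFA` = c("CLI", "EFA"),
       `LULC+EFA` = c("LULC", "EFA"),
       `CLI+LULC+EFA` = c("CLI", "LULC", "EFA"))
}

#' Sample regional (coarse-grid) occurrences for one species
#'
#' The regional truth uses the species' climate coefficients on the
#' standardized coarse bioclim stack; occurrences are Bernoulli draws at
#' distinct coarse cells.
#'
#' @param species One row of the virtual-species tibble.
#' @param coarse_bioclim Named list of coarse `bio5`, `bio12`, `bio15` grids
#'   (unstandardized).
#' @param n_points Number of coarse survey cells.
#' @param seed Integer seed.
#' @return Tibble (`x`, `y`, `detected`).
#' @export
sample_regional_occurrences <- function(species, coarse_bioclim, n_points = 400,
                                        seed = 1L) {
  std <- standardize_stack(coarse_bioclim)
  beta <- species$beta[[1]]
  clim <- beta[intersect(names(beta), names(coarse_bioclim))]
  truth <- true_suitability(list(beta0 = species$beta0[1], beta = clim),
                            std$layers)
  cells <- cell_centres(truth)
  ok <- !truth$nodata_mask[cbind(cells$row, cells$col)]
  cells <- cells[ok, ]
  with_seed(child_seed(seed, 51L), {
    idx <- sample(nrow(cells), min(n_points, nrow(cells)))
    p <- extract_at(truth, cells$x[idx], cells$y[idx])
    tibble::tibble(x = cells$x[idx], y = cells$y[idx],
                   detected = rbinom(length(idx), 1L, p))
  })
}

extract_stack <- function(stack, occ) {
  out <- tibble::as_tibble(lapply(stack, function(g) extract_at(g, occ$x, occ$y)))
  out$detected <- occ$detected
  out
}

#' Run the full in-silico experiment
#'
#' Orchestrates the pipeline end to end: simulate the two-epoch world and
#' virtual species; derive predictors; sample the three surveys and apply the
#' prevalence filter; fit the seven predictor sets under the hierarchical and
#' non-hierarchical approaches per species; evaluate cross-validation and
#' internal/external temporal transferability; compute the niche-overlap
#' matrices; and run the AIC multimodel inference and trait contrasts.
#' Deterministic for a fixed seed.
#'
#' Predictor sets that involve no climate (LULC, EFA, LULC+EFA) are identical
#' under the two approaches; they are fitted once and reported under both
#' labels. Under the hierarchical approach the climate component is the
#' direct-downscaled projection of the regional climate ensemble.
#'
#' @param config An [experiment_config()].
#' @param seed Integer master seed.
#' @param verbose Emit stage-level progress messages.
#' @return List of class `enm_experiment`: `eval_records`, `overlap`,
#'   `inference`, `trait_contrasts`, `species`, `prevalence`, `occurrences`,
#'   `n_transferable`, `manifest`, `world`.
#' @export
run_experiment <- function(config = experiment_config(), seed = 1L,
                           verbose = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  t_start <- Sys.time()
  hash <- config_hash(config)
  say <- function(...) if (verbose) message(sprintf(...))
  warnings_log <- character()
  log_warning <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  # --- simulate ------------------------------------------------------------
  say("stage simulate: world + species")
  world <- make_world(config$world, seed = child_seed(seed, 1L))
  world <- apply_change(world, config$change, seed = child_seed(seed, 2L))
  species <- make_virtual_species(config$n_species, config$trait_design,
                                  config$beta_ranges, config$families,
                                  seed = child_seed(seed, 3L))

  # --- derive --------------------------------------------------------------
  say("stage derive: predictor families at both epochs")
  local_t0 <- derive_local_predictors(world, "t0", config$lulc_factor)
  local_t1 <- derive_local_predictors(world, "t1", config$lulc_factor)
  std0 <- standardize_stack(local_t0)
  std1 <- standardize_stack(local_t1, reference_stats = std0$stats)
  coarse_bio0 <- derive_regional_bioclim(world, "t0")
  fine_bio0 <- local_t0[c("bio5", "bio12", "bio15")]
  fine_bio1 <- local_t1[c("bio5", "bio12", "bio15")]

  suit_t0 <- purrr::map(seq_len(nrow(species)), function(i) {
    true_suitability(species[i, ], std0$layers)
  })
  suit_t1 <- purrr::map(seq_len(nrow(species)), function(i) {
    true_suitability(species[i, ], std1$layers,
                     logit_offset = disturbance_field(world, i,
                                                      seed = child_seed(seed, 5L)))
  })
  names(suit_t0) <- names(suit_t1) <- species$species_id

  # --- survey --------------------------------------------------------------
  say("stage survey: %d/%d/%d points", config$design$n_calibration,
      config$design$n_internal, config$design$n_external)
  occ <- sample_surveys(suit_t0, suit_t1, config$design,
                        seed = child_seed(seed, 4L))
  prevalence <- prevalence_filter(occ, config$min_presences)
  retained <- prevalence$species_id[prevalence$retained]
  say("stage survey: %d of %d species pass the prevalence filter",
      length(retained), nrow(species))

  fam <- predictor_families()
  family_stack <- function(std_layers, f) std_layers[fam[[f]]]
  sets <- predictor_sets()
  eval_rows <- list()
  overlap_maps <- list(t0 = list(), t1 = list())

  # --- fit + evaluate ------------------------------------------------------
  for (sid in retained) {
    say("stage fit: species %s", sid)
    sp <- species[species$species_id == sid, ]
    cal <- dplyr::filter(occ, .data$species_id == sid,
                         .data$protocol == "calibration")
    int <- dplyr::filter(occ, .data$species_id == sid,
                         .data$protocol == "internal_tt")
    ext <- dplyr::filter(occ, .data$species_id == sid,
                         .data$protocol == "external_tt")
    sp_seed <- child_seed(seed, 1000L + match(sid, species$species_id))

    fit_fam <- function(f, k) {
      data <- extract_stack(family_stack(std0$layers, f), cal)
      withCallingHandlers(
        fit_ensemble_model(data, fam[[f]], config$algorithms,
                           config$n_replicates, config$train_fraction,
                           config$ensemble_auc_threshold,
                           seed = child_seed(sp_seed, k)),
        warning = log_warning)
    }
    ind <- list(CLI = fit_fam("CLI", 1L), LULC = fit_fam("LULC", 2L),
                EFA = fit_fam("EFA", 3L))
    ind_maps0 <- purrr::map(ind, function(e) {
      predict_map(e, std0$layers[e$predictors])
    })
    ind_maps1 <- purrr::map(ind, function(e) {
      predict_map(e, std1$layers[e$predictors])
    })

    regional <- withCallingHandlers({
      reg_occ <- sample_regional_occurrences(sp, coarse_bio0, config$n_regional,
                                             seed = sp_seed)
      fit_regional_climate(reg_occ, coarse_bio0, algorithms = config$algorithms,
                           n_replicates = config$n_replicates,
                           train_fraction = config$train_fraction,
                           threshold = config$ensemble_auc_threshold,
                           seed = child_seed(sp_seed, 4L))
    }, warning = log_warning)
    hier_cli0 <- project_direct(regional, fine_bio0)
    hier_cli1 <- project_direct(regional, fine_bio1)

    # climate component map per approach, at each epoch
    cli_map <- list(non_hierarchical = list(t0 = ind_maps0$CLI, t1 = ind_maps1$CLI),
                    hierarchical = list(t0 = hier_cli0, t1 = hier_cli1))

    eval_three <- function(ensemble, map0, map1, set_name, approach) {
      scores_all <- extract_at(map0, cal$x, cal$y)
      ok0 <- !is.na(scores_all)
      scores0 <- scores_all[ok0]
      obs0 <- cal$detected[ok0]
      th <- max_tss_threshold(scores0, obs0)
      cv <- if (is.null(ensemble)) {
        # projection-only model (hierarchical CLI): the regional fit never saw
        # local data, so the plain map AUC at calibration points is out-of-sample
        cm <- confusion_metrics(scores0, obs0, th)
        tibble::tibble(eval_type = "crossvalidation",
                       auc = auc(scores0[obs0 == 1], scores0[obs0 == 0]),
                       sensitivity = cm$sensitivity, specificity = cm$specificity,
                       tss = cm$tss, kappa = cm$kappa, threshold = th,
                       n = length(scores0))
      } else {
        evaluate_model(ensemble, map0, cal, "crossvalidation", threshold = th)
      }
      dplyr::bind_rows(
        cv,
        evaluate_model(ensemble %||% list(), map1, int, "internal_tt",
                       threshold = th),
        evaluate_model(ensemble %||% list(), map1, ext, "external_tt",
                       threshold = th)
      ) |>
        dplyr::mutate(species_id = sid, predictor_set = set_name,
                      approach = approach, .before = 1)
    }

    for (approach in c("non_hierarchical", "hierarchical")) {
      for (set_name in names(sets)) {
        comps <- sets[[set_name]]
        no_climate <- !"CLI" %in% comps
        if (no_climate && approach == "hierarchical") {
          # identical to the non-hierarchical fit: relabel those records
          prev <- eval_rows[[paste(sid, set_name, "non_hierarchical")]]
          eval_rows[[paste(sid, set_name, approach)]] <-
            dplyr::mutate(prev, approach = .env$approach)
          next
        }
        if (length(comps) == 1L) {
          if (comps == "CLI") {
            if (approach == "non_hierarchical") {
              rec <- eval_three(ind$CLI, ind_maps0$CLI, ind_maps1$CLI,
                                set_name, approach)
              map0 <- ind_maps0$CLI; map1 <- ind_maps1$CLI
            } else {
              rec <- eval_three(NULL, hier_cli0, hier_cli1, set_name, approach)
              map0 <- hier_cli0; map1 <- hier_cli1
            }
          } else {
            rec <- eval_three(ind[[comps]], ind_maps0[[comps]],
                              ind_maps1[[comps]], set_name, approach)
            map0 <- ind_maps0[[comps]]; map1 <- ind_maps1[[comps]]
          }
        } else {
          maps0 <- purrr::map(stats::setNames(comps, comps), function(f) {
            if (f == "CLI") cli_map[[approach]]$t0 else ind_maps0[[f]]
          })
          maps1 <- purrr::map(stats::setNames(comps, comps), function(f) {
            if (f == "CLI") cli_map[[approach]]$t1 else ind_maps1[[f]]
          })
          comb <- withCallingHandlers(
            build_combined(maps0, cal, algorithms = config$algorithms,
                           n_replicates = config$n_replicates,
                           train_fraction = config$train_fraction,
                           threshold = config$ensemble_auc_threshold,
                           seed = child_seed(sp_seed, 10L + match(set_name, names(sets)) +
                                               ifelse(approach == "hierarchical", 20L, 0L))),
            warning = log_warning)
          map0 <- predict_map(comb, maps0)
          map1 <- predict_map(comb, maps1)
          rec <- eval_three(comb, map0, map1, set_name, approach)
        }
        eval_rows[[paste(sid, set_name, approach)]] <- rec
        if (approach == "non_hierarchical") {
          overlap_maps$t0[[sid]][[set_name]] <- map0
          overlap_maps$t1[[sid]][[set_name]] <- map1
        }
      }
    }
  }

  say("stage evaluate: assembling records + overlap matrices")
  eval_records <- dplyr::bind_rows(eval_rows) |>
    dplyr::left_join(dplyr::select(species, "species_id", "origin", "phenology",
                                   "specialization", "preference"),
                     by = "species_id")
  attr(eval_records, "config_hash") <- hash

  overlap <- purrr::imap_dfr(overlap_maps, function(maps, ep) {
    dplyr::mutate(overlap_matrix(maps), epoch = ep)
  })

  n_transferable <- eval_records |>
    dplyr::filter(.data$eval_type != "crossvalidation") |>
    dplyr::group_by(.data$eval_type, .data$predictor_set, .data$approach) |>
    dplyr::summarise(n_species = dplyr::n(),
                     n_transferable = count_transferable(
                       dplyr::pick("auc"), config$auc_cut),
                     .groups = "drop")

  # --- infer ---------------------------------------------------------------
  say("stage infer: multimodel inference + trait contrasts")
  inference <- run_inference(eval_records, traits = config$traits,
                             support_cut = config$support_cut)
  trait_contrasts <- purrr::map_dfr(config$traits, function(tr) {
    withCallingHandlers(
      trait_contrast_table(eval_records, tr, alpha = config$alpha),
      warning = log_warning)
  })

  manifest <- list(config_hash = hash, seed = seed,
                   package_version = as.character(utils::packageVersion("nichetransfer")),
                   r_version = as.character(getRversion()),
                   n_species_retained = length(retained),
                   warnings = warnings_log,
                   wall_time_s = as.numeric(difftime(Sys.time(), t_start,
                                                     units = "secs")))
  structure(list(eval_records = eval_records, overlap = overlap,
                 inference = inference, trait_contrasts = trait_contrasts,
                 species = species, prevalence = prevalence, occurrences = occ,
                 n_transferable = n_transferable, manifest = manifest,
                 world = world, config = config),
            class = "enm_experiment")
}

#' @export
print.enm_experiment <- function(x, ...) {
  cat(sprintf("<enm_experiment> %d species, %d eval records, seed hash %s\n",
              x$manifest$n_species_retained, nrow(x$eval_records),
              substr(x$manifest$config_hash, 1, 8)))
  summ <- x$eval_records |>
    dplyr::group_by(.data$eval_type) |>
    dplyr::summarise(auc_mean = mean(.data$auc), auc_sd = stats::sd(.data$auc))
  print(summ)
  invisible(x)
}

#' Multimodel inference on an eval-record table
#'
#' Runs the all-subsets Gaussian GLM dredge on AUC with factors PRED
#' (predictor set), APP (modelling approach) and TRAIT, separately per
#' evaluation regime; the TRAIT term cycles through the trait columns, one
#' dredge per trait. Tables from a different run (mismatching config hash on
#' the records) are rejected.
#'
#' @param eval_records Eval-record tibble from [run_experiment()].
#' @param traits Trait columns to use as the TRAIT factor.
#' @param support_cut Delta-AIC support cutoff.
#' @param expected_hash Optional config hash the records must carry.
#' @return Nested list: `inference[[eval_type]][[trait]]` is an
#'   `inference_table`.
#' @export
run_inference <- function(eval_records,
                          traits = c("origin", "phenology", "specialization",
                                     "preference"),
                          support_cut = 7, expected_hash = NULL) {
  if (!is.null(expected_hash) &&
      !identical(attr(eval_records, "config_hash"), expected_hash)) {
    stop("run_inference: eval records carry a different config hash — ",
         "refusing to mix tables from different runs", call. = FALSE)
  }
  purrr::map(split(eval_records, eval_records$eval_type), function(sub) {
    purrr::map(stats::setNames(traits, traits), function(tr) {
      d <- tibble::tibble(auc = sub$auc, PRED = sub$predictor_set,
                          APP = sub$approach, TRAIT = sub[[tr]])
      keep <- c("PRED", "APP", "TRAIT")[c(length(unique(d$PRED)) > 1,
                                          length(unique(d$APP)) > 1,
                                          length(unique(d$TRAIT)) > 1)]
      dredge_all_subsets(d, "auc", keep, support_cut)
    })
  })
}
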