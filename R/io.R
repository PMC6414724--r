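occ_protocols <- c("calibration", "internal_tt", "external_tt")

#' Write / read occurrence tables
#'
#' CSV with header `species_id, x, y, detected, epoch, protocol`. Reading
#' validates the schema: a missing column, a non-binary `detected`, an unknown
#' epoch or protocol all raise an error naming the column and the first
#' offending row.
#'
#' @param occ Occurrence tibble.
#' @param path CSV path.
#' @return `path` invisibly / the validated tibble.
#' @export
write_occurrences <- function(occ, path) {
  readr::write_csv(occ[c("species_id", "x", "y", "detected", "epoch",
                         "protocol")], path)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  occ <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("species_id", "x", "y", "detected", "epoch", "protocol")
  missing <- setdiff(need, names(occ))
  if (length(missing)) {
    stop("read_occurrences: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  check_vocab <- function(col, vocab) {
    bad <- which(!occ[[col]] %in% vocab)
    if (length(bad)) {
      stop("read_occurrences: invalid value '", occ[[col]][bad[1]],
           "' in column '", col, "' at row ", bad[1], call. = FALSE)
    }
  }
  check_vocab("detected", c(0L, 1L))
  check_vocab("epoch", c("t0", "t1"))
  check_vocab("protocol", occ_protocols)
  occ
}

trait_vocab <- list(origin = c("Eurosiberian", "Mediterranean"),
                    specialization = c("generalist", "specialist"),
                    preference = c("forest", "open"),
                    phenology = c("sedentary", "migrant"))

#' Read a species-trait table
#'
#' CSV with header `species_id, acronym, origin, specialization, preference,
#' phenology`; every trait cell must come from the controlled binary
#' vocabularies. With no `path`, loads the packaged 27-species reference table
#' of breeding-bird traits (biogeographic origin, habitat specialization and
#' preference, phenology).
#'
#' @param path Optional CSV path.
#' @return Validated trait tibble.
#' @export
read_trait_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "species_traits.csv",
                                package = "nichetransfer", mustWork = TRUE)
  tr <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("species_id", "acronym", names(trait_vocab))
  missing <- setdiff(need, names(tr))
  if (length(missing)) {
    stop("read_trait_table: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in names(trait_vocab)) {
    bad <- which(!tr[[col]] %in% trait_vocab[[col]])
    if (length(bad)) {
      stop("read_trait_table: invalid value '", tr[[col]][bad[1]],
           "' in column '", col, "' at row ", bad[1], call. = FALSE)
    }
  }
  tr
}

#' Write / read an experiment configuration as YAML
#'
#' The configuration round-trips losslessly: reading a written file rebuilds
#' the same [experiment_config()] (component constructors re-validate every
#' field on the way in).
#'
#' @param config An [experiment_config()].
#' @param path YAML file path.
#' @return `path` invisibly / the rebuilt `experiment_config`.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  plain <- unclass(config)
  plain$world <- unclass(plain$world)
  plain$world$class_props <- as.list(plain$world$class_props)
  plain$change <- unclass(plain$change)
  plain$design <- unclass(plain$design)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  plain <- yaml::read_yaml(path)
  plain$world$class_props <- unlist(plain$world$class_props)
  plain$world <- do.call(world_config, plain$world)
  plain$change <- do.call(change_scenario, plain$change)
  plain$design <- do.call(survey_design, plain$design)
  plain$beta_ranges <- as.numeric(plain$beta_ranges)
  do.call(experiment_config, plain)
}

#' Write the experiment's result tables and figures to a directory
#'
#' Long-format eval records, the niche-overlap matrix, the per-regime
#' inference tables, the trait contrasts, the run manifest (JSON), and the
#' standard figure panels (accuracy box plots by predictor set and by trait,
#' overlap heat map) as PDF.
#'
#' @param experiment An `enm_experiment` from [run_experiment()].
#' @param outdir Output directory (created if needed).
#' @param figures Also write the PDF panels.
#' @return `outdir`, invisibly.
#' @export
write_report <- function(experiment, outdir, figures = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(experiment$eval_records, file.path(outdir, "eval_records.csv"))
  readr::write_csv(experiment$overlap, file.path(outdir, "niche_overlap.csv"))
  readr::write_csv(experiment$trait_contrasts,
                   file.path(outdir, "trait_contrasts.csv"))
  readr::write_csv(experiment$n_transferable,
                   file.path(outdir, "n_transferable.csv"))
  inf <- purrr::imap_dfr(experiment$inference, function(by_trait, et) {
    purrr::imap_dfr(by_trait, function(tab, tr) {
      dplyr::mutate(tidy(tab), eval_type = et, trait = tr, .before = 1)
    })
  })
  readr::write_csv(inf, file.path(outdir, "inference_tables.csv"))
  jsonlite::write_json(experiment$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (figures) {
    ggplot2::ggsave(file.path(outdir, "performance.pdf"),
                    plot_performance(experiment$eval_records),
                    width = 9, height = 5)
    ggplot2::ggsave(file.path(outdir, "overlap.pdf"),
                    plot_overlap(experiment$overlap), width = 7, height = 5)
    ggplot2::ggsave(file.path(outdir, "traits.pdf"),
                    plot_trait_performance(experiment$eval_records),
                    width = 9, height = 7)
  }
  invisible(outdir)
}
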