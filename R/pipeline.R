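#' Run the full moult-versus-warming analysis
#'
#' Orchestrates every stage on a dataset list (from
#' [simulate_moult_dataset()] or [load_moult_dataset()]): (1) specimen
#' scoring into moulted area and relative extent, (2) the year-averaged
#' normalised moult index, (3) per-species Gamma-GLM AICc selection against
#' GMTA, (4) the comparative stage — PGLS contrasts of the per-species GMTA
#' response between migration-distance classes and between pre- and
#' post-migration moult strategies, and the PGLS regression of the
#' GMTA-by-sex interaction on the male-minus-female ornamentation score —
#' and (5) a run manifest with a config hash. Identical inputs and options
#' give byte-identical outputs; any stage failure aborts with a
#' stage-named error and removes partial outputs.
#'
#' Species with fewer than `min_specimens` usable records are excluded from
#' the modelling and comparative stages with a logged list (the original
#' study restricted itself to species with over a hundred specimens each).
#'
#' @param dataset List with `specimens`, `areas`, `gmta`, `metadata`,
#'   `tree` (and optionally `layout`).
#' @param response,covariate,threshold Passed to [fit_species_models()].
#' @param lambda Pagel's lambda mode for the comparative stage, `"ML"` or a
#'   fixed value.
#' @param min_specimens Minimum usable records per species (default 30).
#' @param min_species_per_year Passed to [annual_moult_index()].
#' @param migration_cutoff_km Distance above which a species counts as a
#'   long-distance migrant when no `migration_class` column is given
#'   (default 2000 km).
#' @param out_dir Optional directory; when given, all result tables (CSV),
#'   PGLS reports (JSON) and the manifest are written there, each table
#'   carrying the manifest hash in a `run_hash` column.
#' @return A list of class `moult_analysis`: `extents`, `moult_index`,
#'   `species_fits`, `selection_table`, `contrast_migration`,
#'   `contrast_strategy`, `ornamentation_fit`, `excluded_species`,
#'   `manifest`.
#' @export
run_full_analysis <- function(dataset,
                              response = c("area", "relative"),
                              covariate = c("gmta", "year"),
                              threshold = 2.00,
                              lambda = "ML",
                              min_specimens = 30L,
                              min_species_per_year = 1L,
                              migration_cutoff_km = 2000,
                              out_dir = NULL) {
  response <- match.arg(response)
  covariate <- match.arg(covariate)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
  }
  need <- c("specimens", "areas", "gmta", "metadata", "tree")
  miss <- need[!need %in% names(dataset)]
  if (length(miss) > 0) {
    rlang::abort(sprintf("[stage validate] dataset is missing: %s",
                         paste(miss, collapse = ", ")))
  }
  layout <- dataset$layout %||% feather_tract_layout()
  if (threshold <= 0) rlang::abort("[stage validate] threshold must be positive.")

  extents <- stage("score", score_moult(dataset$specimens, dataset$areas, layout))
  index <- stage("index", annual_moult_index(extents, min_species_per_year))

  counts <- dplyr::count(extents, .data$species_id)
  excluded <- counts$species_id[counts$n < min_specimens]
  if (length(excluded) > 0) {
    message(sprintf("Excluding %d species with fewer than %d specimens: %s",
                    length(excluded), min_specimens,
                    paste(excluded, collapse = ", ")))
  }
  usable <- extents[!extents$species_id %in% excluded, ]

  species_fits <- stage("fit", fit_species_models(
    usable, dataset$gmta, dataset$metadata,
    response = response, covariate = covariate, threshold = threshold))

  meta <- dplyr::left_join(species_fits, dataset$metadata, by = "species_id")
  if (!"migration_class" %in% names(meta)) {
    meta$migration_class <- ifelse(meta$migration_distance_km > migration_cutoff_km,
                                   "long", "short")
  }

  contrast_migration <- stage("pgls", group_contrast(
    meta, "gmta_coef", "migration_class", dataset$tree, lambda = lambda))
  contrast_strategy <- stage("pgls", group_contrast(
    meta, "gmta_coef", "moult_strategy", dataset$tree, lambda = lambda))

  dich <- meta[meta$sex_testable, ]
  ornamentation_fit <- stage("pgls", ornamentation_regression(
    dich, dataset$tree, lambda = lambda))

  config <- list(response = response, covariate = covariate,
                 threshold = threshold, lambda = lambda,
                 min_specimens = min_specimens,
                 min_species_per_year = min_species_per_year,
                 migration_cutoff_km = migration_cutoff_km,
                 n_species = nrow(species_fits),
                 n_specimens = nrow(extents))
  manifest <- list(config = config,
                   hash = config_hash(config),
                   package_version = as.character(utils::packageVersion("moultclim")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."))

  result <- structure(list(
    extents = extents,
    moult_index = index,
    species_fits = species_fits,
    selection_table = selection_table(species_fits),
    contrast_migration = contrast_migration,
    contrast_strategy = contrast_strategy,
    ornamentation_fit = ornamentation_fit,
    excluded_species = excluded,
    manifest = manifest
  ), class = "moult_analysis")

  if (!is.null(out_dir)) stage("write", write_analysis_bundle(result, out_dir))
  result
}

# md5 of the canonical JSON serialisation of the config
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

write_analysis_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  h <- result$manifest$hash
  emit_csv <- function(d, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(dplyr::mutate(tibble::as_tibble(d), run_hash = h), p)
    written <<- c(written, p)
  }
  tryCatch({
    emit_csv(result$extents, "extents.csv")
    emit_csv(result$moult_index, "moult_index.csv")
    emit_csv(dplyr::select(result$species_fits, -"selection"),
             "species_fits.csv")
    emit_csv(result$selection_table, "selection.csv")
    for (nm in c("contrast_migration", "contrast_strategy",
                 "ornamentation_fit")) {
      p <- file.path(out_dir, paste0(nm, ".json"))
      write_pgls_json(result[[nm]], p)
      written <- c(written, p)
    }
    p <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(result$manifest, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, p)
  }, error = function(e) {
    unlink(written)
    rlang::abort(sprintf("Failed writing the result bundle (partial outputs removed): %s",
                         conditionMessage(e)))
  })
  invisible(out_dir)
}

#' @export
print.moult_analysis <- function(x, ...) {
  cat(sprintf("Moult-vs-warming analysis: %d specimens, %d species analysed (%d excluded)\n",
              nrow(x$extents), nrow(x$species_fits), length(x$excluded_species)))
  sel <- x$species_fits$selected
  cat(sprintf("  GMTA-containing model selected for %d/%d species; 'none' for %d\n",
              sum(grepl("gmta", sel)), length(sel), sum(sel == "none")))
  cat(sprintf("  Ornamentation regression: slope = %.3f, r2 = %.3f, F%d,%d = %.2f, P = %.4f, lambda = %.2f\n",
              x$ornamentation_fit$coefficients[2],
              x$ornamentation_fit$r_squared,
              x$ornamentation_fit$df["df1"], x$ornamentation_fit$df["df2"],
              x$ornamentation_fit$f_statistic, x$ornamentation_fit$p_value,
              x$ornamentation_fit$lambda))
  invisible(x)
}
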