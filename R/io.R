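#' Read pipeline input tables
#'
#' Readers for the three CSV dialects the pipeline consumes. Column
#' conventions: specimen files carry `specimen_id, species_id, year, sex,
#' lc_prop, mc_prop` followed by the 48 feather columns (missing scores as
#' empty cells); tract-area files carry `species_id, tract, area_mm2`;
#' species metadata carries `species_id, dichromatic, male_ornamentation,
#' female_ornamentation, migration_distance_km, moult_strategy, start_year`
#' (and optionally `migration_class`).
#'
#' @param path CSV file path.
#' @param layout Tract layout (specimens only).
#' @return A validated tibble.
#' @export
read_specimens <- function(path, layout = feather_tract_layout()) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_specimens(d, layout)
  d
}

#' @rdname read_specimens
#' @export
read_tract_areas <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("species_id", "tract", "area_mm2")
  if (!all(need %in% names(d))) {
    rlang::abort(sprintf("%s: expected columns %s.", path,
                         paste(need, collapse = ", ")))
  }
  d
}

#' @rdname read_specimens
#' @export
read_species_metadata <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("species_id", "dichromatic") %in% names(d))) {
    rlang::abort(sprintf("%s: expected at least species_id and dichromatic.", path))
  }
  d$dichromatic <- as.logical(d$dichromatic)
  d
}

#' Load a full dataset from a directory of input files
#'
#' Reads the file set written by [write_moult_dataset()]: specimens, tract
#' areas, both GMTA sources (composited with instrumental precedence),
#' species metadata and the Newick tree.
#'
#' @param dir Directory containing `specimens.csv`, `areas.csv`,
#'   `gmta_instrumental.csv`, `gmta_reconstructed.csv`, `metadata.csv`,
#'   `tree.nwk`.
#' @return A dataset list consumable by [run_full_analysis()].
#' @export
load_moult_dataset <- function(dir) {
  need <- c("specimens.csv", "areas.csv", "gmta_instrumental.csv",
            "gmta_reconstructed.csv", "metadata.csv", "tree.nwk")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0) {
    rlang::abort(sprintf("Input file(s) missing from %s: %s", dir,
                         paste(missing, collapse = ", ")))
  }
  instrumental <- read_gmta(file.path(dir, "gmta_instrumental.csv"),
                            "instrumental")
  reconstruction <- read_gmta(file.path(dir, "gmta_reconstructed.csv"),
                              "reconstructed")
  list(
    specimens = read_specimens(file.path(dir, "specimens.csv")),
    areas = read_tract_areas(file.path(dir, "areas.csv")),
    gmta = composite_gmta(instrumental, reconstruction),
    metadata = read_species_metadata(file.path(dir, "metadata.csv")),
    tree = read_tree_newick(file.path(dir, "tree.nwk")),
    layout = feather_tract_layout()
  )
}
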