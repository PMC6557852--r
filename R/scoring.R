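#' Score specimens: moulted plumage area and relative extent
#'
#' Converts per-feather 0/1 moult indicators into the moulted-plumage-area
#' statistic. For every specimen the moulted fraction of each tract is
#' computed — for discrete tracts the share of moulted feathers among the
#' *observed* (non-missing) feathers, for LC/MC the recorded proportion —
#' and multiplied by the species-specific tract area in mm². The per-tract
#' contributions sum to the moulted area; dividing by the species' total
#' wing + tail area gives the relative extent in \[0, 1\].
#'
#' Missing feather scores (damaged skins) rescale their tract's denominator
#' rather than counting as non-moulted, so damage does not bias the extent
#' downward. A tract in which *every* feather is missing has an undefined
#' fraction and is an error.
#'
#' @param specimens Data frame with columns `specimen_id`, `species_id`,
#'   `year`, `sex`, `lc_prop`, `mc_prop` and the 48 feather columns named by
#'   [feather_labels()]; feather scores are 0, 1 or `NA`.
#' @param areas Data frame with columns `species_id`, `tract`, `area_mm2`
#'   giving the total area of each tract per species (all strictly
#'   positive).
#' @param layout Tract layout, see [feather_tract_layout()].
#'
#' @return The input tibble (metadata columns only) with `moulted_area_mm2`,
#'   `total_area_mm2` and `relative_extent` appended.
#' @export
#' @examples
#' d <- simulate_moult_dataset(synth_config(n_species = 3, n_per_species = 20,
#'                                          seed = 1))
#' scored <- score_moult(d$specimens, d$areas)
#' dplyr::summarise(scored, mean_extent = mean(relative_extent))
score_moult <- function(specimens, areas, layout = feather_tract_layout()) {
  specimens <- tibble::as_tibble(specimens)
  areas <- tibble::as_tibble(areas)
  check_specimens(specimens, layout)
  check_area_table(areas, specimens$species_id, layout)

  area_wide <- tidyr::pivot_wider(areas, id_cols = "species_id",
                                  names_from = "tract",
                                  values_from = "area_mm2")
  aw <- area_wide[match(specimens$species_id, area_wide$species_id), ]

  frac <- matrix(NA_real_, nrow(specimens), nrow(layout),
                 dimnames = list(NULL, layout$tract))
  for (i in seq_len(nrow(layout))) {
    tr <- layout$tract[i]
    if (layout$type[i] == "proportion") {
      frac[, i] <- specimens[[if (tr == "LC") "lc_prop" else "mc_prop"]]
    } else {
      scores <- as.matrix(specimens[, layout$labels[[i]], drop = FALSE])
      n_obs <- rowSums(!is.na(scores))
      if (any(n_obs == 0)) {
        bad <- specimens$specimen_id[which(n_obs == 0)[1]]
        rlang::abort(sprintf(
          "Tract %s of specimen %s has no observed feather scores; its moulted fraction is undefined.",
          tr, bad))
      }
      frac[, i] <- rowSums(scores, na.rm = TRUE) / n_obs
    }
  }
  if (any(frac < 0 | frac > 1, na.rm = TRUE)) {
    rlang::abort("Moulted fractions outside [0, 1]; check feather scores and proportions.")
  }
  area_mat <- as.matrix(aw[, layout$tract, drop = FALSE])
  moulted <- rowSums(frac * area_mat)
  total <- rowSums(area_mat)

  dplyr::bind_cols(
    specimens[, c("specimen_id", "species_id", "year", "sex")],
    tibble::tibble(moulted_area_mm2 = moulted,
                   total_area_mm2 = total,
                   relative_extent = moulted / total)
  )
}

#' Year-averaged, min-max normalised moult index
#'
#' Per year, each species' mean relative moult extent is computed and the
#' species means are averaged with equal species weight (so well-sampled
#' species do not dominate). The yearly averages are then min-max normalised
#' so the lowest yearly mean maps to 0 and the highest to 1.
#'
#' @param scored Output of [score_moult()] (needs `species_id`, `year`,
#'   `relative_extent`).
#' @param min_species Years with fewer contributing species are dropped
#'   before normalisation (default 1: keep all).
#'
#' @return A tibble of class `moult_index` with columns `year`, `n_species`,
#'   `n_specimens`, `raw_mean` and `index`; the raw yearly means used as the
#'   normalisation endpoints are stored in attributes `raw_min`/`raw_max`.
#' @export
annual_moult_index <- function(scored, min_species = 1L) {
  stopifnot(all(c("species_id", "year", "relative_extent") %in% names(scored)))
  yearly <- scored |>
    dplyr::group_by(.data$year, .data$species_id) |>
    dplyr::summarise(species_mean = mean(.data$relative_extent),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(n_species = dplyr::n(),
                     n_specimens = sum(.data$n),
                     raw_mean = mean(.data$species_mean),
                     .groups = "drop") |>
    dplyr::filter(.data$n_species >= min_species) |>
    dplyr::arrange(.data$year)

  if (nrow(yearly) < 2) {
    rlang::abort("The moult index needs records from at least two years.")
  }
  rng <- range(yearly$raw_mean)
  if (diff(rng) == 0) {
    rlang::abort("All yearly mean extents are identical; the min-max normalised index is undefined.")
  }
  yearly$index <- (yearly$raw_mean - rng[1]) / diff(rng)
  attr(yearly, "raw_min") <- rng[1]
  attr(yearly, "raw_max") <- rng[2]
  class(yearly) <- c("moult_index", class(yearly))
  yearly
}

check_specimens <- function(specimens, layout) {
  need <- specimen_columns(layout)
  miss <- setdiff(need, names(specimens))
  if (length(miss) > 0) {
    rlang::abort(sprintf("Specimen table is missing columns: %s",
                         paste(miss, collapse = ", ")))
  }
  fl <- feather_labels(layout)
  sc <- as.matrix(specimens[, fl, drop = FALSE])
  if (!all(sc %in% c(0, 1, NA))) {
    rlang::abort("Feather scores must be 0, 1 or missing.")
  }
  props <- c(specimens$lc_prop, specimens$mc_prop)
  if (anyNA(props) || any(props < 0 | props > 1)) {
    rlang::abort("lc_prop/mc_prop must lie in [0, 1] and be non-missing.")
  }
  invisible(specimens)
}

check_area_table <- function(areas, species_ids, layout) {
  need <- c("species_id", "tract", "area_mm2")
  if (!all(need %in% names(areas))) {
    rlang::abort("Area table needs columns species_id, tract, area_mm2.")
  }
  if (any(areas$area_mm2 <= 0)) {
    rlang::abort("All tract areas must be strictly positive.")
  }
  for (sp in unique(species_ids)) {
    have <- areas$tract[areas$species_id == sp]
    miss <- setdiff(layout$tract, have)
    if (length(miss) > 0) {
      rlang::abort(sprintf("Species %s lacks tract areas for: %s",
                           sp, paste(miss, collapse = ", ")))
    }
  }
  invisible(areas)
}

#' @export
print.moult_index <- function(x, ...) {
  cat(sprintf("Annual moult index: %d years (%d-%d), raw yearly means %.4f-%.4f\n",
              nrow(x), min(x$year), max(x$year),
              attr(x, "raw_min"), attr(x, "raw_max")))
  NextMethod()
}
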