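# Shared fixtures built in code: a tiny two-species world with round tract
# areas so weighted sums can be checked by hand.

fixture_layout <- feather_tract_layout()

fixture_areas <- function(species = c("spA", "spB")) {
  base <- c(LC = 100, MC = 200, GC = 120, CC = 10, AL = 30,
            PC = 90, P = 1000, S = 600, T = 150, R = 300)  # total 2600
  tidyr::expand_grid(species_id = species, tract = names(base)) |>
    dplyr::mutate(area_mm2 = unname(base[tract]))
}

# one specimen row with every feather at `score` and both proportions `prop`
blank_specimen <- function(id = "s1", species = "spA", year = 1900,
                           sex = "unknown", score = 0, prop = 0,
                           layout = fixture_layout) {
  row <- tibble::tibble(specimen_id = id, species_id = species,
                        year = year, sex = sex,
                        lc_prop = prop, mc_prop = prop)
  for (lb in feather_labels(layout)) row[[lb]] <- score
  row
}

# independent scoring oracle: per-feather brute force, each discrete feather
# weighted by tract_area / tract_count, proportions by their full tract area
brute_force_area <- function(record, areas, layout = fixture_layout) {
  a <- areas[areas$species_id == record$species_id, ]
  area_of <- function(tr) a$area_mm2[a$tract == tr]
  total <- record$lc_prop * area_of("LC") + record$mc_prop * area_of("MC")
  for (i in which(layout$type == "discrete")) {
    labels <- layout$labels[[i]]
    per_feather <- area_of(layout$tract[i]) / layout$n_feathers[i]
    scores <- as.numeric(record[1, labels])
    obs <- !is.na(scores)
    # missing feathers rescale the tract weight over the observed ones
    w <- per_feather * layout$n_feathers[i] / sum(obs)
    total <- total + sum(scores[obs]) * w
  }
  total
}

random_specimens <- function(n, species = "spA", na_frac = 0,
                             layout = fixture_layout) {
  purrr::map(seq_len(n), function(i) {
    r <- blank_specimen(sprintf("r%03d", i), species = species,
                        year = 1900 + (i %% 50))
    for (lb in feather_labels(layout)) {
      r[[lb]] <- if (stats::runif(1) < na_frac) NA_real_ else
        stats::rbinom(1, 1, 0.5)
    }
    # keep at least one observed feather per tract
    for (j in which(layout$type == "discrete")) {
      labels <- layout$labels[[j]]
      if (all(is.na(r[, labels]))) r[[labels[1]]] <- 1
    }
    r$lc_prop <- stats::runif(1)
    r$mc_prop <- stats::runif(1)
    r
  }) |> dplyr::bind_rows()
}
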