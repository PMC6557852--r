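#' Configuration for the synthetic museum-specimen generator
#'
#' Bundles every knob of the generative model the analysis assumes: a
#' pure-birth phylogeny; species-level intercepts, GMTA slopes and
#' sex-by-GMTA interactions drawn from a multivariate normal whose
#' covariance is the (depth-normalised) Brownian matrix under
#' `lambda_true`; an accelerating anomaly series centred on the 1951-1980
#' reference window; and per-specimen moulted areas drawn from a Gamma with
#' identity-link mean. Defaults describe a museum-scale study: 12 species
#' of which 10 are sexually dichromatic, around 200 specimens per species
#' collected between a species-specific start year (1805-1864) and 2016,
#' moulted areas near 1500 mm² out of ~7700 mm² of wing + tail, a warming
#' signal of about 400 mm² per degree C, and a built-in negative
#' ornamentation effect on the interaction coefficient.
#'
#' @param n_species Number of species (tree tips).
#' @param n_per_species Specimens per species.
#' @param years Study span `c(first, last)` calendar years.
#' @param ref_window GMTA reference window, default `c(1951, 1980)`.
#' @param start_year_range Range the per-species data start year is drawn
#'   from.
#' @param intercept_mean,intercept_sd Mean/SD (mm²) of species intercepts.
#' @param slope_mean,slope_sd Mean/SD (mm² per degree C) of species GMTA
#'   slopes.
#' @param sex_effect Additive male effect on the mean (mm²), shared by all
#'   dichromatic species.
#' @param interaction_mean,interaction_sd Mean/SD of the species
#'   GMTA-by-sex interaction around the ornamentation trend.
#' @param ornamentation_effect Slope (mm² per degree C per ornamentation
#'   unit) linking a species' male-minus-female ornamentation score to its
#'   interaction coefficient; negative by default.
#' @param lambda_true Pagel's lambda of the species-effect covariance in
#'   \[0, 1\].
#' @param shape Gamma shape of the specimen-level noise.
#' @param dichromatic_fraction Fraction of species that are sexually
#'   dichromatic.
#' @param gmta_rise Total anomaly rise (degrees C) over the study span.
#' @param gmta_noise_sd SD of the annual white noise around the trend.
#' @param seed Integer master seed; every stage derives its stream from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_species = 12L, n_per_species = 200L,
                         years = c(1805L, 2016L),
                         ref_window = c(1951L, 1980L),
                         start_year_range = c(1805L, 1864L),
                         intercept_mean = 1500, intercept_sd = 150,
                         slope_mean = 400, slope_sd = 100,
                         sex_effect = 100,
                         interaction_mean = 0, interaction_sd = 25,
                         ornamentation_effect = -12,
                         lambda_true = 0, shape = 20,
                         dichromatic_fraction = 10 / 12,
                         gmta_rise = 2.0, gmta_noise_sd = 0.05,
                         seed = 1L) {
  cfg <- as.list(environment())
  if (any(c(intercept_sd, slope_sd, interaction_sd, gmta_noise_sd) < 0)) {
    rlang::abort("Standard deviations must be non-negative.")
  }
  if (shape <= 0) rlang::abort("Gamma shape must be positive.")
  if (lambda_true < 0 || lambda_true > 1) rlang::abort("lambda_true must lie in [0, 1].")
  if (ref_window[1] < years[1] || ref_window[2] > years[2]) {
    rlang::abort("The reference window must lie inside the study span.")
  }
  if (n_species < 2) rlang::abort("Need at least two species.")
  structure(cfg, class = "synth_config")
}

#' Simulate an ultrametric pure-birth phylogeny
#'
#' Yule (pure-birth) tree with exponential waiting times, via
#' [ape::rphylo()]; tips are renamed `sp01, sp02, ...`. Deterministic per
#' seed.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed.
#' @return An ultrametric `phylo` object.
#' @export
simulate_tree <- function(n_tips, seed = 1L) {
  if (n_tips < 2) rlang::abort("Need at least two tips.")
  withr::local_seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  tree
}

#' Simulate a GMTA series with an accelerating warming trend
#'
#' A quadratic-in-time trend scaled so the deterministic rise over the span
#' equals `total_rise`, plus annual white noise, then centred so the mean
#' anomaly over the reference window is exactly zero. Years before 1880
#' are tagged `reconstructed`, later ones `instrumental`.
#'
#' @param years Span `c(first, last)`.
#' @param total_rise Trend rise over the span, degrees C (default 2.0).
#' @param noise_sd SD of annual white noise, degrees C.
#' @param ref_window Centring window, default `c(1951, 1980)`; must lie
#'   inside the span.
#' @param seed Integer seed.
#' @return A `gmta_series` tibble.
#' @export
simulate_gmta <- function(years = c(1805L, 2016L), total_rise = 2.0,
                          noise_sd = 0.05, ref_window = c(1951L, 1980L),
                          seed = 1L) {
  if (diff(years) < 1) rlang::abort("The span must cover at least two years.")
  if (ref_window[1] < years[1] || ref_window[2] > years[2]) {
    rlang::abort("The reference window must lie inside the span.")
  }
  withr::local_seed(seed)
  yr <- seq(years[1], years[2])
  tt <- (yr - years[1]) / (years[2] - years[1])
  raw <- total_rise * tt^2 + stats::rnorm(length(yr), 0, noise_sd)
  ref <- yr >= ref_window[1] & yr <= ref_window[2]
  anom <- raw - mean(raw[ref])
  new_gmta_series(yr, anom,
                  ifelse(yr >= 1880L, "instrumental", "reconstructed"))
}

#' Simulate species-level true coefficients on a tree
#'
#' Intercepts, GMTA slopes and interaction deviations are drawn from
#' multivariate normals with covariance sd² * V*(lambda_true), where V* is
#' the tree's Brownian matrix normalised to unit diagonal, so `lambda_true`
#' controls the phylogenetic correlation of species effects without
#' rescaling their variance. Dichromatic species receive male and female
#' ornamentation scores; the true interaction coefficient is
#' `interaction_mean + ornamentation_effect * (male - female) +`
#' lambda-structured noise. Monomorphic species carry no sex or interaction
#' effect (their specimens are recorded as unsexed). Migration distance
#' (km), migration class and moult strategy are assigned with both levels
#' represented whenever n allows.
#'
#' @param tree A `phylo` from [simulate_tree()].
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return A tibble with one row per species: identifiers, dichromatism,
#'   ornamentation scores, migration and moult-strategy metadata,
#'   `start_year`, and the true `intercept`, `slope`, `sex_effect`,
#'   `interaction` coefficients.
#' @export
simulate_species_params <- function(tree, config, seed = config$seed) {
  withr::local_seed(seed)
  sp <- tree$tip.label
  n <- length(sp)
  V <- brownian_vcv(tree, sp)
  Vn <- V / mean(diag(V))
  Vl <- apply_lambda(Vn, config$lambda_true)

  draw <- function(mu, sd) {
    if (sd == 0) return(rep(mu, n))
    drop(MASS::mvrnorm(1, rep(mu, n), sd^2 * Vl))
  }
  intercept <- draw(config$intercept_mean, config$intercept_sd)
  slope <- draw(config$slope_mean, config$slope_sd)

  n_dichro <- round(config$dichromatic_fraction * n)
  dichromatic <- seq_len(n) %in% sample(n, n_dichro)

  female_orn <- stats::runif(n, 30, 60)
  orn_diff <- ifelse(dichromatic, stats::runif(n, 0, 30), 0)
  male_orn <- female_orn + orn_diff

  inter_noise <- draw(config$interaction_mean, config$interaction_sd) -
    config$interaction_mean
  interaction <- ifelse(
    dichromatic,
    config$interaction_mean + config$ornamentation_effect * orn_diff + inter_noise,
    0)
  sex_effect <- ifelse(dichromatic, config$sex_effect, 0)

  # guarantee two species per contrast level when n allows (study design
  # mirrors a 12-short / 7-long, 15-pre / 4-post species split)
  n_long <- if (n >= 4) max(2L, round(n * 7 / 19)) else 0L
  long <- seq_len(n) %in% sample(n, n_long)
  dist_km <- ifelse(long, stats::runif(n, 2500, 6000), stats::runif(n, 300, 1800))
  n_post <- if (n >= 4) max(2L, round(n * 4 / 19)) else 0L
  post <- seq_len(n) %in% sample(n, n_post)

  tibble::tibble(
    species_id = sp,
    dichromatic = dichromatic,
    male_ornamentation = male_orn,
    female_ornamentation = female_orn,
    migration_distance_km = dist_km,
    migration_class = ifelse(long, "long", "short"),
    moult_strategy = ifelse(post, "post", "pre"),
    start_year = sample(seq(config$start_year_range[1],
                            config$start_year_range[2]), n, replace = TRUE),
    intercept = intercept,
    slope = slope,
    sex_effect = sex_effect,
    interaction = interaction
  )
}

#' Simulate species-specific feather-tract areas
#'
#' Baseline tract areas typical of a mid-sized passerine wing and tail
#' (primaries and rectrices dominate; the carpal covert is tiny), scaled
#' per species-tract by a uniform factor in \[0.8, 1.2\].
#'
#' @param species_ids Character vector of species.
#' @param seed Integer seed.
#' @param layout Tract layout.
#' @return Tibble `species_id`, `tract`, `area_mm2`.
#' @export
simulate_tract_areas <- function(species_ids, seed = 1L,
                                 layout = feather_tract_layout()) {
  withr::local_seed(seed)
  base <- c(LC = 300, MC = 350, GC = 500, CC = 30, AL = 150,
            PC = 250, P = 2500, S = 1200, T = 450, R = 2000)
  base <- base[layout$tract]
  tidyr::expand_grid(species_id = species_ids, tract = layout$tract) |>
    dplyr::mutate(area_mm2 = unname(base[.data$tract]) *
                    stats::runif(dplyr::n(), 0.8, 1.2))
}

#' Simulate per-feather specimen records
#'
#' For each specimen: a collection year uniform over the species' span, a
#' sex (Bernoulli 0.5 for dichromatic species, `unknown` otherwise), and a
#' moulted area drawn from a Gamma with shape `config$shape` and mean
#' `intercept + slope * GMTA(year) + sex_effect * male +
#' interaction * male * GMTA(year)`, capped at the species' total area
#' (cap events are counted in attribute `n_capped`). The drawn area is then
#' realised into per-feather 0/1 scores deterministically: tracts fill in
#' the layout's priority order, feathers within a tract in label order and
#' with equal share of the tract area, until the area is exhausted; LC/MC
#' fill as continuous proportions. Re-scoring a generated record therefore
#' recovers the drawn area to within one feather's area (exactly, when the
#' area stops inside LC/MC).
#'
#' @param params Species table from [simulate_species_params()].
#' @param gmta A `gmta_series` covering the study span.
#' @param areas Tract-area table covering every species.
#' @param config A [synth_config()].
#' @param layout Tract layout.
#' @param seed Integer seed.
#' @return Specimen tibble in the layout's column convention (see
#'   [specimen_columns()]); the drawn areas are kept in attribute
#'   `drawn_area` and the cap count in `n_capped`.
#' @export
simulate_specimens <- function(params, gmta, areas, config,
                               layout = feather_tract_layout(),
                               seed = config$seed) {
  withr::local_seed(seed)
  end_year <- config$years[2]

  per_species <- purrr::pmap(
    params[, c("species_id", "dichromatic", "start_year", "intercept",
               "slope", "sex_effect", "interaction")],
    function(species_id, dichromatic, start_year, intercept, slope,
             sex_effect, interaction) {
      m <- config$n_per_species
      year <- sample(seq(start_year, end_year), m, replace = TRUE)
      g <- gmta_anomaly(gmta, year)
      sex <- if (dichromatic) {
        sample(c("female", "male"), m, replace = TRUE)
      } else rep("unknown", m)
      male <- as.numeric(sex == "male")

      g_rng <- range(gmta_anomaly(gmta, seq(start_year, end_year)))
      worst <- min(intercept + slope * g_rng,
                   intercept + slope * g_rng + sex_effect + interaction * g_rng)
      if (worst <= 0) {
        rlang::abort(sprintf(
          "Species %s: implied Gamma mean is nonpositive (%.1f) somewhere in its span; raise the intercept or shrink the slope/interaction parameters.",
          species_id, worst))
      }
      mu <- intercept + slope * g + (sex_effect + interaction * g) * male
      area <- stats::rgamma(m, shape = config$shape, rate = config$shape / mu)
      tibble::tibble(species_id = species_id, year = year, sex = sex,
                     drawn_area = area)
    })
  d <- dplyr::bind_rows(per_species)
  d$specimen_id <- sprintf("spec%05d", seq_len(nrow(d)))

  # cap at the species' total wing + tail area
  totals <- areas |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(total = sum(.data$area_mm2), .groups = "drop")
  tot <- totals$total[match(d$species_id, totals$species_id)]
  n_capped <- sum(d$drawn_area > tot)
  d$drawn_area <- pmin(d$drawn_area, tot)

  scores <- allocate_area_to_feathers(d$drawn_area, d$species_id, areas, layout)
  out <- dplyr::bind_cols(
    d[, c("specimen_id", "species_id", "year", "sex")], scores)
  attr(out, "drawn_area") <- d$drawn_area
  attr(out, "n_capped") <- n_capped
  if (n_capped > 0) {
    message(sprintf("%d drawn area(s) exceeded the total plumage area and were capped.", n_capped))
  }
  out
}

# deterministic greedy fill: tracts in priority order, feathers in label
# order; proportion tracts absorb area continuously.
allocate_area_to_feathers <- function(area, species_id, areas, layout) {
  n <- length(area)
  area_wide <- tidyr::pivot_wider(areas, id_cols = "species_id",
                                  names_from = "tract", values_from = "area_mm2")
  aw <- area_wide[match(species_id, area_wide$species_id), ]
  remaining <- area
  cols <- list()
  ord <- order(layout$priority)
  for (i in ord) {
    tr <- layout$tract[i]
    ta <- aw[[tr]]
    if (layout$type[i] == "proportion") {
      take <- pmin(remaining, ta)
      cols[[if (tr == "LC") "lc_prop" else "mc_prop"]] <- as.vector(take / ta)
      remaining <- remaining - take
    } else {
      nf <- layout$n_feathers[i]
      fa <- ta / nf
      k <- pmin(nf, floor(remaining / fa + 1e-9))
      for (j in seq_len(nf)) {
        cols[[layout$labels[[i]][j]]] <- as.numeric(j <= k)
      }
      remaining <- remaining - k * fa
    }
  }
  tibble::as_tibble(cols)[, c("lc_prop", "mc_prop", feather_labels(layout))]
}

#' Generate a complete synthetic study dataset
#'
#' Runs every generator stage from one master seed: tree, GMTA series,
#' species parameters, tract areas and specimen records. Identical configs
#' give identical output, byte for byte once written.
#'
#' @param config A [synth_config()].
#' @return A list: `tree`, `gmta`, `params` (species truth), `metadata`
#'   (the observable species table the pipeline consumes), `areas`,
#'   `specimens`, `layout`, `config`.
#' @export
#' @examples
#' d <- simulate_moult_dataset(synth_config(n_species = 4, n_per_species = 30,
#'                                          seed = 42))
#' names(d)
simulate_moult_dataset <- function(config = synth_config()) {
  seed <- config$seed
  layout <- feather_tract_layout()
  tree <- simulate_tree(config$n_species, seed + 1L)
  gmta <- simulate_gmta(config$years, config$gmta_rise, config$gmta_noise_sd,
                        config$ref_window, seed + 2L)
  params <- simulate_species_params(tree, config, seed + 3L)
  areas <- simulate_tract_areas(params$species_id, seed + 4L, layout)
  specimens <- simulate_specimens(params, gmta, areas, config, layout,
                                  seed + 5L)
  metadata <- params[, c("species_id", "dichromatic", "male_ornamentation",
                         "female_ornamentation", "migration_distance_km",
                         "migration_class", "moult_strategy", "start_year")]
  list(tree = tree, gmta = gmta, params = params, metadata = metadata,
       areas = areas, specimens = specimens, layout = layout, config = config)
}

#' Write a synthetic dataset in the pipeline's file dialects
#'
#' Emits `specimens.csv`, `areas.csv`, `gmta_instrumental.csv`,
#' `gmta_reconstructed.csv`, `metadata.csv`, `tree.nwk` and a
#' `manifest.json` recording the full config and seed.
#'
#' @param dataset Output of [simulate_moult_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_moult_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(dataset$specimens, file.path(dir, "specimens.csv"))
  readr::write_csv(dataset$areas, file.path(dir, "areas.csv"))
  g <- dataset$gmta
  readr::write_csv(g[g$source == "instrumental", c("year", "anomaly_c")],
                   file.path(dir, "gmta_instrumental.csv"))
  readr::write_csv(g[g$source == "reconstructed", c("year", "anomaly_c")],
                   file.path(dir, "gmta_reconstructed.csv"))
  readr::write_csv(dataset$metadata, file.path(dir, "metadata.csv"))
  ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(unclass(dataset$config),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
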