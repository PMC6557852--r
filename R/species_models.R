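#' Per-species Gamma-GLM model selection against GMTA
#'
#' For every species: the moult-extent response (moulted area in mm² by
#' default, or relative extent) is regressed on the temperature anomaly of
#' each specimen's collection year with an identity-link Gamma GLM; in
#' sexually dichromatic species sex (female = 0, male = 1) and the
#' GMTA-by-sex interaction enter the candidate set. Candidates are compared
#' by AICc and a model is selected only when the runner-up's ΔAICc exceeds
#' `threshold`.
#'
#' Records with zero moulted extent lie outside the Gamma support and are
#' dropped with a message. In dichromatic species, unknown-sex records are
#' dropped and *all* candidates are refitted on the common sexed subset so
#' AICc values stay comparable; if fewer than `min_sexed_fraction` of a
#' dichromatic species' records are sexed, the species falls back to the
#' monomorphic candidate set (sex untestable) with a warning. Species with
#' too few records for the largest candidate are skipped with a warning.
#'
#' @param scored Output of [score_moult()].
#' @param gmta A `gmta_series` covering every collection year.
#' @param metadata Data frame with `species_id` and logical `dichromatic`.
#' @param response `"area"` (mm², default) or `"relative"` (extent in
#'   (0, 1]).
#' @param covariate `"gmta"` (default) or `"year"` (calendar year swapped in
#'   as the covariate; identical machinery).
#' @param threshold ΔAICc selection threshold, default 2.00.
#' @param min_sexed_fraction Minimum share of sexed records for a
#'   dichromatic species to keep sex terms (default 0.9).
#' @return A tibble, one row per analysed species: `species_id`, `n_used`,
#'   `n_dropped_zero`, `n_dropped_unsexed`, `sex_testable`, `selected`
#'   (label or `"none"`), `gmta_coef` (coefficient of the covariate in the
#'   best-supported covariate-containing candidate), `interaction_coef`
#'   (GMTA-by-sex coefficient of the full model; `NA` when sex is
#'   untestable) and `selection` (list-column of [select_model()] tables).
#' @export
fit_species_models <- function(scored, gmta, metadata,
                               response = c("area", "relative"),
                               covariate = c("gmta", "year"),
                               threshold = 2.00,
                               min_sexed_fraction = 0.9) {
  response <- match.arg(response)
  covariate <- match.arg(covariate)
  stopifnot(all(c("species_id", "dichromatic") %in% names(metadata)))

  scored <- dplyr::mutate(
    scored,
    .response = if (response == "area") .data$moulted_area_mm2 else .data$relative_extent,
    .covariate = if (covariate == "gmta") gmta_anomaly(gmta, .data$year) else as.numeric(.data$year)
  )

  rows <- purrr::map(split(scored, scored$species_id), function(d) {
    sp <- d$species_id[1]
    dichro <- metadata$dichromatic[match(sp, metadata$species_id)]
    if (is.na(dichro)) {
      rlang::abort(sprintf("Species %s missing from the metadata table.", sp))
    }

    n_zero <- sum(d$.response <= 0)
    if (n_zero > 0) {
      message(sprintf("%s: dropped %d record(s) with zero moult extent (outside Gamma support).",
                      sp, n_zero))
      d <- d[d$.response > 0, ]
    }

    n_unsexed <- 0L
    sex_testable <- isTRUE(dichro)
    if (sex_testable) {
      sexed <- d$sex %in% c("male", "female")
      if (mean(sexed) < min_sexed_fraction) {
        warning(sprintf("%s: only %.0f%% of records sexed; sex effects untestable, using the monomorphic candidate set.",
                        sp, 100 * mean(sexed)), call. = FALSE)
        sex_testable <- FALSE
      } else {
        n_unsexed <- sum(!sexed)
        d <- d[sexed, ]
      }
    }

    cand <- build_candidate_set(sex_testable)
    k_max <- max(vapply(cand$terms, length, integer(1))) + 2L
    if (nrow(d) <= k_max + 1L) {
      warning(sprintf("%s: only %d usable records (need > %d); species skipped.",
                      sp, nrow(d), k_max + 1L), call. = FALSE)
      return(NULL)
    }

    fits <- purrr::map2(cand$terms, cand$label, function(tm, lb) {
      X <- candidate_design(d, tm)
      fit_gamma_identity(d$.response, X, label = lb)
    })
    sel <- select_model(fits, threshold = threshold)

    cov_fits <- fits[vapply(fits, function(f) "gmta" %in% names(f$coefficients),
                            logical(1))]
    best_cov <- cov_fits[[which.min(vapply(cov_fits, function(f) f$aicc, numeric(1)))]]
    full <- fits[[length(fits)]]

    tibble::tibble(
      species_id = sp,
      n_used = nrow(d),
      n_dropped_zero = n_zero,
      n_dropped_unsexed = n_unsexed,
      sex_testable = sex_testable,
      selected = attr(sel, "selected_label"),
      gmta_coef = unname(best_cov$coefficients["gmta"]),
      interaction_coef = if (sex_testable) unname(full$coefficients["gmta:sex"]) else NA_real_,
      selection = list(sel)
    )
  })
  dplyr::bind_rows(rows)
}

candidate_design <- function(d, terms) {
  X <- cbind(intercept = rep(1, nrow(d)))
  if ("gmta" %in% terms) X <- cbind(X, gmta = d$.covariate)
  if ("sex" %in% terms) X <- cbind(X, sex = as.numeric(d$sex == "male"))
  if ("gmta:sex" %in% terms) {
    X <- cbind(X, "gmta:sex" = d$.covariate * as.numeric(d$sex == "male"))
  }
  X
}

#' Flatten per-species selection tables
#'
#' @param species_fits Output of [fit_species_models()].
#' @return One tibble with a `species_id` column followed by every
#'   candidate's label, k, n, logLik, AICc, ΔAICc and selected flag.
#' @export
selection_table <- function(species_fits) {
  purrr::map2(species_fits$selection, species_fits$species_id, function(s, sp) {
    out <- tibble::as_tibble(s)
    dplyr::bind_cols(tibble::tibble(species_id = sp), out)
  }) |> dplyr::bind_rows()
}
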