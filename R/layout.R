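#' Canonical wing and tail feather-tract layout
#'
#' The fixed scoring layout used throughout the package: ten tract labels
#' covering the juvenile wing and tail. Two tracts with many small,
#' hard-to-distinguish feathers (lesser and median coverts, LC/MC) are scored
#' as moulted *proportions*; the remaining eight are scored feather by
#' feather with 0/1 indicators and together hold exactly 48 discrete
#' feathers: greater coverts GC1-GC10, the carpal covert CC, alula AL1-AL3,
#' primary coverts PC1-PC9, primaries P1-P10, secondaries S1-S6, tertials
#' T7-T9 and rectrices R1-R6. Numbering is descendant for coverts and
#' ascendant for primaries: P1 is the innermost primary; this convention is
#' fixed and assumed by all I/O.
#'
#' The `priority` column gives the canonical fill order used by the
#' synthetic-data generator when it converts a drawn moulted area back into
#' per-feather scores. It approximates the typical passerine post-juvenile
#' moult sequence (body-near coverts first, remiges last) and is a
#' generator-side abstraction, not a biological claim.
#'
#' @param priority_order Character vector of the ten tract names giving the
#'   fill order for area-to-feather allocation. Defaults to the standard
#'   sequence `LC, MC, GC, CC, AL, T, R, PC, S, P`.
#'
#' @return A tibble with one row per tract: `tract`, `type`
#'   (`"proportion"` or `"discrete"`), `n_feathers` (`NA` for proportion
#'   tracts), `priority` (rank in the fill order) and `labels` (list-column
#'   of per-feather column labels; empty for proportion tracts).
#' @export
#' @examples
#' layout <- feather_tract_layout()
#' sum(layout$n_feathers, na.rm = TRUE) # 48
feather_tract_layout <- function(priority_order = c("LC", "MC", "GC", "CC",
                                                    "AL", "T", "R", "PC",
                                                    "S", "P")) {
  tracts <- tibble::tibble(
    tract = c("LC", "MC", "GC", "CC", "AL", "PC", "P", "S", "T", "R"),
    type = c("proportion", "proportion", rep("discrete", 8)),
    n_feathers = c(NA_integer_, NA_integer_, 10L, 1L, 3L, 9L, 10L, 6L, 3L, 6L)
  )
  tracts$labels <- purrr::pmap(tracts, function(tract, type, n_feathers) {
    if (type == "proportion") return(character(0))
    switch(tract,
      GC = paste0("GC", 1:10),
      CC = "CC",
      AL = paste0("AL", 1:3),
      PC = paste0("PC", 1:9),
      P  = paste0("P", 1:10),
      S  = paste0("S", 1:6),
      T  = paste0("T", 7:9),   # tertials carry secondary numbering 7-9
      R  = paste0("R", 1:6)
    )
  })
  if (!setequal(priority_order, tracts$tract) ||
      anyDuplicated(priority_order) > 0) {
    rlang::abort("`priority_order` must be a permutation of the ten tract names.")
  }
  tracts$priority <- match(tracts$tract, priority_order)
  stopifnot(sum(tracts$n_feathers, na.rm = TRUE) == 48L)
  tracts
}

#' All discrete feather labels of a layout
#'
#' @param layout A layout from [feather_tract_layout()].
#' @return Character vector of the 48 discrete feather column labels, in
#'   tract order.
#' @export
feather_labels <- function(layout = feather_tract_layout()) {
  unlist(layout$labels, use.names = FALSE)
}

#' Columns a specimen table must carry
#'
#' @param layout A layout from [feather_tract_layout()].
#' @return Character vector: identifier/metadata columns, the two proportion
#'   columns, then the 48 feather columns.
#' @export
specimen_columns <- function(layout = feather_tract_layout()) {
  c("specimen_id", "species_id", "year", "sex", "lc_prop", "mc_prop",
    feather_labels(layout))
}
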