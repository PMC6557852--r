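test_that("tract layout matches the scoring convention", {
  layout <- feather_tract_layout()
  expect_equal(sum(layout$n_feathers, na.rm = TRUE), 48L)
  expect_equal(length(feather_labels(layout)), 48L)
  expect_false(anyDuplicated(layout$tract) > 0)
  expect_setequal(layout$priority, seq_len(nrow(layout)))
  expect_equal(layout$type[layout$tract %in% c("LC", "MC")],
               c("proportion", "proportion"))
  expect_error(feather_tract_layout(c("LC", "MC")), "permutation")
})

test_that("moulted area spans from zero to the full plumage area", {
  areas <- fixture_areas()
  none <- score_moult(blank_specimen(score = 0, prop = 0), areas)
  expect_equal(none$moulted_area_mm2, 0)
  expect_equal(none$relative_extent, 0)

  all <- score_moult(blank_specimen(score = 1, prop = 1), areas)
  expect_equal(all$moulted_area_mm2, 2600)
  expect_equal(all$total_area_mm2, 2600)
  expect_equal(all$relative_extent, 1)
})

test_that("a single fully moulted tract contributes exactly its area", {
  areas <- fixture_areas()
  rec <- blank_specimen()
  rec[paste0("GC", 1:10)] <- 1
  expect_equal(score_moult(rec, areas)$moulted_area_mm2, 120)
})

test_that("half-moulted tracts give the hand-computed weighted sum", {
  areas <- fixture_areas()
  rec <- blank_specimen(prop = 0.5)
  rec[paste0("GC", 1:5)] <- 1   # 5/10
  rec[paste0("P", 1:5)] <- 1    # 5/10
  rec[paste0("S", 1:3)] <- 1    # 3/6
  rec[paste0("R", 1:3)] <- 1    # 3/6
  # 0.5 * (LC 100 + MC 200 + GC 120 + P 1000 + S 600 + R 300) = 1160
  expect_equal(score_moult(rec, areas)$moulted_area_mm2, 1160)
})

test_that("missing feathers rescale the tract denominator, all-missing errors", {
  areas <- fixture_areas()
  rec <- blank_specimen()
  rec[paste0("S", 1:3)] <- 1
  rec[paste0("S", 4:6)] <- NA   # 3 moulted of 3 observed -> whole tract
  expect_equal(score_moult(rec, areas)$moulted_area_mm2, 600)

  rec2 <- blank_specimen()
  rec2[paste0("AL", 1:3)] <- NA
  expect_error(score_moult(rec2, areas), "AL")
})

test_that("scoring rejects unknown species and bad values", {
  areas <- fixture_areas("spB")
  expect_error(score_moult(blank_specimen(species = "spA"), areas), "spA")
  rec <- blank_specimen()
  rec$lc_prop <- 1.3
  expect_error(score_moult(rec, fixture_areas()), "\\[0, 1\\]")
  rec2 <- blank_specimen()
  rec2$GC1 <- 2
  expect_error(score_moult(rec2, fixture_areas()), "0, 1 or missing")
})

test_that("area is monotone in single-feather flips and additive over tracts", {
  withr::local_seed(11)
  areas <- fixture_areas()
  recs <- random_specimens(20, na_frac = 0.1)
  base <- score_moult(recs, areas)
  for (i in sample(nrow(recs), 5)) {
    zeros <- feather_labels()[which(recs[i, feather_labels()] == 0)]
    if (length(zeros) == 0) next
    flip <- recs
    flip[i, sample(zeros, 1)] <- 1
    expect_gte(score_moult(flip, areas)$moulted_area_mm2[i],
               base$moulted_area_mm2[i])
  }
  # additivity: sum of single-tract contributions equals the full score
  rec <- recs[1, ]
  contribs <- purrr::map_dbl(seq_len(nrow(fixture_layout)), function(j) {
    solo <- blank_specimen()
    tr <- fixture_layout$tract[j]
    if (fixture_layout$type[j] == "proportion") {
      col <- if (tr == "LC") "lc_prop" else "mc_prop"
      solo[[col]] <- rec[[col]]
    } else {
      solo[fixture_layout$labels[[j]]] <- rec[fixture_layout$labels[[j]]]
    }
    score_moult(solo, areas)$moulted_area_mm2
  })
  expect_equal(sum(contribs), score_moult(rec, areas)$moulted_area_mm2,
               tolerance = 1e-12)
})

test_that("annual index min-max normalises species-equal-weighted yearly means", {
  scored <- tibble::tibble(
    species_id = "spA",
    year = c(1900, 1950, 2000),
    relative_extent = c(0.2, 0.4, 0.6))
  idx <- annual_moult_index(scored)
  expect_equal(idx$index, c(0, 0.5, 1))
  expect_equal(attr(idx, "raw_min"), 0.2)
  expect_equal(attr(idx, "raw_max"), 0.6)

  # equal species weight: spA has 3 specimens, spB one; the yearly mean is
  # the mean of the two species means, not the specimen mean
  uneven <- tibble::tibble(
    species_id = c("spA", "spA", "spA", "spB", "spA", "spB"),
    year = c(1900, 1900, 1900, 1900, 2000, 2000),
    relative_extent = c(0.1, 0.2, 0.3, 0.6, 0.2, 0.8))
  idx2 <- annual_moult_index(uneven)
  expect_equal(idx2$raw_mean, c((0.2 + 0.6) / 2, (0.2 + 0.8) / 2))
  expect_equal(idx2$n_specimens, c(4L, 2L))
})

test_that("degenerate index inputs error rather than divide by zero", {
  one_year <- tibble::tibble(species_id = "spA", year = 1900,
                             relative_extent = 0.5)
  expect_error(annual_moult_index(one_year), "two years")
  flat <- tibble::tibble(species_id = "spA", year = c(1900, 1950),
                         relative_extent = c(0.4, 0.4))
  expect_error(annual_moult_index(flat), "identical")
})
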