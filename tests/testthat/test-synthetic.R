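test_that("simulated trees are ultrametric, reproducible pure-birth trees", {
  cherry <- simulate_tree(2, seed = 1)
  depths <- ape::node.depth.edgelength(cherry)[1:2]
  expect_equal(depths[1], depths[2], tolerance = 1e-12)

  t1 <- simulate_tree(10, seed = 3)
  t2 <- simulate_tree(10, seed = 3)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))

  big <- simulate_tree(50, seed = 5)
  d <- ape::node.depth.edgelength(big)[1:50]
  expect_lt(diff(range(d)), 1e-9)
  expect_error(simulate_tree(1), "two tips")
})

test_that("species coefficients honour sd = 0, seeds and lambda structure", {
  tr <- simulate_tree(6, seed = 11)
  cfg <- synth_config(n_species = 6, intercept_sd = 0, slope_sd = 0,
                      interaction_sd = 0, seed = 11)
  p1 <- simulate_species_params(tr, cfg)
  expect_equal(p1$intercept, rep(cfg$intercept_mean, 6))
  expect_equal(p1$slope, rep(cfg$slope_mean, 6))
  p2 <- simulate_species_params(tr, cfg)
  expect_identical(p1, p2)

  # lambda_true = 0: across replicates the cross-species covariance of the
  # intercept has off-diagonals near zero
  cfg0 <- synth_config(n_species = 6, intercept_mean = 0, intercept_sd = 1,
                       lambda_true = 0, seed = 1)
  draws <- vapply(1:500, function(r) {
    simulate_species_params(tr, cfg0, seed = r)$intercept
  }, numeric(6))
  emp_cov <- cov(t(draws))
  off <- emp_cov[upper.tri(emp_cov)]
  expect_lt(abs(mean(off)), 0.1)
  expect_equal(mean(diag(emp_cov)), 1, tolerance = 0.25)
})

test_that("metadata keeps both contrast levels represented", {
  tr <- simulate_tree(12, seed = 21)
  p <- simulate_species_params(tr, synth_config(seed = 21))
  expect_gte(min(table(p$migration_class)), 2L)
  expect_gte(min(table(p$moult_strategy)), 2L)
  expect_equal(sum(p$dichromatic), 10L)
  expect_true(all(p$male_ornamentation[p$dichromatic] >=
                    p$female_ornamentation[p$dichromatic]))
  # monomorphic species carry no sex-linked effects
  expect_equal(p$sex_effect[!p$dichromatic], rep(0, sum(!p$dichromatic)))
  expect_equal(p$interaction[!p$dichromatic], rep(0, sum(!p$dichromatic)))
})

test_that("area allocation is exact at the boundaries", {
  layout <- feather_tract_layout()
  areas <- fixture_areas("spA")
  total <- sum(areas$area_mm2)
  full <- moultclim:::allocate_area_to_feathers(total, "spA", areas, layout)
  expect_equal(as.numeric(full[1, feather_labels(layout)]), rep(1, 48))
  expect_equal(full$lc_prop, 1)
  expect_equal(full$mc_prop, 1)

  none <- moultclim:::allocate_area_to_feathers(0, "spA", areas, layout)
  expect_equal(as.numeric(none[1, feather_labels(layout)]), rep(0, 48))
  expect_equal(none$lc_prop + none$mc_prop, 0)
})

test_that("re-scoring generated records recovers the drawn area within one feather", {
  cfg <- synth_config(n_species = 5, n_per_species = 200, seed = 31)
  d <- simulate_moult_dataset(cfg)
  drawn <- attr(d$specimens, "drawn_area")
  scored <- score_moult(d$specimens, d$areas, d$layout)
  # the largest single feather is one primary: tract area / 10
  max_feather <- max((d$areas |>
                        dplyr::filter(tract == "P"))$area_mm2) / 10
  expect_equal(length(drawn), 1000L)
  expect_true(all(scored$moulted_area_mm2 <= drawn + 1e-9))
  expect_lt(max(drawn - scored$moulted_area_mm2), max_feather + 1e-9)
})

test_that("implied nonpositive Gamma means are rejected with guidance", {
  cfg <- synth_config(n_species = 3, n_per_species = 10,
                      intercept_mean = 100, intercept_sd = 0,
                      slope_mean = 5000, slope_sd = 0,
                      dichromatic_fraction = 0, seed = 41)
  expect_error(simulate_moult_dataset(cfg), "nonpositive")
})

test_that("identical configs give byte-identical written datasets", {
  cfg <- synth_config(n_species = 3, n_per_species = 25, seed = 51)
  d1 <- simulate_moult_dataset(cfg)
  d2 <- simulate_moult_dataset(cfg)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_moult_dataset(d1, dir1)
  write_moult_dataset(d2, dir2)
  for (f in list.files(dir1)) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     label = f)
  }
  # and the loaders round-trip the written files
  back <- load_moult_dataset(dir1)
  expect_equal(nrow(back$specimens), nrow(d1$specimens))
  expect_equal(back$gmta$anomaly_c, d1$gmta$anomaly_c, tolerance = 1e-12)
  expect_identical(sort(back$tree$tip.label), sort(d1$tree$tip.label))
})
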