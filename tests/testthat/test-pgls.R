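worked_tree <- function() read_tree_newick(text = "((A:1,B:1):1,C:2);")

test_that("Newick trees parse, validate and round-trip", {
  tr <- worked_tree()
  expect_equal(ape::Ntip(tr), 3L)
  expect_error(read_tree_newick(text = "((A:1,A:1):1,C:2);"), "Duplicate")
  expect_error(read_tree_newick(text = "((A:1,B:1):1,C:2;"), "parse")
  expect_error(read_tree_newick(text = "((A,B),C);"), "branch lengths")

  p <- withr::local_tempfile(fileext = ".nwk")
  big <- simulate_tree(20, seed = 4)
  ape::write.tree(big, p, digits = 15)
  back <- read_tree_newick(p)
  expect_equal(ape::Ntip(back), 20L)
  expect_equal(brownian_vcv(back, big$tip.label), brownian_vcv(big),
               tolerance = 1e-12)
})

test_that("the Brownian VCV holds shared path lengths", {
  V <- brownian_vcv(worked_tree(), c("A", "B", "C"))
  expect_equal(unname(V), rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)))
  star <- read_tree_newick(text = "(A:1,B:1,C:1);")
  expect_equal(unname(brownian_vcv(star)), diag(3))
  expect_error(brownian_vcv(worked_tree(), c("A", "Z")), "Z")

  for (seed in 1:25) {
    V <- brownian_vcv(simulate_tree(8, seed = seed))
    expect_equal(V, t(V))
    expect_gte(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("Pagel's lambda rescales only the off-diagonals", {
  C <- rbind(c(2, 1), c(1, 2))
  expect_equal(apply_lambda(C, 1), C)
  expect_equal(apply_lambda(C, 0), diag(c(2, 2)))
  expect_equal(apply_lambda(C, 0.5), rbind(c(2, 0.5), c(0.5, 2)))
  expect_error(apply_lambda(C, 1.2), "\\[0, 1\\]")
})

test_that("lambda = 0 PGLS on an ultrametric tree equals OLS", {
  withr::local_seed(9)
  tr <- simulate_tree(12, seed = 9)
  d <- data.frame(species_id = tr$tip.label,
                  x = rnorm(12), z = runif(12))
  d$y <- 1 + 2 * d$x - d$z + rnorm(12, 0, 0.3)
  fit <- pgls_fit(d, y ~ x + z, tr, lambda = 0)
  ols <- lm(y ~ x + z, data = d)
  s <- summary(ols)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(fit$r_squared, s$r.squared, tolerance = 1e-8)
  expect_equal(fit$f_statistic, unname(s$fstatistic[1]), tolerance = 1e-8)
  expect_equal(unname(fit$se), unname(s$coefficients[, 2]), tolerance = 1e-8)
})

test_that("fixed-lambda GLS matches explicit matrix inversion on the worked tree", {
  tr <- worked_tree()
  d <- data.frame(species_id = c("A", "B", "C"), y = c(1, 2, 3), x = c(0, 1, 2))
  fit <- pgls_fit(d, y ~ x, tr, lambda = 1)
  V <- rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2))
  X <- cbind(1, d$x)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% d$y)
  expect_equal(unname(coef(fit)), drop(beta), tolerance = 1e-8)
})

test_that("the ML profile optimum dominates a 21-point lambda grid", {
  withr::local_seed(14)
  tr <- simulate_tree(30, seed = 14)
  V <- brownian_vcv(tr)
  y <- drop(MASS::mvrnorm(1, rep(0, 30), V))
  d <- data.frame(species_id = tr$tip.label, y = y, x = rnorm(30))
  fit <- pgls_fit(d, y ~ x, tr, lambda = "ML")
  grid_ll <- vapply(seq(0, 1, length.out = 21), function(l) {
    pgls_fit(d, y ~ x, tr, lambda = l)$log_likelihood
  }, numeric(1))
  expect_gte(fit$log_likelihood, max(grid_ll) - 1e-9)
})

test_that("F, r2 and df are mutually consistent and order-invariant", {
  withr::local_seed(15)
  tr <- simulate_tree(15, seed = 15)
  d <- data.frame(species_id = tr$tip.label, x = rnorm(15))
  d$y <- 0.5 + d$x + rnorm(15, 0, 0.5)
  fit <- pgls_fit(d, y ~ x, tr)
  expect_equal(fit$f_statistic,
               (fit$r_squared / fit$df["df1"]) /
                 ((1 - fit$r_squared) / fit$df["df2"]),
               tolerance = 1e-10, ignore_attr = TRUE)
  perm <- d[sample(nrow(d)), ]
  fit2 <- pgls_fit(perm, y ~ x, tr)
  expect_equal(fit$lambda, fit2$lambda, tolerance = 1e-6)
  expect_equal(coef(fit), coef(fit2), tolerance = 1e-10)
  expect_equal(fit$p_value, fit2$p_value, tolerance = 1e-10)
})

test_that("ML lambda agrees with an independent PGLS implementation", {
  skip_if_not_installed("nlme")
  withr::local_seed(16)
  tr <- simulate_tree(40, seed = 16)
  V <- brownian_vcv(tr)
  d <- data.frame(species_id = tr$tip.label, x = rnorm(40))
  d$y <- 1 + 0.8 * d$x + drop(MASS::mvrnorm(1, rep(0, 40), 0.5 * V))
  fit <- pgls_fit(d, y ~ x, tr, lambda = "ML")
  ref <- nlme::gls(y ~ x, data = d,
                   correlation = ape::corPagel(0.5, tr, form = ~species_id),
                   method = "ML")
  lam_ref <- unname(coef(ref$modelStruct$corStruct, unconstrained = FALSE))
  # corPagel optimises lambda unbounded; clamp to the [0, 1] domain used here
  expect_equal(fit$lambda, min(max(lam_ref, 0), 1), tolerance = 0.05)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-3)
})

test_that("degenerate PGLS inputs error clearly", {
  tr <- simulate_tree(6, seed = 2)
  d <- data.frame(species_id = tr$tip.label, y = rnorm(6), x = rep(1, 6))
  expect_error(pgls_fit(d, y ~ x, tr), "Constant predictor")
  d2 <- data.frame(species_id = c(tr$tip.label[-1], "ghost"),
                   y = rnorm(6), x = rnorm(6))
  expect_error(pgls_fit(d2, y ~ x, tr), "ghost")
})

test_that("group contrasts behave on designed null and strong cases", {
  tr <- simulate_tree(10, seed = 77)
  # symmetric null: identical group means, large within-group spread
  d <- data.frame(species_id = tr$tip.label,
                  trait = rep(c(-1, 1), 5),
                  grp = rep(c("g1", "g2"), each = 5))
  null_fit <- group_contrast(d, "trait", "grp", tr, lambda = 0)
  expect_gt(null_fit$p_value, 0.5)
  expect_equal(unname(null_fit$df), c(1, 8))

  d$trait <- ifelse(d$grp == "g2", 10, 0) + rep(c(-0.5, 0.5), 5)
  strong_fit <- group_contrast(d, "trait", "grp", tr, lambda = 0)
  expect_lt(strong_fit$p_value, 0.001)

  d$grp <- "g1"
  expect_error(group_contrast(d, "trait", "grp", tr), "two levels")
})

test_that("the ornamentation regression recovers a negative built-in slope", {
  withr::local_seed(88)
  tr <- simulate_tree(10, seed = 88)
  diff <- runif(10, 0, 30)
  d <- data.frame(species_id = tr$tip.label,
                  interaction_coef = -12 * diff + rnorm(10, 0, 20),
                  male_ornamentation = 40 + diff,
                  female_ornamentation = 40)
  fit <- ornamentation_regression(d, tr)
  expect_lt(coef(fit)["orn_diff"], 0)
  expect_lt(fit$p_value, 0.05)

  d$male_ornamentation <- d$female_ornamentation
  expect_error(ornamentation_regression(d, tr), "Constant predictor")
  d$male_ornamentation[3] <- NA
  expect_error(ornamentation_regression(d, tr), d$species_id[3])
})

test_that("a null ornamentation effect is rarely declared significant", {
  reps <- 200
  hits <- 0
  for (r in seq_len(reps)) {
    tr <- simulate_tree(10, seed = 4000 + r)
    withr::with_seed(90000 + r, {
      d <- data.frame(species_id = tr$tip.label,
                      interaction_coef = rnorm(10, 0, 30),
                      male_ornamentation = 40 + runif(10, 0, 30),
                      female_ornamentation = 40)
      fit <- ornamentation_regression(d, tr)
      if (fit$p_value < 0.05) hits <- hits + 1
    })
  }
  expect_lte(hits / reps, 0.10)
})
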