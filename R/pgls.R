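#' Read and validate a Newick phylogeny
#'
#' Thin wrapper around [ape::read.tree()] that enforces the contracts the
#' comparative stage needs: unique tip labels and branch lengths on every
#' edge. Non-ultrametric trees are accepted with a warning, since the
#' Brownian covariance matrix remains well defined but the interpretation
#' of Pagel's lambda weakens.
#'
#' @param path Path to a Newick file, or `NULL` when `text` is given.
#' @param text Newick string (alternative to `path`).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_tree_newick <- function(path = NULL, text = NULL) {
  tree <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) rlang::abort(sprintf("Newick parse error: %s", conditionMessage(e))),
    warning = function(w) rlang::abort(sprintf("Newick parse error: %s", conditionMessage(w)))
  )
  if (is.null(tree)) rlang::abort("Newick parse error: no tree found.")
  if (anyDuplicated(tree$tip.label) > 0) {
    rlang::abort(sprintf("Duplicate tip label(s): %s",
                         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                               collapse = ", ")))
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    rlang::abort("Tree must carry branch lengths on every edge.")
  }
  if (any(tree$edge.length < 0)) rlang::abort("Negative branch lengths are not allowed.")
  if (!ape::is.ultrametric(tree, tol = 1e-6)) {
    warning("Tree is not ultrametric; Pagel's lambda remains defined but its interpretation weakens.",
            call. = FALSE)
  }
  tree
}

#' Brownian-motion variance-covariance matrix of a tree
#'
#' Entry (i, j) is the shared root-to-tip path length of tips i and j (their
#' common evolutionary history); the diagonal holds root-to-tip depths.
#'
#' @param tree A `phylo` object.
#' @param tip_order Character vector of tip labels giving the row/column
#'   order; defaults to the tree's tip order.
#' @return A symmetric positive semi-definite matrix with dimnames.
#' @export
brownian_vcv <- function(tree, tip_order = tree$tip.label) {
  missing <- setdiff(tip_order, tree$tip.label)
  if (length(missing) > 0) {
    rlang::abort(sprintf("Tip(s) not in the tree: %s", paste(missing, collapse = ", ")))
  }
  V <- ape::vcv.phylo(tree)
  V[tip_order, tip_order, drop = FALSE]
}

#' Apply Pagel's lambda to a Brownian covariance matrix
#'
#' Multiplies the off-diagonal (shared-history) entries by lambda, leaving
#' the diagonal untouched. lambda = 0 removes all phylogenetic signal;
#' lambda = 1 leaves the Brownian structure intact.
#'
#' @param C Symmetric covariance matrix.
#' @param lambda Scalar in \[0, 1\].
#' @return The rescaled matrix.
#' @export
apply_lambda <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0 || lambda > 1) {
    rlang::abort("lambda must be a single value in [0, 1].")
  }
  out <- C * lambda
  diag(out) <- diag(C)
  out
}

# GLS solve under a fixed covariance: returns coefficients, the quadratic
# form r' V^-1 r, log|V| and the ML log-likelihood (sigma^2 profiled out).
gls_solve <- function(y, X, V) {
  L <- tryCatch(chol(V), error = function(e) {
    rlang::abort("Phylogenetic covariance matrix is singular or not positive definite.")
  })
  ty <- backsolve(L, y, transpose = TRUE)
  tX <- backsolve(L, X, transpose = TRUE)
  qrx <- qr(tX)
  beta <- stats::setNames(qr.coef(qrx, ty), colnames(X))
  r <- ty - tX %*% beta
  rss <- sum(r^2)
  n <- length(y)
  logdet <- 2 * sum(log(diag(L)))
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1) - logdet / 2
  list(beta = drop(beta), rss = rss, logdet = logdet, log_likelihood = ll,
       xtx_inv = chol2inv(qr.R(qrx)))
}

#' Phylogenetic generalised least squares with Pagel's lambda
#'
#' Fits `formula` across species by generalised least squares under the
#' covariance sigma^2 * V(lambda), where V is the Brownian matrix of the
#' tree and lambda rescales its off-diagonals. With `lambda = "ML"` the
#' profile log-likelihood (residual variance profiled out) is maximised
#' over \[0, 1\]: a 21-point grid locates the basin, golden-section search
#' refines it, and ties are broken toward the smaller lambda because the
#' profile can be flat or bimodal at small n.
#'
#' Reported alongside lambda-hat: GLS coefficients with standard errors and
#' two-tailed t-tests, the GLS r² against the GLS intercept-only model
#' under the same V(lambda-hat), the overall F statistic with
#' (p - 1, n - p) degrees of freedom and its two-tailed p-value, the
#' residual variance on n - p degrees of freedom, and the ML
#' log-likelihood.
#'
#' @param data Data frame with one row per species, containing
#'   `species_col` plus every variable in `formula`.
#' @param formula Model formula, e.g. `trait ~ predictor`; must include an
#'   intercept and at least one predictor.
#' @param tree A `phylo` object whose tips cover the species.
#' @param lambda `"ML"` (default) or a fixed value in \[0, 1\].
#' @param species_col Name of the species identifier column
#'   (default `"species_id"`).
#' @return An object of class `pgls_fit`.
#' @export
#' @examples
#' tr <- read_tree_newick(text = "((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
#' d <- data.frame(species_id = c("A", "B", "C", "D"),
#'                 y = c(1, 1.4, 2.9, 3.1), x = c(0, 0.5, 2, 2.2))
#' pgls_fit(d, y ~ x, tr, lambda = 0)
pgls_fit <- function(data, formula, tree, lambda = "ML",
                     species_col = "species_id") {
  data <- as.data.frame(data)
  if (!species_col %in% names(data)) {
    rlang::abort(sprintf("Column '%s' not found in data.", species_col))
  }
  species <- as.character(data[[species_col]])
  if (anyDuplicated(species) > 0) rlang::abort("Duplicated species in data.")
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  p <- ncol(X)
  if (!"(Intercept)" %in% colnames(X)) rlang::abort("PGLS requires an intercept.")
  if (p < 2) rlang::abort("PGLS needs at least one predictor besides the intercept.")
  if (n < p + 1) rlang::abort(sprintf("Need at least %d species for %d coefficients.", p + 1, p))
  pred_sd <- apply(X[, -1, drop = FALSE], 2, stats::sd)
  if (any(pred_sd == 0)) {
    rlang::abort(sprintf("Constant predictor(s): %s",
                         paste(names(pred_sd)[pred_sd == 0], collapse = ", ")))
  }
  if (qr(X)$rank < p) rlang::abort("Design matrix is rank deficient.")

  C <- brownian_vcv(tree, species)

  profile_ll <- function(lam) gls_solve(y, X, apply_lambda(C, lam))$log_likelihood

  if (identical(lambda, "ML")) {
    grid <- seq(0, 1, length.out = 21)
    ll_grid <- vapply(grid, profile_ll, numeric(1))
    i <- which.max(ll_grid)   # ties break toward smaller lambda (first max)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(21L, i + 1L)]
    opt <- stats::optimize(profile_ll, interval = c(lo, hi), maximum = TRUE,
                           tol = 1e-8)
    # keep whichever candidate dominates; prefer the smaller lambda on ties
    cand <- c(opt$maximum, grid[i])
    cand_ll <- c(opt$objective, ll_grid[i])
    best <- order(-cand_ll, cand)[1]
    lambda_hat <- cand[best]
    mode <- "ML"
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
      rlang::abort("lambda must be 'ML' or a value in [0, 1].")
    }
    lambda_hat <- lambda
    mode <- "fixed"
  }

  Vl <- apply_lambda(C, lambda_hat)
  full <- gls_solve(y, X, Vl)
  null <- gls_solve(y, cbind(`(Intercept)` = rep(1, n)), Vl)

  df1 <- p - 1L
  df2 <- n - p
  r2 <- 1 - full$rss / null$rss
  f_stat <- (r2 / df1) / ((1 - r2) / df2)
  p_value <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)

  sigma2 <- full$rss / df2           # OLS-analogue residual variance (n - p)
  se <- sqrt(sigma2 * diag(full$xtx_inv))
  tval <- full$beta / se
  coef_p <- 2 * stats::pt(abs(tval), df2, lower.tail = FALSE)

  structure(list(
    lambda = lambda_hat,
    lambda_mode = mode,
    coefficients = full$beta,
    se = stats::setNames(se, names(full$beta)),
    t_value = tval,
    coef_p_value = coef_p,
    sigma2 = sigma2,
    r_squared = r2,
    f_statistic = f_stat,
    df = c(df1 = df1, df2 = df2),
    p_value = p_value,
    log_likelihood = full$log_likelihood,
    n = n,
    species = species,
    formula = formula,
    model_frame = mf
  ), class = "pgls_fit")
}

#' Two-group phylogenetic contrast of a species trait
#'
#' PGLS of a trait on a 0/1 group indicator — used for the migration
#' distance classes (short vs long) and for pre- vs post-migration moult
#' strategy. With n species and one indicator the F test has (1, n - 2)
#' degrees of freedom.
#'
#' @param data One row per species with the trait and group columns.
#' @param trait,group Column names (strings) of the response trait and the
#'   two-level grouping.
#' @param tree A `phylo` object.
#' @param lambda `"ML"` or fixed value, as in [pgls_fit()].
#' @param species_col Species identifier column name.
#' @return A `pgls_fit`; the second coefficient is the group-mean contrast.
#' @export
group_contrast <- function(data, trait, group, tree, lambda = "ML",
                           species_col = "species_id") {
  g <- data[[group]]
  lev <- sort(unique(as.character(g)))
  if (length(lev) != 2) {
    rlang::abort(sprintf("Grouping '%s' must have exactly two levels (found %d).",
                         group, length(lev)))
  }
  if (any(table(g) < 2)) rlang::abort("Each group needs at least two species.")
  d <- data.frame(data[[species_col]], data[[trait]],
                  as.numeric(as.character(g) == lev[2]))
  names(d) <- c(species_col, ".trait", ".group")
  fit <- pgls_fit(d, .trait ~ .group, tree, lambda = lambda,
                  species_col = species_col)
  fit$group_levels <- lev
  fit
}

#' Ornamentation-difference regression of the sex-by-GMTA interaction
#'
#' Across dichromatic species, regresses the GMTA-by-sex interaction
#' coefficient (male coded relative to female) on the male-minus-female
#' plumage ornamentation score, by PGLS with ML lambda. A negative slope
#' means females of strongly dichromatic species respond more steeply to
#' warming than males.
#'
#' @param data One row per species with columns `interaction_coef`,
#'   `male_ornamentation`, `female_ornamentation`.
#' @param tree A `phylo` object.
#' @param lambda `"ML"` or fixed value.
#' @param species_col Species identifier column name.
#' @return A `pgls_fit` with the slope on `orn_diff`.
#' @export
ornamentation_regression <- function(data, tree, lambda = "ML",
                                     species_col = "species_id") {
  need <- c("interaction_coef", "male_ornamentation", "female_ornamentation")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    rlang::abort(sprintf("Missing column(s): %s", paste(miss, collapse = ", ")))
  }
  bad <- !stats::complete.cases(data[, need])
  if (any(bad)) {
    rlang::abort(sprintf("Missing score or interaction coefficient for species: %s",
                         paste(data[[species_col]][bad], collapse = ", ")))
  }
  d <- data.frame(data[[species_col]], data$interaction_coef,
                  data$male_ornamentation - data$female_ornamentation)
  names(d) <- c(species_col, "interaction_coef", "orn_diff")
  pgls_fit(d, interaction_coef ~ orn_diff, tree, lambda = lambda,
           species_col = species_col)
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS fit (lambda %s = %.3f), n = %d species\n",
              x$lambda_mode, x$lambda, x$n))
  print(data.frame(estimate = x$coefficients, se = x$se,
                   t = x$t_value, p = x$coef_p_value))
  cat(sprintf("r2 = %.3f, F%d,%d = %.3f, P = %.4f, logLik = %.3f\n",
              x$r_squared, x$df["df1"], x$df["df2"], x$f_statistic,
              x$p_value, x$log_likelihood))
  invisible(x)
}

#' @export
coef.pgls_fit <- function(object, ...) object$coefficients

#' Broom-style summaries of fitted objects
#'
#' `tidy()` returns one row per model term; `glance()` returns a one-row
#' model summary. Methods are provided for `pgls_fit` and `gamma_glm`
#' objects.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pgls_fit
#' @export
tidy.pgls_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(x$se),
                 statistic = unname(x$t_value),
                 p.value = unname(x$coef_p_value))
}

#' @rdname tidy.pgls_fit
#' @method glance pgls_fit
#' @export
glance.pgls_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, r.squared = x$r_squared,
                 statistic = x$f_statistic, df1 = unname(x$df["df1"]),
                 df2 = unname(x$df["df2"]), p.value = x$p_value,
                 logLik = x$log_likelihood, nobs = x$n)
}

#' Serialise a PGLS fit to JSON
#'
#' @param fit A `pgls_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pgls_json <- function(fit, path) {
  obj <- list(
    lambda = fit$lambda, lambda_mode = fit$lambda_mode,
    coefficients = as.list(fit$coefficients), se = as.list(fit$se),
    sigma2 = fit$sigma2, r_squared = fit$r_squared,
    f_statistic = fit$f_statistic,
    df1 = unname(fit$df["df1"]), df2 = unname(fit$df["df2"]),
    p_value = fit$p_value, log_likelihood = fit$log_likelihood, n = fit$n
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
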