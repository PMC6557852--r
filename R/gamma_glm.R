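#' Fit an identity-link Gamma GLM by maximum likelihood
#'
#' Fits the model y_i ~ Gamma(shape = nu, mean = mu_i) with mu_i = x_i'beta
#' (identity link: the mean *is* the linear predictor, so coefficients are
#' in response units per covariate unit). The mean coefficients are found by
#' iteratively reweighted least squares — for the identity link the working
#' response is y itself and the weights are 1/mu_i^2 — with step-halving so
#' every fitted mean stays strictly positive. Because the Gamma
#' log-likelihood factorises, the coefficient ML does not depend on the
#' shape; nu is then profiled out by solving its score equation, and the
#' reported log-likelihood is the full Gamma likelihood at (beta-hat,
#' nu-hat). The parameter count `k` includes the shape, so AICc values
#' compare full likelihoods across candidates.
#'
#' @param y Strictly positive response vector (moulted area in mm², or
#'   relative extent).
#' @param X Design matrix with an intercept column, full column rank.
#' @param label Optional candidate label carried into summaries.
#' @param max_iter,tol IRLS iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return An object of class `gamma_glm`: coefficients, `shape`,
#'   `log_likelihood`, `n`, `k` (mean parameters + 1 for the shape), `aicc`,
#'   fitted values.
#' @export
#' @examples
#' fit <- fit_gamma_identity(c(2, 4, 6), cbind(intercept = rep(1, 3)))
#' coef(fit) # the Gamma ML intercept is the sample mean: 4
fit_gamma_identity <- function(y, X, label = NULL, max_iter = 200L,
                               tol = 1e-10) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) rlang::abort("nrow(X) must equal length(y).")
  if (any(!is.finite(y)) || any(y <= 0)) {
    bad <- which(!is.finite(y) | y <= 0)[1]
    rlang::abort(sprintf(
      "Gamma responses must be strictly positive and finite; offending observation %d (value %g). The Gamma distribution has support (0, Inf).",
      bad, y[bad]))
  }
  if (qr(X)$rank < p) rlang::abort("Design matrix is rank deficient.")
  if (n <= p + 1) {
    rlang::abort(sprintf("Need n > p + 1 observations (n = %d, p = %d).", n, p))
  }

  # start from OLS; fall back to a flat mean if OLS predicts nonpositive
  beta <- stats::lm.fit(X, y)$coefficients
  mu <- drop(X %*% beta)
  if (any(mu <= 0)) {
    beta <- c(mean(y), rep(0, p - 1))
    mu <- drop(X %*% beta)
    if (any(mu <= 0)) {
      rlang::abort("No starting value with all fitted means positive (is the first column an intercept?).")
    }
  }

  ll_old <- -Inf
  shape <- NA_real_
  for (iter in seq_len(max_iter)) {
    w <- 1 / mu^2
    beta_new <- stats::lm.wfit(X, y, w)$coefficients
    step <- 1
    repeat {
      beta_try <- beta + step * (beta_new - beta)
      mu_try <- drop(X %*% beta_try)
      if (all(mu_try > 0)) break
      step <- step / 2
      if (step < 1e-12) {
        rlang::abort("IRLS step-halving failed: no step keeps all fitted means positive.")
      }
    }
    beta <- beta_try
    mu <- mu_try
    shape <- gamma_shape_ml(y, mu)
    ll <- sum(stats::dgamma(y, shape = shape, rate = shape / mu, log = TRUE))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }

  k <- p + 1L
  structure(list(
    label = label %||% "model",
    coefficients = stats::setNames(as.numeric(beta), colnames(X)),
    shape = shape,
    fitted = mu,
    log_likelihood = ll,
    n = n,
    k = k,
    # AICc needs n > k + 1; tiny fits are legal but carry no AICc
    aicc = if (n > k + 1) aicc(ll, k, n) else NA_real_,
    iterations = iter
  ), class = "gamma_glm")
}

# ML of the Gamma shape given fitted means: solves
#   log(nu) + 1 - digamma(nu) = mean(y/mu - log(y/mu))
# the LHS decreases monotonically from +Inf to 1; the RHS is >= 1 by
# Jensen, with equality only when y == mu exactly.
gamma_shape_ml <- function(y, mu) {
  r <- mean(y / mu - log(y / mu))
  if (r <= 1 + 1e-12) return(1e8)  # degenerate: noiseless data
  g <- function(lnu) {
    nu <- exp(lnu)
    log(nu) + 1 - digamma(nu) - r
  }
  stats::uniroot(g, interval = c(log(1e-8), log(1e8)), tol = 1e-12)$root |>
    exp()
}

#' Corrected Akaike information criterion
#'
#' AICc = -2*logLik + 2k + 2k(k+1)/(n - k - 1); the small-sample correction
#' vanishes as n grows.
#'
#' @param log_likelihood Maximised log-likelihood.
#' @param k Number of estimated parameters (including any dispersion/shape).
#' @param n Number of observations; must exceed k + 1.
#' @return The AICc value.
#' @export
#' @examples
#' aicc(-10, 2, 10) # 24 + 12/7
aicc <- function(log_likelihood, k, n) {
  if (n <= k + 1) {
    rlang::abort(sprintf("AICc undefined for n <= k + 1 (n = %d, k = %d).", n, k))
  }
  -2 * log_likelihood + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Candidate model set for one species
#'
#' Monomorphic species (sex not identifiable) get the null model and the
#' GMTA model. Dichromatic species additionally get sex, additive GMTA+sex,
#' and the full model with the GMTA-by-sex interaction. Candidates are
#' hierarchical: the interaction appears only together with both main
#' effects.
#'
#' @param dichromatic Logical flag.
#' @return A tibble with `label` and `terms` (list-column of predictor term
#'   names drawn from `"gmta"`, `"sex"`, `"gmta:sex"`; the intercept is
#'   implicit).
#' @export
build_candidate_set <- function(dichromatic) {
  specs <- list(
    "intercept"            = character(0),
    "gmta"                 = "gmta",
    "sex"                  = "sex",
    "gmta+sex"             = c("gmta", "sex"),
    "gmta*sex"             = c("gmta", "sex", "gmta:sex")
  )
  if (!dichromatic) specs <- specs[c("intercept", "gmta")]
  tibble::tibble(label = names(specs), terms = unname(specs))
}

#' AICc model selection with an ambiguity threshold
#'
#' Computes each candidate's ΔAICc relative to the minimum. The best model
#' is *selected* only when the runner-up's ΔAICc strictly exceeds the
#' threshold (default 2.00); otherwise the evidence is ambiguous and the
#' selection is `"none"`.
#'
#' @param fits List of `gamma_glm` fits of the *same* observations
#'   (identical n enforced).
#' @param threshold ΔAICc ambiguity threshold, default 2.00.
#' @return A `model_selection` tibble: `label`, `k`, `n`, `logLik`, `AICc`,
#'   `delta_aicc`, `selected`; attributes `selected_label` and `threshold`.
#' @export
select_model <- function(fits, threshold = 2.00) {
  if (length(fits) < 2) rlang::abort("Need at least two candidate fits.")
  ns <- vapply(fits, function(f) f$n, integer(1))
  if (length(unique(ns)) != 1) {
    rlang::abort("Candidates were fitted to differing numbers of observations; AICc values are not comparable.")
  }
  tab <- tibble::tibble(
    label = vapply(fits, function(f) f$label, character(1)),
    k = vapply(fits, function(f) f$k, integer(1)),
    n = ns,
    logLik = vapply(fits, function(f) f$log_likelihood, numeric(1)),
    AICc = vapply(fits, function(f) f$aicc, numeric(1))
  )
  tab$delta_aicc <- tab$AICc - min(tab$AICc)
  ord <- order(tab$delta_aicc)
  runner_up <- tab$delta_aicc[ord[2]]
  sel <- if (runner_up > threshold) tab$label[ord[1]] else "none"
  tab$selected <- tab$label == sel
  attr(tab, "selected_label") <- sel
  attr(tab, "threshold") <- threshold
  attr(tab, "fits") <- fits
  class(tab) <- c("model_selection", class(tab))
  tab
}

#' @export
print.gamma_glm <- function(x, ...) {
  cat(sprintf("Gamma GLM (identity link) '%s': n = %d, k = %d, shape = %.3f\n",
              x$label, x$n, x$k, x$shape))
  print(x$coefficients)
  cat(sprintf("logLik = %.3f, AICc = %.3f\n", x$log_likelihood, x$aicc))
  invisible(x)
}

#' @export
coef.gamma_glm <- function(object, ...) object$coefficients

#' @export
logLik.gamma_glm <- function(object, ...) {
  structure(object$log_likelihood, df = object$k, nobs = object$n,
            class = "logLik")
}

#' @rdname tidy.pgls_fit
#' @method tidy gamma_glm
#' @export
tidy.gamma_glm <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname tidy.pgls_fit
#' @method glance gamma_glm
#' @export
glance.gamma_glm <- function(x, ...) {
  tibble::tibble(nobs = x$n, k = x$k, shape = x$shape,
                 logLik = x$log_likelihood, AICc = x$aicc)
}
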