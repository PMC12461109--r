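#' Observed site-level species richness
#'
#' Number of species with at least one detection by any method at each site,
#' straight from the raw detection histories.
#'
#' @param data A [detection_data()] object.
#' @return Named integer vector over sites.
#' @export
observed_richness <- function(data) {
  validate_detection_data(data)
  det <- Reduce(`|`, lapply(data$methods, function(m) data$Y[[m]] > 0))
  stats::setNames(as.integer(rowSums(det)), data$sites)
}

#' Detectability-corrected site richness from the posterior
#'
#' For every retained draw, site richness is the number of occupied species
#' `sum_k Z[i, k]`; the table reports its posterior mean and central 95%
#' credible interval. Because detections force occupancy, every draw's
#' richness is at least the number of species detected at the site. Setting
#' `method = "psi_mean"` instead sums posterior mean occupancy probabilities
#' per species (a smooth, non-integer alternative without a credible
#' interval on the sum of latent states).
#'
#' @param posterior A `"pom_fit"` with retained `Z` draws.
#' @param method `"z_draws"` (default, per-draw latent richness) or
#'   `"psi_mean"`.
#' @return Data frame with columns `site`, `mean`, `q2.5`, `q97.5` (the last
#'   two `NA` for `method = "psi_mean"`).
#' @export
estimated_richness <- function(posterior, method = c("z_draws", "psi_mean")) {
  stopifnot(inherits(posterior, "pom_fit"))
  method <- match.arg(method)
  Z <- z_draws(posterior)
  if (method == "psi_mean") {
    zbar <- apply(Z, c(1, 2), mean)
    return(data.frame(site = posterior$sites, mean = rowSums(zbar),
                      q2.5 = NA_real_, q97.5 = NA_real_))
  }
  rich <- apply(Z, 3, rowSums)                  # I x S
  data.frame(
    site = posterior$sites,
    mean = rowMeans(rich),
    q2.5 = apply(rich, 1, stats::quantile, 0.025, type = 7),
    q97.5 = apply(rich, 1, stats::quantile, 0.975, type = 7),
    row.names = NULL
  )
}

#' Poisson regression with log link by IRLS
#'
#' Self-contained iteratively reweighted least squares for the Poisson GLM
#' with a log link, usable with non-integer responses (quasi-likelihood
#' estimating equations, as needed to regress posterior-mean richness).
#' Standard errors come from the inverse Fisher information; z-values and
#' two-sided normal p-values follow. Convergence is declared when the
#' relative deviance change drops below `tol`.
#'
#' @param y Non-negative response vector.
#' @param X Design matrix including the intercept column; must be full rank.
#' @param max_iter,tol Iteration control.
#' @return Object of class `"pom_glm"`: list with `coefficients`, `se`, `z`,
#'   `p`, `deviance`, `deviance_path`, `converged`, `fitted`.
#' @export
poisson_glm <- function(y, X, max_iter = 100L, tol = 1e-10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X))
  if (any(y < 0)) stop("y must be non-negative", call. = FALSE)
  if (all(y == 0)) stop("all-zero response: intercept diverges", call. = FALSE)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)

  mu <- pmax(y, 0.1) + mean(y) / 2              # standard Poisson start
  eta <- log(mu)
  dev <- poisson_deviance(y, mu)
  path <- numeric(0)   # records model-constrained iterates only (the
                       # heuristic start is not an IRLS iterate)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- mu                                     # Fisher weights, log link
    z <- eta + (y - mu) / mu                    # working response
    fit <- stats::lm.wfit(X, z, w)
    beta <- fit$coefficients
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    dev_new <- poisson_deviance(y, mu)
    path <- c(path, dev_new)
    if (abs(dev_new - dev) / (abs(dev_new) + 0.1) < tol) {
      converged <- TRUE
      dev <- dev_new
      break
    }
    dev <- dev_new
  }
  if (!converged) stop("IRLS did not converge after ", max_iter, " iterations",
                       call. = FALSE)
  info <- crossprod(X * sqrt(mu))               # X' W X
  cov <- solve(info)
  se <- sqrt(diag(cov))
  zval <- beta / se
  structure(
    list(coefficients = stats::setNames(beta, colnames(X)),
         se = stats::setNames(se, colnames(X)),
         z = stats::setNames(zval, colnames(X)),
         p = stats::setNames(2 * stats::pnorm(-abs(zval)), colnames(X)),
         deviance = dev, deviance_path = path, converged = converged,
         fitted = mu),
    class = "pom_glm"
  )
}

# Poisson (quasi-)deviance valid for non-integer y; y log y -> 0 at 0
poisson_deviance <- function(y, mu) {
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  2 * sum(t1 - (y - mu))
}

#' @export
print.pom_glm <- function(x, ...) {
  tab <- data.frame(Estimate = x$coefficients, `Z value` = x$z, p = x$p,
                    check.names = FALSE)
  print(round(tab, 4))
  invisible(x)
}

#' Richness-environment Poisson regressions
#'
#' Reproduces the standard four-model layout: observed and estimated
#' (posterior-mean) richness each regressed on (i) standardized elevation
#' with linear and quadratic terms and (ii) standardized temperature,
#' precipitation and forest cover. Predictors are standardized with the
#' population-SD convention; the quadratic term is the square of
#' standardized elevation.
#'
#' @param table Data frame with columns `site`, `observed`, `estimated`
#'   (e.g. built from [observed_richness()] and [estimated_richness()]).
#' @param covariates A [site_covariates()] object (raw or standardized).
#' @return Named list of four `"pom_glm"` fits: `observed_elevation`,
#'   `estimated_elevation`, `observed_environment`, `estimated_environment`.
#' @export
richness_regressions <- function(table, covariates) {
  stopifnot(all(c("site", "observed", "estimated") %in% names(table)))
  if (nrow(table) < 6L) stop("need at least 6 sites", call. = FALSE)
  cov <- standardize(covariates)
  idx <- match(table$site, cov$site)
  if (anyNA(idx)) stop("sites missing from covariates", call. = FALSE)
  ele <- cov$elevation[idx]
  Xe <- cbind(Intercept = 1, elevation = ele, `elevation^2` = ele^2)
  Xv <- cbind(Intercept = 1,
              temperature = cov$temperature[idx],
              precipitation = cov$precipitation[idx],
              forest_cover = cov$forest_cover[idx])
  list(
    observed_elevation = poisson_glm(table$observed, Xe),
    estimated_elevation = poisson_glm(table$estimated, Xe),
    observed_environment = poisson_glm(table$observed, Xv),
    estimated_environment = poisson_glm(table$estimated, Xv)
  )
}

#' Assemble the observed/estimated richness table
#'
#' @param data A [detection_data()] object.
#' @param posterior A `"pom_fit"` for the same data.
#' @return Data frame with `site`, `observed`, `estimated`, `q2.5`, `q97.5`.
#' @export
richness_table <- function(data, posterior) {
  obs <- observed_richness(data)
  est <- estimated_richness(posterior)
  data.frame(site = data$sites, observed = unname(obs[data$sites]),
             estimated = est$mean, q2.5 = est$q2.5, q97.5 = est$q97.5)
}
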