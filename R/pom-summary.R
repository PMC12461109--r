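#' Joint occupancy-detection log-likelihood of a model state
#'
#' Sums, over methods, sites and masked-in species, the binomial log-mass of
#' the season-level detections `Y ~ Binomial(N, p * Z)` plus the Bernoulli
#' log-mass of the latent states `Z ~ Bernoulli(psi)` with
#' `logit(psi) = alpha_k + x_i' beta_k`. This is the reference (pure R)
#' likelihood used to check the compiled sampler against exact enumeration.
#'
#' @param state List with `alpha` (K), `beta` (K x J), `p` (named list per
#'   method of per-species detection probabilities) and `Z` (I x K 0/1).
#' @param data A [detection_data()] object.
#' @param covariates Standardized [site_covariates()] (or bare I x J matrix).
#' @return Scalar log-likelihood (finite for valid states).
#' @export
occupancy_detection_loglik <- function(state, data, covariates) {
  validate_detection_data(data)
  beta <- state$beta
  X <- model_covariate_matrix(covariates, ncol(beta))
  psi <- stats::plogis(sweep(X %*% t(beta), 2, state$alpha, "+"))
  Z <- state$Z
  stopifnot(all(Z %in% c(0, 1)), all(dim(Z) == dim(psi)))
  ll <- sum(Z * log(psi) + (1 - Z) * log(1 - psi))
  for (m in data$methods) {
    p <- state$p[[m]]
    if (any(p < 0 | p > 1)) {
      stop("detection probability outside [0, 1] for method ", m, call. = FALSE)
    }
    msk <- data$mask[[m]]
    N <- data$N[[m]]
    for (k in which(msk)) {
      pk <- p[k] * Z[, k]              # 0 when unoccupied
      ll <- ll + sum(stats::dbinom(data$Y[[m]][, k], N, pk, log = TRUE))
    }
  }
  ll
}

#' Gibbs update of the latent occupancy states
#'
#' Species/site cells with any detection by an applicable method are occupied
#' with probability one. Otherwise `Z ~ Bernoulli(psi q / (psi q + 1 - psi))`
#' where `q = prod_m (1 - p[m][k])^N[m][i]` over the species' applicable
#' methods, i.e. the probability of the observed all-zero history given
#' presence.
#'
#' @param state List with `psi` (I x K), `p` (named list per method) and
#'   optionally `Z`.
#' @param data A [detection_data()] object.
#' @return The state with refreshed `Z`; the conditional probabilities are
#'   attached as `state$z_prob`.
#' @export
gibbs_update_Z <- function(state, data) {
  validate_detection_data(data)
  psi <- state$psi
  I <- length(data$sites); K <- length(data$species)
  stopifnot(all(dim(psi) == c(I, K)))
  q <- matrix(1, I, K)
  anyY <- matrix(FALSE, I, K)
  for (m in data$methods) {
    pk <- state$p[[m]]
    for (k in which(data$mask[[m]])) {
      q[, k] <- q[, k] * (1 - pk[k])^data$N[[m]]
    }
    anyY <- anyY | (data$Y[[m]] > 0)
  }
  prob <- psi * q / (psi * q + 1 - psi)
  prob[anyY] <- 1
  state$z_prob <- prob
  state$Z <- matrix(stats::rbinom(I * K, 1L, prob), I, K,
                    dimnames = dimnames(psi))
  state
}

#' Bayes factor for phylogenetic signal from spike-and-slab draws
#'
#' With equal prior odds (spike mass 0.5), the Bayes factor for
#' `lambda > 0` versus `lambda = 0` is the ratio of posterior draws above
#' zero to draws exactly at zero. When no draws sit at zero the ratio is
#' reported as capped at the number of draws (`"BF > n"`).
#'
#' @param draws Numeric vector of lambda draws (each exactly 0 or in (0, 1]).
#' @return Numeric Bayes factor with attributes `capped` (logical), `n_pos`,
#'   `n_zero`; `format()`/`print()` render the capped case as `"> n"`.
#' @export
bayes_factor <- function(draws) {
  if (length(draws) == 0L) stop("no draws supplied", call. = FALSE)
  n_pos <- sum(draws > 0)
  n_zero <- sum(draws == 0)
  capped <- n_zero == 0L
  bf <- if (capped) as.numeric(length(draws)) else n_pos / n_zero
  structure(bf, class = "pom_bayes_factor", capped = capped,
            n_pos = n_pos, n_zero = n_zero)
}

#' @export
format.pom_bayes_factor <- function(x, ...) {
  if (isTRUE(attr(x, "capped"))) paste0("> ", format(unclass(x)))
  else format(round(unclass(x), 2))
}

#' @export
print.pom_bayes_factor <- function(x, ...) {
  cat("Bayes factor (lambda > 0 vs lambda = 0):", format(x), "\n")
  invisible(x)
}

#' Split-chain Gelman-Rubin potential scale reduction factor
#'
#' Each chain is split in half and the usual R-hat computed over the
#' resulting 2m half-chains. Chains with zero variance everywhere are, by
#' decision rule, perfectly converged (`R-hat = 1`).
#'
#' @param chains A draws x chains matrix, or list of equal-length numeric
#'   vectors (>= 2 chains of >= 10 draws each).
#' @return Scalar R-hat.
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  n <- nrow(chains); m <- ncol(chains)
  stopifnot(m >= 2, n >= 10)
  half <- floor(n / 2)
  splits <- cbind(chains[seq_len(half), , drop = FALSE],
                  chains[(n - half + 1):n, , drop = FALSE])
  W <- mean(apply(splits, 2, stats::var))
  if (W == 0) return(1)
  mu <- colMeans(splits)
  B <- half * stats::var(mu)
  vhat <- (half - 1) / half * W + B / half
  sqrt(vhat / W)
}

#' Posterior summary table
#'
#' One row per scalar parameter: posterior mean, central 95% credible
#' interval (quantiles by linear interpolation), split-chain R-hat, and a
#' support flag that is `TRUE` iff the interval excludes zero (both endpoints
#' share a sign).
#'
#' @param posterior A `"pom_fit"` object.
#' @param params Optional regular expression to filter parameter names.
#' @return A data frame with columns `parameter`, `mean`, `q2.5`, `q97.5`,
#'   `rhat`, `supported`.
#' @export
summarize <- function(posterior, params = NULL) {
  stopifnot(inherits(posterior, "pom_fit"))
  fit <- posterior
  draws <- pooled_param_draws(fit)
  nm <- names(draws)
  if (!is.null(params)) {
    keep <- grepl(params, nm)
    draws <- draws[keep]; nm <- nm[keep]
  }
  out <- data.frame(
    parameter = nm,
    mean = vapply(draws, mean, numeric(1)),
    q2.5 = vapply(draws, function(x) unname(stats::quantile(x, 0.025, type = 7)),
                  numeric(1)),
    q97.5 = vapply(draws, function(x) unname(stats::quantile(x, 0.975, type = 7)),
                   numeric(1)),
    row.names = NULL
  )
  out$rhat <- unname(fit$rhat[match(out$parameter, names(fit$rhat))])
  out$supported <- sign(out$q2.5) == sign(out$q97.5) & out$q2.5 != 0
  out
}

# named list of pooled draws for every scalar parameter (incl. lambda)
pooled_param_draws <- function(fit) {
  pool <- function(fn) unlist(lapply(fit$chains, fn), use.names = FALSE)
  out <- list()
  for (k in fit$species) {
    out[[paste0("alpha[", k, "]")]] <- pool(function(ch) ch$alpha[, k])
  }
  for (j in fit$covariates) {
    for (k in fit$species) {
      out[[paste0("beta[", j, ",", k, "]")]] <-
        pool(function(ch) ch$beta[, k, j])
    }
    out[[paste0("mu[", j, "]")]] <- pool(function(ch) ch$mu[, j])
    out[[paste0("sigma[", j, "]")]] <- pool(function(ch) ch$sigma[, j])
    out[[paste0("lambda[", j, "]")]] <- pool(function(ch) ch$lambda[, j])
    for (g in colnames(fit$chains[[1]]$gamma)) {
      out[[paste0("gamma[", g, ",", j, "]")]] <-
        pool(function(ch) ch$gamma[, g, j])
    }
  }
  out[["mu_alpha"]] <- pool(function(ch) ch$mu_alpha)
  out[["sigma_alpha"]] <- pool(function(ch) ch$sigma_alpha)
  for (m in fit$methods) {
    for (k in fit$species[fit$mask[[m]]]) {
      out[[paste0("p[", m, ",", k, "]")]] <-
        stats::plogis(pool(function(ch) ch$lp[, k, m]))
    }
    out[[paste0("mu_p[", m, "]")]] <- pool(function(ch) ch$mu_p[, m])
    out[[paste0("sigma_p[", m, "]")]] <- pool(function(ch) ch$sigma_p[, m])
  }
  out
}
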