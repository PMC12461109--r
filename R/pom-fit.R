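#' Specification of the community occupancy model and its MCMC settings
#'
#' @param covariates Names of the environmental covariates entering the
#'   occupancy linear predictor (columns of the site-covariate table).
#' @param include_traits Fit the trait-environment layer (model 2)? When
#'   `TRUE`, species slopes get means that are linear in species traits.
#' @param traits Trait names to use (default: all columns of the supplied
#'   trait matrix).
#' @param sd_hyper Prior SD of community hypermeans and trait-effect
#'   coefficients (Normal(0, sd_hyper^2); default 5, weakly informative).
#' @param sd_sigma Scale of the half-normal prior on hierarchical SDs.
#' @param spike Prior mass of the point mass at `lambda = 0` in the
#'   spike-and-slab prior (default 0.5; the slab is Uniform(0, 1)).
#' @param chains,iterations,burnin,thinning MCMC settings. Defaults are
#'   desk-scale (3 x 20,000, burn-in 10,000, thin 10); production-scale runs
#'   (e.g. 3 x 800,000 / 600,000 / 200) are a matter of configuration.
#' @param seed Integer seed controlling all chains.
#' @return Object of class `"pom_spec"`.
#' @export
pom_spec <- function(covariates = c("temperature", "precipitation", "forest_cover"),
                     include_traits = FALSE, traits = NULL,
                     sd_hyper = 5, sd_sigma = 2, spike = 0.5,
                     chains = 3L, iterations = 20000L, burnin = 10000L,
                     thinning = 10L, seed = 1L) {
  stopifnot(spike > 0, spike < 1, burnin < iterations, thinning >= 1,
            chains >= 1, sd_hyper > 0, sd_sigma > 0)
  structure(
    list(covariates = covariates, include_traits = include_traits,
         traits = traits, sd_hyper = sd_hyper, sd_sigma = sd_sigma,
         spike = spike, chains = as.integer(chains),
         iterations = as.integer(iterations), burnin = as.integer(burnin),
         thinning = as.integer(thinning), seed = as.integer(seed)),
    class = "pom_spec"
  )
}

#' Fit the phylogenetic multi-species occupancy model by MCMC
#'
#' Runs a Metropolis-within-Gibbs sampler over the joint posterior of the
#' model: latent occupancy states `Z` (Gibbs, exact), species intercepts and
#' slopes (adaptive random-walk Metropolis; adaptation frozen at the end of
#' burn-in), community hypermeans / trait effects (Gibbs), hierarchical SDs
#' (random walk on the log scale), the spike-and-slab Pagel's lambda per
#' covariate (mixture Metropolis move between the point mass at 0 and a
#' Uniform(0,1) slab, plus a reflected random walk within the slab), a
#' uniformly proposed tree index over the candidate phylogeny set, and
#' species- and method-specific detection probabilities on the logit scale.
#' Sweep order: Z, then occupancy regression parameters, then
#' hyperparameters, then lambda, then tree, then detection.
#'
#' Chains are deterministic given `spec$seed`. Any split-chain R-hat above
#' 1.1 flags the fit as not converged (a warning; the draws are returned
#' either way).
#'
#' @param data A [detection_data()] object.
#' @param covariates A standardized [site_covariates()] object whose sites
#'   match `data$sites`.
#' @param trees A `"phylo"` object or list of candidate trees; each must
#'   contain all species in `data`.
#' @param traits Optional complete [trait_matrix()] (required when
#'   `spec$include_traits` is `TRUE`; impute first if values are missing).
#' @param spec A [pom_spec()].
#' @param prior_only Drop all data likelihood terms so the sampler targets
#'   the joint prior (used for prior-calibration checks).
#' @param control Expert switches: list with any of `update_occ_params`,
#'   `update_det_params`, `update_lambda`, `update_tree` (logicals) and
#'   `init` (named list overriding initial values, e.g. to hold parameters
#'   fixed with all updates disabled).
#' @return Object of class `"pom_fit"`; see [summarize()], [lambda_draws()],
#'   [estimated_richness()].
#' @export
fit_pom <- function(data, covariates, trees, traits = NULL, spec = pom_spec(),
                    prior_only = FALSE, control = list()) {
  validate_detection_data(data)
  stopifnot(inherits(spec, "pom_spec"))
  if (inherits(covariates, "site_covariates")) {
    if (!isTRUE(attr(covariates, "standardized"))) {
      stop("covariates must be standardized (see standardize())", call. = FALSE)
    }
    if (!identical(as.character(covariates$site), data$sites)) {
      stop("site order of covariates must match the detection data", call. = FALSE)
    }
    X <- as.matrix(as.data.frame(covariates)[, spec$covariates, drop = FALSE])
  } else {
    # a bare, already-standardized design matrix (sites x covariates)
    X <- as.matrix(covariates)[, spec$covariates, drop = FALSE]
  }
  if (inherits(trees, "phylo")) trees <- list(trees)
  species <- data$species
  K <- length(species); I <- length(data$sites)
  J <- length(spec$covariates)
  M <- length(data$methods)

  # eigendecomposition of each candidate tree's correlation matrix
  Tn <- length(trees)
  V <- array(0, c(K, K, Tn)); dmat <- matrix(0, K, Tn)
  for (t in seq_len(Tn)) {
    C <- correlation_from_tree(trees[[t]], species = species)
    eg <- eigen(C, symmetric = TRUE)
    V[, , t] <- eg$vectors
    dmat[, t] <- pmax(eg$values, 0)
  }

  # trait design for the model-2 mean layer
  if (spec$include_traits) {
    if (is.null(traits)) stop("spec$include_traits = TRUE requires traits", call. = FALSE)
    tn <- spec$traits %||% traits$traits
    Wt <- traits$values[species, tn, drop = FALSE]
    if (anyNA(Wt)) stop("traits contain missing values; impute first", call. = FALSE)
    for (j in seq_along(tn)) {       # standardize continuous traits only
      if (!traits$binary[match(tn[j], traits$traits)]) {
        x <- Wt[, j]
        Wt[, j] <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
      }
    }
    W <- cbind(`(intercept)` = 1, Wt)
  } else {
    tn <- character(0)
    W <- matrix(1, K, 1, dimnames = list(species, "(intercept)"))
  }

  Ycube <- array(0, c(I, K, M))
  Nmat <- matrix(0, I, M)
  maskm <- matrix(FALSE, K, M)
  for (m in seq_len(M)) {
    Ycube[, , m] <- data$Y[[data$methods[m]]]
    Nmat[, m] <- data$N[[data$methods[m]]]
    maskm[, m] <- data$mask[[data$methods[m]]]
  }

  upd <- function(name, default = TRUE) {
    if (!is.null(control[[name]])) isTRUE(control[[name]]) else default
  }

  set.seed(spec$seed)
  chains <- vector("list", spec$chains)
  for (ch in seq_len(spec$chains)) {
    init <- list(
      alpha = stats::rnorm(K, 0, 1),
      beta = matrix(stats::rnorm(K * J, 0, 0.25), K, J),
      gamma = matrix(0, ncol(W), J),
      sigma = stats::runif(J, 0.5, 1.5),
      mu_alpha = stats::rnorm(1, 0, 1), sigma_alpha = stats::runif(1, 0.5, 1.5),
      lp = matrix(stats::rnorm(K * M, 0, 1), K, M),
      mu_p = stats::rnorm(M, 0, 1), sigma_p = stats::runif(M, 0.5, 1.5),
      lambda = ifelse(stats::runif(J) < spec$spike, 0, stats::runif(J)),
      Z = matrix(stats::rbinom(I * K, 1, 0.5), I, K),
      tree = sample.int(Tn, 1) - 1L
    )
    if (!is.null(control$init)) init[names(control$init)] <- control$init
    raw <- .pom_mcmc_cpp(
      Ycube, Nmat, maskm * 1L, X, V, dmat, W,
      spec$iterations, spec$burnin, spec$thinning,
      prior_only,
      upd("update_occ_params"), upd("update_det_params"),
      upd("update_lambda"), upd("update_tree"),
      spec$sd_hyper, spec$sd_sigma, spec$spike, init)
    chains[[ch]] <- label_chain(raw, species, spec$covariates, tn,
                                data$methods)
  }

  fit <- structure(
    list(chains = chains, species = species, sites = data$sites,
         methods = data$methods, covariates = spec$covariates,
         traits = tn, spec = spec, prior_only = prior_only,
         mask = data$mask, n_trees = Tn),
    class = "pom_fit"
  )
  fit$rhat <- pom_rhat(fit)
  fit$converged <- all(fit$rhat < 1.1, na.rm = TRUE)
  if (!fit$converged) {
    warning("some R-hat values exceed 1.1; treat results as not converged",
            call. = FALSE)
  }
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# attach dimnames to one chain's raw draw arrays
label_chain <- function(raw, species, covs, traits, methods) {
  J <- length(covs)
  colnames(raw$alpha) <- species
  dimnames(raw$beta) <- list(NULL, species, covs)
  dimnames(raw$gamma) <- list(NULL, c("(intercept)", traits), covs)
  colnames(raw$mu) <- covs
  colnames(raw$sigma) <- covs
  colnames(raw$lambda) <- covs
  dimnames(raw$lp) <- list(NULL, species, methods)
  colnames(raw$mu_p) <- methods
  colnames(raw$sigma_p) <- methods
  raw
}

#' Pooled posterior draws of Pagel's lambda for one covariate
#' @param fit A `"pom_fit"`.
#' @param covariate Covariate name (default first).
#' @return Numeric vector of draws, exactly 0 at the spike.
#' @export
lambda_draws <- function(fit, covariate = fit$covariates[1]) {
  stopifnot(inherits(fit, "pom_fit"), covariate %in% fit$covariates)
  unlist(lapply(fit$chains, function(ch) ch$lambda[, covariate]),
         use.names = FALSE)
}

#' Pooled posterior draws of the latent occupancy matrix
#' @param fit A `"pom_fit"`.
#' @return An I x K x S binary array (S = total retained draws, all chains).
#' @export
z_draws <- function(fit) {
  stopifnot(inherits(fit, "pom_fit"))
  arrs <- lapply(fit$chains, function(ch) ch$Z)
  out <- array(0L, c(dim(arrs[[1]])[1:2], sum(vapply(arrs, function(a) dim(a)[3], 0))))
  at <- 0L
  for (a in arrs) {
    s <- dim(a)[3]
    out[, , at + seq_len(s)] <- a
    at <- at + s
  }
  dimnames(out) <- list(fit$sites, fit$species, NULL)
  out
}

#' Number of retained draws per chain times chains
#' @param fit A `"pom_fit"`.
#' @return Integer draw count.
#' @export
n_draws <- function(fit) {
  sum(vapply(fit$chains, function(ch) nrow(ch$alpha), 0L))
}

# split-chain R-hat over all continuous parameters (NA with a single chain)
pom_rhat <- function(fit) {
  ch1 <- fit$chains[[1]]
  single <- length(fit$chains) < 2L
  names_out <- c()
  cols <- list()
  add <- function(nm, fn) {
    cols[[length(cols) + 1]] <<- fn
    names_out <<- c(names_out, nm)
  }
  for (k in fit$species) add(paste0("alpha[", k, "]"),
                             local({ kk <- k; function(ch) ch$alpha[, kk] }))
  for (j in fit$covariates) {
    for (k in fit$species) add(paste0("beta[", j, ",", k, "]"),
                               local({ jj <- j; kk <- k
                                       function(ch) ch$beta[, kk, jj] }))
    add(paste0("mu[", j, "]"), local({ jj <- j; function(ch) ch$mu[, jj] }))
    add(paste0("sigma[", j, "]"), local({ jj <- j; function(ch) ch$sigma[, jj] }))
    for (g in colnames(ch1$gamma)) add(paste0("gamma[", g, ",", j, "]"),
                                       local({ gg <- g; jj <- j
                                               function(ch) ch$gamma[, gg, jj] }))
  }
  add("mu_alpha", function(ch) ch$mu_alpha)
  add("sigma_alpha", function(ch) ch$sigma_alpha)
  for (m in seq_along(fit$methods)) {
    mm <- fit$methods[m]
    for (k in fit$species[fit$mask[[mm]]]) {
      add(paste0("p[", mm, ",", k, "]"),
          local({ kk <- k; mmn <- mm; function(ch) ch$lp[, kk, mmn] }))
    }
    add(paste0("mu_p[", mm, "]"), local({ mmn <- mm; function(ch) ch$mu_p[, mmn] }))
    add(paste0("sigma_p[", mm, "]"), local({ mmn <- mm; function(ch) ch$sigma_p[, mmn] }))
  }
  r <- vapply(cols, function(fn) {
    if (single) return(NA_real_)
    gelman_rubin(vapply(fit$chains, fn, numeric(nrow(ch1$alpha))))
  }, numeric(1))
  stats::setNames(r, names_out)
}

#' @export
print.pom_fit <- function(x, ...) {
  cat(sprintf("Phylogenetic occupancy model fit: %d species, %d sites, %d chains x %d draws\n",
              length(x$species), length(x$sites), length(x$chains),
              nrow(x$chains[[1]]$alpha)))
  mr <- suppressWarnings(max(x$rhat, na.rm = TRUE))
  cat(sprintf("  model %s; %d candidate tree(s); converged: %s (max R-hat %s)\n",
              if (x$spec$include_traits) "2 (with traits)" else "1",
              x$n_trees, x$converged,
              if (is.finite(mr)) sprintf("%.3f", mr) else "NA"))
  for (j in x$covariates) {
    bf <- bayes_factor(lambda_draws(x, j))
    cat(sprintf("  lambda[%s]: mean %.3f, BF %s\n", j,
                mean(lambda_draws(x, j)), format(bf)))
  }
  invisible(x)
}
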