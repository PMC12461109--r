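test_that("fit_pom is deterministic given the seed", {
  w <- tiny_world
  sp <- quick_spec()
  f1 <- suppressWarnings(fit_pom(w$data, w$covariates, w$trees[1:3], spec = sp))
  f2 <- suppressWarnings(fit_pom(w$data, w$covariates, w$trees[1:3], spec = sp))
  expect_identical(f1$chains[[1]]$lambda, f2$chains[[1]]$lambda)
  expect_identical(f1$chains[[2]]$alpha, f2$chains[[2]]$alpha)
  expect_identical(f1$chains[[1]]$Z, f2$chains[[1]]$Z)
})

test_that("detections force occupancy in every retained draw", {
  d <- tiny_world$data
  anyY <- Reduce(`|`, lapply(d$methods, function(m) d$Y[[m]] > 0))
  Z <- z_draws(tiny_fit)
  for (s in seq_len(dim(Z)[3])) {
    expect_true(all(Z[, , s][anyY] == 1L))
  }
})

test_that("all-zero detection histories do not crash and lower occupancy", {
  w <- tiny_world
  d <- w$data
  for (m in d$methods) d$Y[[m]][] <- 0L
  # detection probability held at 0.5 so the zero histories are informative
  # (with vague detection priors, zero detections can also be explained by
  # p -> 0 and occupancy would stay unidentified)
  K <- length(d$species); M <- length(d$methods)
  fit <- suppressWarnings(fit_pom(
    d, w$covariates, w$trees[1:3], spec = quick_spec(),
    control = list(update_det_params = FALSE,
                   init = list(lp = matrix(0, K, M)))))
  expect_lt(mean(z_draws(fit)), 0.25)
})

test_that("known parameters are recovered on a two-species, 1500-site world", {
  set.seed(60)
  n <- 1500
  tr <- parse_newick("(A:1,B:1);")
  X <- matrix(rnorm(n), n, 1, dimnames = list(paste0("s", 1:n), "temperature"))
  X <- scale(X) * sqrt(n / (n - 1))     # population-SD standardization
  beta_true <- matrix(1, 2, 1); alpha_true <- c(0, 0); p_true <- 0.7
  psi <- plogis(sweep(X %*% t(beta_true), 2, alpha_true, "+"))
  Z <- matrix(rbinom(2 * n, 1, psi), n, 2)
  Y <- matrix(rbinom(2 * n, 3L, p_true * Z), n, 2,
              dimnames = list(rownames(X), c("A", "B")))
  d <- detection_data(c("A", "B"), rownames(X),
                      Y = list(mist_net = Y), N = list(mist_net = rep(3L, n)),
                      mask = list(mist_net = c(TRUE, TRUE)))
  sp <- pom_spec(covariates = "temperature", chains = 2, iterations = 6000,
                 burnin = 3000, thinning = 5, seed = 61)
  fit <- suppressWarnings(fit_pom(d, X, tr, spec = sp))
  s <- summarize(fit)
  get <- function(nm) s$mean[s$parameter == nm]
  expect_lt(abs(get("alpha[A]") - 0), 0.2)
  expect_lt(abs(get("alpha[B]") - 0), 0.2)
  expect_lt(abs(get("beta[temperature,A]") - 1), 0.2)
  expect_lt(abs(get("beta[temperature,B]") - 1), 0.2)
  expect_lt(abs(get("p[mist_net,A]") - 0.7), 0.1)
  expect_lt(abs(get("p[mist_net,B]") - 0.7), 0.1)
})

test_that("strong phylogenetic signal (lambda 0.9) earns Bayes factors > 3", {
  # scaled-down version of the lambda-recovery property (6 replicates)
  ok <- logical(6)
  for (r in seq_along(ok)) {
    w <- study_mimic(seed = 9000 + r, n_sites = 100, lambda_temp = 0.9)
    sp <- pom_spec(chains = 2, iterations = 8000, burnin = 4000,
                   thinning = 10, seed = 9100 + r)
    fit <- suppressWarnings(fit_pom(w$data, w$covariates, w$trees[1:20],
                                    spec = sp))
    ok[r] <- as.numeric(bayes_factor(lambda_draws(fit, "temperature"))) > 3
  }
  expect_gte(mean(ok), 0.8)
})

test_that("nominal 95% BCIs for the temperature hypermean are calibrated", {
  # simulation-based calibration, scaled down to 20 unconditioned replicates
  # (the spec-scale experiment uses 50; binomial tolerance adjusted)
  mu_true <- 1.0
  covered <- logical(20)
  for (r in seq_along(covered)) {
    set.seed(8000 + r)
    tr <- simulate_clade_tree()
    C <- correlation_from_tree(tr)
    co <- simulate_coefficients(C, lambdas = c(temperature = 0.6),
                                mu = mu_true, sigma = 1,
                                mu_alpha = -0.5, sigma_alpha = 1)
    X <- matrix(rnorm(40), 40, 1,
                dimnames = list(paste0("s", 1:40), "temperature"))
    X <- scale(X) * sqrt(40 / 39)
    occ <- simulate_occupancy(co$alpha, co$beta, X)
    d <- simulate_detections(
      occ$Z, p = list(mist_net = stats::setNames(rep(0.5, 27), rownames(C))),
      N = list(mist_net = rep(3L, 40)),
      mask = list(mist_net = stats::setNames(rep(TRUE, 27), rownames(C))))
    sp <- pom_spec(covariates = "temperature", chains = 2, iterations = 5000,
                   burnin = 2500, thinning = 5, seed = 8100 + r)
    fit <- suppressWarnings(fit_pom(d, X, tr, spec = sp))
    mu_d <- unlist(lapply(fit$chains, function(ch) ch$mu[, "temperature"]))
    ci <- quantile(mu_d, c(0.025, 0.975))
    covered[r] <- ci[1] <= mu_true && mu_true <= ci[2]
  }
  expect_gte(sum(covered), 16)   # 80% of 20, the binomial band for 95%
})

test_that("tree resampling discriminates between candidate phylogenies", {
  # beta held fixed at a draw from tree A's phylogenetic prior; with only
  # the tree index updating, its posterior follows the prior density ratio
  # and must favour tree A over a very different tree B
  w <- tiny_world
  set.seed(71)
  trA <- simulate_clade_tree(sizes = c(9, 9, 9), stem = 0.8)
  trB <- simulate_tree(27)
  trA$tip.label <- trB$tip.label <- w$data$species
  CA <- correlation_from_tree(trA)
  beta_fix <- vapply(1:3, function(j) {
    drop(phylopom:::rmvn(1, rep(0, 27), 0.95 * CA + 0.05 * diag(27)))
  }, numeric(27))
  sp <- pom_spec(chains = 2, iterations = 4000, burnin = 1000, thinning = 5,
                 seed = 76)
  fit <- suppressWarnings(fit_pom(
    w$data, w$covariates, list(trA, trB), spec = sp, prior_only = TRUE,
    control = list(update_occ_params = FALSE, update_lambda = FALSE,
                   init = list(beta = beta_fix,
                               gamma = matrix(0, 1, 3),
                               sigma = rep(1, 3),
                               lambda = rep(0.95, 3)))))
  tree_draws <- unlist(lapply(fit$chains, function(ch) ch$tree))
  expect_gt(mean(tree_draws == 0), 0.5)

  # with a single candidate tree the index never moves
  f1 <- suppressWarnings(fit_pom(
    w$data, w$covariates, w$trees[[1]],
    spec = pom_spec(chains = 1, iterations = 600, burnin = 100,
                    thinning = 5, seed = 77)))
  expect_true(all(unlist(lapply(f1$chains, function(ch) ch$tree)) == 0))
})
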