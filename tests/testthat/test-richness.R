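test_that("observed richness counts species detected by any method", {
  d <- toy_detections()
  # s1: sp1 (net) and sp2 (net + aru); s2: sp2 (aru) only
  expect_equal(observed_richness(d), c(s1 = 2L, s2 = 1L))
  d$Y$mist_net[] <- 0L; d$Y$aru[] <- 0L
  expect_equal(observed_richness(d), c(s1 = 0L, s2 = 0L))
  # brute-force recount on the study-shaped fixture
  w <- tiny_world
  obs <- observed_richness(w$data)
  for (i in seq_along(w$data$sites)) {
    cnt <- 0L
    for (k in seq_along(w$data$species)) {
      hit <- FALSE
      for (m in w$data$methods) hit <- hit || w$data$Y[[m]][i, k] > 0
      cnt <- cnt + hit
    }
    expect_identical(unname(obs[i]), cnt)
  }
})

# minimal hand-built posterior carrying prescribed Z draws
fake_fit <- function(Zarr, sites, species) {
  structure(list(
    chains = list(list(Z = Zarr, alpha = matrix(0, dim(Zarr)[3], length(species)))),
    sites = sites, species = species),
    class = "pom_fit")
}

test_that("estimated richness summarises per-draw latent sums", {
  sites <- paste0("s", 1:2); species <- paste0("sp", 1:27)
  Z1 <- array(1L, c(2, 27, 40))
  est <- estimated_richness(fake_fit(Z1, sites, species))
  expect_equal(est$mean, c(27, 27))
  expect_equal(est$q2.5, c(27, 27))
  expect_equal(est$q97.5, c(27, 27))

  set.seed(2)
  Zr <- array(rbinom(2 * 20 * 4000, 1, 0.5), c(2, 20, 4000))
  est2 <- estimated_richness(fake_fit(Zr, sites, paste0("x", 1:20)))
  expect_lt(max(abs(est2$mean - 10)), 0.2)
})

test_that("per-draw richness respects the detection floor and subsetting", {
  d <- tiny_world$data
  Z <- z_draws(tiny_fit)
  anyY <- Reduce(`|`, lapply(d$methods, function(m) d$Y[[m]] > 0))
  floor_i <- rowSums(anyY)
  rich <- apply(Z, 3, rowSums)
  expect_true(all(rich >= floor_i))
  est <- estimated_richness(tiny_fit)
  expect_true(all(est$q2.5 <= est$mean & est$mean <= est$q97.5))
  # subset commutation: richness over a species subset is the subset sum
  sub <- c(3, 9, 15)
  expect_equal(apply(Z[, sub, , drop = FALSE], 3, rowSums),
               Reduce(`+`, lapply(sub, function(k) Z[, k, ])))
})

test_that("poisson_glm matches closed forms and the reference fit", {
  # intercept-only: exact log mean
  f <- poisson_glm(c(1, 2, 3), matrix(1, 3, 1))
  expect_lt(abs(f$coefficients[1] - log(2)), 1e-10)
  # against stats::glm on 20 simulated datasets
  set.seed(14)
  for (r in 1:20) {
    n <- 50
    x <- rnorm(n)
    y <- rpois(n, exp(0.5 + 1.0 * x))
    X <- cbind(1, x)
    mine <- poisson_glm(y, X)
    ref <- glm(y ~ x, family = poisson(),
               control = glm.control(epsilon = 1e-12))
    expect_lt(max(abs(mine$coefficients - coef(ref))), 1e-6)
    expect_lt(max(abs(mine$se - summary(ref)$coefficients[, 2])), 1e-6)
    expect_true(mine$converged)
    # deviance non-increasing along the IRLS path
    expect_true(all(diff(mine$deviance_path) <= 1e-8 *
                      (1 + abs(mine$deviance))))
  }
  expect_error(poisson_glm(rep(0, 5), matrix(1, 5, 1)), "all-zero")
  expect_error(poisson_glm(1:4, cbind(1, c(1, 2, 3, 4), c(2, 4, 6, 8))),
               "rank")
})

test_that("richness regressions fit the four standard models", {
  w <- tiny_world
  tab <- data.frame(site = w$data$sites,
                    observed = as.numeric(observed_richness(w$data)),
                    estimated = as.numeric(observed_richness(w$data)) + 1.3)
  fits <- richness_regressions(tab, w$covariates_raw)
  expect_named(fits, c("observed_elevation", "estimated_elevation",
                       "observed_environment", "estimated_environment"))
  expect_length(fits$observed_elevation$coefficients, 3)
  expect_length(fits$observed_environment$coefficients, 4)
  # invariant to site order
  perm <- sample(nrow(tab))
  fits2 <- richness_regressions(tab[perm, ], w$covariates_raw)
  expect_equal(fits2$observed_elevation$coefficients,
               fits$observed_elevation$coefficients, tolerance = 1e-10)
})

test_that("regression calibration: quadratic term, active driver, null", {
  w <- tiny_world
  cov <- standardize(w$covariates_raw)
  ele <- cov$elevation
  # (i) linear truth: quadratic term non-significant in >= 90% of 50 reps
  set.seed(15)
  quad_sig <- replicate(50, {
    y <- rpois(14, exp(2.2 - 0.5 * ele))
    f <- poisson_glm(y, cbind(1, ele, ele^2))
    f$p[3] < 0.05
  })
  expect_lte(mean(quad_sig), 0.10)
  # (ii) temperature-only truth: temperature significant, others not,
  # in >= 80% of 20 replicates
  set.seed(16)
  ok <- replicate(20, {
    y <- rpois(14, exp(2.2 + 0.5 * cov$temperature))
    tab <- data.frame(site = cov$site, observed = y, estimated = y)
    f <- richness_regressions(tab, w$covariates_raw)$observed_environment
    f$p["temperature"] < 0.05 && f$p["precipitation"] > 0.05 &&
      f$p["forest_cover"] > 0.05
  })
  expect_gte(mean(ok), 0.8)
  # (iii) permuted covariates: spurious significance <= 15% per term.
  # Richness is held at a flat Poisson world so the check isolates the
  # GLM's type-I calibration (permuting a covariate-driven world would add
  # overdispersion that is not the regression machinery's fault).
  set.seed(17)
  sig <- replicate(100, {
    y <- rpois(14, exp(2.2))
    shuffled <- as.data.frame(w$covariates_raw)
    shuffled[, -1] <- shuffled[sample(14), -1]
    tab <- data.frame(site = shuffled$site, observed = y, estimated = y)
    f <- richness_regressions(tab, site_covariates(shuffled))$observed_environment
    f$p[-1] < 0.05
  })
  expect_true(all(rowMeans(sig) <= 0.15))
})
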