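single_cell_data <- function(Y, N) {
  detection_data("sp", "s1",
                 Y = list(mist_net = matrix(as.integer(Y), 1, 1,
                                            dimnames = list("s1", "sp"))),
                 N = list(mist_net = N),
                 mask = list(mist_net = TRUE))
}

test_that("occupancy_detection_loglik matches hand-computed terms", {
  X <- matrix(0, 1, 1, dimnames = list("s1", "temperature"))
  d <- single_cell_data(1, 2L)
  st <- list(alpha = 0, beta = matrix(0, 1, 1),
             p = list(mist_net = 0.5), Z = matrix(1, 1, 1))
  # Z = 1, p = 0.5, N = 2, Y = 1: binomial term log(2 * 0.5 * 0.5)
  expect_equal(occupancy_detection_loglik(st, d, X),
               log(0.5) + log(0.5))   # + Bernoulli(psi = 0.5) of Z = 1
  # Z = 0 with Y = 0: detection contributes probability one
  d0 <- single_cell_data(0, 2L)
  st$Z <- matrix(0, 1, 1)
  expect_equal(occupancy_detection_loglik(st, d0, X), log(0.5))
  st$p$mist_net <- 1.5
  expect_error(occupancy_detection_loglik(st, d0, X), "outside")
})

test_that("the joint likelihood factorizes over cells (enumeration identity)", {
  set.seed(4)
  I <- 3; K <- 2
  X <- matrix(rnorm(I), I, 1, dimnames = list(paste0("s", 1:I), "temperature"))
  d <- detection_data(
    c("a", "b"), rownames(X),
    Y = list(mist_net = matrix(c(1L, 0L, 0L, 0L, 2L, 0L), I, K,
                               dimnames = list(rownames(X), c("a", "b")))),
    N = list(mist_net = rep(2L, I)),
    mask = list(mist_net = c(TRUE, TRUE)))
  st <- list(alpha = c(-0.3, 0.4), beta = matrix(c(0.8, -0.5), K, 1),
             p = list(mist_net = c(0.6, 0.3)))
  # marginal likelihood by enumeration over all 2^6 Z configurations
  configs <- as.matrix(expand.grid(rep(list(0:1), I * K)))
  total <- sum(apply(configs, 1, function(z) {
    st$Z <- matrix(z, I, K)
    exp(occupancy_detection_loglik(st, d, X))
  }))
  # direct per-cell marginal: sum_z psi-weighted binomial
  psi <- plogis(sweep(X %*% t(st$beta), 2, st$alpha, "+"))
  cellwise <- 1
  for (i in 1:I) for (k in 1:K) {
    p1 <- psi[i, k] * dbinom(d$Y$mist_net[i, k], 2, st$p$mist_net[k])
    p0 <- (1 - psi[i, k]) * (d$Y$mist_net[i, k] == 0)
    cellwise <- cellwise * (p1 + p0)
  }
  expect_equal(total, unname(cellwise), tolerance = 1e-12)
})

test_that("gibbs_update_Z conditional probabilities follow Bayes rule", {
  I <- 1; K <- 1
  d <- single_cell_data(0, 2L)
  st <- list(psi = matrix(0.5, 1, 1), p = list(mist_net = 0.5))
  set.seed(1)
  out <- gibbs_update_Z(st, d)
  # q = (1 - 0.5)^2 = 0.25; P = 0.5 * 0.25 / (0.5 * 0.25 + 0.5) = 0.2
  expect_equal(out$z_prob[1, 1], 0.2)
  # detection forces occupancy
  d1 <- single_cell_data(1, 2L)
  expect_equal(gibbs_update_Z(st, d1)$z_prob[1, 1], 1)
  # no surveys: conditional equals psi
  d0 <- detection_data("sp", "s1",
                       Y = list(mist_net = matrix(0L, 1, 1),
                                aru = matrix(0L, 1, 1)),
                       N = list(mist_net = 0L, aru = 1L),
                       mask = list(mist_net = TRUE, aru = FALSE))
  expect_equal(gibbs_update_Z(st, d0)$z_prob[1, 1], 0.5)
})

test_that("bayes_factor is the positive-to-zero draw ratio with capping", {
  expect_equal(as.numeric(bayes_factor(c(rep(0.5, 5000), rep(0, 5000)))), 1)
  bf <- bayes_factor(c(runif(9138), rep(0, 862)))
  expect_equal(as.numeric(bf), 9138 / 862)
  expect_equal(format(bf), "10.6")
  capped <- bayes_factor(runif(10000))
  expect_true(attr(capped, "capped"))
  expect_equal(format(capped), "> 10000")
  expect_error(bayes_factor(numeric(0)), "no draws")
})

test_that("gelman_rubin separates converged from shifted chains", {
  set.seed(8)
  same <- cbind(rnorm(5000), rnorm(5000))
  expect_lt(gelman_rubin(same), 1.05)
  shifted <- cbind(rnorm(5000), rnorm(5000) + 5)
  expect_gt(gelman_rubin(shifted), 1.1)
  expect_identical(gelman_rubin(cbind(rep(2, 50), rep(2, 50))), 1)
})

test_that("summarize reports means, BCIs, and support flags", {
  s <- summarize(tiny_fit)
  expect_true(all(c("parameter", "mean", "q2.5", "q97.5", "rhat", "supported")
                  %in% names(s)))
  # draw-count invariant: chains x (iterations - burnin) / thinning
  expect_equal(n_draws(tiny_fit), 2 * (1500 - 500) / 10)
  expect_true(all(s$q2.5 <= s$mean + 1e-12 & s$mean <= s$q97.5 + 1e-12))
  expect_equal(s$supported,
               sign(s$q2.5) == sign(s$q97.5) & s$q2.5 != 0)
  # lambda draws are exactly 0 or in (0, 1]
  ld <- lambda_draws(tiny_fit, "temperature")
  expect_true(all(ld == 0 | (ld > 0 & ld <= 1)))
})
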