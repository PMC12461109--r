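test_that("simulate_tree yields unit-depth ultrametric Yule trees", {
  t2 <- simulate_tree(2, seed = 1)
  expect_equal(sort(t2$edge.length), c(1, 1))
  t27a <- simulate_tree(27, seed = 9)
  t27b <- simulate_tree(27, seed = 9)
  expect_identical(ape::write.tree(t27a), ape::write.tree(t27b))
  expect_lt(abs(max(ape::node.depth.edgelength(t27a)) - 1), 1e-12)

  # property sweep: correlation matrices always PSD, mean off-diagonal in (0,1)
  set.seed(2)
  offd <- replicate(500, {
    C <- correlation_from_tree(simulate_tree(10))
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
    mean(C[upper.tri(C)])
  })
  expect_true(all(offd > 0 & offd < 1))
})

test_that("simulate_tree_set perturbs branch lengths but stays ultrametric", {
  base <- simulate_clade_tree(seed = 3)
  trees <- simulate_tree_set(base, n_trees = 20, seed = 4)
  expect_length(trees, 20)
  for (tr in trees[1:5]) {
    d <- ape::node.depth.edgelength(tr)[seq_len(ape::Ntip(tr))]
    expect_lt(max(d) - min(d), 1e-8)
    expect_true(all(tr$edge.length >= 0))
    expect_identical(tr$tip.label, base$tip.label)
  }
  # branch lengths actually vary between trees
  expect_gt(sd(vapply(trees, function(tr) tr$edge.length[1], numeric(1))), 0)
})

test_that("simulate_traits has the requested covariance structure", {
  tr <- parse_newick("((A:0.1,B:0.1):0.9,C:1);")   # corr(A,B) = 0.9
  # lambda = 1: empirical sister correlation approx 0.9
  set.seed(5)
  ab <- replicate(1000, {
    v <- simulate_traits(tr, lambda = 1, sigma2 = 1)$values[, 1]
    v[c("A", "B")]
  })
  expect_lt(abs(cor(ab[1, ], ab[2, ]) - 0.9), 0.05)
  # lambda = 0: independence
  set.seed(6)
  ab0 <- replicate(1000, simulate_traits(tr, lambda = 0, sigma2 = 1)$values[1:2, 1])
  expect_lt(abs(cor(ab0[1, ], ab0[2, ])), 0.07)
  # sigma2 = 0 collapses onto the root mean
  v <- simulate_traits(tr, lambda = 1, sigma2 = 0, mu = 2.5, seed = 1)$values
  expect_true(all(v == 2.5))
})

test_that("simulate_coefficients honours hyperparameters and traits", {
  C <- correlation_from_tree(parse_newick("((A:0.2,B:0.2):0.8,(C:0.5,D:0.5):0.5);"))
  co <- simulate_coefficients(C, lambdas = c(x = 0.5), mu = 2, sigma = 0,
                              seed = 1)
  expect_true(all(co$beta[, 1] == 2))
  # lambda = 1: empirical correlation matrix approximates C
  set.seed(2)
  B <- replicate(1000, simulate_coefficients(C, lambdas = c(x = 1), mu = 0,
                                             sigma = 1)$beta[, 1])
  expect_lt(max(abs(cor(t(B)) - C)), 0.06)
  # trait effect gamma recovered by regression
  set.seed(3)
  tm <- trait_matrix(matrix(rnorm(4), 4, 1,
                            dimnames = list(rownames(C), "mass")))
  tm$values[, 1] <- (tm$values[, 1] - mean(tm$values[, 1])) /
    sd(tm$values[, 1])
  gamma <- matrix(c(0, 0.5), 2, 1)
  sim <- replicate(1000, simulate_coefficients(
    C, lambdas = c(x = 0), mu = NULL, sigma = 0.5,
    traits = tm, gamma = gamma)$beta[, 1])
  slope <- coef(lm(as.vector(sim) ~ rep(tm$values[, 1], 1000)))[2]
  expect_lt(abs(slope - 0.5), 0.05)
  expect_error(simulate_coefficients(C, c(x = 0), mu = 0, sigma = 1,
                                     traits = tm), "together")
})

test_that("simulate_occupancy follows the logit-linear model", {
  X <- matrix(seq(-2, 2, length.out = 9), 9, 1,
              dimnames = list(paste0("s", 1:9), "temperature"))
  occ <- simulate_occupancy(alpha = 0, beta = matrix(0, 1, 1), X, seed = 1)
  expect_true(all(occ$psi == 0.5))
  occ2 <- simulate_occupancy(alpha = 0, beta = matrix(2, 1, 1), X, seed = 1)
  expect_true(all(diff(occ2$psi[, 1]) > 0))   # monotone in temperature
  # Z frequencies match psi
  set.seed(2)
  Zbar <- matrix(0, 9, 1)
  for (r in 1:10000) {
    Zbar <- Zbar + simulate_occupancy(0.3, matrix(1, 1, 1), X)$Z
  }
  expect_lt(max(abs(Zbar / 10000 - plogis(0.3 + X))), 0.02)
})

test_that("simulate_detections respects Z, p, N and masks", {
  Z <- matrix(c(1, 0), 2, 2, dimnames = list(c("s1", "s2"), c("a", "b")))
  p <- list(mist_net = c(a = 1, b = 1), aru = c(a = 0.5, b = 0.5))
  N <- list(mist_net = c(3L, 3L), aru = c(2L, 2L))
  mask <- list(mist_net = c(a = TRUE, b = TRUE), aru = c(a = TRUE, b = FALSE))
  d <- simulate_detections(Z, p, N, mask, seed = 1)
  expect_equal(unname(d$Y$mist_net["s1", ]), c(3L, 3L))  # Z=1, p=1, N=3
  expect_equal(unname(d$Y$mist_net["s2", ]), c(0L, 0L))  # Z=0
  expect_true(all(d$Y$aru[, "b"] == 0))                  # masked out
  # binomial mean
  set.seed(2)
  ys <- replicate(10000, simulate_detections(
    Z, list(mist_net = c(a = 0.5, b = 0.5)), list(mist_net = c(3L, 3L)),
    list(mist_net = c(a = TRUE, b = TRUE)))$Y$mist_net["s1", "a"])
  expect_lt(abs(mean(ys) - 1.5), 0.05)
})

test_that("study_mimic reproduces the survey design facts", {
  w <- tiny_world
  d <- w$data
  expect_silent(validate_detection_data(d))
  expect_length(d$species, 27)
  expect_length(d$sites, 14)
  expect_equal(sum(d$N$mist_net), 32)            # 32 nights, mean 2.29
  expect_true(all(d$N$mist_net %in% 1:3))
  expect_equal(sum(d$mask$mist_net), 22)
  expect_equal(sum(d$mask$aru), 10)
  expect_equal(sum(d$mask$mist_net & d$mask$aru), 5)
  # exactly the congeneric pair responds negatively to temperature
  bt <- w$truth$beta[, "temperature"]
  expect_equal(sum(bt < 0), 2)
  expect_setequal(names(bt)[bt < 0], w$truth$negative_pair)
  C <- correlation_from_tree(w$trees[[1]])
  expect_gt(C[w$truth$negative_pair[1], w$truth$negative_pair[2]], 0.5)
  # temperature ~ elevation confounding as designed
  r <- cor(as.data.frame(w$covariates_raw)[, -1])
  expect_lt(r["temperature", "elevation"], -0.97)
  expect_equal(w$truth$lambdas[["temperature"]], 0.6)
})

test_that("study_mimic is deterministic and serialization is byte-identical", {
  w1 <- study_mimic(seed = 33)
  w2 <- study_mimic(seed = 33)
  expect_identical(w1$data$Y, w2$data$Y)
  expect_identical(w1$truth$beta, w2$truth$beta)
  f1 <- tempfile(); f2 <- tempfile()
  write_truth(w1$truth, f1)
  write_truth(w2$truth, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_truth(f1)
  expect_equal(back$beta, w1$truth$beta, tolerance = 1e-12)
  expect_equal(back$Z, w1$truth$Z)
})

test_that("seeded calls equal seed-then-call composition", {
  set.seed(101)
  a <- simulate_tree(12)
  b <- simulate_traits(a, 0.5, 1)
  set.seed(101)
  a2 <- simulate_tree(12)
  b2 <- simulate_traits(a2, 0.5, 1)
  expect_identical(ape::write.tree(a), ape::write.tree(a2))
  expect_identical(b$values, b2$values)
  expect_identical(simulate_tree(8, seed = 5)$edge.length,
                   {set.seed(5); simulate_tree(8)$edge.length})
})
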