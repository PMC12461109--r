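# Shared fixtures, built in code. Everything deterministic under fixed seeds.

# a small synthetic world reused across files (14 sites, 27 species)
tiny_world <- study_mimic(seed = 7)

# quick MCMC settings for structural tests (not for inference quality)
quick_spec <- function(...) {
  pom_spec(chains = 2L, iterations = 1500L, burnin = 500L, thinning = 10L,
           seed = 42L, ...)
}

tiny_fit <- suppressWarnings(
  fit_pom(tiny_world$data, tiny_world$covariates, tiny_world$trees[1:5],
          spec = quick_spec())
)

# hand-built two-species, two-method toy dataset
toy_detections <- function() {
  species <- c("sp1", "sp2")
  sites <- c("s1", "s2")
  Y <- list(
    mist_net = matrix(c(2L, 0L, 1L, 0L), 2, 2,
                      dimnames = list(sites, species)),
    aru = matrix(c(0L, 0L, 3L, 1L), 2, 2, dimnames = list(sites, species))
  )
  N <- list(mist_net = c(3L, 2L), aru = c(3L, 3L))
  mask <- list(mist_net = c(TRUE, TRUE), aru = c(FALSE, TRUE))
  detection_data(species, sites, Y, N, mask)
}

# site covariates with prescribed columns
toy_covariates <- function(n = 10, seed = 1) {
  set.seed(seed)
  site_covariates(data.frame(
    site = paste0("s", seq_len(n)),
    elevation = seq(400, 1700, length.out = n),
    temperature = seq(16, 8, length.out = n) + rnorm(n, 0, 0.2),
    precipitation = 2000 + rnorm(n, 0, 100),
    forest_cover = runif(n, 50, 100)
  ))
}

# brute-force shared-path correlation for an ultrametric tree
bruteforce_corr <- function(tree) {
  n <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  total <- max(depth[seq_len(n)])
  mrcas <- ape::mrca(tree)
  C <- matrix(1, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      C[i, j] <- C[j, i] <- depth[mrcas[i, j]] / total
    }
  }
  C
}

# independent brute-force grid oracle for Pagel's lambda (coarse 101-point
# grid, then a 1e-4 fine grid around the best coarse point)
grid_lambda_oracle <- function(y, C) {
  eg <- eigen(C, symmetric = TRUE)
  u <- drop(crossprod(eg$vectors, y))
  v <- drop(crossprod(eg$vectors, rep(1, length(y))))
  f <- function(l) phylopom:::pagel_profile_loglik(l, eg$values, u, v, length(y))
  coarse <- seq(0, 1, by = 0.01)
  ll <- vapply(coarse, f, numeric(1))
  best <- coarse[which.max(ll)]
  fine <- seq(max(0, best - 0.01), min(1, best + 0.01), by = 1e-4)
  llf <- vapply(fine, f, numeric(1))
  fine[which.max(llf)]
}
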