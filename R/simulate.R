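# split n species into three family-like clades proportional to 12:10:5
clade_split <- function(n) {
  base <- c(12L, 10L, 5L)
  if (n == 27L) return(base)
  sz <- pmax(1L, round(base / 27 * n))
  sz[1] <- sz[1] + (n - sum(sz))
  sz
}

#' Internal: seed the RNG if a seed is supplied
#'
#' All generators in this package draw from R's global RNG stream. Passing a
#' seed makes a call self-contained and reproducible; passing `NULL` makes it
#' consume the current stream, so that a pipeline seeded once at the top
#' produces exactly the same draws as its composed parts.
#' @keywords internal
maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# One multivariate-normal draw (or n draws as rows) via Cholesky; tolerates a
# PSD covariance by eigenvalue clipping when the Cholesky fails.
rmvn <- function(n, mean, Sigma) {
  K <- length(mean)
  if (all(Sigma == 0)) return(matrix(rep(mean, each = n), n, K))
  L <- tryCatch(chol(Sigma), error = function(e) {
    eg <- eigen(Sigma, symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    chol(eg$vectors %*% diag(ev, K) %*% t(eg$vectors) + 1e-12 * diag(K))
  })
  Z <- matrix(stats::rnorm(n * K), n, K)
  sweep(Z %*% L, 2, mean, "+")
}

#' Simulate a Yule (pure-birth) tree, rescaled to unit depth
#'
#' Stand-in for posterior samples of an empirical dated phylogeny: only the
#' induced correlation structure matters downstream, so an ultrametric
#' pure-birth tree rescaled to depth 1 is sufficient.
#'
#' @param n_tips Number of tips (>= 2). Tips are labelled `t1..tn`.
#' @param seed Optional integer seed (`NULL` = use current RNG stream).
#' @return An ultrametric `"phylo"` object with root-to-tip depth 1.
#' @export
simulate_tree <- function(n_tips, seed = NULL) {
  stopifnot(n_tips >= 2)
  maybe_seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$edge.length <- tree$edge.length / max(tip_depths(tree))
  tree
}

#' Pseudo-posterior tree set by node-height perturbation
#'
#' Emulates a posterior sample of trees from a single base tree: each internal
#' node height is scaled by an independent lognormal factor (sd `sd_log` on
#' the log scale, i.e. roughly +/-10% by default) and clamped so the tree
#' stays ultrametric with positive branch lengths; trees are re-normalised to
#' unit depth. Topology is shared, branch lengths vary.
#'
#' @param base_tree Ultrametric `"phylo"` tree.
#' @param n_trees Number of trees to generate.
#' @param sd_log SD of the log-scale height perturbation.
#' @param seed Optional seed.
#' @return List of `"phylo"` objects of length `n_trees`.
#' @export
simulate_tree_set <- function(base_tree, n_trees = 100L, sd_log = 0.1,
                              seed = NULL) {
  stopifnot(inherits(base_tree, "phylo"), n_trees >= 1)
  maybe_seed(seed)
  ntip <- ape::Ntip(base_tree)
  depth_all <- ape::node.depth.edgelength(base_tree)
  D <- max(depth_all[seq_len(ntip)])
  lapply(seq_len(n_trees), function(i) {
    h <- depth_all
    # preorder over internal nodes (root first) keeps parent < child
    ord <- order(depth_all[(ntip + 1):length(depth_all)]) + ntip
    for (nd in ord) {
      if (nd == ntip + 1L) next        # root stays at height 0
      parent <- base_tree$edge[base_tree$edge[, 2] == nd, 1]
      hmin <- h[parent]
      hmax <- D * (1 - 1e-3)           # keep tip branches > 0.1% of depth
      h[nd] <- min(max(depth_all[nd] * exp(stats::rnorm(1, 0, sd_log)), hmin), hmax)
    }
    h[seq_len(ntip)] <- D              # tips pinned: ultrametric
    tr <- base_tree
    tr$edge.length <- (h[tr$edge[, 2]] - h[tr$edge[, 1]]) / D
    tr
  })
}

#' Simulate phylogenetically correlated traits
#'
#' Draws each trait from `MVN(mu, sigma2 * lambda_transform(C, lambda))`
#' across species: `lambda = 1` is plain Brownian motion on the tree,
#' `lambda = 0` is i.i.d. variation.
#'
#' @param tree A `"phylo"` tree (ultrametric).
#' @param lambda Phylogenetic signal in `[0, 1]`.
#' @param sigma2 Brownian rate (variance over unit depth); `0` collapses all
#'   species onto the root mean.
#' @param seed Optional seed.
#' @param n_traits Number of independent traits to draw.
#' @param mu Root mean (recycled over traits).
#' @param names Trait names.
#' @return A [trait_matrix()] with `n_traits` columns.
#' @export
simulate_traits <- function(tree, lambda, sigma2, seed = NULL, n_traits = 1L,
                            mu = 0, names = paste0("trait", seq_len(n_traits))) {
  maybe_seed(seed)
  C <- correlation_from_tree(tree)
  K <- nrow(C)
  mu <- rep_len(mu, n_traits)
  vals <- vapply(seq_len(n_traits), function(j) {
    drop(rmvn(1, rep(mu[j], K), sigma2 * lambda_transform(C, lambda)))
  }, numeric(K))
  vals <- matrix(vals, K, n_traits, dimnames = list(rownames(C), names))
  trait_matrix(vals, binary = rep(FALSE, n_traits))
}

#' Simulate species-level occupancy coefficients
#'
#' Species slopes for covariate `j` are drawn from
#' `MVN(mean_j, sigma_j^2 * lambda_transform(C, lambda_j))` where `mean_j` is
#' either a common community mean `mu[j]` (model 1) or a linear function
#' `gamma[1, j] + sum_t gamma[t + 1, j] * trait_t` of species traits
#' (model 2). Intercepts are independent `N(mu_alpha, sigma_alpha^2)`.
#'
#' @param C Phylogenetic correlation matrix (species order defines output order).
#' @param lambdas Numeric vector, one lambda per covariate.
#' @param mu,sigma Community hypermeans and SDs per covariate (model 1; `mu`
#'   ignored when `gamma` is given).
#' @param traits Optional [trait_matrix()] (complete, no missing values).
#' @param gamma Optional `(P + 1) x J` matrix of trait effects (first row =
#'   intercept); must be supplied together with `traits`.
#' @param mu_alpha,sigma_alpha Intercept hyperparameters.
#' @param seed Optional seed.
#' @return List with `alpha` (length K) and `beta` (K x J matrix).
#' @export
simulate_coefficients <- function(C, lambdas, mu, sigma, traits = NULL,
                                  gamma = NULL, mu_alpha = 0, sigma_alpha = 1,
                                  seed = NULL) {
  if (is.null(traits) != is.null(gamma)) {
    stop("traits and gamma must be supplied together", call. = FALSE)
  }
  J <- length(lambdas)
  stopifnot(length(sigma) == J)
  K <- nrow(C)
  maybe_seed(seed)
  means <- if (is.null(gamma)) {
    stopifnot(length(mu) == J)
    matrix(rep(mu, each = K), K, J)
  } else {
    stopifnot(nrow(gamma) == ncol(traits$values) + 1L, ncol(gamma) == J)
    W <- cbind(1, traits$values[rownames(C), , drop = FALSE])
    W %*% gamma
  }
  beta <- vapply(seq_len(J), function(j) {
    drop(rmvn(1, means[, j], sigma[j]^2 * lambda_transform(C, lambdas[j])))
  }, numeric(K))
  beta <- matrix(beta, K, J, dimnames = list(rownames(C), names(lambdas)))
  alpha <- stats::rnorm(K, mu_alpha, sigma_alpha)
  names(alpha) <- rownames(C)
  list(alpha = alpha, beta = beta)
}

#' Simulate latent occupancy states
#'
#' `psi = plogis(alpha_k + x_i' beta_k)` and `Z ~ Bernoulli(psi)`.
#'
#' @param alpha Species intercepts (length K).
#' @param beta K x J species slopes.
#' @param covariates Either a standardized [site_covariates()] object (the
#'   model covariates temperature, precipitation, forest cover are used) or a
#'   bare I x J design matrix.
#' @param seed Optional seed.
#' @return List with `psi` and `Z`, both I x K matrices.
#' @export
simulate_occupancy <- function(alpha, beta, covariates, seed = NULL) {
  X <- model_covariate_matrix(covariates, ncol(beta))
  maybe_seed(seed)
  linpred <- sweep(X %*% t(beta), 2, alpha, "+")
  psi <- stats::plogis(linpred)
  Z <- matrix(stats::rbinom(length(psi), 1L, psi), nrow(psi), ncol(psi),
              dimnames = dimnames(psi))
  list(psi = psi, Z = Z)
}

model_covariate_matrix <- function(covariates, J) {
  if (inherits(covariates, "site_covariates")) {
    if (!isTRUE(attr(covariates, "standardized"))) {
      stop("covariates must be standardized (see standardize())", call. = FALSE)
    }
    X <- as.matrix(as.data.frame(covariates)[, c("temperature", "precipitation",
                                                 "forest_cover")])
    rownames(X) <- covariates$site
  } else {
    X <- as.matrix(covariates)
  }
  if (ncol(X) != J) stop("covariate matrix has ", ncol(X),
                         " columns; expected ", J, call. = FALSE)
  X
}

#' Simulate season-level detection histories
#'
#' `Y[m][i, k] ~ Binomial(N[m][i], p[m][k] * Z[i, k])` for masked-in species;
#' zero for masked-out ones.
#'
#' @param Z I x K occupancy matrix (0/1) with site/species dimnames.
#' @param p Named list per method of per-species detection probabilities.
#' @param N Named list per method of per-site season counts.
#' @param mask Named list per method of logical per-species inclusion flags.
#' @param seed Optional seed.
#' @return A [detection_data()] object.
#' @export
simulate_detections <- function(Z, p, N, mask, seed = NULL) {
  maybe_seed(seed)
  methods <- names(p)
  stopifnot(identical(names(N), methods), identical(names(mask), methods))
  I <- nrow(Z); K <- ncol(Z)
  sites <- rownames(Z); species <- colnames(Z)
  Y <- stats::setNames(vector("list", length(methods)), methods)
  for (m in methods) {
    stopifnot(all(p[[m]] >= 0 & p[[m]] <= 1))
    prob <- outer(rep(1, I), p[[m]] * mask[[m]]) * Z
    size <- matrix(N[[m]], I, K)
    Y[[m]] <- matrix(stats::rbinom(I * K, as.vector(size), as.vector(prob)),
                     I, K, dimnames = list(sites, species))
  }
  detection_data(species, sites, Y, N, mask)
}

#' Simulate a family-structured ultrametric tree
#'
#' Builds a tree with the depth profile of an empirical multi-family
#' assemblage: `length(sizes)` clades ("families") whose stems attach at the
#' root and span `stem` of the unit depth, each crowned by a coalescent
#' radiation (which, unlike a pure-birth tree, retains internal structure at
#' intermediate depths). Used as the base tree of [study_mimic()]: the deep,
#' nested structure is what makes Pagel's lambda statistically identifiable
#' from a single 27-species community.
#'
#' @param sizes Integer vector of clade sizes.
#' @param stem Fraction of total depth taken by the clade stems, in (0, 1).
#' @param seed Optional seed.
#' @return An ultrametric `"phylo"` tree of depth 1 with tips `t01, t02, ...`.
#' @export
simulate_clade_tree <- function(sizes = c(12L, 10L, 5L), stem = 0.45,
                                seed = NULL) {
  stopifnot(all(sizes >= 1), stem > 0, stem < 1)
  maybe_seed(seed)
  subs <- vapply(sizes, function(n) {
    if (n == 1L) return(paste0("x:", 1 - stem))
    tr <- ape::rcoal(n)
    tr$edge.length <- tr$edge.length * (1 - stem) /
      max(tip_depths(tr))
    sub(";$", "", ape::write.tree(tr))
  }, character(1))
  txt <- paste0("(", paste0(subs, ":", stem, collapse = ","), ");")
  tree <- ape::read.tree(text = txt)
  tree$tip.label <- sprintf("t%02d", seq_along(tree$tip.label))
  clamp_tip_divergence(tree)
}

# Enforce a minimum evolutionary divergence between any two tips: internal
# node heights are capped at (1 - min_frac) of the depth, so no pair of
# distinct species is perfectly correlated and the correlation matrix stays
# numerically invertible (coalescent trees can otherwise produce splits
# arbitrarily close to the present).
clamp_tip_divergence <- function(tree, min_frac = 0.01) {
  ntip <- ape::Ntip(tree)
  h <- ape::node.depth.edgelength(tree)
  D <- max(h[seq_len(ntip)])
  cap <- D * (1 - min_frac)
  internal <- (ntip + 1L):length(h)
  h[internal] <- pmin(h[internal], cap)
  h[seq_len(ntip)] <- D
  tree$edge.length <- h[tree$edge[, 2]] - h[tree$edge[, 1]]
  tree
}

#' Simulate a community mimicking a two-method bat survey design
#'
#' One call builds a full synthetic world with the shape of a 27-species,
#' 14-site, <= 3-season, two-method survey along a steep elevational gradient:
#' a pseudo-posterior set of 27-tip trees; covariates with temperature almost
#' perfectly (negatively) collinear with elevation (r ~ -0.99) and much
#' weaker elevation correlations for precipitation and forest cover; species
#' temperature responses phylogenetically correlated with `lambda_temp`
#' (default 0.6), strongly positive for all species except one closely
#' related pair of cold-specialists with negative responses; no precipitation
#' or forest-cover signal; 17 mist-net-only, 5 both-method and 5
#' acoustic-only species; and uneven site x method season coverage (mist-net
#' seasons 1-3 averaging 32/14 ~ 2.29 per site; recorder seasons 2-3).
#' Four traits (body mass, trophic level, aspect ratio, roost type) are
#' simulated with strong, strong, moderate and no phylogenetic signal and a
#' few missing entries to exercise imputation; by default traits do not drive
#' the occupancy coefficients (`gamma = 0`).
#'
#' @param seed Integer seed (required: the generator is a stated world, and
#'   every dataset is a pure function of its seed).
#' @param n_sites Number of sites (default 14; use more for parameter-recovery
#'   experiments).
#' @param lambda_temp Phylogenetic signal of the temperature response.
#' @param n_trees Size of the pseudo-posterior tree set.
#' @param n_species Number of species.
#' @return List with `data` ([detection_data()]), `covariates` (standardized
#'   [site_covariates()]), `covariates_raw`, `trees`, `traits`
#'   ([trait_matrix()] with some `NA`s), and `truth` (all generating
#'   parameters incl. `psi`, `Z`, `p`, and the seed).
#' @export
study_mimic <- function(seed, n_sites = 14L, lambda_temp = 0.6,
                        n_trees = 100L, n_species = 27L) {
  stopifnot(!is.null(seed))
  set.seed(as.integer(seed))

  sizes <- clade_split(n_species)
  base_tree <- simulate_clade_tree(sizes)
  trees <- simulate_tree_set(base_tree, n_trees = n_trees)
  C <- correlation_from_tree(base_tree)
  species <- rownames(C)

  # --- covariates along the elevational gradient -------------------------
  elev <- seq(450, 1710, length.out = n_sites)
  zele <- (elev - mean(elev)) / sqrt(mean((elev - mean(elev))^2))
  temp <- 16 - 9 * (elev - 450) / 1260 + stats::rnorm(n_sites, 0, 0.3)
  prec <- 2100 - 30 * zele + stats::rnorm(n_sites, 0, 165)
  forest <- pmin(100, pmax(50, 76.6 - 8 * zele + stats::rnorm(n_sites, 0, 9.6)))
  cov_raw <- site_covariates(data.frame(
    site = sprintf("site%02d", seq_len(n_sites)),
    elevation = elev, temperature = temp,
    precipitation = prec, forest_cover = forest))
  cov_std <- standardize(cov_raw)

  # --- traits ------------------------------------------------------------
  trait_lambda <- c(body_mass = 0.99, trophic_level = 1.0,
                    aspect_ratio = 0.92, roost_type = 0.0)
  tvals <- vapply(names(trait_lambda), function(nm) {
    drop(rmvn(1, rep(0, n_species),
              lambda_transform(C, trait_lambda[[nm]])))
  }, numeric(n_species))
  tvals <- matrix(tvals, n_species, 4,
                  dimnames = list(species, names(trait_lambda)))
  for (nm in c("trophic_level", "roost_type")) {
    tvals[, nm] <- as.numeric(tvals[, nm] >= stats::median(tvals[, nm]))
  }
  traits_complete <- trait_matrix(
    tvals, binary = c(FALSE, TRUE, FALSE, TRUE))
  # knock out a few entries as in a typical literature-compiled trait table
  traits_obs <- tvals
  traits_obs[sample.int(n_species, 4), "aspect_ratio"] <- NA
  traits_obs[sample.int(n_species, 2), "roost_type"] <- NA
  traits <- trait_matrix(traits_obs, binary = c(FALSE, TRUE, FALSE, TRUE))

  # --- species coefficients ----------------------------------------------
  # Temperature responses are one draw from the common-mean phylogenetic
  # model, conditioned on the qualitative pattern of the emulated study:
  # (i) the two cold specialists are the most closely related pair inside
  # the second ("vespertilionid-like") clade and are the only species with
  # negative responses -- their negativity is a shared deep deviation, not a
  # separate mean component; (ii) that clade's mean response sits at least
  # half a hyper-SD below the rest of the community, the family-dominance
  # pattern of highland assemblages. Conditioning is by rejection, so the
  # truth remains a draw from the stated model given those events.
  cl2 <- seq(sizes[1] + 1L, sizes[1] + sizes[2])
  Csub <- C[cl2, cl2]; diag(Csub) <- 0
  pr <- which(Csub == max(Csub), arr.ind = TRUE)[1, ]
  pair <- cl2[sort(c(pr[[1]], pr[[2]]))]
  lambdas <- c(temperature = lambda_temp, precipitation = 0, forest_cover = 0)
  sigma_beta <- c(1.0, 0.5, 0.5)
  mu_temp <- 1.5
  clade_gap <- 0.5
  Sig_temp <- sigma_beta[1]^2 * lambda_transform(C, lambdas[1])
  beta_temp <- NULL
  for (batch in seq_len(40L)) {
    cand <- rmvn(500, rep(mu_temp, n_species), Sig_temp)
    hit <- which(apply(cand, 1, function(b) {
      all(b[pair] < 0) && all(b[-pair] > 0) &&
        mean(b[cl2]) < mean(b[-cl2]) - clade_gap
    }))
    if (length(hit) > 0L) { beta_temp <- cand[hit[1], ]; break }
  }
  if (is.null(beta_temp)) {
    # fallback for pathological trees: take the draw with the fewest sign
    # violations and reflect the offending components about the origin
    target <- rep(1, n_species); target[pair] <- -1
    miss <- apply(cand, 1, function(b) sum(sign(b) != target))
    beta_temp <- cand[which.min(miss), ]
    beta_temp <- abs(beta_temp) * target
  }
  beta <- cbind(
    temperature = beta_temp,
    precipitation = drop(rmvn(1, rep(0, n_species),
                              sigma_beta[2]^2 * lambda_transform(C, lambdas[2]))),
    forest_cover = drop(rmvn(1, rep(0, n_species),
                             sigma_beta[3]^2 * lambda_transform(C, lambdas[3]))))
  rownames(beta) <- species
  mu_alpha <- -0.5; sigma_alpha <- 1
  alpha <- stats::rnorm(n_species, mu_alpha, sigma_alpha)
  names(alpha) <- species

  occ <- simulate_occupancy(alpha, beta, cov_std)

  # --- detection design ---------------------------------------------------
  # method composition: the cold pair is detected by both methods
  both <- c(species[pair], sample(setdiff(species, species[pair]), 3))
  aru_only <- sample(setdiff(species, both), 5)
  mask <- list(
    mist_net = stats::setNames(!(species %in% aru_only), species),
    aru = stats::setNames(species %in% c(both, aru_only), species))
  if (n_sites == 14L) {
    N_mist <- as.integer(c(3, 3, 3, 3, 2, 2, 2, 2, 2, 2, 2, 2, 3, 1)) # sum 32
    N_aru <- as.integer(c(3, 3, 3, 3, 3, 2, 2, 2, 3, 3, 2, 2, 3, 3))  # sum 37
  } else {
    N_mist <- sample(1:3, n_sites, replace = TRUE, prob = c(0.1, 0.5, 0.4))
    N_aru <- sample(2:3, n_sites, replace = TRUE, prob = c(0.36, 0.64))
  }
  N <- list(mist_net = N_mist, aru = N_aru)
  p <- list(
    mist_net = stats::setNames(stats::plogis(stats::rnorm(n_species, -0.4, 0.7)),
                               species),
    aru = stats::setNames(stats::plogis(stats::rnorm(n_species, 0.6, 0.7)),
                          species))
  p$mist_net[!mask$mist_net] <- 0
  p$aru[!mask$aru] <- 0

  data <- simulate_detections(occ$Z, p, N, mask)

  truth <- list(
    seed = as.integer(seed), n_species = n_species, n_sites = n_sites,
    species = species, lambdas = lambdas, trait_lambda = trait_lambda,
    mu = c(temperature = mu_temp, precipitation = 0, forest_cover = 0),
    sigma = stats::setNames(sigma_beta, names(lambdas)),
    mu_alpha = mu_alpha, sigma_alpha = sigma_alpha,
    gamma = matrix(0, 5, 3,
                   dimnames = list(c("(intercept)", names(trait_lambda)),
                                   names(lambdas))),
    negative_pair = species[pair],
    alpha = alpha, beta = beta, psi = occ$psi, Z = occ$Z, p = p,
    mask = mask, N = N)

  list(data = data, covariates = cov_std, covariates_raw = cov_raw,
       trees = trees, traits = traits, traits_complete = traits_complete,
       truth = truth)
}

#' Serialize / restore a simulation truth object as JSON
#'
#' @param truth The `truth` component of [study_mimic()].
#' @param path JSON file path.
#' @return `write_truth()` the path invisibly; `read_truth()` the truth list.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth_to_json(truth), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

truth_to_json <- function(truth) {
  mat2l <- function(m) {
    list(dim = dim(m), dimnames = dimnames(m), values = as.vector(m))
  }
  out <- truth
  for (f in c("gamma", "beta", "psi", "Z")) out[[f]] <- mat2l(truth[[f]])
  out
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  l2mat <- function(l) {
    m <- matrix(as.numeric(l$values), l$dim[1], l$dim[2])
    dimnames(m) <- l$dimnames
    m
  }
  for (f in c("gamma", "beta", "psi", "Z")) raw[[f]] <- l2mat(raw[[f]])
  raw
}
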