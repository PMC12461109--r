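#' Construct a species trait matrix
#'
#' Container for species-level ecological traits (e.g. body mass, trophic
#' level, aspect ratio, roost type). Binary traits are coded 0/1 and, like
#' continuous ones, may contain `NA` for missing values. Binary status is
#' auto-detected (all non-missing values in {0, 1}) unless given explicitly.
#'
#' @param values Numeric matrix, species in rows (rownames required), traits
#'   in columns (colnames required); `NA` marks missing entries.
#' @param binary Optional logical vector per trait.
#' @return Object of class `"trait_matrix"` with fields `species`, `traits`,
#'   `values`, `missing` (logical mask) and `binary`.
#' @export
trait_matrix <- function(values, binary = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have species rownames and trait colnames", call. = FALSE)
  }
  if (is.null(binary)) {
    binary <- apply(values, 2, function(x) {
      x <- x[!is.na(x)]
      length(x) > 0 && all(x %in% c(0, 1))
    })
  }
  stopifnot(length(binary) == ncol(values))
  miss <- is.na(values)
  if (any(colSums(!miss) == 0L)) {
    stop("trait entirely missing: ",
         paste(colnames(values)[colSums(!miss) == 0L], collapse = ", "),
         call. = FALSE)
  }
  for (j in which(binary)) {
    obs <- values[!miss[, j], j]
    if (!all(obs %in% c(0, 1))) {
      stop("binary trait ", colnames(values)[j], " has values outside {0,1}",
           call. = FALSE)
    }
  }
  structure(
    list(species = rownames(values), traits = colnames(values),
         values = values, missing = miss, binary = as.logical(binary)),
    class = "trait_matrix"
  )
}

#' Read traits from CSV (`species,<trait1>,<trait2>,...`; empty cell = missing)
#' @param path CSV file path.
#' @return A [trait_matrix()].
#' @export
read_traits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "species") stop("first column must be 'species'", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$species
  trait_matrix(m)
}

#' Write traits to CSV (missing entries as empty cells)
#' @param traits A [trait_matrix()].
#' @param path Output file path.
#' @export
write_traits <- function(traits, path) {
  stopifnot(inherits(traits, "trait_matrix"))
  df <- data.frame(species = traits$species, traits$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Phylogenetic imputation of missing trait values
#'
#' Missing entries are replaced by their conditional expectations under a
#' multivariate Brownian-motion model: writing the K x P trait matrix as a
#' single vector, its covariance is the Kronecker product `R %x% C` of an
#' across-trait covariance `R` with the phylogenetic correlation `C`, and its
#' mean is one ancestral (root) value per trait. `R` and the root means are
#' estimated from the observed entries by iterated conditional expectation:
#' impute, re-estimate by phylogenetic GLS on the completed matrix, repeat
#' until the largest parameter/imputation change falls below `tol`. Observed
#' entries are never modified. Binary traits are imputed on the continuous
#' scale; `values_thresholded` additionally reports them cut at 0.5.
#'
#' @param traits A [trait_matrix()]; each trait must be observed for at least
#'   3 species and missing for fewer than 50% of species.
#' @param C Phylogenetic correlation matrix covering all species in `traits`.
#' @param max_iter,tol Iteration control (error if not converged).
#' @return A `"trait_matrix"` with completed `values`, plus components
#'   `values_thresholded`, `mu` (root means), `R` (across-trait covariance)
#'   and `iterations`.
#' @export
impute_traits <- function(traits, C, max_iter = 500L, tol = 1e-8) {
  stopifnot(inherits(traits, "trait_matrix"))
  validate_phylo_corr(C)
  sp <- traits$species
  missing_sp <- setdiff(sp, rownames(C))
  if (length(missing_sp) > 0L) {
    stop("species absent from correlation matrix: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  }
  C <- C[sp, sp, drop = FALSE]
  X <- traits$values
  miss <- traits$missing
  K <- nrow(X); P <- ncol(X)

  n_obs <- colSums(!miss)
  if (any(n_obs < 3L)) {
    stop("each trait must be observed for >= 3 species", call. = FALSE)
  }
  if (any(colMeans(miss) >= 0.5)) {
    stop("missing fraction per trait must be < 50%", call. = FALSE)
  }

  out <- traits
  if (!any(miss)) {                    # nothing to do: identity, idempotent
    out$values_thresholded <- threshold_binary(X, traits$binary)
    out$mu <- gls_root_means(X, C)
    out$R <- gls_trait_cov(X, out$mu, C)
    out$iterations <- 0L
    return(out)
  }

  Cinv <- solve(C)
  # initialise missing cells at each trait's observed phylogenetic GLS mean
  for (j in seq_len(P)) {
    o <- !miss[, j]
    Coo_inv <- solve(C[o, o, drop = FALSE])
    one <- rep(1, sum(o))
    mu_j <- sum(Coo_inv %*% X[o, j]) / sum(Coo_inv %*% one)
    X[miss[, j], j] <- mu_j
  }

  midx <- which(as.vector(miss))       # indices into vec(X), column-major
  oidx <- which(!as.vector(miss))
  delta <- Inf
  iter <- 0L
  mu <- rep(NA_real_, P); R <- diag(P)
  while (iter < max_iter) {
    iter <- iter + 1L
    mu_new <- gls_root_means(X, C, Cinv = Cinv)
    R_new <- gls_trait_cov(X, mu_new, C, Cinv = Cinv)
    Sigma <- kronecker(R_new, C)       # block (t,s) = R[t,s] * C
    mean_vec <- rep(mu_new, each = K)
    x <- as.vector(X)
    cond <- mean_vec[midx] +
      Sigma[midx, oidx, drop = FALSE] %*%
      solve(Sigma[oidx, oidx, drop = FALSE], x[oidx] - mean_vec[oidx])
    X_new <- X
    X_new[midx] <- as.vector(cond)
    delta <- max(abs(c(mu_new - mu, R_new - R, X_new[midx] - X[midx])),
                 na.rm = TRUE)
    mu <- mu_new; R <- R_new; X <- X_new
    if (is.finite(delta) && delta < tol) break
  }
  if (!(is.finite(delta) && delta < tol)) {
    stop(sprintf("imputation did not converge after %d iterations (last delta %.3g)",
                 max_iter, delta), call. = FALSE)
  }
  names(mu) <- colnames(X)
  dimnames(R) <- list(colnames(X), colnames(X))
  out$values <- X
  out$values_thresholded <- threshold_binary(X, traits$binary)
  out$mu <- mu
  out$R <- R
  out$iterations <- iter
  out
}

# Phylogenetic GLS root mean per trait: (1' C^-1 x) / (1' C^-1 1).
gls_root_means <- function(X, C, Cinv = solve(C)) {
  w <- rowSums(Cinv)                   # C^-1 1
  drop(crossprod(X, w)) / sum(w)
}

# Across-trait covariance under Brownian motion, ML divisor K.
gls_trait_cov <- function(X, mu, C, Cinv = solve(C)) {
  D <- sweep(X, 2, mu)
  crossprod(D, Cinv %*% D) / nrow(X)
}

threshold_binary <- function(X, binary) {
  out <- X
  for (j in which(binary)) out[, j] <- as.numeric(X[, j] >= 0.5)
  out
}
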