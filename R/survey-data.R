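#' Methods recognised by the detection-data model
#' @keywords internal
POM_METHODS <- c("mist_net", "aru")

#' Construct a multi-method detection dataset
#'
#' Season-level detection histories for a community surveyed by up to two
#' methods (mist nets and autonomous recording units). For method `m`,
#' `Y[[m]][i, k]` is the number of sampling seasons in which species `k` was
#' detected at site `i` and `N[[m]][i]` the number of seasons surveyed there
#' by that method; `mask[[m]][k]` says whether species `k` enters method `m`'s
#' likelihood at all (e.g. species never scored acoustically are masked out of
#' the ARU likelihood).
#'
#' @param species,sites Character vectors of labels.
#' @param Y Named list (per method) of integer site x species matrices.
#' @param N Named list (per method) of integer per-site season counts.
#' @param mask Named list (per method) of logical per-species vectors.
#' @return Object of class `"detection_data"`.
#' @export
detection_data <- function(species, sites, Y, N, mask) {
  methods <- names(Y)
  stopifnot(!is.null(methods), identical(names(N), methods),
            identical(names(mask), methods))
  unknown <- setdiff(methods, POM_METHODS)
  if (length(unknown) > 0L) {
    stop("unknown method: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  obj <- structure(
    list(species = as.character(species), sites = as.character(sites),
         methods = methods,
         Y = lapply(Y, function(m) {
           m <- as.matrix(m); storage.mode(m) <- "integer"; m
         }),
         N = lapply(N, function(n) stats::setNames(as.integer(n),
                                                   as.character(sites))),
         mask = lapply(mask, function(m) stats::setNames(as.logical(m),
                                                         as.character(species)))),
    class = "detection_data"
  )
  validate_detection_data(obj)
  obj
}

#' Validate a detection dataset's invariants
#' @param x A `"detection_data"` object.
#' @return `x` invisibly, or an error describing the violated invariant.
#' @export
validate_detection_data <- function(x) {
  stopifnot(inherits(x, "detection_data"))
  I <- length(x$sites); K <- length(x$species)
  for (m in x$methods) {
    Y <- x$Y[[m]]; N <- x$N[[m]]; msk <- x$mask[[m]]
    if (!all(dim(Y) == c(I, K))) stop("Y[", m, "] has wrong shape", call. = FALSE)
    if (length(N) != I) stop("N[", m, "] has wrong length", call. = FALSE)
    if (length(msk) != K) stop("mask[", m, "] has wrong length", call. = FALSE)
    if (any(is.na(Y)) || any(Y < 0)) stop("Y[", m, "] must be non-negative", call. = FALSE)
    if (any(is.na(N)) || any(N < 0)) stop("N[", m, "] must be non-negative", call. = FALSE)
    over <- which(Y > matrix(N, I, K), arr.ind = TRUE)
    if (nrow(over) > 0L) {
      stop(sprintf("detections exceed surveyed seasons (method %s, site %s, species %s)",
                   m, x$sites[over[1, 1]], x$species[over[1, 2]]), call. = FALSE)
    }
    if (any(Y[, !msk, drop = FALSE] > 0)) {
      stop("nonzero detections for species masked out of method ", m, call. = FALSE)
    }
  }
  Ns <- do.call(cbind, x$N)
  if (any(rowSums(Ns) == 0L)) {
    stop("every site needs at least one surveyed season by some method", call. = FALSE)
  }
  invisible(x)
}

#' Load detection histories from long-format CSV
#'
#' Expects columns `species,site,method,seasons_surveyed,seasons_detected`.
#' A species is masked into a method's likelihood iff any row for that
#' species/method pair exists. `seasons_surveyed` must agree across species
#' within a site/method.
#'
#' @param path CSV file path.
#' @return A [detection_data()] object.
#' @export
load_detections <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "site", "method", "seasons_surveyed", "seasons_detected")
  if (!all(need %in% names(df))) {
    stop("detections CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(df$method), POM_METHODS)
  if (length(unknown) > 0L) {
    stop("unknown method: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad <- df$seasons_detected > df$seasons_surveyed
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("row %d: seasons_detected (%d) > seasons_surveyed (%d)",
                 i, df$seasons_detected[i], df$seasons_surveyed[i]),
         call. = FALSE)
  }
  species <- sort(unique(df$species))
  sites <- sort(unique(df$site))
  methods <- intersect(POM_METHODS, unique(df$method))
  I <- length(sites); K <- length(species)
  Y <- N <- mask <- stats::setNames(vector("list", length(methods)), methods)
  for (m in methods) {
    sub <- df[df$method == m, , drop = FALSE]
    Ym <- matrix(0L, I, K, dimnames = list(sites, species))
    Nm <- stats::setNames(integer(I), sites)
    for (s in unique(sub$site)) {
      ns <- unique(sub$seasons_surveyed[sub$site == s])
      if (length(ns) > 1L) {
        stop(sprintf("inconsistent seasons_surveyed at site %s, method %s",
                     s, m), call. = FALSE)
      }
      Nm[s] <- as.integer(ns)
    }
    Ym[cbind(match(sub$site, sites), match(sub$species, species))] <-
      as.integer(sub$seasons_detected)
    Y[[m]] <- Ym
    N[[m]] <- Nm
    mask[[m]] <- stats::setNames(species %in% sub$species, species)
  }
  detection_data(species, sites, Y, N, mask)
}

#' Write detection histories to long-format CSV
#'
#' Emits one row per masked-in species x site x method, the exact inverse of
#' [load_detections()].
#'
#' @param data A [detection_data()] object.
#' @param path Output CSV path.
#' @export
write_detections <- function(data, path) {
  validate_detection_data(data)
  rows <- list()
  for (m in data$methods) {
    keep_sp <- data$species[data$mask[[m]]]
    keep_site <- data$sites[data$N[[m]] > 0L]
    if (length(keep_sp) == 0L || length(keep_site) == 0L) next
    g <- expand.grid(species = keep_sp, site = keep_site,
                     stringsAsFactors = FALSE)
    g$method <- m
    g$seasons_surveyed <- data$N[[m]][match(g$site, data$sites)]
    g$seasons_detected <- data$Y[[m]][cbind(match(g$site, data$sites),
                                            match(g$species, data$species))]
    rows[[m]] <- g
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$method, out$site, out$species), ]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Construct site covariates
#'
#' @param df Data frame with columns `site`, `elevation` (m a.s.l.),
#'   `temperature` (degrees C), `precipitation` (mm/yr), `forest_cover`
#'   (proportion or %).
#' @return Object of class `"site_covariates"` (a data frame with
#'   standardization bookkeeping attributes).
#' @export
site_covariates <- function(df) {
  need <- c("site", "elevation", "temperature", "precipitation", "forest_cover")
  if (!all(need %in% names(df))) {
    stop("covariates need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  df <- df[, need]
  structure(df, class = c("site_covariates", "data.frame"),
            standardized = FALSE, center = NULL, scale = NULL)
}

#' Read site covariates from CSV
#' @param path CSV path with header `site,elevation,temperature,precipitation,forest_cover`.
#' @return A [site_covariates()] object.
#' @export
read_covariates <- function(path) {
  site_covariates(utils::read.csv(path, stringsAsFactors = FALSE))
}

covariate_vars <- function() c("elevation", "temperature", "precipitation", "forest_cover")

#' Standardize site covariates to mean 0, SD 1
#'
#' Z-scores each covariate using the population SD (divisor `n`) of the
#' supplied sites, the convention used throughout this package so that
#' standardization is a deterministic function of the site set. Originals are
#' retained in attributes for back-transformation.
#'
#' @param cov A [site_covariates()] object.
#' @return The standardized object; `attr(, "standardized")` is `TRUE` and
#'   `attr(, "center")`/`attr(, "scale")` hold the original moments.
#' @export
standardize <- function(cov) {
  stopifnot(inherits(cov, "site_covariates"))
  if (isTRUE(attr(cov, "standardized"))) return(cov)
  vars <- covariate_vars()
  n <- nrow(cov)
  ctr <- scl <- stats::setNames(numeric(length(vars)), vars)
  for (v in vars) {
    x <- cov[[v]]
    if (length(unique(x)) < 2L) stop("constant covariate: ", v, call. = FALSE)
    ctr[v] <- mean(x)
    scl[v] <- sqrt(mean((x - mean(x))^2))   # population SD
    cov[[v]] <- (x - ctr[v]) / scl[v]
  }
  attr(cov, "standardized") <- TRUE
  attr(cov, "center") <- ctr
  attr(cov, "scale") <- scl
  cov
}

#' Pairwise correlations and variance inflation factors
#'
#' Collinearity screen: pairwise Pearson r among the requested covariates and,
#' for each, the VIF `1 / (1 - R^2)` from an OLS regression on the remaining
#' ones. Perfect collinearity is reported as `Inf`, not an error.
#'
#' @param cov A [site_covariates()] object (standardized or not; VIFs are
#'   invariant to affine rescaling).
#' @param vars Covariate names to screen (default: temperature, precipitation,
#'   forest cover).
#' @return List with `r` (correlation matrix) and `vif` (named vector).
#' @export
collinearity_screen <- function(cov,
                                vars = c("temperature", "precipitation", "forest_cover")) {
  stopifnot(inherits(cov, "site_covariates"))
  bad <- setdiff(vars, names(cov))
  if (length(bad) > 0L) stop("unknown covariates: ", paste(bad, collapse = ", "),
                             call. = FALSE)
  if (nrow(cov) < 3L) stop("need at least 3 sites", call. = FALSE)
  X <- as.matrix(as.data.frame(cov)[, vars, drop = FALSE])
  r <- stats::cor(X)
  vif <- stats::setNames(rep(1, length(vars)), vars)
  if (length(vars) > 1L) {
    for (v in vars) {
      others <- setdiff(vars, v)
      fit <- stats::lm.fit(cbind(1, X[, others, drop = FALSE]), X[, v])
      rss <- sum(fit$residuals^2)
      tss <- sum((X[, v] - mean(X[, v]))^2)
      r2 <- 1 - rss / tss
      vif[v] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }
  }
  list(r = r, vif = vif)
}

#' Mist-net sampling effort
#'
#' Total effort is per-night effort times the number of survey nights; the
#' per-night effort of a net array is net area times number of nets times
#' hours open (m^2 h).
#'
#' @param per_night_effort Effort of one survey night (m^2 h).
#' @param nights Number of survey nights.
#' @return Total effort in m^2 h.
#' @export
mistnet_effort <- function(per_night_effort, nights) {
  stopifnot(per_night_effort >= 0, nights >= 0)
  per_night_effort * nights
}

#' @rdname mistnet_effort
#' @param net_area Area of one net (m^2).
#' @param n_nets Number of nets operated.
#' @param hours Hours the nets were open.
#' @export
mistnet_night_effort <- function(net_area, n_nets, hours) {
  stopifnot(net_area >= 0, n_nets >= 0, hours >= 0)
  net_area * n_nets * hours
}

#' Acoustic-recorder sampling effort
#'
#' Recording effort in recorder-hours given units deployed, site-nights, audio
#' files triggered per night, and file duration; `aru_files()` gives the file
#' count.
#'
#' @param n_units Number of recording units per site-night.
#' @param nights Number of site-nights.
#' @param files_per_night Audio files recorded per unit per night.
#' @param file_seconds Duration of one file (s, at most 60).
#' @return Effort in recorder-hours.
#' @export
aru_effort <- function(n_units, nights, files_per_night, file_seconds) {
  stopifnot(n_units >= 0, nights >= 0, files_per_night >= 0,
            file_seconds >= 0, file_seconds <= 60)
  n_units * nights * files_per_night * file_seconds / 3600
}

#' @rdname aru_effort
#' @export
aru_files <- function(n_units, nights, files_per_night) {
  stopifnot(n_units >= 0, nights >= 0, files_per_night >= 0)
  n_units * nights * files_per_night
}
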