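#' Build a pipeline configuration
#'
#' @param mode `"simulate"` (emit a synthetic dataset), `"fit"` (analyse
#'   existing input files) or `"full"` (simulate then analyse).
#' @param outdir Output directory (created if needed).
#' @param seed Global seed; per-stage child seeds are derived from it
#'   deterministically so stages can be rerun in isolation.
#' @param spec A [pom_spec()] holding model and MCMC settings.
#' @param detections,covariates,trees,traits Input file paths (required in
#'   `"fit"` mode; filled in by the simulate stage otherwise).
#' @param n_sites,lambda_temp,n_trees Passed to [study_mimic()] when
#'   simulating.
#' @return A list of class `"pom_config"`.
#' @export
pipeline_config <- function(mode = c("full", "simulate", "fit"),
                            outdir = "pom_output", seed = 1L,
                            spec = pom_spec(seed = seed),
                            detections = NULL, covariates = NULL,
                            trees = NULL, traits = NULL,
                            n_sites = 14L, lambda_temp = 0.6, n_trees = 100L) {
  mode <- match.arg(mode)
  structure(
    list(mode = mode, outdir = outdir, seed = as.integer(seed), spec = spec,
         paths = list(detections = detections, covariates = covariates,
                      trees = trees, traits = traits),
         n_sites = n_sites, lambda_temp = lambda_temp, n_trees = n_trees),
    class = "pom_config"
  )
}

# stage seeds: one deterministic fan-out from the global seed
stage_seeds <- function(seed, n = 8L) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Cross-check the input files of a pipeline configuration
#'
#' Report-only validation: species-set agreement between detections, trees
#' and traits; method-mask summaries; missing-trait counts (with the
#' imputation plan); covariate collinearity screen. Never throws; problems
#' are listed in `issues` with a severity.
#'
#' @param config A [pipeline_config()] whose input paths exist.
#' @return List with `issues` (data frame `severity`/`message`), `masks`,
#'   `missing_traits`, `collinearity`.
#' @export
validate_inputs <- function(config) {
  data <- load_detections(config$paths$detections)
  cov <- read_covariates(config$paths$covariates)
  trees <- read_tree_set(config$paths$trees)
  traits <- if (!is.null(config$paths$traits)) read_traits(config$paths$traits)
  issues <- data.frame(severity = character(0), message = character(0))
  note <- function(sev, msg) {
    issues <<- rbind(issues, data.frame(severity = sev, message = msg))
  }
  for (t in seq_along(trees)) {
    miss <- setdiff(data$species, trees[[t]]$tip.label)
    if (length(miss) > 0L) {
      note("fatal", sprintf("tree %d is missing species: %s", t,
                            paste(miss, collapse = ", ")))
    }
  }
  if (!setequal(data$sites, cov$site)) {
    note("fatal", "site sets of detections and covariates differ")
  }
  if (!is.null(traits)) {
    miss_sp <- setdiff(data$species, traits$species)
    if (length(miss_sp) > 0L) {
      note("fatal", sprintf("traits missing species: %s",
                            paste(miss_sp, collapse = ", ")))
    }
    nmiss <- colSums(traits$missing)
    for (j in which(nmiss > 0)) {
      note("info", sprintf(
        "trait %s has %d missing value(s); will be phylogenetically imputed",
        traits$traits[j], nmiss[j]))
    }
  }
  masks <- lapply(data$mask, sum)
  scr <- tryCatch(collinearity_screen(cov), error = function(e) NULL)
  list(issues = issues, masks = masks,
       missing_traits = if (!is.null(traits)) colSums(traits$missing),
       collinearity = scr)
}

#' Run the full analysis pipeline
#'
#' Simulate (optional), validate, screen covariates, impute traits, estimate
#' per-trait phylogenetic signal, fit the occupancy model without (model 1)
#' and with (model 2) trait-environment interactions, compute per-covariate
#' Bayes factors, derive observed and detectability-corrected richness, and
#' fit the four richness regressions. Results are written to
#' `config$outdir` as CSV/JSON; reruns with the same config and seed are
#' bit-identical apart from the timing block.
#'
#' @param config A [pipeline_config()].
#' @return The report list, invisibly (also written to `report.json`).
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "pom_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  failed_marker <- file.path(config$outdir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  seeds <- stage_seeds(config$seed)
  timing <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)), failed_marker)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timing[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out
  }

  paths <- config$paths
  if (config$mode %in% c("simulate", "full")) {
    sim <- stage("simulate", {
      world <- study_mimic(seeds[1], n_sites = config$n_sites,
                           lambda_temp = config$lambda_temp,
                           n_trees = config$n_trees)
      paths$detections <- file.path(config$outdir, "detections.csv")
      paths$covariates <- file.path(config$outdir, "covariates.csv")
      paths$trees <- file.path(config$outdir, "trees.nwk")
      paths$traits <- file.path(config$outdir, "traits.csv")
      write_detections(world$data, paths$detections)
      utils::write.csv(as.data.frame(world$covariates_raw),
                       paths$covariates, row.names = FALSE)
      write_tree_set(world$trees, paths$trees)
      write_traits(world$traits, paths$traits)
      write_truth(world$truth, file.path(config$outdir, "truth.json"))
      world
    })
    if (config$mode == "simulate") {
      report <- list(mode = "simulate", seed = config$seed,
                     files = paths, timing = timing)
      jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      return(invisible(report))
    }
  }
  config$paths <- paths

  validation <- stage("validate", validate_inputs(config))
  if (any(validation$issues$severity == "fatal")) {
    writeLines(validation$issues$message, failed_marker)
    stop("pipeline stage 'validate' failed: fatal input mismatches",
         call. = FALSE)
  }

  data <- stage("load", load_detections(paths$detections))
  cov_df <- as.data.frame(read_covariates(paths$covariates))
  cov_df <- cov_df[match(data$sites, cov_df$site), ]
  cov <- standardize(site_covariates(cov_df))
  trees <- read_tree_set(paths$trees)
  traits <- read_traits(paths$traits)

  screen <- stage("collinearity", collinearity_screen(cov))

  C0 <- correlation_from_tree(trees[[1]], species = traits$species)
  # generous iteration cap: strongly correlated sister pairs contract slowly
  traits_full <- stage("impute", impute_traits(traits, C0, max_iter = 5000L))

  trait_signal <- stage("trait_lambda", {
    lapply(stats::setNames(traits$traits, traits$traits), function(nm) {
      f <- fit_pagel_lambda_trees(traits_full$values[, nm], trees,
                                  species = traits$species)
      list(lambda_mean = f$lambda_mean, lambda = f$lambda)
    })
  })

  spec1 <- config$spec; spec1$include_traits <- FALSE; spec1$seed <- seeds[2]
  spec2 <- config$spec; spec2$include_traits <- TRUE; spec2$seed <- seeds[3]
  # binary traits enter the interaction layer thresholded back to 0/1;
  # continuous traits keep their raw imputed values
  vals <- traits_full$values
  vals[, traits_full$binary] <-
    traits_full$values_thresholded[, traits_full$binary]
  ord_traits <- trait_matrix(vals[data$species, , drop = FALSE],
                             binary = traits_full$binary)
  fit1 <- stage("fit_model1",
                fit_pom(data, cov, trees, spec = spec1))
  fit2 <- stage("fit_model2",
                fit_pom(data, cov, trees, traits = ord_traits, spec = spec2))

  bf <- function(fit) {
    lapply(stats::setNames(fit$covariates, fit$covariates), function(j) {
      b <- bayes_factor(lambda_draws(fit, j))
      list(bf = as.numeric(b), capped = attr(b, "capped"),
           label = format(b), lambda_mean = mean(lambda_draws(fit, j)),
           lambda_q2.5 = unname(stats::quantile(lambda_draws(fit, j), 0.025)),
           lambda_q97.5 = unname(stats::quantile(lambda_draws(fit, j), 0.975)))
    })
  }

  rich <- stage("richness", richness_table(data, fit1))
  glms <- stage("regressions", richness_regressions(rich, cov))

  glm_table <- function(g) {
    data.frame(term = names(g$coefficients), estimate = g$coefficients,
               z = g$z, p = g$p, row.names = NULL)
  }
  report <- list(
    mode = config$mode, seed = config$seed,
    validation_issues = validation$issues,
    collinearity = list(r = screen$r, vif = as.list(screen$vif)),
    trait_lambda = trait_signal,
    model1 = list(lambda = bf(fit1),
                  summary = summarize(fit1, "^(mu|sigma|lambda)\\["),
                  converged = fit1$converged, max_rhat = max(fit1$rhat)),
    model2 = list(lambda = bf(fit2),
                  trait_interactions = summarize(fit2, "^gamma\\["),
                  converged = fit2$converged, max_rhat = max(fit2$rhat)),
    richness = rich,
    glm = lapply(glms, glm_table),
    timing = timing
  )
  utils::write.csv(rich, file.path(config$outdir, "richness.csv"),
                   row.names = FALSE)
  utils::write.csv(summarize(fit1), file.path(config$outdir, "model1_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(summarize(fit2, "^gamma\\["),
                   file.path(config$outdir, "model2_trait_interactions.csv"),
                   row.names = FALSE)
  for (nm in names(glms)) {
    utils::write.csv(glm_table(glms[[nm]]),
                     file.path(config$outdir, paste0("glm_", nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Command-line entry point
#'
#' Thin verb dispatcher for scripted use:
#' `Rscript -e 'phylopom::pom_cli()' simulate --outdir out --seed 1`.
#' Verbs: `simulate`, `validate`, `fit`, `richness`, `report`, `full`.
#' Flags: `--config <json>`, `--seed <int>`, `--model {1,2}`,
#' `--chains <int>`, `--iters <int>`, `--outdir <dir>`.
#'
#' @param args Character vector of arguments (default: the command line).
#' @return The verb's result, invisibly.
#' @export
pom_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    stop("usage: pom_cli <simulate|validate|fit|richness|report|full> [--flags]",
         call. = FALSE)
  }
  verb <- args[1]
  flags <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    flags[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  cfg <- if (!is.null(flags$config)) {
    raw <- jsonlite::read_json(flags$config, simplifyVector = TRUE)
    do.call(pipeline_config, raw)
  } else {
    pipeline_config()
  }
  if (!is.null(flags$seed)) {
    cfg$seed <- as.integer(flags$seed)
    cfg$spec$seed <- cfg$seed
  }
  if (!is.null(flags$outdir)) cfg$outdir <- flags$outdir
  if (!is.null(flags$chains)) cfg$spec$chains <- as.integer(flags$chains)
  if (!is.null(flags$iters)) {
    cfg$spec$iterations <- as.integer(flags$iters)
    cfg$spec$burnin <- as.integer(flags$iters) %/% 2L
  }
  cfg$mode <- switch(verb,
                     simulate = "simulate",
                     fit = , richness = , report = "fit",
                     full = "full",
                     validate = "fit",
                     stop("unknown verb: ", verb, call. = FALSE))
  if (verb == "validate") {
    out <- validate_inputs(cfg)
    print(out$issues)
    return(invisible(out))
  }
  invisible(run_full(cfg))
}
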