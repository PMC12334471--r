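# End-to-end fitting driver chaining the pipeline stages.

#' Fit a DELT occurrence model end to end
#'
#' Chains the pipeline stages: study-window filtering, anomaly crosswalk
#' harmonization (when per-anomaly records are supplied), naive prevalence
#' summaries, Spearman collinearity screening and standardization of the
#' landscape predictors (conditional variants), model specification,
#' posterior sampling, and the convergence check. Fails loudly on a
#' failing convergence verdict unless `allow_unconverged = TRUE`.
#'
#' @param observations Per-fish observation data frame; `delt` may be
#'   unresolved if `anomalies` and `crosswalk` are given.
#' @param predictor_table Stream-by-predictor table (conditional
#'   variants).
#' @param variant `"unconditional"`, `"conditional"` or
#'   `"species_specific"`.
#' @param species Species label to subset to (required for
#'   `species_specific`); the species must satisfy the focal-species rule
#'   (naive prevalence >= `focal_min_prevalence` and sample size >
#'   `focal_min_n`).
#' @param anomalies,crosswalk Optional per-anomaly flags (aligned with
#'   `observations`) and agency crosswalk, applied to rows with
#'   unresolved `delt`.
#' @param window Optional `c(start_year, end_year)` study window.
#' @param screen_threshold Spearman threshold for [drop_collinear()];
#'   default 0.90.
#' @param screen_priority Optional predictor visiting order for the
#'   screen.
#' @param standardize Standardization rows, see [assemble_model_data()].
#' @param hyper [model_hyper()] prior settings.
#' @param config [sampler_config()] sampler settings.
#' @param focal_min_prevalence,focal_min_n Focal-species rule thresholds.
#' @param allow_unconverged Keep going on a failing convergence verdict
#'   (default `TRUE`: the verdict flags, the caller decides).
#' @return A `delt_pipeline_fit` list: `fit` (the `delt_draws`),
#'   `convergence`, `screen` (drop report or NULL), `prevalence` (overall
#'   and per species), `spec`, and `dropped_rows` bookkeeping.
#' @export
fit_delt_model <- function(observations, predictor_table = NULL,
                           variant = c("unconditional", "conditional",
                                       "species_specific"),
                           species = NULL, anomalies = NULL,
                           crosswalk = NULL, window = NULL,
                           screen_threshold = 0.90, screen_priority = NULL,
                           standardize = "observations",
                           hyper = model_hyper(),
                           config = sampler_config(),
                           focal_min_prevalence = 0.05, focal_min_n = 100,
                           allow_unconverged = TRUE) {
  variant <- match.arg(variant)
  dropped <- list()

  if (!is.null(window)) {
    n_before <- nrow(observations)
    keep <- observations$year >= window[1L] & observations$year <= window[2L]
    if (!is.null(anomalies)) anomalies <- anomalies[keep, , drop = FALSE]
    observations <- filter_observation_window(observations, window[1L],
                                              window[2L])
    dropped$window <- n_before - nrow(observations)
  }

  if (anyNA(observations$delt)) {
    if (is.null(anomalies) || is.null(crosswalk)) {
      stop("observations carry unresolved delt flags and no anomaly ",
           "records/crosswalk were supplied", call. = FALSE)
    }
    unresolved <- is.na(observations$delt)
    observations$delt[unresolved] <- crosswalk_anomalies(
      anomalies[unresolved, , drop = FALSE],
      observations$agency[unresolved], crosswalk)
  }

  prevalence <- list(
    overall = compute_naive_prevalence(observations, "overall"),
    species = compute_naive_prevalence(observations, "species"))

  if (variant == "species_specific") {
    if (is.null(species) || length(species) != 1L) {
      stop("species_specific fits require a single 'species' argument",
           call. = FALSE)
    }
    focal <- select_focal_species(prevalence$species,
                                  focal_min_prevalence, focal_min_n)
    if (!(species %in% prevalence$species$group)) {
      stop("species '", species, "' not present in the observations",
           call. = FALSE)
    }
    if (!(species %in% focal)) {
      row <- prevalence$species[prevalence$species$group == species, ]
      stop("species '", species, "' fails the focal-species rule ",
           "(prevalence ", signif(row$prevalence, 3), ", n ",
           row$n_inspected, "): requires prevalence >= ",
           focal_min_prevalence, " and n > ", focal_min_n, call. = FALSE)
    }
    observations <- observations[observations$species == species, ,
                                 drop = FALSE]
  }

  screen <- NULL
  predictors <- character(0)
  if (variant %in% c("conditional", "species_specific")) {
    if (is.null(predictor_table)) {
      stop("variant '", variant, "' requires a predictor_table",
           call. = FALSE)
    }
    # exclude streams with missing screened predictor values (no imputation)
    pred_cols <- .predictor_columns(predictor_table)
    complete <- stats::complete.cases(predictor_table[pred_cols])
    dropped$missing_predictor_streams <- sum(!complete)
    predictor_table <- predictor_table[complete, , drop = FALSE]
    n_before <- nrow(observations)
    keep <- observations$stream_id %in% predictor_table$stream_id
    if (!any(keep)) {
      stop("join error: no observation stream_id matches the predictor ",
           "table", call. = FALSE)
    }
    observations <- observations[keep, , drop = FALSE]
    dropped$missing_predictor_obs <- n_before - nrow(observations)

    screen <- drop_collinear(predictor_table, threshold = screen_threshold,
                             priority = screen_priority)
    predictor_table <- screen$table
    predictors <- screen$retained
  }

  spec <- build_spec(
    variant = variant,
    species = if (variant == "species_specific") species
              else sort(unique(observations$species)),
    agencies = sort(unique(observations$agency)),
    ecoregions = sort(unique(observations$ecoregion)),
    predictors = predictors,
    hyper = hyper)

  data <- assemble_model_data(spec, observations, predictor_table,
                              standardize = standardize)
  fit <- sample_posterior(spec, data, config)
  convergence <- check_convergence(fit)
  if (!convergence$pass && !allow_unconverged) {
    stop("convergence verdict: fail (max R-hat ",
         signif(max(convergence$summary$rhat, na.rm = TRUE), 4),
         ", min bulk ESS ",
         signif(min(convergence$summary$ess_bulk, na.rm = TRUE), 4),
         ", divergences ", convergence$divergences, ")", call. = FALSE)
  }

  structure(list(fit = fit, convergence = convergence, screen = screen,
                 prevalence = prevalence, spec = spec,
                 dropped_rows = dropped),
            class = "delt_pipeline_fit")
}

#' @export
print.delt_pipeline_fit <- function(x, ...) {
  cat("<delt_pipeline_fit>", x$spec$variant, "model on",
      x$prevalence$overall$n_inspected, "fish\n")
  cat("  naive prevalence:",
      signif(x$prevalence$overall$prevalence, 3), "\n")
  if (!is.null(x$screen)) {
    cat("  screen: retained", length(x$screen$retained), "predictors,",
        "dropped", nrow(x$screen$dropped), "\n")
  }
  cat("  convergence:", if (x$convergence$pass) "pass" else "FAIL",
      "(", x$convergence$divergences, "divergences )\n")
  invisible(x)
}
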