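# Occurrence model variants as explicit joint log densities over data and
# parameters.
#
# All three variants are Bernoulli-logit regressions on a per-fish linear
# predictor:
#   unconditional:    beta0 + gamma[agency] + phi[ecoregion] + eta[species]
#   conditional:      beta0 + X beta + gamma + phi + eta
#   species_specific: beta0 + X beta + gamma + phi     (single species)
# Random effects are exchangeable normals with half-Cauchy priors on their
# standard deviations; landscape coefficients beta carry a regularized
# horseshoe prior (per-coefficient local scales lambda_f, a global scale
# tau, and a slab scale c bounding the largest unshrunk coefficients).

#' Numerically stable inverse logit
#'
#' `1 / (1 + exp(-x))`, evaluated in a branch that avoids overflow for
#' large `|x|`. Strictly increasing; maps the linear predictor of the
#' occurrence models to a probability.
#'
#' @param x Finite numeric vector.
#' @return Probabilities in (0, 1).
#' @export
inverse_logit <- function(x) {
  if (!all(is.finite(x))) stop("non-finite input", call. = FALSE)
  ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))
}

#' @rdname inverse_logit
#' @param p Probabilities in (0, 1).
#' @export
logit <- function(p) {
  stopifnot(all(p > 0 & p < 1))
  log(p / (1 - p))
}

# log(1 + exp(x)) without overflow
.log1pexp <- function(x) {
  out <- x
  small <- x <= 18
  mid <- x > 18 & x <= 33.3
  out[small] <- log1p(exp(x[small]))
  out[mid] <- x[mid] + exp(-x[mid])
  out
}

#' Regularized horseshoe shrunk local scale
#'
#' The squared regularized local scale
#' `lambda_tilde^2 = c^2 lambda^2 / (c^2 + tau^2 lambda^2)`, so that each
#' coefficient prior is `N(0, tau^2 lambda_tilde^2)`. As `c` grows at
#' fixed `tau`, `lambda`, the slab stops binding and `lambda_tilde^2`
#' approaches `lambda^2`.
#'
#' @param tau Positive global scale.
#' @param lambda Positive local scale(s).
#' @param c Positive slab scale.
#' @return `lambda_tilde^2`, same length as `lambda`.
#' @export
horseshoe_shrunk_scale <- function(tau, lambda, c) {
  vals <- c(tau, lambda, c)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all arguments must be positive and finite", call. = FALSE)
  }
  c^2 * lambda^2 / (c^2 + tau^2 * lambda^2)
}

#' Prior hyperparameters for the occurrence models
#'
#' @param intercept_scale SD of the diffuse normal prior on the intercept
#'   (logit scale); default 5, weakly informative for probabilities
#'   spanning roughly (0.001, 0.999).
#' @param sigma_scale Half-Cauchy scale for the random-effect SDs;
#'   default 2.5.
#' @param lambda_scale Half-Cauchy scale of the horseshoe local scales;
#'   default 1.
#' @param p0 Prior guess of the number of nonzero landscape coefficients;
#'   drives the global-scale prior `tau ~ half-Cauchy(p0 / ((P - p0)
#'   sqrt(n)))`. Default 5. If `p0 >= P` the guard `p0 = P / 2` applies.
#' @param slab_scale,slab_df Scale and degrees of freedom of the
#'   inverse-gamma prior on the squared slab scale `c^2`; defaults 2 and 4.
#' @param tau0 Optional fixed half-Cauchy scale for `tau`, overriding the
#'   `p0`-based value.
#' @return List of hyperparameters.
#' @export
model_hyper <- function(intercept_scale = 5, sigma_scale = 2.5,
                        lambda_scale = 1, p0 = 5, slab_scale = 2,
                        slab_df = 4, tau0 = NULL) {
  vals <- c(intercept_scale, sigma_scale, lambda_scale, p0, slab_scale,
            slab_df)
  if (any(vals <= 0)) stop("hyperparameters must be positive", call. = FALSE)
  list(intercept_scale = intercept_scale, sigma_scale = sigma_scale,
       lambda_scale = lambda_scale, p0 = p0, slab_scale = slab_scale,
       slab_df = slab_df, tau0 = tau0)
}

# global-scale prior scale from the expected-nonzero-count construction
.hs_tau0 <- function(hyper, P, n) {
  if (!is.null(hyper$tau0)) return(hyper$tau0)
  p0 <- hyper$p0
  if (p0 >= P) p0 <- P / 2
  p0 / ((P - p0) * sqrt(n))
}

#' Build an occurrence model specification
#'
#' Declares which of the model variants to fit, the factor levels of the
#' included random effects, the landscape predictors (conditional and
#' species-specific variants), and the prior hyperparameters.
#'
#' @param variant `"unconditional"` (random effects only),
#'   `"conditional"` (adds horseshoe-prior landscape coefficients),
#'   `"species_specific"` (conditional structure without the species
#'   random effect, for a single-species subset), or `"intercept_only"`
#'   (no random effects or predictors; small-scale checks).
#' @param species,agencies,ecoregions Character vectors of factor levels.
#'   `species` must be absent (or length one, as a record) for
#'   `species_specific`; all of them absent for `intercept_only`.
#' @param predictors Character vector of landscape predictor names (empty
#'   for `unconditional`/`intercept_only`).
#' @param hyper Output of [model_hyper()].
#' @return A `delt_model_spec` object.
#' @export
build_spec <- function(variant = c("unconditional", "conditional",
                                   "species_specific", "intercept_only"),
                       species = NULL, agencies = NULL, ecoregions = NULL,
                       predictors = character(0), hyper = model_hyper()) {
  variant <- match.arg(variant)
  predictors <- as.character(predictors)
  has_species <- variant %in% c("unconditional", "conditional")
  has_groups <- variant != "intercept_only"

  if (variant %in% c("unconditional", "intercept_only") &&
      length(predictors) > 0L) {
    stop("variant '", variant, "' takes no predictors", call. = FALSE)
  }
  if (variant %in% c("conditional", "species_specific") &&
      length(predictors) == 0L) {
    stop("variant '", variant, "' requires predictors", call. = FALSE)
  }
  if (variant == "species_specific" && length(species) > 1L) {
    stop("species_specific models are fitted per species: subset the ",
         "observations to a single species first", call. = FALSE)
  }
  if (has_species && length(species) == 0L) {
    stop("variant '", variant, "' requires species levels", call. = FALSE)
  }
  if (has_groups && (length(agencies) == 0L || length(ecoregions) == 0L)) {
    stop("variant '", variant, "' requires agency and ecoregion levels",
         call. = FALSE)
  }
  if (anyDuplicated(predictors) > 0L) {
    stop("duplicated predictor names", call. = FALSE)
  }

  structure(list(
    variant = variant,
    species = if (has_species) as.character(species)
              else as.character(species %||% character(0)),
    agencies = if (has_groups) as.character(agencies) else character(0),
    ecoregions = if (has_groups) as.character(ecoregions) else character(0),
    predictors = predictors,
    hyper = hyper,
    has_species_effect = has_species,
    P = length(predictors),
    K = if (has_groups) length(agencies) else 0L,
    R = if (has_groups) length(ecoregions) else 0L,
    S = if (has_species) length(species) else 0L
  ), class = "delt_model_spec")
}

#' @export
print.delt_model_spec <- function(x, ...) {
  cat("<delt_model_spec>", x$variant, "\n")
  cat("  predictors:", x$P, " agencies:", x$K, " ecoregions:", x$R,
      " species:", x$S, "\n")
  invisible(x)
}

#' Assemble aligned model data from observations and predictors
#'
#' Joins each fish to its stream's landscape predictor row, encodes the
#' grouping factors against the spec's level sets, and (for the
#' conditional variants) standardizes the design matrix. Standardization
#' is computed over the observation-aligned rows by default (one row per
#' fish, stream values repeated), with a per-stream alternative.
#'
#' @param spec A [build_spec()] model specification.
#' @param observations Observation data frame with resolved binary `delt`.
#' @param predictor_table Stream-by-predictor data frame (required when the
#'   spec has predictors).
#' @param standardize `"observations"` (default) or `"streams"`: which rows
#'   the standardization moments are computed over. `"none"` takes the
#'   table as already standardized.
#' @return List with `y`, `X` (standardized matrix or NULL), integer index
#'   vectors `agency`, `ecoregion`, `species` (NULL where absent), `n`,
#'   `transform` (standardization record) and the `spec`.
#' @export
assemble_model_data <- function(spec, observations, predictor_table = NULL,
                                standardize = c("observations", "streams",
                                                "none")) {
  standardize <- match.arg(standardize)
  stopifnot(inherits(spec, "delt_model_spec"))
  if (anyNA(observations$delt)) {
    stop("observations carry unresolved delt flags", call. = FALSE)
  }
  n <- nrow(observations)
  y <- as.integer(observations$delt)

  code <- function(values, levels, what) {
    idx <- match(values, levels)
    if (anyNA(idx)) {
      stop("observation ", what, " label(s) not in spec levels: ",
           paste(head(unique(values[is.na(idx)]), 5L), collapse = ", "),
           call. = FALSE)
    }
    idx
  }
  agency <- ecoregion <- species <- NULL
  if (spec$K > 0L) agency <- code(observations$agency, spec$agencies, "agency")
  if (spec$R > 0L) {
    ecoregion <- code(observations$ecoregion, spec$ecoregions, "ecoregion")
  }
  if (spec$has_species_effect) {
    species <- code(observations$species, spec$species, "species")
  } else if (spec$variant == "species_specific" &&
             length(unique(observations$species)) > 1L) {
    stop("species_specific models are fitted per species: subset the ",
         "observations to a single species first", call. = FALSE)
  }

  X <- NULL
  transform <- NULL
  if (spec$P > 0L) {
    if (is.null(predictor_table)) {
      stop("spec has predictors but no predictor_table supplied",
           call. = FALSE)
    }
    missing_p <- setdiff(spec$predictors, names(predictor_table))
    if (length(missing_p) > 0L) {
      stop("predictor_table lacks column(s): ",
           paste(missing_p, collapse = ", "), call. = FALSE)
    }
    row <- match(observations$stream_id, predictor_table$stream_id)
    if (anyNA(row)) {
      offenders <- head(unique(observations$stream_id[is.na(row)]), 10L)
      stop("join error: observation stream_id(s) missing from predictor ",
           "table: ", paste(offenders, collapse = ", "), call. = FALSE)
    }
    if (standardize == "streams") {
      std <- standardize_predictors(
        predictor_table[, c("stream_id", spec$predictors), drop = FALSE])
      X <- .predictor_matrix(std$table)[row, , drop = FALSE]
      transform <- std$transform
    } else {
      aligned <- predictor_table[row, c("stream_id", spec$predictors),
                                 drop = FALSE]
      if (standardize == "observations") {
        std <- standardize_predictors(aligned)
        X <- .predictor_matrix(std$table)
        transform <- std$transform
      } else {
        X <- .predictor_matrix(aligned)
      }
    }
    colnames(X) <- spec$predictors
  }

  list(y = y, X = X, agency = agency, ecoregion = ecoregion,
       species = species, n = n, transform = transform, spec = spec,
       stream = match(observations$stream_id,
                      unique(observations$stream_id)))
}

.check_point <- function(spec, point) {
  lens <- c(beta = spec$P, gamma = spec$K, phi = spec$R, eta = spec$S,
            lambda = spec$P)
  for (nm in names(lens)) {
    got <- length(point[[nm]] %||% numeric(0))
    if (got != lens[[nm]]) {
      stop("spec error: parameter '", nm, "' has length ", got,
           " but spec requires ", lens[[nm]], call. = FALSE)
    }
  }
  scales <- c(point$sigma_agency, point$sigma_region, point$sigma_species,
              point$tau, point$lambda, point$c)
  if (length(scales) > 0L && any(scales <= 0)) {
    stop("spec error: scale parameters must be positive", call. = FALSE)
  }
  invisible(TRUE)
}

#' Joint log density of a model variant
#'
#' Sum of the Bernoulli log likelihood at the variant's linear predictor
#' and all log priors: diffuse normal on the intercept, exchangeable
#' normals on the random effects with half-Cauchy priors on their SDs, and
#' (for the conditional variants) the regularized horseshoe prior on the
#' landscape coefficients. This is the density the sampler targets, up to
#' the change of variables to unconstrained coordinates.
#'
#' @param spec A [build_spec()] specification.
#' @param data Output of [assemble_model_data()].
#' @param point Named list of parameter values: `beta0`, and as required by
#'   the spec `beta`, `gamma`, `phi`, `eta`, `sigma_agency`,
#'   `sigma_region`, `sigma_species`, `tau`, `lambda`, `c`.
#' @return Scalar log density (finite for finite inputs).
#' @export
joint_log_density <- function(spec, data, point) {
  stopifnot(inherits(spec, "delt_model_spec"))
  .check_point(spec, point)
  if (data$n != length(data$y)) stop("shape error: n mismatch", call. = FALSE)

  eta_lin <- rep(point$beta0, data$n)
  if (spec$P > 0L) {
    if (!is.matrix(data$X) || ncol(data$X) != spec$P ||
        nrow(data$X) != data$n) {
      stop("shape error: design matrix does not match spec/observations",
           call. = FALSE)
    }
    eta_lin <- eta_lin + as.numeric(data$X %*% point$beta)
  }
  if (spec$K > 0L) eta_lin <- eta_lin + point$gamma[data$agency]
  if (spec$R > 0L) eta_lin <- eta_lin + point$phi[data$ecoregion]
  if (spec$S > 0L) eta_lin <- eta_lin + point$eta[data$species]

  ll <- sum(data$y * eta_lin) - sum(.log1pexp(eta_lin))

  h <- spec$hyper
  lp <- dnorm(point$beta0, 0, h$intercept_scale, log = TRUE)
  half_cauchy <- function(x, scale) log(2) + dcauchy(x, 0, scale, log = TRUE)
  if (spec$K > 0L) {
    lp <- lp + sum(dnorm(point$gamma, 0, point$sigma_agency, log = TRUE)) +
      half_cauchy(point$sigma_agency, h$sigma_scale)
  }
  if (spec$R > 0L) {
    lp <- lp + sum(dnorm(point$phi, 0, point$sigma_region, log = TRUE)) +
      half_cauchy(point$sigma_region, h$sigma_scale)
  }
  if (spec$S > 0L) {
    lp <- lp + sum(dnorm(point$eta, 0, point$sigma_species, log = TRUE)) +
      half_cauchy(point$sigma_species, h$sigma_scale)
  }
  if (spec$P > 0L) {
    tau0 <- .hs_tau0(h, spec$P, data$n)
    lt2 <- horseshoe_shrunk_scale(point$tau, point$lambda, point$c)
    lp <- lp + sum(dnorm(point$beta, 0, point$tau * sqrt(lt2), log = TRUE)) +
      sum(half_cauchy(point$lambda, h$lambda_scale)) +
      half_cauchy(point$tau, tau0)
    a <- h$slab_df / 2
    b <- h$slab_df * h$slab_scale^2 / 2
    c2 <- point$c^2
    lp <- lp + a * log(b) - lgamma(a) - (a + 1) * log(c2) - b / c2
  }
  ll + lp
}
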