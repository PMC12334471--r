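# Synthetic fish-community DELT data with known ground truth.
#
# The generator mirrors the generative reading of the occurrence models:
# streams carry static landscape predictor values and belong to one
# ecoregion and one sampling agency; fish are allocated to streams with
# skewed counts and to species with skewed abundances; each fish's DELT
# indicator is Bernoulli at the inverse-logit of
# beta0 + X beta + gamma[agency] + phi[ecoregion] + eta[species].

#' Configuration of the synthetic DELT data generator
#'
#' @param n_species,n_agencies,n_ecoregions,n_streams,n_predictors Counts
#'   of factor levels, streams and landscape predictors.
#' @param fish_per_stream_mean Mean number of inspected fish per stream.
#' @param fish_per_stream_size Negative-binomial dispersion of per-stream
#'   fish counts (smaller = more skewed); `NULL` gives deterministic
#'   counts at the mean (exact total sample sizes for tests).
#' @param beta0 True intercept on the logit scale. Alternatively supply
#'   `target_prevalence` and the intercept is calibrated by quadrature so
#'   the marginal prevalence implied by the random-effect and coefficient
#'   variances matches it.
#' @param target_prevalence Optional marginal DELT prevalence target.
#' @param beta True landscape coefficients: a numeric vector of length
#'   `n_predictors` (typically sparse), or a shorter named/numeric vector
#'   placed on the first predictors with zeros elsewhere.
#' @param sigma_agency,sigma_region,sigma_species True random-effect SDs
#'   (>= 0; exact zeros give identical group effects).
#' @param predictor_correlation `"independent"`, `"block"` (exchangeable
#'   correlation `block_rho` within blocks of `block_size`), or
#'   `"collinear_pair"` (first two predictors correlated at
#'   `collinear_rho`, to exercise the collinearity screen).
#' @param collinear_rho,block_rho,block_size Correlation options.
#' @param species_weight_sdlog Log-normal SD of relative species
#'   abundances (drives the skew of per-species sample sizes).
#' @param inclusion_shape1,inclusion_shape2 Beta parameters of per-species
#'   stream-inclusion probabilities (drive how many streams each species
#'   occupies).
#' @param years Calendar years sampled uniformly for each fish.
#' @param seed Integer seed; the full dataset is a deterministic function
#'   of the configuration.
#' @return A `delt_generator_config` list.
#' @export
generator_config <- function(n_species = 20, n_agencies = 5,
                             n_ecoregions = 5, n_streams = 300,
                             n_predictors = 30,
                             fish_per_stream_mean = 50,
                             fish_per_stream_size = NULL,
                             beta0 = NULL, target_prevalence = NULL,
                             beta = numeric(0),
                             sigma_agency = 0.3, sigma_region = 0.3,
                             sigma_species = 0.3,
                             predictor_correlation = c("independent",
                                                       "block",
                                                       "collinear_pair"),
                             collinear_rho = 0.95, block_rho = 0.5,
                             block_size = 5,
                             species_weight_sdlog = 1.2,
                             inclusion_shape1 = 1.5, inclusion_shape2 = 4,
                             years = 2008:2019, seed = 1) {
  predictor_correlation <- match.arg(predictor_correlation)
  stopifnot(n_species >= 1, n_agencies >= 1, n_ecoregions >= 1,
            n_streams >= 1, n_predictors >= 0,
            sigma_agency >= 0, sigma_region >= 0, sigma_species >= 0)
  full_beta <- numeric(n_predictors)
  if (length(beta) > n_predictors) {
    stop("beta longer than n_predictors", call. = FALSE)
  }
  if (length(beta) > 0L) full_beta[seq_along(beta)] <- as.numeric(beta)
  if (is.null(beta0) && is.null(target_prevalence)) beta0 <- qlogis(0.05)
  cfg <- list(n_species = n_species, n_agencies = n_agencies,
              n_ecoregions = n_ecoregions, n_streams = n_streams,
              n_predictors = n_predictors,
              fish_per_stream_mean = fish_per_stream_mean,
              fish_per_stream_size = fish_per_stream_size,
              beta0 = beta0, target_prevalence = target_prevalence,
              beta = full_beta,
              sigma_agency = sigma_agency, sigma_region = sigma_region,
              sigma_species = sigma_species,
              predictor_correlation = predictor_correlation,
              collinear_rho = collinear_rho, block_rho = block_rho,
              block_size = block_size,
              species_weight_sdlog = species_weight_sdlog,
              inclusion_shape1 = inclusion_shape1,
              inclusion_shape2 = inclusion_shape2,
              years = years, seed = as.integer(seed))
  class(cfg) <- "delt_generator_config"
  cfg
}

# marginal prevalence of logit-normal occurrence by Gauss-Hermite quadrature
.marginal_prevalence <- function(beta0, total_sd) {
  if (total_sd == 0) return(plogis(beta0))
  gh <- 41L
  # Hermite nodes via eigen-decomposition of the Jacobi matrix
  k <- seq_len(gh - 1L)
  J <- matrix(0, gh, gh)
  J[cbind(k, k + 1L)] <- sqrt(k / 2)
  J[cbind(k + 1L, k)] <- sqrt(k / 2)
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- e$vectors[1L, ]^2
  sum(weights * plogis(beta0 + sqrt(2) * total_sd * nodes))
}

.calibrated_beta0 <- function(cfg) {
  if (!is.null(cfg$beta0)) return(cfg$beta0)
  total_sd <- sqrt(cfg$sigma_agency^2 + cfg$sigma_region^2 +
                     cfg$sigma_species^2 + sum(cfg$beta^2))
  target <- cfg$target_prevalence
  uniroot(function(b0) .marginal_prevalence(b0, total_sd) - target,
          lower = qlogis(1e-6), upper = qlogis(1 - 1e-6))$root
}

.stream_ids <- function(J) sprintf("comid%05d", seq_len(J))

.gen_pred_internal <- function(cfg) {
  J <- cfg$n_streams
  P <- cfg$n_predictors
  Z <- matrix(rnorm(J * P), J, P)
  if (P > 0L && cfg$predictor_correlation == "block") {
    nb <- ceiling(P / cfg$block_size)
    f <- matrix(rnorm(J * nb), J, nb)
    blk <- rep(seq_len(nb), each = cfg$block_size)[seq_len(P)]
    Z <- sqrt(cfg$block_rho) * f[, blk, drop = FALSE] +
      sqrt(1 - cfg$block_rho) * Z
  }
  if (P >= 2L && cfg$predictor_correlation == "collinear_pair") {
    rho <- cfg$collinear_rho
    Z[, 2L] <- rho * Z[, 1L] + sqrt(1 - rho^2) * Z[, 2L]
  }
  out <- data.frame(stream_id = .stream_ids(J), stringsAsFactors = FALSE)
  if (P > 0L) {
    pred <- as.data.frame(Z)
    names(pred) <- sprintf("x%02d", seq_len(P))
    out <- cbind(out, pred)
  }
  out
}

#' Generate a synthetic stream-by-predictor landscape table
#'
#' Streams-by-predictors draws from a multivariate normal with the
#' configured correlation structure; reproducible from the seed.
#'
#' @param config A [generator_config()].
#' @return Predictor data frame (`stream_id` + numeric columns).
#' @export
generate_predictor_matrix <- function(config) {
  stopifnot(inherits(config, "delt_generator_config"))
  set.seed(config$seed)
  .gen_pred_internal(config)
}

.deterministic_counts <- function(mean, J) {
  diff(c(0L, round(cumsum(rep(mean, J)))))
}

#' Simulate a full DELT dataset with ground truth
#'
#' Draws random effects from their normals, allocates fish to streams,
#' species, agencies and ecoregions, and draws each fish's binary DELT
#' indicator from the logit-linear occurrence model. The ground-truth
#' record (all sampled effects and per-stream linear predictors) is
#' returned separately and is never consumed by the fitting path.
#'
#' @param config A [generator_config()].
#' @return List with `observations` (per-fish data frame), `predictors`
#'   (stream-by-predictor table), `truth` (ground-truth list) and the
#'   `config`.
#' @export
simulate_delt_dataset <- function(config) {
  stopifnot(inherits(config, "delt_generator_config"))
  set.seed(config$seed)
  predictors <- .gen_pred_internal(config)

  J <- config$n_streams
  S <- config$n_species
  K <- config$n_agencies
  R <- config$n_ecoregions
  species_lvls <- sprintf("sp%02d", seq_len(S))
  agency_lvls <- sprintf("agency%d", seq_len(K))
  eco_lvls <- sprintf("eco%d", seq_len(R))

  stream_agency <- sample.int(K, J, replace = TRUE)
  stream_eco <- sample.int(R, J, replace = TRUE)

  # skewed species abundances and stream occupancy
  w <- rlnorm(S, 0, config$species_weight_sdlog)
  q <- rbeta(S, config$inclusion_shape1, config$inclusion_shape2)
  pool <- matrix(runif(S * J) < q, nrow = S)         # species x stream
  empty <- which(colSums(pool) == 0L)
  for (j in empty) pool[sample.int(S, 1L, prob = q + 1e-9), j] <- TRUE

  counts <- if (is.null(config$fish_per_stream_size)) {
    .deterministic_counts(config$fish_per_stream_mean, J)
  } else {
    pmax(1L, rnbinom(J, size = config$fish_per_stream_size,
                     mu = config$fish_per_stream_mean))
  }

  gamma <- rnorm(K, 0, config$sigma_agency)
  phi <- rnorm(R, 0, config$sigma_region)
  eta <- rnorm(S, 0, config$sigma_species)
  beta0 <- .calibrated_beta0(config)
  beta <- config$beta

  xb <- if (config$n_predictors > 0L) {
    as.numeric(.predictor_matrix(predictors) %*% beta)
  } else {
    numeric(J)
  }
  stream_base <- beta0 + xb + gamma[stream_agency] + phi[stream_eco]

  stream_of_fish <- rep.int(seq_len(J), counts)
  n <- length(stream_of_fish)
  species_of_fish <- integer(n)
  pos <- 1L
  for (j in seq_len(J)) {
    in_pool <- which(pool[, j])
    nj <- counts[j]
    species_of_fish[pos:(pos + nj - 1L)] <- if (length(in_pool) == 1L) {
      rep.int(in_pool, nj)
    } else {
      sample(in_pool, nj, replace = TRUE, prob = w[in_pool])
    }
    pos <- pos + nj
  }

  linpred <- stream_base[stream_of_fish] + eta[species_of_fish]
  y <- rbinom(n, 1L, plogis(linpred))

  observations <- data.frame(
    stream_id = .stream_ids(J)[stream_of_fish],
    species = species_lvls[species_of_fish],
    agency = agency_lvls[stream_agency[stream_of_fish]],
    ecoregion = eco_lvls[stream_eco[stream_of_fish]],
    year = sample(config$years, n, replace = TRUE),
    delt = y,
    stringsAsFactors = FALSE
  )

  truth <- list(beta0 = beta0, beta = setNames(beta, .predictor_columns(predictors)),
                gamma = setNames(gamma, agency_lvls),
                phi = setNames(phi, eco_lvls),
                eta = setNames(eta, species_lvls),
                sigma_agency = config$sigma_agency,
                sigma_region = config$sigma_region,
                sigma_species = config$sigma_species,
                stream_linpred = setNames(stream_base, .stream_ids(J)),
                stream_agency = setNames(agency_lvls[stream_agency],
                                         .stream_ids(J)),
                stream_ecoregion = setNames(eco_lvls[stream_eco],
                                            .stream_ids(J)))

  list(observations = observations, predictors = predictors, truth = truth,
       config = config)
}

#' Canned configuration mimicking the regional study's scale
#'
#' 57 species, 7 agencies, 9 ecoregions, 1,196 streams and 46 landscape
#' predictors, with the intercept calibrated so the marginal DELT
#' prevalence is about 1.4%. The default fish count per stream is scaled
#' down roughly twenty-fold from the study's median for desk-scale
#' integration tests; raise `fish_per_stream_mean` toward 149 for
#' full-scale structure. Intended for end-to-end exercising of the
#' pipeline, not for fidelity claims about any real dataset.
#'
#' @param fish_per_stream_mean Mean inspected fish per stream; default 8.
#' @param seed Integer seed.
#' @param ... Overrides passed to [generator_config()].
#' @return A `delt_generator_config`.
#' @export
study_mimic_config <- function(fish_per_stream_mean = 8, seed = 1, ...) {
  args <- list(
    n_species = 57, n_agencies = 7, n_ecoregions = 9, n_streams = 1196,
    n_predictors = 46,
    fish_per_stream_mean = fish_per_stream_mean,
    fish_per_stream_size = 2,
    target_prevalence = 0.014,
    beta = c(0.8, -0.6, 0.5, -0.4, 0.3),
    sigma_agency = 1.5, sigma_region = 0.3, sigma_species = 1.2,
    seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(generator_config, args)
}
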