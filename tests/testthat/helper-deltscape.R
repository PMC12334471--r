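# Shared fixtures, built in code.

# a tiny observation table with known counts
tiny_observations <- function() {
  data.frame(
    stream_id = c("c1", "c1", "c2", "c2", "c3", "c3", "c3", "c3"),
    species = c("A", "A", "A", "B", "B", "B", "A", "B"),
    agency = "ag1",
    ecoregion = "e1",
    year = c(2008L, 2010L, 2012L, 2015L, 2019L, 2009L, 2011L, 2013L),
    delt = c(1L, 0L, 1L, 0L, 0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE
  )
}

# a small simulated dataset shared by several tests
small_sim <- function(seed = 42, ...) {
  simulate_delt_dataset(generator_config(
    n_species = 5, n_agencies = 3, n_ecoregions = 3, n_streams = 40,
    n_predictors = 4, fish_per_stream_mean = 15, beta0 = qlogis(0.2),
    beta = c(0.8, -0.8, 0, 0), sigma_agency = 0.2, sigma_region = 0.2,
    sigma_species = 0.2, seed = seed, ...))
}

# hand-assembled delt_draws object for summary-level tests
fake_draws <- function(beta0, beta = NULL, eta = NULL, predictors = NULL,
                       species = NULL) {
  stopifnot(is.matrix(beta0))
  params <- list(beta0 = beta0)
  if (!is.null(beta)) {
    dimnames(beta)[[3]] <- predictors
    params$beta <- beta
  }
  if (!is.null(eta)) {
    dimnames(eta)[[3]] <- species
    params$eta <- eta
  }
  structure(list(parameters = params,
                 spec = list(variant = "fake"),
                 config = list(chains = ncol(beta0)),
                 divergences = rep(0L, ncol(beta0)),
                 transform = NULL),
            class = "delt_draws")
}

# independent brute-force Spearman: Pearson correlation of mid-ranks
spearman_oracle <- function(x, y) {
  midrank <- function(v) {
    sapply(seq_along(v), function(i) {
      sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    })
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# naive per-observation / per-prior summation oracle for the joint density
joint_density_oracle <- function(spec, data, point) {
  ll <- 0
  for (i in seq_len(data$n)) {
    lin <- point$beta0
    if (spec$P > 0) {
      for (f in seq_len(spec$P)) lin <- lin + data$X[i, f] * point$beta[f]
    }
    if (spec$K > 0) lin <- lin + point$gamma[data$agency[i]]
    if (spec$R > 0) lin <- lin + point$phi[data$ecoregion[i]]
    if (spec$S > 0) lin <- lin + point$eta[data$species[i]]
    p <- 1 / (1 + exp(-lin))
    ll <- ll + if (data$y[i] == 1) log(p) else log(1 - p)
  }
  h <- spec$hyper
  hc <- function(x, s) log(2) + dcauchy(x, 0, s, log = TRUE)
  lp <- dnorm(point$beta0, 0, h$intercept_scale, log = TRUE)
  if (spec$K > 0) {
    for (k in seq_len(spec$K)) {
      lp <- lp + dnorm(point$gamma[k], 0, point$sigma_agency, log = TRUE)
    }
    lp <- lp + hc(point$sigma_agency, h$sigma_scale)
  }
  if (spec$R > 0) {
    for (r in seq_len(spec$R)) {
      lp <- lp + dnorm(point$phi[r], 0, point$sigma_region, log = TRUE)
    }
    lp <- lp + hc(point$sigma_region, h$sigma_scale)
  }
  if (spec$S > 0) {
    for (s in seq_len(spec$S)) {
      lp <- lp + dnorm(point$eta[s], 0, point$sigma_species, log = TRUE)
    }
    lp <- lp + hc(point$sigma_species, h$sigma_scale)
  }
  if (spec$P > 0) {
    p0 <- h$p0; if (p0 >= spec$P) p0 <- spec$P / 2
    tau0 <- h$tau0
    if (is.null(tau0)) tau0 <- p0 / ((spec$P - p0) * sqrt(data$n))
    for (f in seq_len(spec$P)) {
      lt2 <- point$c^2 * point$lambda[f]^2 /
        (point$c^2 + point$tau^2 * point$lambda[f]^2)
      lp <- lp + dnorm(point$beta[f], 0, point$tau * sqrt(lt2), log = TRUE)
      lp <- lp + hc(point$lambda[f], h$lambda_scale)
    }
    lp <- lp + hc(point$tau, tau0)
    a <- h$slab_df / 2; b <- h$slab_df * h$slab_scale^2 / 2
    lp <- lp + a * log(b) - lgamma(a) - (a + 1) * log(point$c^2) -
      b / point$c^2
  }
  ll + lp
}

# a random conforming parameter point
random_point <- function(spec, sd = 0.7) {
  list(beta0 = rnorm(1, 0, sd),
       beta = rnorm(spec$P, 0, sd),
       lambda = exp(rnorm(spec$P, 0, 0.4)),
       tau = exp(rnorm(1, -1, 0.4)),
       c = exp(rnorm(1, 0.5, 0.3)),
       gamma = rnorm(spec$K, 0, sd),
       phi = rnorm(spec$R, 0, sd),
       eta = rnorm(spec$S, 0, sd),
       sigma_agency = exp(rnorm(1, -0.5, 0.3)),
       sigma_region = exp(rnorm(1, -0.5, 0.3)),
       sigma_species = exp(rnorm(1, -0.5, 0.3)))
}

# relabel a simulated dataset's levels to given names (for spec alignment)
assemble_from_sim <- function(sim, variant, predictors = NULL, ...) {
  spec <- build_spec(
    variant,
    species = sort(unique(sim$observations$species)),
    agencies = sort(unique(sim$observations$agency)),
    ecoregions = sort(unique(sim$observations$ecoregion)),
    predictors = predictors %||% character(0), ...)
  data <- assemble_model_data(spec, sim$observations,
                              if (!is.null(predictors)) sim$predictors)
  list(spec = spec, data = data)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
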