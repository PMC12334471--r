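# Fitting a model spec by NUTS and packaging the posterior draws.

#' Sampler configuration
#'
#' @param chains Number of MCMC chains (>= 2; run sequentially).
#' @param warmup,sampling Warmup and post-warmup draws per chain.
#' @param seed Integer seed; every source of randomness in a fit derives
#'   from it, so identical (seed, config, data) reproduce identical draws
#'   on one platform.
#' @param target_accept Dual-averaging target acceptance statistic in
#'   (0, 1); default 0.95, conservative for hierarchical logistic
#'   posteriors with funnel-like geometry.
#' @param parameterization `"non_centered"` (default; random effects
#'   sampled as standard normals scaled by their SD, which mixes better
#'   when group information is weak) or `"centered"`.
#' @param max_treedepth Cap on NUTS doublings per iteration; default 10.
#' @param init_retries Re-draws of the random initialization on a
#'   non-finite density; default 10.
#' @return A `delt_sampler_config` list.
#' @export
sampler_config <- function(chains = 4, warmup = 1000, sampling = 1000,
                           seed = 1, target_accept = 0.95,
                           parameterization = c("non_centered", "centered"),
                           max_treedepth = 10, init_retries = 10) {
  parameterization <- match.arg(parameterization)
  if (chains < 2) stop("chains must be >= 2", call. = FALSE)
  if (warmup < 1 || sampling < 1) stop("draws must be >= 1", call. = FALSE)
  if (!(target_accept > 0 && target_accept < 1)) {
    stop("target_accept must be in (0, 1)", call. = FALSE)
  }
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 sampling = as.integer(sampling), seed = as.integer(seed),
                 target_accept = target_accept,
                 parameterization = parameterization,
                 max_treedepth = as.integer(max_treedepth),
                 init_retries = as.integer(init_retries)),
            class = "delt_sampler_config")
}

# Unconstrained parameter layout; must mirror the C++ offsets.
.param_layout <- function(spec) {
  nm <- "beta0"
  if (spec$P > 0L) {
    nm <- c(nm, paste0("z_beta[", spec$predictors, "]"),
            paste0("log_lambda[", spec$predictors, "]"),
            "log_tau", "log_c")
  }
  if (spec$K > 0L) {
    nm <- c(nm, paste0("u_gamma[", spec$agencies, "]"), "log_sigma_agency")
  }
  if (spec$R > 0L) {
    nm <- c(nm, paste0("u_phi[", spec$ecoregions, "]"), "log_sigma_region")
  }
  if (spec$S > 0L) {
    nm <- c(nm, paste0("u_eta[", spec$species, "]"), "log_sigma_species")
  }
  nm
}

.pack_cpp_data <- function(spec, data, config) {
  h <- spec$hyper
  tau0 <- if (spec$P > 0L) .hs_tau0(h, spec$P, data$n) else 1.0

  # Fish sharing a stream (hence predictor row) and the same factor levels
  # have identical linear predictors: the Bernoulli likelihood aggregates
  # exactly to binomial success/trial counts per cell, which cuts the
  # sampler's per-gradient cost without changing the joint density.
  zero <- rep.int(0L, data$n)
  key <- paste(if (spec$P > 0L) data$stream else zero,
               data$agency %||% zero, data$ecoregion %||% zero,
               data$species %||% zero)
  cell <- match(key, unique(key))
  first <- which(!duplicated(cell))
  f <- factor(cell, levels = seq_len(length(first)))
  successes <- as.numeric(tapply(data$y, f, sum))
  trials <- as.numeric(tapply(data$y, f, length))

  list(y = successes, trials = trials,
       X = if (spec$P > 0L) data$X[first, , drop = FALSE]
           else matrix(0, 0, 0),
       agency = as.integer(data$agency[first] %||% integer(0)),
       ecoregion = as.integer(data$ecoregion[first] %||% integer(0)),
       species = as.integer(data$species[first] %||% integer(0)),
       n = length(first), P = spec$P, K = spec$K, R = spec$R, S = spec$S,
       centered = config$parameterization == "centered",
       hyper = list(intercept_scale = h$intercept_scale,
                    sigma_scale = h$sigma_scale,
                    lambda_scale = h$lambda_scale,
                    tau0 = tau0, slab_df = h$slab_df,
                    slab_scale = h$slab_scale))
}

# moderate-range random initialization in unconstrained coordinates
.random_init <- function(spec, tau0, centered) {
  th <- rnorm(1, 0, 1)                              # beta0
  if (spec$P > 0L) {
    th <- c(th,
            rnorm(spec$P, 0, 0.5),                  # z_beta
            rnorm(spec$P, 0, 0.5),                  # log lambda
            rnorm(1, log(tau0), 0.5),               # log tau
            rnorm(1, log(spec$hyper$slab_scale), 0.2))  # log c
  }
  re_block <- function(L) {
    if (centered) c(rnorm(L, 0, 0.3), rnorm(1, log(0.5), 0.3))
    else c(rnorm(L, 0, 0.5), rnorm(1, log(0.5), 0.3))
  }
  if (spec$K > 0L) th <- c(th, re_block(spec$K))
  if (spec$R > 0L) th <- c(th, re_block(spec$R))
  if (spec$S > 0L) th <- c(th, re_block(spec$S))
  th
}

# map an iter x D matrix of unconstrained draws to natural parameters
.unpack_chain <- function(M, spec, centered) {
  o <- 1L
  take <- function(k) {
    cols <- M[, o:(o + k - 1L), drop = FALSE]
    o <<- o + k
    cols
  }
  out <- list(beta0 = as.numeric(take(1L)))
  if (spec$P > 0L) {
    zb <- take(spec$P)
    lam <- exp(take(spec$P))
    tau <- exp(as.numeric(take(1L)))
    cc <- exp(as.numeric(take(1L)))
    lt <- lam / sqrt(1 + (tau * lam / cc)^2)
    out$beta <- zb * (tau * lt)
    colnames(out$beta) <- spec$predictors
    out$lambda <- lam
    colnames(out$lambda) <- spec$predictors
    out$tau <- tau
    out$c <- cc
  }
  re_block <- function(L, levels) {
    z <- take(L)
    sig <- exp(as.numeric(take(1L)))
    eff <- if (centered) z else z * sig
    colnames(eff) <- levels
    list(eff = eff, sig = sig)
  }
  if (spec$K > 0L) {
    b <- re_block(spec$K, spec$agencies)
    out$gamma <- b$eff; out$sigma_agency <- b$sig
  }
  if (spec$R > 0L) {
    b <- re_block(spec$R, spec$ecoregions)
    out$phi <- b$eff; out$sigma_region <- b$sig
  }
  if (spec$S > 0L) {
    b <- re_block(spec$S, spec$species)
    out$eta <- b$eff; out$sigma_species <- b$sig
  }
  out
}

#' Draw from the posterior of an occurrence model by NUTS
#'
#' Runs the package's Hamiltonian Monte Carlo sampler (No-U-Turn variant
#' with dual-averaging step-size adaptation and a warmup-estimated diagonal
#' mass matrix) on the joint log density declared by the spec. Chains run
#' sequentially; chain `k` is seeded with `seed + k - 1`.
#'
#' @param spec A [build_spec()] specification.
#' @param data Output of [assemble_model_data()] conforming to the spec.
#' @param config A [sampler_config()].
#' @return A `delt_draws` object: named draw arrays (`iterations x chains`
#'   or `iterations x chains x levels`) for `beta0`, `beta`, `gamma`,
#'   `phi`, `eta`, the random-effect SDs, `tau`, `lambda`, `c`, plus
#'   sampler metadata (divergence counts, seed, config, spec, transform).
#' @export
sample_posterior <- function(spec, data, config = sampler_config()) {
  stopifnot(inherits(spec, "delt_model_spec"),
            inherits(config, "delt_sampler_config"))
  if (!identical(data$spec$variant, spec$variant)) {
    stop("spec error: data were assembled for variant '",
         data$spec$variant, "'", call. = FALSE)
  }
  if (all(data$y == 0L) || all(data$y == 1L)) {
    warning("degenerate outcome vector (all ", data$y[1],
            "): expect an extreme intercept", call. = FALSE)
  }
  cpp_data <- .pack_cpp_data(spec, data, config)
  cpp_cfg <- list(warmup = config$warmup, sampling = config$sampling,
                  max_treedepth = config$max_treedepth,
                  target_accept = config$target_accept)
  centered <- config$parameterization == "centered"

  chains <- vector("list", config$chains)
  divergences <- integer(config$chains)
  step_sizes <- numeric(config$chains)
  for (k in seq_len(config$chains)) {
    set.seed(config$seed + k - 1L)
    init <- NULL
    for (try in seq_len(config$init_retries)) {
      cand <- .random_init(spec, cpp_data$hyper$tau0, centered)
      lp <- .delt_logp_grad_cpp(cpp_data, cand)$lp
      if (is.finite(lp)) { init <- cand; break }
    }
    if (is.null(init)) {
      stop("initialization error: non-finite density after ",
           config$init_retries, " retries", call. = FALSE)
    }
    res <- .nuts_chain_cpp(cpp_data, cpp_cfg, init)
    chains[[k]] <- .unpack_chain(res$draws, spec, centered)
    divergences[k] <- res$divergences
    step_sizes[k] <- res$step_size
  }

  # stack per-parameter arrays across chains
  params <- list()
  for (nm in names(chains[[1L]])) {
    first <- chains[[1L]][[nm]]
    if (is.matrix(first)) {
      arr <- array(NA_real_,
                   dim = c(nrow(first), config$chains, ncol(first)),
                   dimnames = list(NULL, NULL, colnames(first)))
      for (k in seq_len(config$chains)) arr[, k, ] <- chains[[k]][[nm]]
    } else {
      arr <- matrix(NA_real_, nrow = length(first), ncol = config$chains)
      for (k in seq_len(config$chains)) arr[, k] <- chains[[k]][[nm]]
    }
    params[[nm]] <- arr
  }

  structure(list(parameters = params, spec = spec, config = config,
                 divergences = divergences, step_sizes = step_sizes,
                 transform = data$transform, n_obs = data$n),
            class = "delt_draws")
}

#' @export
print.delt_draws <- function(x, ...) {
  cat("<delt_draws>", x$spec$variant, "model:",
      dim(x$parameters$beta0)[1L], "draws x",
      dim(x$parameters$beta0)[2L], "chains\n")
  cat("  divergences per chain:", paste(x$divergences, collapse = ", "), "\n")
  invisible(x)
}

#' Flatten a fit to a named draw matrix
#'
#' One column per scalar parameter (vector blocks expand to
#' `name[level]`), rows stacking all chains; used by the convergence
#' diagnostics and summary tables.
#'
#' @param fit A `delt_draws` object.
#' @param parameters Optional character vector of parameter blocks to
#'   include (default: all).
#' @param split_chains If `TRUE`, return a list of per-chain matrices
#'   instead of one stacked matrix.
#' @return Named numeric matrix (or list of them).
#' @export
as_parameter_matrix <- function(fit, parameters = NULL,
                                split_chains = FALSE) {
  stopifnot(inherits(fit, "delt_draws"))
  blocks <- fit$parameters
  if (!is.null(parameters)) blocks <- blocks[parameters]
  per_chain <- function(k) {
    cols <- lapply(names(blocks), function(nm) {
      b <- blocks[[nm]]
      if (length(dim(b)) == 3L) {
        m <- b[, k, , drop = FALSE]
        m <- matrix(m, nrow = dim(b)[1L], ncol = dim(b)[3L])
        colnames(m) <- paste0(nm, "[", dimnames(b)[[3L]], "]")
        m
      } else {
        m <- matrix(b[, k], ncol = 1L)
        colnames(m) <- nm
        m
      }
    })
    do.call(cbind, cols)
  }
  mats <- lapply(seq_len(ncol(blocks[[1L]])), per_chain)
  if (split_chains) mats else do.call(rbind, mats)
}
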