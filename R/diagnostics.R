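# Convergence diagnostics: split potential-scale-reduction and effective
# sample size, with a pass/fail verdict replacing visual chain inspection.

.split_chains <- function(x) {
  # x: iterations x chains -> iterations/2 x (2*chains)
  n <- nrow(x)
  half <- n %/% 2L
  x <- x[seq_len(2L * half), , drop = FALSE]
  cbind(x[seq_len(half), , drop = FALSE],
        x[half + seq_len(half), , drop = FALSE])
}

#' Split potential-scale-reduction statistic (R-hat)
#'
#' Each chain is split in half and the classical between/within variance
#' ratio is computed over the split halves, so slow within-chain trends
#' register as non-convergence.
#'
#' @param x Numeric matrix of draws, iterations x chains (>= 2 chains).
#' @return Scalar R-hat (NA for constant draws).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("split R-hat requires >= 2 chains", call. = FALSE)
  x <- .split_chains(x)
  n <- nrow(x)
  m <- ncol(x)
  means <- colMeans(x)
  vars <- apply(x, 2L, var)
  W <- mean(vars)
  B <- n * var(means)
  if (!is.finite(W) || W == 0) return(NA_real_)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

# rank-normalize draws jointly across chains (preserving matrix shape)
.rank_normalize <- function(x) {
  r <- rank(as.numeric(x), ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow = nrow(x), ncol = ncol(x))
}

#' Bulk effective sample size
#'
#' Multi-chain effective sample size on rank-normalized split chains:
#' per-chain autocovariances are combined into pooled autocorrelations and
#' truncated by Geyer's initial monotone positive-pair sequence.
#'
#' @param x Numeric matrix of draws, iterations x chains.
#' @return Scalar effective sample size (NA for constant draws).
#' @export
ess_bulk <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("ESS requires >= 2 chains", call. = FALSE)
  x <- .rank_normalize(.split_chains(x))
  n <- nrow(x)
  m <- ncol(x)
  if (n < 4L) return(NA_real_)
  acovs <- vapply(seq_len(m), function(k) {
    a <- acf(x[, k], lag.max = n - 1L, plot = FALSE, type = "covariance")
    as.numeric(a$acf) * (n - 1) / n
  }, numeric(n))
  chain_vars <- acovs[1L, ] * n / (n - 1)
  W <- mean(chain_vars)
  mean_acov <- rowMeans(acovs)
  var_plus <- W * (n - 1) / n + var(colMeans(x))
  if (!is.finite(var_plus) || var_plus == 0) return(NA_real_)
  rho <- 1 - (W - mean_acov) / var_plus
  # Geyer pairs: truncate at the first negative pair, enforce monotone
  max_pairs <- (n - 1L) %/% 2L
  tau <- rho[1L]
  prev_pair <- Inf
  t <- 2L
  for (p in seq_len(max_pairs)) {
    pair <- rho[t] + rho[t + 1L]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev_pair)
    tau <- tau + 2 * pair
    prev_pair <- pair
    t <- t + 2L
  }
  ess <- m * n / max(tau, 1 / (m * n))
  min(ess, m * n * log10(m * n))   # cap for antithetic chains
}

#' Convergence report for a fit
#'
#' Per-parameter split R-hat and bulk effective sample size over all
#' natural parameters, plus the divergence count, with a pass/fail
#' verdict: pass iff every monitored R-hat is at most `rhat_max`, every
#' bulk ESS is at least `ess_min`, and total divergences do not exceed
#' `max_divergences`. A failing verdict flags the draws; it does not
#' discard them.
#'
#' @param fit A `delt_draws` object (>= 2 chains).
#' @param rhat_max,ess_min,max_divergences Verdict thresholds; defaults
#'   1.01, 400 and 0.
#' @return List with `summary` (data frame: parameter, rhat, ess_bulk),
#'   `divergences`, and logical `pass`.
#' @export
check_convergence <- function(fit, rhat_max = 1.01, ess_min = 400,
                              max_divergences = 0) {
  stopifnot(inherits(fit, "delt_draws"))
  if (fit$config$chains < 2L) {
    stop("split R-hat undefined for a single chain", call. = FALSE)
  }
  per_chain <- as_parameter_matrix(fit, split_chains = TRUE)
  pnames <- colnames(per_chain[[1L]])
  stats <- vapply(seq_along(pnames), function(j) {
    draws <- vapply(per_chain, function(mm) mm[, j], numeric(nrow(per_chain[[1L]])))
    c(split_rhat(draws), ess_bulk(draws))
  }, numeric(2L))
  summary <- data.frame(parameter = pnames,
                        rhat = stats[1L, ],
                        ess_bulk = stats[2L, ],
                        stringsAsFactors = FALSE)
  total_div <- sum(fit$divergences)
  ok <- is.finite(summary$rhat) & is.finite(summary$ess_bulk)
  pass <- all(summary$rhat[ok] <= rhat_max) &&
    all(summary$ess_bulk[ok] >= ess_min) &&
    total_div <= max_divergences
  list(summary = summary, divergences = total_div, pass = pass)
}
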