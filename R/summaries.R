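# Posterior decision summaries: credible intervals, probability of
# direction, significance classes, group occurrence probabilities,
# response curves.

#' Equal-tailed credible interval
#'
#' Empirical quantiles at `(1 - level)/2` and `1 - (1 - level)/2`, using
#' linear interpolation of order statistics (R's default type-7 quantile
#' rule, fixed and documented because endpoint values at a few thousand
#' draws depend on the rule).
#'
#' @param draws Numeric vector of at least 2 finite draws.
#' @param level Interval mass in (0, 1); default 0.90.
#' @return Named vector `c(lower, upper)`.
#' @export
equal_tailed_interval <- function(draws, level = 0.90) {
  if (length(draws) < 2L || !all(is.finite(draws))) {
    stop("need >= 2 finite draws", call. = FALSE)
  }
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)", call. = FALSE)
  alpha <- (1 - level) / 2
  q <- quantile(draws, probs = c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(lower = q[1L], upper = q[2L])
}

#' Probability of direction
#'
#' Posterior probability that an effect shares the sign of its posterior
#' mean: the larger of the positive-sign and negative-sign draw fractions,
#' with draws exactly zero counted half toward each side (so the result is
#' sign-symmetric and continuous); 0.5 when the posterior mean is exactly
#' zero. Ranges from 0.5 (direction fully uncertain) to 1.
#'
#' @param draws Numeric vector of at least 2 finite draws.
#' @return pd in \[0.5, 1\].
#' @export
probability_of_direction <- function(draws) {
  if (length(draws) < 2L || !all(is.finite(draws))) {
    stop("need >= 2 finite draws", call. = FALSE)
  }
  if (mean(draws) == 0) return(0.5)
  n <- length(draws)
  p_pos <- (sum(draws > 0) + 0.5 * sum(draws == 0)) / n
  max(p_pos, 1 - p_pos)
}

#' Three-way significance classification of an effect
#'
#' `"significant"` iff the credible interval excludes zero;
#' `"pd_significant"` (potentially biologically meaningful direction) iff
#' not significant but pd strictly exceeds `pd_threshold`; otherwise
#' `"not_significant"`. A pd exactly at the threshold does not qualify.
#'
#' @param mean Posterior mean(s) (carried for reporting; not used by the
#'   rule).
#' @param lower,upper Interval endpoints.
#' @param pd Probability of direction.
#' @param pd_threshold Strict pd threshold; default 0.90.
#' @return Character vector of classes.
#' @export
classify_effect <- function(mean, lower, upper, pd, pd_threshold = 0.90) {
  stopifnot(all(lower <= upper))
  significant <- lower > 0 | upper < 0
  ifelse(significant, "significant",
         ifelse(pd > pd_threshold, "pd_significant", "not_significant"))
}

.summarize_draws <- function(draws, level, pd_threshold) {
  ci <- equal_tailed_interval(draws, level)
  pd <- probability_of_direction(draws)
  m <- mean(draws)
  data.frame(mean = m, lower = unname(ci[1L]), upper = unname(ci[2L]),
             pd = pd,
             class = classify_effect(m, ci[1L], ci[2L], pd, pd_threshold),
             stringsAsFactors = FALSE)
}

#' Effect summary table for a fit
#'
#' Posterior mean, equal-tailed interval, probability of direction and
#' significance class for each scalar parameter of the requested blocks
#' (by default the landscape coefficients `beta`).
#'
#' @param fit A `delt_draws` object.
#' @param parameters Parameter blocks to summarize; default `"beta"`.
#' @param level Interval mass; default 0.90.
#' @param pd_threshold Strict pd threshold for `"pd_significant"`.
#' @return Data frame with columns `parameter`, `mean`, `lower`, `upper`,
#'   `pd`, `class`.
#' @export
summarize_effects <- function(fit, parameters = "beta", level = 0.90,
                              pd_threshold = 0.90) {
  stopifnot(inherits(fit, "delt_draws"))
  missing_b <- setdiff(parameters, names(fit$parameters))
  if (length(missing_b) > 0L) {
    stop("parameter block(s) absent from fit: ",
         paste(missing_b, collapse = ", "), call. = FALSE)
  }
  m <- as_parameter_matrix(fit, parameters = parameters)
  out <- do.call(rbind, lapply(colnames(m), function(nm) {
    s <- .summarize_draws(m[, nm], level, pd_threshold)
    cbind(data.frame(parameter = nm, stringsAsFactors = FALSE), s)
  }))
  rownames(out) <- NULL
  out
}

.factor_block <- c(species = "eta", agency = "gamma", ecoregion = "phi")

#' Group occurrence probabilities from an unconditional fit
#'
#' For each level of the chosen factor, summarizes
#' `inverse_logit(beta0 + effect_level)` over draws, with the other
#' random-effect blocks held at zero (their prior means), plus a
#' population-average row summarizing `inverse_logit(beta0)`.
#'
#' @param fit A `delt_draws` object whose spec includes the factor.
#' @param factor `"species"`, `"agency"` or `"ecoregion"`.
#' @param level Interval mass; default 0.90.
#' @return Data frame with one row per level plus a `"(population)"` row;
#'   columns `level`, `mean`, `lower`, `upper`, `pd`, `class` on the
#'   probability scale.
#' @export
group_probability_table <- function(fit, factor = c("species", "agency",
                                                    "ecoregion"),
                                    level = 0.90) {
  stopifnot(inherits(fit, "delt_draws"))
  factor <- match.arg(factor)
  block <- .factor_block[[factor]]
  if (is.null(fit$parameters[[block]])) {
    stop("factor '", factor, "' absent from the fitted spec", call. = FALSE)
  }
  b0 <- as.numeric(fit$parameters$beta0)
  eff <- fit$parameters[[block]]
  levels <- dimnames(eff)[[3L]]
  rows <- lapply(seq_along(levels), function(j) {
    p <- inverse_logit(b0 + as.numeric(eff[, , j]))
    cbind(data.frame(level = levels[j], stringsAsFactors = FALSE),
          .summarize_draws(p, level, 0.90))
  })
  pop <- cbind(data.frame(level = "(population)", stringsAsFactors = FALSE),
               .summarize_draws(inverse_logit(b0), level, 0.90))
  out <- rbind(do.call(rbind, rows), pop)
  rownames(out) <- NULL
  out
}

#' Single-predictor posterior response curve
#'
#' Predicted probability of DELT occurrence as a function of one landscape
#' predictor, in its original units, with all other predictors held at
#' their study means (zero on the standardized scale) and random effects
#' at zero: per grid point the draws of
#' `inverse_logit(beta0 + beta_f * z(g))` are summarized by their mean and
#' equal-tailed band.
#'
#' @param fit A conditional-variant `delt_draws` object.
#' @param predictor Name of a fitted predictor.
#' @param grid Numeric grid of predictor values in original units.
#' @param transform Standardization record mapping the grid onto the
#'   fitted scale; defaults to the record stored with the fit.
#' @param level Band mass; default 0.90.
#' @return Data frame with columns `predictor`, `value`, `mean`, `lower`,
#'   `upper`.
#' @export
prediction_curve <- function(fit, predictor, grid, transform = NULL,
                             level = 0.90) {
  stopifnot(inherits(fit, "delt_draws"))
  if (is.null(fit$parameters$beta) ||
      !(predictor %in% dimnames(fit$parameters$beta)[[3L]])) {
    stop("unknown predictor '", predictor, "': not among fitted predictors",
         call. = FALSE)
  }
  transform <- transform %||% fit$transform
  if (is.null(transform)) {
    stop("no standardization transform available to map the grid",
         call. = FALSE)
  }
  z <- standardize_with(transform, grid, predictor)
  b0 <- as.numeric(fit$parameters$beta0)
  bf <- as.numeric(fit$parameters$beta[, , predictor])
  alpha <- (1 - level) / 2
  rows <- lapply(seq_along(grid), function(i) {
    p <- inverse_logit(b0 + bf * z[i])
    q <- quantile(p, c(alpha, 1 - alpha), names = FALSE, type = 7)
    data.frame(predictor = predictor, value = grid[i], mean = mean(p),
               lower = q[1L], upper = q[2L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
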