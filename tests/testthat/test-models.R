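test_that("inverse_logit is stable, symmetric and inverts logit", {
  expect_equal(inverse_logit(0), 0.5)
  x <- c(-40, -3.8918, -1, 0.5, 40)
  expect_equal(inverse_logit(x) + inverse_logit(-x), rep(1, length(x)))
  expect_equal(inverse_logit(-3.8918), 0.020, tolerance = 1e-3)
  expect_true(all(diff(inverse_logit(seq(-30, 30, by = 0.5))) > 0))
  p <- seq(0.001, 0.999, length.out = 101)
  expect_equal(inverse_logit(logit(p)), p, tolerance = 1e-12)
  expect_error(inverse_logit(Inf), "non-finite")
})

test_that("horseshoe shrunk scale follows the closed form and its limits", {
  expect_equal(horseshoe_shrunk_scale(1, 1, 1), 1 / 2)
  expect_equal(horseshoe_shrunk_scale(2, 3, 1), 9 / 37)
  # slab-dominated limit: lambda_tilde^2 -> lambda^2 as c -> infinity
  lt2 <- horseshoe_shrunk_scale(1, 3, 1e6)
  expect_lt(abs(lt2 - 9) / 9, 1e-6)
  expect_error(horseshoe_shrunk_scale(-1, 1, 1), "positive")

  # algebraic bound: lambda_tilde^2 <= min(lambda^2, c^2 / tau^2)
  set.seed(20)
  for (i in 1:200) {
    tau <- exp(rnorm(1)); lam <- exp(rnorm(1)); cc <- exp(rnorm(1))
    expect_lte(horseshoe_shrunk_scale(tau, lam, cc),
               min(lam^2, cc^2 / tau^2) + 1e-12)
  }
})

test_that("build_spec enforces variant structure", {
  sp <- paste0("s", 1:57); ag <- paste0("a", 1:7); ec <- paste0("e", 1:9)
  un <- build_spec("unconditional", sp, ag, ec)
  expect_equal(un$P, 0L)
  expect_equal(c(un$S, un$K, un$R), c(57L, 7L, 9L))

  cond <- build_spec("conditional", sp, ag, ec,
                     predictors = sprintf("x%02d", 1:46))
  expect_equal(cond$P, 46L)

  ss <- build_spec("species_specific", species = "s1", agencies = ag,
                   ecoregions = ec, predictors = c("x1", "x2"))
  expect_false(ss$has_species_effect)
  expect_equal(ss$S, 0L)

  expect_error(build_spec("unconditional", sp, ag, ec, predictors = "x1"),
               "no predictors")
  expect_error(build_spec("conditional", sp, ag, ec), "requires predictors")
  expect_error(build_spec("species_specific", species = c("s1", "s2"),
                          agencies = ag, ecoregions = ec,
                          predictors = "x1"),
               "single species")
})

test_that("joint_log_density reduces to log(0.5) for the null single case", {
  obs <- data.frame(stream_id = "s", species = "sp", agency = "a",
                    ecoregion = "e", year = 2010L, delt = 1L)
  spec <- build_spec("unconditional", "sp", "a", "e")
  data <- assemble_model_data(spec, obs)
  pt <- list(beta0 = 0, gamma = 0, phi = 0, eta = 0,
             sigma_agency = 1, sigma_region = 1, sigma_species = 1)
  lp <- joint_log_density(spec, data, pt)
  # likelihood contribution is exactly log(0.5); priors are the remainder
  prior <- dnorm(0, 0, 5, log = TRUE) +
    3 * dnorm(0, 0, 1, log = TRUE) +
    3 * (log(2) + dcauchy(1, 0, 2.5, log = TRUE))
  expect_equal(lp, log(0.5) + prior, tolerance = 1e-12)
})

test_that("joint_log_density matches the naive summation oracle", {
  set.seed(21)
  for (variant in c("unconditional", "conditional", "species_specific")) {
    sim <- small_sim(seed = 30 + match(variant, c("unconditional",
                                                  "conditional",
                                                  "species_specific")))
    obs <- sim$observations[1:50, ]
    if (variant == "species_specific") {
      obs$species <- obs$species[1]
    }
    preds <- if (variant != "unconditional") names(sim$predictors)[-1]
    spec <- build_spec(variant,
                       species = if (variant == "species_specific")
                         obs$species[1] else sort(unique(obs$species)),
                       agencies = sort(unique(obs$agency)),
                       ecoregions = sort(unique(obs$ecoregion)),
                       predictors = preds %||% character(0))
    data <- assemble_model_data(spec, obs,
                                if (spec$P > 0) sim$predictors)
    for (rep in 1:5) {
      pt <- random_point(spec)
      expect_equal(joint_log_density(spec, data, pt),
                   joint_density_oracle(spec, data, pt),
                   tolerance = 1e-10)
    }
  }
})

test_that("non-conforming parameter points are rejected", {
  obs <- tiny_observations()
  spec <- build_spec("unconditional", c("A", "B"), "ag1", "e1")
  data <- assemble_model_data(spec, obs)
  pt <- list(beta0 = 0, beta = 0.5, gamma = 0, phi = 0, eta = c(0, 0),
             sigma_agency = 1, sigma_region = 1, sigma_species = 1)
  expect_error(joint_log_density(spec, data, pt), "beta")
  pt$beta <- NULL
  pt$sigma_agency <- -1
  expect_error(joint_log_density(spec, data, pt), "positive")
})

test_that("flipping an outcome against a concordant predictor lowers it", {
  sim <- small_sim(seed = 33)
  obs <- sim$observations[1:40, ]
  spec <- build_spec("unconditional", sort(unique(obs$species)),
                     sort(unique(obs$agency)),
                     sort(unique(obs$ecoregion)))
  data <- assemble_model_data(spec, obs)
  pt <- list(beta0 = 3, gamma = rep(0, spec$K), phi = rep(0, spec$R),
             eta = rep(0, spec$S), sigma_agency = 1, sigma_region = 1,
             sigma_species = 1)
  data1 <- data; data1$y[1] <- 1L
  data0 <- data; data0$y[1] <- 0L
  # beta0 = 3 strongly favours y = 1, so flipping to 0 lowers the density
  expect_gt(joint_log_density(spec, data1, pt),
            joint_log_density(spec, data0, pt))
})

test_that("with tiny sigmas and zero effects only the intercept remains", {
  sim <- small_sim(seed = 34)
  obs <- sim$observations[1:60, ]
  spec <- build_spec("unconditional", sort(unique(obs$species)),
                     sort(unique(obs$agency)), sort(unique(obs$ecoregion)))
  data <- assemble_model_data(spec, obs)
  b0 <- -0.7
  pt <- list(beta0 = b0, gamma = rep(0, spec$K), phi = rep(0, spec$R),
             eta = rep(0, spec$S), sigma_agency = 1e-6, sigma_region = 1e-6,
             sigma_species = 1e-6)
  lp <- joint_log_density(spec, data, pt)
  bern <- sum(data$y * b0 - log1p(exp(b0)))
  consts <- dnorm(b0, 0, 5, log = TRUE) +
    (spec$K + spec$R + spec$S) * dnorm(0, 0, 1e-6, log = TRUE) +
    3 * (log(2) + dcauchy(1e-6, 0, 2.5, log = TRUE))
  expect_equal(lp, bern + consts, tolerance = 1e-8)
})

test_that("sampler-space gradient matches finite differences", {
  sim <- small_sim(seed = 35)
  preds <- names(sim$predictors)[-1]
  built <- assemble_from_sim(sim, "conditional", predictors = preds)
  for (par in c("non_centered", "centered")) {
    cfg <- sampler_config(chains = 2, warmup = 10, sampling = 10, seed = 1,
                          parameterization = par)
    cpp_data <- deltscape:::.pack_cpp_data(built$spec, built$data, cfg)
    D <- 1 + 2 * built$spec$P + 2 + built$spec$K + 1 + built$spec$R + 1 +
      built$spec$S + 1
    set.seed(36)
    th <- rnorm(D, 0, 0.4)
    res <- deltscape:::.delt_logp_grad_cpp(cpp_data, th)
    num <- vapply(seq_len(D), function(d) {
      h <- 1e-6
      tp <- th; tp[d] <- tp[d] + h
      tm <- th; tm[d] <- tm[d] - h
      (deltscape:::.delt_logp_grad_cpp(cpp_data, tp)$lp -
         deltscape:::.delt_logp_grad_cpp(cpp_data, tm)$lp) / (2 * h)
    }, numeric(1))
    expect_equal(as.numeric(res$grad), num, tolerance = 1e-5)
  }
})
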