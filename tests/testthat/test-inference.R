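test_that("sampler config validates its contract", {
  expect_error(sampler_config(chains = 1), "chains")
  expect_error(sampler_config(sampling = 0), "draws")
  expect_error(sampler_config(target_accept = 1.2), "target_accept")
})

test_that("intercept-only fit recovers a symmetric prevalence", {
  set.seed(50)
  y <- rbinom(2000, 1, 0.5)
  obs <- data.frame(stream_id = "s", species = "sp", agency = "a",
                    ecoregion = "e", year = 2010L, delt = y)
  spec <- build_spec("intercept_only")
  data <- assemble_model_data(spec, obs)
  fit <- sample_posterior(spec, data,
                          sampler_config(chains = 2, warmup = 300,
                                         sampling = 300, seed = 51))
  p_hat <- mean(inverse_logit(as.numeric(fit$parameters$beta0)))
  expect_lt(abs(p_hat - 0.5), 0.03)
})

test_that("identical seed, config and data reproduce identical draws", {
  sim <- small_sim(seed = 52)
  built <- assemble_from_sim(sim, "unconditional")
  cfg <- sampler_config(chains = 2, warmup = 150, sampling = 100, seed = 7)
  f1 <- sample_posterior(built$spec, built$data, cfg)
  f2 <- sample_posterior(built$spec, built$data, cfg)
  expect_identical(f1$parameters, f2$parameters)
  f3 <- sample_posterior(built$spec, built$data,
                         sampler_config(chains = 2, warmup = 150,
                                        sampling = 100, seed = 8))
  expect_false(identical(f1$parameters$beta0, f3$parameters$beta0))
})

test_that("an all-zero outcome vector warns but completes", {
  obs <- data.frame(stream_id = "s", species = "sp", agency = "a",
                    ecoregion = "e", year = 2010L,
                    delt = rep(0L, 100))
  spec <- build_spec("intercept_only")
  data <- assemble_model_data(spec, obs)
  expect_warning(
    fit <- sample_posterior(spec, data,
                            sampler_config(chains = 2, warmup = 150,
                                           sampling = 100, seed = 9)),
    "degenerate outcome")
  expect_true(all(is.finite(fit$parameters$beta0)))
  expect_lt(mean(fit$parameters$beta0), 0)
})

test_that("centered and non-centered runs agree on population summaries", {
  sim <- small_sim(seed = 53)
  built <- assemble_from_sim(sim, "unconditional")
  f_nc <- sample_posterior(built$spec, built$data,
                           sampler_config(chains = 2, warmup = 400,
                                          sampling = 400, seed = 10))
  f_c <- sample_posterior(built$spec, built$data,
                          sampler_config(chains = 2, warmup = 400,
                                         sampling = 400, seed = 10,
                                         parameterization = "centered"))
  m_nc <- mean(f_nc$parameters$beta0)
  m_c <- mean(f_c$parameters$beta0)
  se <- sd(f_nc$parameters$beta0) /
    sqrt(ess_bulk(f_nc$parameters$beta0)) +
    sd(f_c$parameters$beta0) / sqrt(ess_bulk(f_c$parameters$beta0))
  expect_lt(abs(m_nc - m_c), 4 * se)
})

test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(54)
  good <- matrix(rnorm(2000), ncol = 2)
  r_good <- split_rhat(good)
  expect_gte(r_good, 0.99)
  expect_lte(r_good, 1.02)

  bad <- good
  bad[, 2] <- bad[, 2] + 10
  expect_gt(split_rhat(bad), 1.5)
  expect_error(split_rhat(matrix(rnorm(100), ncol = 1)), "2 chains")
})

test_that("split R-hat agrees with a direct variance-ratio computation", {
  set.seed(55)
  x <- matrix(rnorm(800, sd = 2), ncol = 4) +
    matrix(rep(c(0, 0.3, -0.2, 0.1), each = 200), ncol = 4)
  # direct textbook formula on split halves, written independently
  half <- 100
  chains <- do.call(cbind, lapply(1:4, function(k) {
    cbind(x[1:half, k], x[(half + 1):(2 * half), k])
  }))
  m <- ncol(chains); n <- nrow(chains)
  W <- mean(apply(chains, 2, var))
  B <- n * var(colMeans(chains))
  oracle <- sqrt(((n - 1) / n * W + B / n) / W)
  expect_equal(split_rhat(x), oracle, tolerance = 1e-8)
})

test_that("ESS is near nominal for independent draws, small for sticky ones", {
  set.seed(56)
  iid <- matrix(rnorm(4000), ncol = 4)
  expect_gt(ess_bulk(iid), 2000)
  walk <- matrix(0, 1000, 4)
  for (k in 1:4) walk[, k] <- cumsum(rnorm(1000)) / 30
  expect_lt(ess_bulk(walk), 400)
})

test_that("check_convergence flags rather than hides bad fits", {
  sim <- small_sim(seed = 57)
  built <- assemble_from_sim(sim, "unconditional")
  fit <- sample_posterior(built$spec, built$data,
                          sampler_config(chains = 2, warmup = 200,
                                         sampling = 150, seed = 11))
  rep <- check_convergence(fit, ess_min = 10^6)   # unattainable ESS gate
  expect_false(rep$pass)
  expect_true(all(c("parameter", "rhat", "ess_bulk") %in%
                    names(rep$summary)))
  # draws survive the failing verdict
  expect_equal(dim(fit$parameters$beta0), c(150L, 2L))
})
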