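test_that("equal-tailed intervals follow the declared quantile rule", {
  expect_equal(equal_tailed_interval(rep(3.5, 10)),
               c(lower = 3.5, upper = 3.5))

  set.seed(60)
  v <- rnorm(500)
  expect_equal(equal_tailed_interval(v), equal_tailed_interval(sample(v)))

  # sort-and-interpolate oracle on 1..1000 at level 0.90:
  # type-7 index h = (n-1)p + 1 on the sorted values
  draws <- 1:1000
  h_lo <- (1000 - 1) * 0.05 + 1
  h_hi <- (1000 - 1) * 0.95 + 1
  oracle <- c(floor(h_lo) + (h_lo - floor(h_lo)),
              floor(h_hi) + (h_hi - floor(h_hi)))
  ci <- equal_tailed_interval(draws, 0.90)
  expect_equal(unname(ci), oracle)

  expect_error(equal_tailed_interval(1), "2 finite")
  expect_error(equal_tailed_interval(1:10, level = 1), "level")
})

test_that("probability of direction counts signed draws", {
  expect_equal(probability_of_direction(c(0.2, 1, 3)), 1.0)
  expect_equal(probability_of_direction(c(-1, 1)), 0.5)
  expect_equal(probability_of_direction(c(-1, 1, 2, 3)), 0.75)
  # zeros count half toward each side
  expect_equal(probability_of_direction(c(0, 1, 1, 1)), 0.875)
  # invariant to positive rescaling, bounded by [0.5, 1]
  set.seed(61)
  for (i in 1:50) {
    d <- rnorm(40, mean = runif(1, -1, 1))
    pd <- probability_of_direction(d)
    expect_gte(pd, 0.5); expect_lte(pd, 1)
    expect_equal(probability_of_direction(3.7 * d), pd)
  }
})

test_that("three-way classification uses strict boundaries", {
  expect_equal(classify_effect(0.5, 0.2, 0.9, 0.99), "significant")
  expect_equal(classify_effect(0.1, -0.1, 0.4, 0.93), "pd_significant")
  expect_equal(classify_effect(0, -0.3, 0.3, 0.80), "not_significant")
  # pd exactly at the threshold does not qualify
  expect_equal(classify_effect(0.1, -0.1, 0.4, 0.90), "not_significant")
  # an interval touching zero at an endpoint still contains zero
  expect_equal(classify_effect(0.2, 0, 0.4, 0.95), "pd_significant")
})

test_that("interval excluding zero with one-signed draws implies pd = 1", {
  set.seed(62)
  for (i in 1:20) {
    d <- abs(rnorm(200)) + 0.01
    ci <- equal_tailed_interval(d)
    expect_gt(ci["lower"], 0)
    expect_equal(probability_of_direction(d), 1.0)
  }
})

test_that("group probabilities equal transform-then-summarize composition", {
  set.seed(63)
  b0 <- matrix(rnorm(400, -2, 0.3), ncol = 2)
  eta <- array(rnorm(400 * 3, 0, 0.5), dim = c(200, 2, 3))
  fit <- fake_draws(b0, eta = eta, species = c("spA", "spB", "spC"))
  tab <- group_probability_table(fit, "species")
  expect_equal(nrow(tab), 4L)
  for (j in 1:3) {
    p <- inverse_logit(as.numeric(b0) + as.numeric(eta[, , j]))
    ci <- equal_tailed_interval(p)
    row <- tab[j, ]
    expect_equal(row$mean, mean(p), tolerance = 1e-12)
    expect_equal(c(row$lower, row$upper), unname(ci), tolerance = 1e-12)
    expect_equal(row$pd, probability_of_direction(p), tolerance = 1e-12)
  }
  pop <- tab[tab$level == "(population)", ]
  expect_equal(pop$mean, mean(inverse_logit(as.numeric(b0))),
               tolerance = 1e-12)
  expect_true(all(tab$mean > 0 & tab$mean < 1))
  expect_error(group_probability_table(fit, "agency"), "absent")
})

test_that("all-zero species effects collapse every row to the population", {
  b0 <- matrix(rnorm(200, -1, 0.2), ncol = 2)
  eta <- array(0, dim = c(100, 2, 3))
  fit <- fake_draws(b0, eta = eta, species = c("a", "b", "c"))
  tab <- group_probability_table(fit, "species")
  pop <- tab[tab$level == "(population)", ]
  for (j in 1:3) {
    expect_equal(tab$mean[j], pop$mean)
    expect_equal(tab$lower[j], pop$lower)
  }
})

test_that("response curves respect degeneracy, monotonicity and nesting", {
  set.seed(64)
  n <- 300
  b0 <- matrix(rnorm(2 * n, -2, 0.3), ncol = 2)
  transform <- data.frame(predictor = "temp", mean = 10, sd = 4)
  grid <- seq(2, 18, length.out = 9)

  # flat curve at inverse_logit(beta0) when the coefficient is zero
  beta <- array(0, dim = c(n, 2, 1))
  fit <- fake_draws(b0, beta = beta, predictors = "temp")
  fit$transform <- transform
  curve0 <- prediction_curve(fit, "temp", grid)
  expect_equal(curve0$mean,
               rep(mean(inverse_logit(as.numeric(b0))), length(grid)),
               tolerance = 1e-12)

  # one-signed coefficient draws give a strictly monotone mean curve
  beta_pos <- array(abs(rnorm(2 * n, 0.8, 0.2)), dim = c(n, 2, 1))
  fit_pos <- fake_draws(b0, beta = beta_pos, predictors = "temp")
  fit_pos$transform <- transform
  curve <- prediction_curve(fit_pos, "temp", grid)
  expect_true(all(diff(curve$mean) > 0))
  expect_true(all(curve$lower <= curve$mean & curve$mean <= curve$upper))
  expect_true(all(curve$mean > 0 & curve$mean < 1))

  # grid point at the standardized mean equals the population composition
  mid <- prediction_curve(fit_pos, "temp", 10)
  expect_equal(mid$mean, mean(inverse_logit(as.numeric(b0))),
               tolerance = 1e-12)

  # 50% band nests inside the 90% band at every grid point
  c50 <- prediction_curve(fit_pos, "temp", grid, level = 0.50)
  c90 <- prediction_curve(fit_pos, "temp", grid, level = 0.90)
  expect_true(all(c90$lower <= c50$lower & c50$upper <= c90$upper))

  expect_error(prediction_curve(fit_pos, "nope", grid), "unknown predictor")
})
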