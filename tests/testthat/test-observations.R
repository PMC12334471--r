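test_that("reading preserves rows and honours the schema map", {
  obs <- tiny_observations()
  path <- withr::local_tempfile(fileext = ".csv")
  write_fish_observations(obs, path)
  out <- read_fish_observations(path)
  expect_equal(nrow(out$observations), nrow(obs))
  expect_null(out$anomalies)
  # delt taken verbatim in passthrough mode
  expect_identical(out$observations$delt, obs$delt)

  # renamed columns resolved through the schema
  renamed <- obs
  names(renamed)[names(renamed) == "species"] <- "taxon"
  write.csv(renamed, path, row.names = FALSE)
  out2 <- read_fish_observations(path, delt_schema(species = "taxon"))
  expect_identical(out2$observations$species, obs$species)
})

test_that("round trip through CSV yields an identical collection", {
  sim <- small_sim()
  path <- withr::local_tempfile(fileext = ".csv")
  write_fish_observations(sim$observations, path)
  back <- read_fish_observations(path)$observations
  ord <- function(d) d[do.call(order, d), ]
  expect_equal(ord(back), ord(sim$observations), ignore_attr = TRUE)
})

test_that("schema errors name the missing column", {
  obs <- tiny_observations()
  obs$species <- NULL
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(obs, path, row.names = FALSE)
  expect_error(read_fish_observations(path), "species")
})

test_that("row-level parse failures report the row", {
  obs <- tiny_observations()
  obs$year <- as.character(obs$year)
  obs$year[3] <- "not-a-year"
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(obs, path, row.names = FALSE)
  expect_error(read_fish_observations(path), "row 3")

  obs2 <- tiny_observations()
  obs2$delt[5] <- 7L
  write.csv(obs2, path, row.names = FALSE)
  expect_error(read_fish_observations(path), "row 5")
})

test_that("anomaly flag columns are parsed and returned aligned", {
  obs <- tiny_observations()
  obs$delt <- NULL
  obs$par <- c("present", "absent", "not_assessed", "absent",
               "present", "absent", "absent", "absent")
  obs$les <- c(0, 0, 1, 0, NA, 0, 0, 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(obs, path, row.names = FALSE)
  out <- read_fish_observations(
    path, delt_schema(anomalies = c(parasite = "par", lesion = "les")))
  expect_true(all(is.na(out$observations$delt)))
  expect_equal(out$anomalies$parasite[1], "present")
  expect_equal(out$anomalies$lesion[5], "not_assessed")
  expect_equal(nrow(out$anomalies), nrow(out$observations))
})

test_that("study-window filtering is inclusive at both ends", {
  obs <- tiny_observations()[1:4, ]
  obs$year <- c(2007L, 2008L, 2019L, 2020L)
  out <- filter_observation_window(obs, 2008, 2019)
  expect_setequal(out$year, c(2008L, 2019L))

  expect_equal(nrow(filter_observation_window(obs[0, ], 2008, 2019)), 0L)

  obs2 <- obs[1:2, ]; obs2$year <- c(2008L, 2008L)
  expect_equal(nrow(filter_observation_window(obs2, 2008, 2008)), 2L)

  expect_error(filter_observation_window(obs, 2019, 2008), "inverted")
})

crosswalk_fixture <- function() {
  rbind(
    expand.grid(agency = "padep",
                category = c("deformity", "erosion", "lesion", "tumor",
                             "parasite"),
                counted = TRUE, stringsAsFactors = FALSE),
    data.frame(agency = "epa",
               category = c("deformity", "erosion", "lesion", "tumor",
                            "parasite"),
               counted = c(TRUE, TRUE, TRUE, TRUE, FALSE),
               stringsAsFactors = FALSE))
}

test_that("crosswalk counts only present flags of counted categories", {
  cw <- crosswalk_fixture()
  none <- data.frame(parasite = "absent", lesion = "absent",
                     stringsAsFactors = FALSE)
  expect_equal(crosswalk_anomalies(none, "padep", cw), 0L)

  par_only <- data.frame(parasite = "present", lesion = "absent",
                         stringsAsFactors = FALSE)
  # most agencies count external parasites ...
  expect_equal(crosswalk_anomalies(par_only, "padep", cw), 1L)
  # ... but an agency whose protocol excludes them yields 0
  expect_equal(crosswalk_anomalies(par_only, "epa", cw), 0L)

  not_assessed <- data.frame(parasite = "not_assessed", lesion = "present",
                             stringsAsFactors = FALSE)
  expect_equal(crosswalk_anomalies(not_assessed, "epa", cw), 1L)

  expect_error(crosswalk_anomalies(par_only, "unknown_agency", cw),
               "unknown_agency")
  bad <- rbind(cw, data.frame(agency = "padep", category = "gill",
                              counted = TRUE))
  expect_error(crosswalk_anomalies(par_only, "padep", bad), "gill")
})

test_that("adding a present flag never flips DELT from 1 to 0", {
  cw <- crosswalk_fixture()
  set.seed(1)
  states <- c("present", "absent", "not_assessed")
  for (rep in 1:50) {
    flags <- data.frame(deformity = sample(states, 1),
                        erosion = sample(states, 1),
                        parasite = sample(states, 1),
                        stringsAsFactors = FALSE)
    ag <- sample(c("padep", "epa"), 1)
    before <- crosswalk_anomalies(flags, ag, cw)
    upgraded <- flags
    col <- sample(names(flags), 1)
    upgraded[[col]] <- "present"
    after <- crosswalk_anomalies(upgraded, ag, cw)
    expect_gte(after, before)
  }
})

test_that("naive prevalence matches direct counting and conserves counts", {
  obs <- tiny_observations()
  overall <- compute_naive_prevalence(obs, "overall")
  expect_equal(overall$n_inspected, 8L)
  expect_equal(overall$n_delt, 2L)
  expect_equal(overall$prevalence, 0.25)

  by_sp <- compute_naive_prevalence(obs, "species")
  # groups {A: 2 of 10, B: 0 of 5} style counting oracle
  expect_equal(by_sp$prevalence[by_sp$group == "A"], 2 / 4)
  expect_equal(by_sp$prevalence[by_sp$group == "B"], 0)
  # conservation over species
  expect_equal(sum(by_sp$n_delt), overall$n_delt)
  expect_equal(sum(by_sp$n_inspected), overall$n_inspected)
  by_st <- compute_naive_prevalence(obs, "stream")
  expect_equal(sum(by_st$n_inspected), overall$n_inspected)

  zero <- obs; zero$delt <- 0L
  expect_equal(compute_naive_prevalence(zero, "overall")$prevalence, 0)

  expect_error(compute_naive_prevalence(obs[0, ], "overall"), "empty")
})

test_that("focal species rule: prevalence inclusive, sample size strict", {
  summaries <- data.frame(
    group = c("channel_catfish", "common_but_rare_delt", "boundary_n",
              "good"),
    n_inspected = c(888L, 10000L, 100L, 5000L),
    n_delt = c(168L, 490L, 6L, 400L),
    prevalence = c(0.189, 0.049, 0.06, 0.08),
    stringsAsFactors = FALSE)
  out <- select_focal_species(summaries)
  expect_true("channel_catfish" %in% out)      # 18.9%, n = 888
  expect_false("common_but_rare_delt" %in% out) # below 5% prevalence
  expect_false("boundary_n" %in% out)           # n = 100 is not > 100
  expect_true("good" %in% out)

  shuffled <- summaries[c(3, 1, 4, 2), ]
  expect_identical(select_focal_species(shuffled), out)
  expect_identical(select_focal_species(summaries[0, ]), character(0))
})
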