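test_that("the packaged layouts reproduce the study structure", {
  fx <- study_layout_fixtures()
  expect_named(fx, c("office", "residential"))
  expect_length(validate_topology(fx$office), 0)
  expect_length(validate_topology(fx$residential), 0)

  oz <- fx$office$zones
  expect_equal(oz[["office-low"]]$served_floors, c(6L, 23L))
  expect_equal(oz[["office-high"]]$served_floors, c(24L, 34L))
  expect_equal(fx$office$tanks$T1$floor_index, -2L)
  expect_equal(fx$office$tanks$T2$floor_index, 23L)
  # riser legs: 23 - (-2) = 25 storeys to the mechanical floor, then 11 up
  expect_equal(oz[["office-low"]]$entry_floor - fx$office$tanks$T1$floor_index, 25L)
  expect_equal(oz[["office-high"]]$entry_floor - fx$office$tanks$T2$floor_index, 11L)

  rz <- fx$residential$zones
  expect_equal(rz[["res-low"]]$served_floors, c(3L, 30L))
  expect_equal(rz[["res-high"]]$served_floors, c(31L, 45L))
  expect_equal(fx$residential$tanks$T3$floor_index, 30L)
})

test_that("demand draws are reproducible and stay inside their bands", {
  d1 <- sample_demands(6:20, rep(c("low", "high"), length.out = 15), seed = 99)
  d2 <- sample_demands(6:20, rep(c("low", "high"), length.out = 15), seed = 99)
  expect_identical(d1, d2)
  expect_true(all(d1$tonnes_per_month[d1$band == "low"] >= 1 &
                    d1$tonnes_per_month[d1$band == "low"] <= 5))
  expect_true(all(d1$tonnes_per_month[d1$band == "high"] >= 10 &
                    d1$tonnes_per_month[d1$band == "high"] <= 14))
  expect_equal(d1$demand, demand_from_monthly(d1$tonnes_per_month))
  expect_error(sample_demands(integer(0), "low", 1), class = "swsshrt_invalid_input")

  big <- sample_demands(seq_len(1e4), "low", seed = 5)
  expect_equal(mean(big$tonnes_per_month), 3.0, tolerance = 0.02)
})

test_that("noise calibration hits the requested population R-squared", {
  x <- c(1, 2, 4, 7, 11)
  expect_equal(calibrate_noise_sd(2, x, 0.5)^2, 4 * var(x))
  expect_lt(calibrate_noise_sd(2, x, 1 - 1e-12), 1e-4)
  expect_error(calibrate_noise_sd(2, rep(3, 5), 0.5), class = "swsshrt_calibration")
  expect_error(calibrate_noise_sd(2, x, 1.2), class = "swsshrt_calibration")

  # simulation check at large n: sample R2 lands near the target
  set.seed(123)
  xs <- runif(1e4, 0, 10)
  sd <- calibrate_noise_sd(0.35, xs, 0.63)
  ys <- 0.35 * xs + rnorm(1e4, 0, sd)
  expect_equal(linfit(xs, ys)$r2, 0.63, tolerance = 0.035)
})

test_that("observation generation is deterministic per master seed", {
  office <- office_topology()
  p <- generator_params(seed = 42)
  o1 <- generate_observations(office, p)
  o2 <- generate_observations(office, p)
  expect_identical(o1, o2)
  o3 <- generate_observations(office, generator_params(seed = 43))
  expect_false(identical(o1$log10_16s, o3$log10_16s))

  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_observations(o1, f1, params = p)
  write_observations(o2, f2, params = p)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(file.exists(paste0(f1, ".params.yaml")))
})

test_that("observations carry labels consistent with the topology", {
  office <- office_topology()
  obs <- generate_observations(office, generator_params(seed = 7))
  expect_identical(nrow(obs), 29L)
  expect_setequal(obs$floor, 6:34)
  expect_true(all(obs$functional_area == "office"))
  expect_identical(obs$supply_label,
                   ifelse(obs$floor <= 23, "swss-first", "swss-second"))
  expect_true(all(obs$consumption_band %in% c("low", "high")))
  expect_true(all(obs$fe >= 0 & obs$zn >= 0 & obs$cu >= 0))
  expect_true(all(is.finite(obs$log10_16s)))
})

test_that("vanishing noise makes the 16S response an exact line in HRT", {
  office <- office_topology()
  p <- generator_params(seed = 3, target_r2_16s = 1 - 1e-12)
  obs <- generate_observations(office, p)
  expect_equal(linfit(obs$hrt_h, obs$log10_16s)$r2, 1, tolerance = 1e-6)
})

test_that("upper-zone taps carry more bacteria than lower-zone taps on average", {
  office <- office_topology()
  obs <- generate_observations(office, generator_params(seed = 11))
  expect_gt(mean(obs$log10_16s[obs$supply_label == "swss-second"]),
            mean(obs$log10_16s[obs$supply_label == "swss-first"]))
})

test_that("metal levels reflect pipe and tap materials", {
  p <- generator_params(seed = 21)
  office <- generate_observations(office_topology(), p)
  res <- generate_observations(residential_topology(), p)
  # galvanized office pipes shed Zn; residential brass taps shed Cu
  expect_gt(mean(office$zn), mean(res$zn))
  expect_gt(mean(res$cu), mean(office$cu))
})

test_that("a fully stagnant building cannot be sampled", {
  dead <- toy_single_zone(n_floors = 2, demand = 0)
  expect_error(generate_observations(dead, generator_params(seed = 1),
                                     resample_demands = FALSE),
               class = "swsshrt_generation")
})

test_that("replicated fits recover the generator slope without bias", {
  office <- office_topology()
  n_rep <- 200
  slopes <- vapply(seq_len(n_rep), function(i) {
    obs <- generate_observations(office, generator_params(seed = 5000 + i))
    linfit(obs$hrt_h, obs$log10_16s)$slope
  }, 0)
  bias <- mean(slopes) - 0.35
  mc_se <- sd(slopes) / sqrt(n_rep)
  expect_lt(abs(bias), 2 * mc_se + 1e-12)
})
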