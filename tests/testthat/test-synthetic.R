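test_that("default landscape matches the sampling design", {
  b <- generate_landscape(synthetic_config(), seed = 1)
  expect_equal(nrow(b$plots), 80L)
  expect_equal(unname(as.vector(table(b$plots$ground_state,
                                      b$plots$polygon_feature))), rep(20L, 4))
  expect_equal(sum(b$plots$flooded), 5L)
  expect_equal(ncol(b$cover) - 1L, 22L)
  expect_equal(length(unique(b$plots$transect_id)), 5L)
  # five species unique to each ground state
  cov <- as.matrix(b$cover[, -1])
  gs <- b$plots$ground_state
  in_ctrl <- colSums(cov[gs == "control", ]) > 0
  in_tk <- colSums(cov[gs == "thermokarst", ]) > 0
  expect_equal(sum(in_ctrl & !in_tk), 5L)
  expect_equal(sum(in_tk & !in_ctrl), 5L)
  # dominant species: widespread and high cover
  expect_gt(mean(cov[, "salix_arctica"] > 0), 0.6)
  expect_gt(mean(cov[cov[, "salix_arctica"] > 0, "salix_arctica"]), 45)
})

test_that("generation is deterministic given (config, seed)", {
  cfg <- scenario_config("paper_like")
  b1 <- generate_landscape(cfg, seed = 33)
  b2 <- generate_landscape(cfg, seed = 33)
  expect_identical(b1[c("plots", "cover", "phenology", "temperature")],
                   b2[c("plots", "cover", "phenology", "temperature")])
  b3 <- generate_landscape(cfg, seed = 34)
  expect_false(identical(b1$temperature$temp_c, b3$temperature$temp_c))
})

test_that("all effects and noise at zero collapse the landscape", {
  cfg <- synthetic_config(
    state_effect_c = 0, feature_effect_c = 0, interaction_effect_c = 0,
    plot_temp_sd = 0, hourly_noise_sd = 0, pheno_noise_sd = 0,
    species_threshold_sd = 0, moisture_threshold_slope = 0,
    flower_obs_prob = 1, habitat_shift_days = matrix(0, 2, 2),
    transect_date_sd = 0
  )
  b <- suppressMessages(filter_flooded(generate_landscape(cfg, seed = 8)))
  tdd <- thaw_degree_days(daily_means(b$temperature))
  expect_lt(diff(range(tdd$tdd)), 1e-9)
  dates <- tapply(b$phenology$julian_date, b$phenology$phenophase,
                  function(x) length(unique(x)))
  expect_true(all(dates == 1))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_per_cell = 0), "counts")
  expect_error(synthetic_config(dominant_occupancy = 1.4), "occupancy")
  expect_error(synthetic_config(pheno_noise_sd = -1), "sds")
  expect_error(synthetic_config(n_flooded_troughs = 25), "n_flooded")
  expect_error(synthetic_config(n_unique_per_state = 12), "pool too small")
  expect_error(scenario_config("bogus"))
})

test_that("paper_like reproduces the thermal ordering and trough delays", {
  for (seed in c(2, 14, 27)) {
    b <- suppressMessages(filter_flooded(generate_landscape(
      scenario_config("paper_like"), seed = seed)))
    tdd <- dplyr::left_join(thaw_degree_days(daily_means(b$temperature)),
                            b$plots, by = "plot_id")
    cell <- tapply(tdd$tdd, list(tdd$ground_state, tdd$polygon_feature), mean)
    expect_gt(cell["control", "top"], cell["thermokarst", "top"])
    expect_gt(mean(cell[, "top"]), mean(cell[, "trough"]))
    cwm <- cwm_table(b)
    sp <- dplyr::left_join(
      dplyr::filter(cwm, variant == "specific", phenophase == "first_leaf_out"),
      b$plots, by = "plot_id")
    expect_gt(mean(sp$value[sp$polygon_feature == "trough"]),
              mean(sp$value[sp$polygon_feature == "top"]))
  }
})

test_that("configured thermal effects are recoverable from generated data", {
  cfg <- synthetic_config()
  diffs <- vapply(1:10, function(s) {
    b <- generate_landscape(cfg, seed = 100 + s)
    tdd <- dplyr::left_join(thaw_degree_days(daily_means(b$temperature)),
                            b$plots, by = "plot_id")
    top <- tdd[tdd$polygon_feature == "top", ]
    mean(top$tdd[top$ground_state == "control"]) -
      mean(top$tdd[top$ground_state == "thermokarst"])
  }, numeric(1))
  # state effect -1.1 degC/day over a 22-day all-positive window = 24.2 dd
  expected <- -cfg$state_effect_c * 22
  mc_se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - expected), 2 * mc_se + 1)
})

test_that("intraspecific_only scenario freezes composition", {
  b <- suppressMessages(filter_flooded(generate_landscape(
    scenario_config("intraspecific_only"), seed = 6)))
  cov <- as.matrix(b$cover[, -1])
  expect_true(all(apply(cov, 2, function(x) length(unique(x)) == 1)))
  cwm <- cwm_table(b)
  fx <- dplyr::filter(cwm, variant == "fixed", phenophase == "first_leaf_out")
  expect_lt(diff(range(fx$value)), 1e-9)
})
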