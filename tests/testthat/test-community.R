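test_that("relative abundance is total standardization", {
  cov <- tibble::tibble(plot_id = c("p1", "p2", "p3"),
                        A = c(60, 42, 1), B = c(30, 0, 1),
                        C = c(10, 0, 1), D = c(0, 0, 1))
  w <- relative_abundance(cov)
  expect_equal(unlist(w[1, -1], use.names = FALSE), c(0.6, 0.3, 0.1, 0))
  expect_equal(w$A[2], 1.0)
  expect_equal(unlist(w[3, -1], use.names = FALSE), rep(0.25, 4))
  bad <- cov
  bad[2, -1] <- 0
  expect_error(relative_abundance(bad), "all-zero")
})

test_that("specific CWM renormalizes weights over observed species", {
  expect_equal(specific_cwm(c(A = 0.75, B = 0.25), c(A = 180, B = 188)), 182.0)
  expect_equal(specific_cwm(c(A = 1), c(A = 185)), 185)
  # A:0.6, B:0.3 observed, C:0.1 unobserved -> weights (2/3, 1/3)
  expect_equal(specific_cwm(c(A = 0.6, B = 0.3, C = 0.1), c(A = 180, B = 190)),
               2 / 3 * 180 + 1 / 3 * 190)
  expect_true(is.na(specific_cwm(c(A = 0.5, B = 0.5), c(C = 180))))
})

test_that("fixed species means are unweighted site-wide averages", {
  ph <- tibble::tibble(plot_id = c("p1", "p2", "p3"),
                       species_id = c("A", "A", "B"),
                       phenophase = "first_leaf_out",
                       julian_date = c(180L, 184L, 190L))
  fm <- fixed_species_means(ph)
  expect_equal(fm$fixed_mean[fm$species_id == "A"], 182.0)
  expect_equal(fm$fixed_mean[fm$species_id == "B"], 190.0)
})

test_that("fixed CWM uses the same species set and weights as specific", {
  w <- c(A = 0.6, B = 0.3, C = 0.1)
  fm <- c(A = 182, B = 190, C = 195)
  # all species at their site means -> fixed == specific
  expect_equal(fixed_cwm(w, fm, observed = c("A", "B", "C")),
               specific_cwm(w, fm))
  # identical composition -> identical fixed CWM regardless of plot
  expect_equal(fixed_cwm(w, fm, observed = c("A", "B")),
               fixed_cwm(w, fm, observed = c("A", "B")))
  expect_equal(intraspecific_component(185.5, 183.0), 2.5)
  expect_equal(intraspecific_component(182.0, 182.0), 0.0)
})

test_that("cwm_table satisfies the identity and convexity invariants", {
  b <- suppressMessages(filter_flooded(generate_landscape(
    scenario_config("paper_like"), seed = 11)))
  cwm <- cwm_table(b)
  wide <- tidyr::pivot_wider(
    dplyr::select(cwm, plot_id, phenophase, variant, value),
    names_from = variant, values_from = value)
  expect_equal(wide$intraspecific, wide$specific - wide$fixed, tolerance = 1e-12)

  # convexity: specific CWM bounded by contributing species dates
  ph <- "first_open_flower"
  obs <- dplyr::filter(b$phenology, phenophase == ph)
  rng <- dplyr::summarise(dplyr::group_by(obs, plot_id),
                          lo = min(julian_date), hi = max(julian_date))
  sp <- dplyr::filter(cwm, variant == "specific", phenophase == ph)
  sp <- dplyr::left_join(sp, rng, by = "plot_id")
  expect_true(all(sp$value >= sp$lo - 1e-9 & sp$value <= sp$hi + 1e-9))
})

test_that("zero intraspecific structure forces a zero intraspecific component", {
  cfg <- synthetic_config(
    state_effect_c = 0, feature_effect_c = 0, interaction_effect_c = 0,
    plot_temp_sd = 0, hourly_noise_sd = 0, pheno_noise_sd = 0,
    species_threshold_sd = 0, moisture_threshold_slope = 0,
    flower_obs_prob = 1, habitat_shift_days = matrix(0, 2, 2)
  )
  b <- suppressMessages(filter_flooded(generate_landscape(cfg, seed = 3)))
  cwm <- cwm_table(b)
  intra <- dplyr::filter(cwm, variant == "intraspecific")
  expect_true(all(abs(intra$value) < 1e-9))
  # every species collapses to a single site-wide date
  by_sp <- tapply(b$phenology$julian_date,
                  paste(b$phenology$species_id, b$phenology$phenophase),
                  function(x) length(unique(x)))
  expect_true(all(by_sp == 1))
})

test_that("single-species extraction joins plot factors and errors when absent", {
  b <- suppressMessages(filter_flooded(generate_landscape(
    scenario_config("paper_like"), seed = 5)))
  sa <- extract_species_phenology(b, "salix_arctica", "first_leaf_out")
  expect_true(all(c("ground_state", "polygon_feature", "value") %in% names(sa)))
  occ <- mean(as.matrix(b$cover[, -1])[, "salix_arctica"] > 0)
  expect_gt(nrow(sa), 0.5 * nrow(b$plots))
  expect_gt(occ, 0.6)
  expect_error(extract_species_phenology(b, "nonexistent_sp", "first_leaf_out"),
               "no phenophase observations")
})
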