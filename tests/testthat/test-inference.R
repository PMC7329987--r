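test_that("transforms are elementwise with domain checks naming the plot", {
  expect_equal(apply_transform(c(4, 9), "sqrt"), c(2, 3))
  expect_equal(apply_transform(c(1.5, -2), "none"), c(1.5, -2))
  expect_equal(apply_transform(8, "ln"), log(8), tolerance = 1e-12)
  expect_error(apply_transform(c(4, -1), "sqrt", ids = c("p1", "p2")), "p2")
  expect_error(apply_transform(0, "ln"), "ln transform undefined")
})

test_that("type II SS match the brute-force nested-RSS oracle", {
  df <- balanced_toy()
  fit <- fit_two_way_type2(df)
  got <- setNames(fit$table$ss, fit$table$term)
  expect_equal(got, oracle_type2_two_way(df), tolerance = 1e-10)
  # classical balanced formulas: SS_A = 4*(mean_tk - mean)^2*2 etc.
  m <- mean(df$value)
  mA <- tapply(df$value, df$ground_state, mean)
  mB <- tapply(df$value, df$polygon_feature, mean)
  expect_equal(unname(got["ground_state"]), sum(4 * (mA - m)^2))
  expect_equal(unname(got["polygon_feature"]), sum(4 * (mB - m)^2))

  for (seed in 1:5) {
    d <- random_two_way(seed)
    f <- fit_two_way_type2(d)
    expect_equal(setNames(f$table$ss, f$table$term), oracle_type2_two_way(d),
                 tolerance = 1e-10)
  }
})

test_that("a purely additive response has zero interaction SS", {
  df <- tidyr::expand_grid(ground_state = c("control", "thermokarst"),
                           polygon_feature = c("top", "trough"),
                           rep = 1:3)
  df$value <- 180 + 2 * (df$ground_state == "thermokarst") +
    3 * (df$polygon_feature == "trough") + rep(c(-1, 0, 1), 4)
  f <- fit_two_way_type2(df)
  expect_equal(f$table$ss[f$table$term == "interaction"], 0, tolerance = 1e-10)
})

test_that("degenerate designs are rejected explicitly", {
  df <- balanced_toy()
  expect_error(fit_two_way_type2(dplyr::mutate(df, value = 5)), "constant")
  expect_error(fit_two_way_type2(dplyr::filter(df, !(ground_state == "control" &
                                                       polygon_feature == "top"))),
               "Empty design cell")
  one_level <- dplyr::mutate(df, ground_state = "control")
  expect_error(fit_two_way_type2(one_level), "does not vary")
})

test_that("EMM cell means equal raw cell means on balanced data", {
  df <- balanced_toy()
  emm <- estimated_marginal_means(fit_two_way_type2(df))
  raw <- aggregate(value ~ ground_state + polygon_feature, df, mean)
  merged <- merge(emm$cells, raw, by = c("ground_state", "polygon_feature"))
  expect_equal(merged$emmean, merged$value, tolerance = 1e-10)
})

test_that("identical cell means give zero contrasts with adjusted p near 1", {
  df <- tidyr::expand_grid(ground_state = c("control", "thermokarst"),
                           polygon_feature = c("top", "trough"), rep = 1:4)
  df$value <- rep(c(-1, -0.5, 0.5, 1), 4) + 100  # same pattern in every cell
  emm <- estimated_marginal_means(fit_two_way_type2(df))
  expect_equal(emm$cell_contrasts$estimate, rep(0, 6), tolerance = 1e-10)
  expect_equal(emm$cell_contrasts$p_value, rep(1, 6), tolerance = 1e-8)
})

test_that("Tukey-adjusted p is monotone nonincreasing in |t|", {
  set.seed(9)
  d <- random_two_way(31)
  d$value <- d$value + 3 * (d$ground_state == "thermokarst") *
    (d$polygon_feature == "trough")
  emm <- estimated_marginal_means(fit_two_way_type2(d))
  ct <- emm$cell_contrasts[order(abs(emm$cell_contrasts$t_ratio)), ]
  expect_true(all(diff(ct$p_value) <= 1e-12))
  expect_true(all(emm$cell_contrasts$p_value >=
                    2 * pt(-abs(emm$cell_contrasts$t_ratio),
                           emm$cell_contrasts$df) - 1e-12))
})

test_that("ANCOVA absorbs a purely covariate-driven response", {
  set.seed(12)
  df <- random_two_way(12)
  df$cum_tdd <- runif(nrow(df), 5, 50)
  # response linear in the covariate plus noise orthogonal to the full
  # design, so every factor SS is exactly zero but the residual SS is not
  e <- rnorm(nrow(df))
  e <- resid(lm(e ~ cum_tdd + factor(ground_state) * factor(polygon_feature),
                data = df))
  df$value <- 150 + 2 * df$cum_tdd + e
  f <- fit_ancova_type2(df, ln_covariate = FALSE)
  facs <- f$table$statistic[f$table$term %in%
                              c("ground_state", "polygon_feature", "interaction")]
  expect_true(all(facs < 1e-10))
  expect_error(fit_ancova_type2(dplyr::mutate(df, cum_tdd = 3)), "constant")
})

test_that("a balanced covariate orthogonal to the factors leaves factor SS unchanged", {
  df <- tidyr::expand_grid(ground_state = c("control", "thermokarst"),
                           polygon_feature = c("top", "trough"), rep = 1:4)
  set.seed(5)
  df$value <- rnorm(16, 180 + 2 * (df$ground_state == "thermokarst"), 1)
  df$cum_tdd <- rep(c(-1, 1), 8) + 10  # identical, centered pattern per cell
  # orthogonalize the response to the covariate so adding it changes nothing
  df$value <- df$value - lm(value ~ cum_tdd, df)$coefficients[2] * df$cum_tdd
  plain <- fit_two_way_type2(df)
  with_cov <- fit_ancova_type2(df, ln_covariate = FALSE)
  for (term in c("ground_state", "polygon_feature", "interaction")) {
    expect_equal(with_cov$table$ss[with_cov$table$term == term],
                 plain$table$ss[plain$table$term == term], tolerance = 1e-8)
  }
})

test_that("regression on cumulative TDD matches closed-form normal equations", {
  x <- c(3, 7, 12, 20, 31)
  y <- c(181, 184, 183, 188, 191)
  df <- tibble::tibble(value = y, cum_tdd = x)
  out <- regress_on_tdd(df, ln_covariate = FALSE)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  r2 <- slope^2 * sum((x - mean(x))^2) / sum((y - mean(y))^2)
  expect_equal(out$slope, slope, tolerance = 1e-12)
  expect_equal(out$intercept, mean(y) - slope * mean(x), tolerance = 1e-12)
  expect_equal(out$r_squared, r2, tolerance = 1e-12)
  expect_equal(out$df, 3L)

  collinear <- tibble::tibble(value = 2 * x + 1, cum_tdd = x)
  # an exact fit makes summary.lm grumble about unreliability; R^2 is still 1
  expect_equal(suppressWarnings(
    regress_on_tdd(collinear, ln_covariate = FALSE)$r_squared), 1,
    tolerance = 1e-12)
  expect_error(regress_on_tdd(tibble::tibble(value = y, cum_tdd = rep(4, 5)),
                              ln_covariate = FALSE), "zero variance")
})

test_that("random-effect AIC check: zero variance gives delta AIC of 2", {
  # Latin-square deviations: transect means equal exactly, so the random
  # intercept variance is estimated at the boundary (0) and the mixed model
  # pays 2 AIC for an unused parameter.
  cells <- tidyr::expand_grid(ground_state = c("control", "thermokarst"),
                              polygon_feature = c("top", "trough"))
  dev <- c(-1.5, -0.5, 0.5, 1.5)
  df <- do.call(rbind, lapply(1:4, function(ci) {
    tibble::tibble(ground_state = cells$ground_state[ci],
                   polygon_feature = cells$polygon_feature[ci],
                   transect_id = paste0("t", 1:4),
                   value = 180 + 3 * ci + dev[((ci + 0:3) %% 4) + 1])
  }))
  out <- compare_random_effect(df)
  expect_true(out$singular)
  expect_equal(out$delta_aic, 2, tolerance = 1e-5)
  expect_equal(out$supported, "fixed")
})

test_that("a strong transect effect is detected by lower mixed-model AIC", {
  cfg <- scenario_config("null", transect_date_sd = 6)
  b <- suppressMessages(filter_flooded(generate_landscape(cfg, seed = 21)))
  cwm <- cwm_table(b)
  df <- dplyr::left_join(
    dplyr::filter(cwm, variant == "specific", phenophase == "first_leaf_out"),
    b$plots, by = "plot_id")
  out <- compare_random_effect(df)
  expect_equal(out$supported, "mixed")
  expect_lt(out$aic_mixed, out$aic_fixed)
  expect_error(compare_random_effect(dplyr::mutate(df, transect_id = "t1")),
               "at least 2 transects")
})
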