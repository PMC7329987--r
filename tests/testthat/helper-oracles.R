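# Independent brute-force least-squares oracle for type II sums of squares
# in the two-way (optionally covariate-first) layout. Design matrices are
# built by hand from 0/1 dummies and RSS comes from QR projections, so this
# shares no code path with the package's car-based fits.

oracle_rss <- function(X, y) {
  sum(qr.resid(qr(X), y)^2)
}

oracle_type2_two_way <- function(df) {
  y <- df$value
  a <- as.numeric(df$ground_state == "thermokarst")
  b <- as.numeric(df$polygon_feature == "trough")
  one <- rep(1, length(y))
  X_a <- cbind(one, a)
  X_b <- cbind(one, b)
  X_ab <- cbind(one, a, b)
  X_full <- cbind(one, a, b, a * b)
  c(
    ground_state = oracle_rss(X_b, y) - oracle_rss(X_ab, y),
    polygon_feature = oracle_rss(X_a, y) - oracle_rss(X_ab, y),
    interaction = oracle_rss(X_ab, y) - oracle_rss(X_full, y),
    residuals = oracle_rss(X_full, y)
  )
}

# Random small unbalanced 2x2 dataset (>= 2 plots per cell).
random_two_way <- function(seed) {
  set.seed(seed)
  n_cell <- sample(2:6, 4, replace = TRUE)
  gs <- rep(rep(c("control", "thermokarst"), each = 2), times = n_cell)
  pf <- rep(rep(c("top", "trough"), times = 2), times = n_cell)
  tibble::tibble(
    plot_id = sprintf("p%02d", seq_along(gs)),
    ground_state = gs,
    polygon_feature = pf,
    value = rnorm(length(gs), mean = 180 + 2 * (gs == "thermokarst") +
                    3 * (pf == "trough"), sd = 2)
  )
}

# Balanced 2x2 toy from hand-checkable values: cells (1,2 | 3,4 | 5,6 | 7,9).
balanced_toy <- function() {
  tibble::tibble(
    ground_state = rep(c("control", "control", "thermokarst", "thermokarst"),
                       each = 2),
    polygon_feature = rep(c("top", "trough", "top", "trough"), each = 2),
    value = c(1, 2, 3, 4, 5, 6, 7, 9)
  )
}

# Minimal hand-built bundle: 2x2 cells x 2 plots, 3 species, simple known
# dates; used for io and community unit tests.
tiny_bundle <- function() {
  plots <- tibble::tibble(
    plot_id = sprintf("p%d", 1:8),
    ground_state = rep(c("control", "thermokarst"), each = 4),
    polygon_feature = rep(rep(c("top", "trough"), each = 2), 2),
    transect_id = rep(c("t1", "t2"), 4),
    flooded = c(rep(FALSE, 7), TRUE)
  )
  cover <- tibble::tibble(
    plot_id = plots$plot_id,
    spA = c(60, 60, 30, 30, 10, 10, 50, 50),
    spB = c(30, 30, 60, 60, 0, 0, 25, 25),
    spC = c(10, 10, 10, 10, 40, 40, 25, 25)
  )
  phen <- expand.grid(plot_id = plots$plot_id, species_id = c("spA", "spB", "spC"),
                      phenophase = "first_leaf_out", stringsAsFactors = FALSE)
  phen <- tibble::as_tibble(phen)
  base <- c(spA = 184, spB = 188, spC = 192)
  phen$julian_date <- as.integer(base[phen$species_id] +
                                   as.integer(factor(phen$plot_id)) %% 3)
  cov_long <- tidyr::pivot_longer(cover, -plot_id, names_to = "species_id",
                                  values_to = "cover")
  phen <- dplyr::semi_join(phen,
                           dplyr::filter(cov_long, cover > 0),
                           by = c("plot_id", "species_id"))
  temp <- tidyr::expand_grid(plot_id = plots$plot_id, julian_day = 179:200,
                             hour = c(0L, 12L))
  temp$temp_c <- 5 + 0.1 * (temp$julian_day - 179) + 2 * (temp$hour == 12)
  phenokarst::new_bundle(plots, cover, phen, temp)
}
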