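#' Configuration for the synthetic thermokarst landscape generator
#'
#' Builds (and validates) the full parameter set for [generate_landscape()].
#' Defaults emulate the study design the analysis pipeline assumes: 80 plots
#' in a fully factorial 2x2 layout (ground state control/thermokarst by
#' polygon feature top/trough, 20 plots per cell) along five transects, five
#' flooded thermokarst-trough plots, a 22-species pool with five species
#' unique to each ground state and one dominant widespread species
#' (occupancy 0.8, mean cover 60%), hourly 10-cm soil temperatures over
#' Julian days 179-200, and phenophase dates produced by a cumulative
#' thaw-degree-day (TDD) threshold mechanism plus habitat shifts and
#' observation noise.
#'
#' Thermal defaults put the control-top daily mean on a 1->11 degC seasonal
#' ramp (seasonal TDD about 132 degC day) with thermokarst plots 1.1 degC
#' colder and troughs 1.4 degC colder, so thermokarst and trough TDD are
#' depressed by roughly 24 and 31 degree-days respectively over the window.
#'
#' @param n_per_cell Plots per ground-state x feature cell.
#' @param n_transects Number of east-west transects plots are assigned to.
#' @param n_flooded_troughs Thermokarst-trough plots flagged as flooded
#'   (submerged all season; excluded from analysis by [filter_flooded()]).
#' @param species_pool_size Total species pool.
#' @param n_unique_per_state Species found only in control (dry-adapted) and
#'   only in thermokarst (wetland) plots, respectively.
#' @param dominant_occupancy,dominant_mean_cover Occupancy probability and
#'   mean percent cover of the dominant widespread species.
#' @param window Integer Julian-day observation window `c(first, last)`.
#' @param baseline_temp_range Daily mean soil temperature (degC) at the
#'   start and end of the window for control-top plots (linear ramp).
#' @param state_effect_c Additive daily-mean shift (degC) for thermokarst
#'   plots (negative = colder).
#' @param feature_effect_c Additive daily-mean shift (degC) for trough plots.
#' @param interaction_effect_c Extra shift (degC) for thermokarst troughs.
#' @param plot_temp_sd SD (degC) of a per-plot constant temperature offset.
#' @param hourly_noise_sd SD (degC) of hourly logger noise.
#' @param diurnal_amplitude_c Amplitude (degC) of the diurnal sine cycle.
#' @param pheno_thresholds Named numeric: cumulative-TDD threshold
#'   (degree-days) at which each phenophase commences for an average species.
#' @param species_threshold_sd SD (degree-days) of per-species threshold
#'   offsets (a species trait, shared across phenophases).
#' @param moisture_threshold_slope Degree-days added to a species' threshold
#'   per unit moisture preference (scaled -1 wet-avoiding to +1 wet-loving),
#'   so wetland species are intrinsically later; this is what makes species
#'   turnover shift community-weighted dates.
#' @param habitat_shift_days 2x2 numeric matrix (rows = ground states,
#'   columns = features) of intraspecific date shifts in days, added to
#'   every species' dates in plots of that cell over and above the
#'   temperature-mediated shift.
#' @param pheno_noise_sd SD (days) of per-observation date noise.
#' @param flower_obs_prob Probability that a species flowers in an occupied
#'   plot (leaf phenophases are always observed; both flowering phenophases
#'   are observed or absent together).
#' @param turnover_strength 0-1 multiplier on moisture-preference-driven
#'   occupancy differences between ground states; 0 removes compositional
#'   turnover entirely.
#' @param identical_composition If `TRUE` every plot carries the full
#'   species pool at fixed covers (no compositional variation at all).
#' @param transect_date_sd SD (days) of a transect-level random intercept
#'   added to all dates, for exercising the random-effect AIC check.
#'
#' @return A validated list of class `karst_config`.
#' @seealso [scenario_config()], [generate_landscape()]
#' @export
synthetic_config <- function(n_per_cell = 20L,
                             n_transects = 5L,
                             n_flooded_troughs = 5L,
                             species_pool_size = 22L,
                             n_unique_per_state = 5L,
                             dominant_occupancy = 0.8,
                             dominant_mean_cover = 60,
                             window = c(179L, 200L),
                             baseline_temp_range = c(1, 11),
                             state_effect_c = -1.1,
                             feature_effect_c = -1.4,
                             interaction_effect_c = 0,
                             plot_temp_sd = 0.6,
                             hourly_noise_sd = 1.5,
                             diurnal_amplitude_c = 3,
                             pheno_thresholds = c(initial_leaf_growth = 8,
                                                  first_leaf_out = 30,
                                                  first_flower_bud = 45,
                                                  first_open_flower = 65),
                             species_threshold_sd = 6,
                             moisture_threshold_slope = 8,
                             habitat_shift_days = matrix(0, 2, 2),
                             pheno_noise_sd = 1.5,
                             flower_obs_prob = 0.75,
                             turnover_strength = 1,
                             identical_composition = FALSE,
                             transect_date_sd = 0) {
  cfg <- list(
    n_per_cell = as.integer(n_per_cell),
    n_transects = as.integer(n_transects),
    n_flooded_troughs = as.integer(n_flooded_troughs),
    species_pool_size = as.integer(species_pool_size),
    n_unique_per_state = as.integer(n_unique_per_state),
    dominant_occupancy = dominant_occupancy,
    dominant_mean_cover = dominant_mean_cover,
    window = as.integer(window),
    baseline_temp_range = baseline_temp_range,
    state_effect_c = state_effect_c,
    feature_effect_c = feature_effect_c,
    interaction_effect_c = interaction_effect_c,
    plot_temp_sd = plot_temp_sd,
    hourly_noise_sd = hourly_noise_sd,
    diurnal_amplitude_c = diurnal_amplitude_c,
    pheno_thresholds = pheno_thresholds,
    species_threshold_sd = species_threshold_sd,
    moisture_threshold_slope = moisture_threshold_slope,
    habitat_shift_days = habitat_shift_days,
    pheno_noise_sd = pheno_noise_sd,
    flower_obs_prob = flower_obs_prob,
    turnover_strength = turnover_strength,
    identical_composition = identical_composition,
    transect_date_sd = transect_date_sd
  )
  dimnames(cfg$habitat_shift_days) <-
    list(.ground_states, .polygon_features)
  validate_config(cfg)
  structure(cfg, class = "karst_config")
}

validate_config <- function(cfg) {
  stopifnot_cfg <- function(ok, msg) if (!ok) abort(paste0("Invalid config: ", msg))
  counts <- c(cfg$n_per_cell, cfg$n_transects, cfg$species_pool_size)
  stopifnot_cfg(all(counts >= 1L), "counts must be positive")
  stopifnot_cfg(cfg$n_flooded_troughs >= 0L &&
                  cfg$n_flooded_troughs <= cfg$n_per_cell,
                "n_flooded_troughs must lie in [0, n_per_cell]")
  stopifnot_cfg(cfg$n_unique_per_state >= 0L &&
                  2L * cfg$n_unique_per_state + 1L <= cfg$species_pool_size,
                "species pool too small for the requested unique species")
  stopifnot_cfg(cfg$dominant_occupancy > 0 && cfg$dominant_occupancy <= 1,
                "dominant_occupancy must be in (0, 1]")
  stopifnot_cfg(length(cfg$window) == 2L && cfg$window[2] > cfg$window[1],
                "window must be an increasing pair of Julian days")
  sds <- c(cfg$plot_temp_sd, cfg$hourly_noise_sd, cfg$species_threshold_sd,
           cfg$pheno_noise_sd, cfg$transect_date_sd)
  stopifnot_cfg(all(sds >= 0), "noise sds must be nonnegative")
  stopifnot_cfg(cfg$flower_obs_prob > 0 && cfg$flower_obs_prob <= 1,
                "flower_obs_prob must be in (0, 1]")
  stopifnot_cfg(cfg$turnover_strength >= 0 && cfg$turnover_strength <= 1,
                "turnover_strength must be in [0, 1]")
  stopifnot_cfg(identical(dim(cfg$habitat_shift_days), c(2L, 2L)),
                "habitat_shift_days must be a 2x2 matrix")
  stopifnot_cfg(setequal(names(cfg$pheno_thresholds), .phenophases),
                "pheno_thresholds must name all four phenophases")
  invisible(cfg)
}

#' Named generator scenarios
#'
#' Preset configurations exercising the statistical structure the pipeline
#' decomposes:
#' \describe{
#'   \item{paper_like}{Thermokarst and trough soil temperatures depressed,
#'     compositional turnover between ground states, and an extra +1 day
#'     intraspecific delay in thermokarst troughs, so troughs show 1-3 day
#'     phenological delays through both turnover and within-species change.}
#'   \item{turnover_only}{No thermal habitat effects and no intraspecific
#'     habitat shifts; ground states differ only in species composition, so
#'     community-weighted date differences are pure species turnover.}
#'   \item{intraspecific_only}{Identical composition in every plot (fixed
#'     covers, all species always flowering) with intraspecific habitat
#'     delays in troughs and thermokarst; the fixed CWM is constant across
#'     plots and all signal is within-species.}
#'   \item{null}{No thermal effects, no habitat shifts, no turnover
#'     structure; only noise. Used for type-I-error calibration.}
#' }
#'
#' @param name One of `"paper_like"`, `"turnover_only"`,
#'   `"intraspecific_only"`, `"null"`.
#' @param ... Overrides passed on to [synthetic_config()].
#' @return A `karst_config`.
#' @export
scenario_config <- function(name = c("paper_like", "turnover_only",
                                     "intraspecific_only", "null"),
                            ...) {
  name <- match.arg(name)
  shift_tk_trough <- matrix(c(0, 0, 0, 1), 2, 2)
  args <- switch(name,
    paper_like = list(habitat_shift_days = shift_tk_trough),
    turnover_only = list(
      state_effect_c = 0, feature_effect_c = 0, interaction_effect_c = 0,
      habitat_shift_days = matrix(0, 2, 2),
      # the scenario is defined by a turnover-dominated state signal: wet
      # and dry specialists differ clearly in timing, and incidental
      # within-species noise is kept small
      species_threshold_sd = 8, moisture_threshold_slope = 16,
      plot_temp_sd = 0.3, pheno_noise_sd = 1, turnover_strength = 1
    ),
    intraspecific_only = list(
      state_effect_c = 0, feature_effect_c = 0, interaction_effect_c = 0,
      identical_composition = TRUE, flower_obs_prob = 1,
      turnover_strength = 0,
      habitat_shift_days = matrix(c(0, 1.5, 1.5, 3), 2, 2)
    ),
    null = list(
      state_effect_c = 0, feature_effect_c = 0, interaction_effect_c = 0,
      habitat_shift_days = matrix(0, 2, 2), turnover_strength = 0
    )
  )
  do.call(synthetic_config, modifyList(args, list(...)))
}

#' Generate a synthetic thermokarst landscape
#'
#' Produces a complete dataset bundle (plot table, cover matrix, hourly soil
#' temperature series, phenophase observations) with known ground truth,
#' deterministic given `(config, seed)`. A single seeded stream is split
#' into four substreams in fixed order (design/species, thermal, cover,
#' phenology) so each table is reproducible independently of the others.
#'
#' Phenophase dates arise mechanistically: each species carries a
#' cumulative-TDD threshold per phenophase; the date is the first Julian day
#' on which the plot's realized cumulative TDD (positive daily means summed)
#' reaches the threshold, plus the cell's intraspecific habitat shift, a
#' transect intercept, and observation noise, floored to an integer day.
#' Events whose threshold is never reached within the window are unobserved.
#'
#' @param config A `karst_config`, e.g. from [synthetic_config()] or
#'   [scenario_config()].
#' @param seed Integer seed.
#' @return A `karst_bundle`: list with tibbles `plots`, `cover` (wide,
#'   `plot_id` + one column per species), `phenology`, `temperature`, and a
#'   `ground_truth` list (config, seed, species traits, cell thermal
#'   offsets).
#' @export
generate_landscape <- function(config = synthetic_config(), seed = 1L) {
  validate_config(config)
  seed <- as.integer(seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sub <- .derive_seeds(4L)  # design, thermal, cover, phenology

  ## ---- design substream: plots, transects, flooding, species traits ----
  set.seed(sub[1])
  n_cell <- config$n_per_cell
  n_plots <- 4L * n_cell
  ground_state <- factor(rep(.ground_states, each = 2L * n_cell),
                         levels = .ground_states)
  polygon_feature <- factor(rep(rep(.polygon_features, each = n_cell), 2L),
                            levels = .polygon_features)
  plot_id <- sprintf("p%03d", seq_len(n_plots))
  transect_id <- paste0("t", rep_len(seq_len(config$n_transects), n_plots))
  flooded <- rep(FALSE, n_plots)
  tk_trough <- which(ground_state == "thermokarst" & polygon_feature == "trough")
  if (config$n_flooded_troughs > 0L) {
    flooded[sample(tk_trough, config$n_flooded_troughs)] <- TRUE
  }

  n_sp <- config$species_pool_size
  species_id <- c("salix_arctica", sprintf("sp%02d", seq_len(n_sp)[-1]))
  unique_to <- rep(NA_character_, n_sp)
  nu <- config$n_unique_per_state
  if (nu > 0L) {
    unique_to[1L + seq_len(nu)] <- "control"
    unique_to[1L + nu + seq_len(nu)] <- "thermokarst"
  }
  moisture <- runif(n_sp, 0.2, 0.8)
  moisture[1] <- 0.5
  moisture[which(unique_to == "control")] <- 0
  moisture[which(unique_to == "thermokarst")] <- 1
  threshold_offset <- rnorm(n_sp, 0, config$species_threshold_sd) +
    config$moisture_threshold_slope * (2 * moisture - 1)
  threshold_offset[1] <- 0  # dominant species sits at the phenophase base

  ## ---- thermal substream: hourly series and realized daily means ----
  set.seed(sub[2])
  days <- seq(config$window[1], config$window[2])
  nd <- length(days)
  ramp <- seq(config$baseline_temp_range[1], config$baseline_temp_range[2],
              length.out = nd)
  cell_shift <- config$state_effect_c * (ground_state == "thermokarst") +
    config$feature_effect_c * (polygon_feature == "trough") +
    config$interaction_effect_c *
      (ground_state == "thermokarst" & polygon_feature == "trough")
  plot_offset <- rnorm(n_plots, 0, config$plot_temp_sd)
  design_daily <- outer(cell_shift + plot_offset, rep(1, nd)) +
    outer(rep(1, n_plots), ramp)                       # plots x days
  hours <- 0:23
  diurnal <- config$diurnal_amplitude_c * sin(2 * pi * hours / 24)
  # plots x (days*24), hour fastest
  hourly <- design_daily[, rep(seq_len(nd), each = 24L)] +
    matrix(rep(diurnal, times = nd), n_plots, nd * 24L, byrow = TRUE) +
    matrix(rnorm(n_plots * nd * 24L, 0, config$hourly_noise_sd),
           n_plots, nd * 24L)
  realized_daily <- hourly %*% kronecker(diag(nd), rep(1 / 24, 24))
  cum_tdd_mat <- t(apply(pmax(realized_daily, 0), 1L, cumsum))  # plots x days

  temperature <- tibble(
    plot_id = rep(plot_id, each = nd * 24L),
    julian_day = rep(rep(days, each = 24L), times = n_plots),
    hour = rep(hours, times = n_plots * nd),
    temp_c = round(as.vector(t(hourly)), 4)
  )

  ## ---- cover substream ----
  set.seed(sub[3])
  if (config$identical_composition) {
    cover_mat <- matrix(rep(c(config$dominant_mean_cover, rep(10, n_sp - 1L)),
                            each = n_plots), n_plots, n_sp)
  } else {
    wet <- ground_state == "thermokarst"
    suit <- 1 + config$turnover_strength *
      outer(ifelse(wet, 1, -1), 2 * moisture - 1)     # plots x species, in [0, 2]
    base_occ <- c(config$dominant_occupancy, rep(0.45, n_sp - 1L))
    occ_prob <- pmin(pmax(t(base_occ * t(suit)), 0), 1)
    occ_prob[, 1] <- config$dominant_occupancy        # dominant spans both states
    occ <- matrix(runif(n_plots * n_sp), n_plots, n_sp) < occ_prob
    cover_dom <- pmin(95, pmax(5, rnorm(n_plots, config$dominant_mean_cover, 12)))
    cover_oth <- matrix(pmin(60, stats::rlnorm(n_plots * (n_sp - 1L),
                                               log(8), 0.7)),
                        n_plots, n_sp - 1L)
    cover_mat <- cbind(cover_dom, cover_oth) * occ
    empty <- rowSums(cover_mat) == 0
    cover_mat[empty, 1] <- cover_dom[empty]           # census never records a bare plot
  }
  cover_mat <- round(cover_mat, 1)
  colnames(cover_mat) <- species_id
  cover <- bind_cols(tibble(plot_id = plot_id), as_tibble(cover_mat))

  ## ---- phenology substream ----
  set.seed(sub[4])
  thresholds <- outer(threshold_offset, config$pheno_thresholds[.phenophases], "+")
  thresholds <- pmax(thresholds, 0.5)                 # species x phenophase
  flowering <- matrix(runif(n_plots * n_sp), n_plots, n_sp) <= config$flower_obs_prob
  transect_eff <- setNames(
    rnorm(config$n_transects, 0, config$transect_date_sd),
    paste0("t", seq_len(config$n_transects))
  )
  shift_by_plot <- config$habitat_shift_days[cbind(as.integer(ground_state),
                                                   as.integer(polygon_feature))]
  noise <- array(rnorm(n_plots * n_sp * 4L, 0, config$pheno_noise_sd),
                 dim = c(n_plots, n_sp, 4L))

  obs <- vector("list", n_plots)
  th_vec <- as.vector(thresholds)                     # species fastest, then phase
  sp_idx <- rep(seq_len(n_sp), times = 4L)
  ph_idx <- rep(seq_len(4L), each = n_sp)
  for (i in seq_len(n_plots)) {
    cum_i <- cum_tdd_mat[i, ]
    pos <- findInterval(th_vec - 1e-9, cum_i) + 1L    # first day cum >= threshold
    reached <- pos <= nd
    present <- cover_mat[i, sp_idx] > 0
    observed <- reached & present &
      (ph_idx <= 2L | flowering[i, sp_idx])
    if (!any(observed)) next
    date <- days[pmin(pos, nd)] + shift_by_plot[i] +
      transect_eff[[transect_id[i]]] +
      noise[cbind(i, sp_idx, ph_idx)]
    date <- pmax(floor(date), config$window[1])
    keep <- observed & date <= config$window[2]
    if (!any(keep)) next
    obs[[i]] <- tibble(
      plot_id = plot_id[i],
      species_id = species_id[sp_idx[keep]],
      phenophase = .phenophases[ph_idx[keep]],
      julian_date = as.integer(date[keep])
    )
  }
  phenology <- bind_rows(obs)

  plots <- tibble(
    plot_id = plot_id,
    ground_state = ground_state,
    polygon_feature = polygon_feature,
    transect_id = transect_id,
    flooded = flooded
  )
  ground_truth <- list(
    seed = seed,
    config = config,
    species = tibble(
      species_id = species_id,
      moisture_preference = moisture,
      threshold_offset = threshold_offset,
      unique_to = unique_to,
      dominant = species_id == "salix_arctica"
    ),
    cell_thermal_shift_c = tapply(cell_shift, list(ground_state, polygon_feature), mean),
    habitat_shift_days = config$habitat_shift_days
  )
  new_bundle(plots, cover, phenology, temperature, ground_truth)
}
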