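#' Run the full thermokarst phenology analysis pipeline
#'
#' Orchestrates: load (or simulate) -> flooded-plot filter -> thermal
#' summaries (TDD ANOVA + EMMs) -> community-weighted means -> per-phenophase
#' two-way type II ANOVA with Tukey-adjusted EMM contrasts -> cumulative-TDD
#' regressions and ANCOVA -> transect random-effect AIC check ->
#' turnover/intraspecific/covariation decomposition -> single-species
#' analyses -> tidy CSV outputs.
#'
#' Exactly one of `paths` or `scenario` must be supplied. When the dataset
#' has no cover census the CWM-based stages are skipped with a warning and
#' the thermal and single-species analyses still run.
#'
#' @param paths Named list of input CSV paths (`plots`, `cover`,
#'   `phenology`, `temperature`); `cover` may be `NULL`.
#' @param scenario Name passed to [scenario_config()] to simulate instead
#'   of loading, or a ready-made `karst_config`.
#' @param seed Seed for simulation (ignored when loading).
#' @param out_dir Output directory for result CSVs, or `NULL` to skip
#'   writing.
#' @param sqrt_ilg Sqrt-transform the initial-leaf-growth CWM response.
#' @param ln_tdd Ln-transform cumulative TDD in regressions and ANCOVA.
#' @param adjust EMM p-value adjustment (`"tukey"` or `"none"`).
#' @param focal_species Species for the single-species analyses; default:
#'   the most widespread species in the cover census (falling back to the
#'   most widespread in the phenology table).
#' @return Invisibly, a named list of tidy result tables plus the filtered
#'   `bundle` and `cwm_fits`/`emm` objects.
#' @export
run_pipeline <- function(paths = NULL, scenario = NULL, seed = 1L,
                         out_dir = NULL, sqrt_ilg = TRUE, ln_tdd = TRUE,
                         adjust = "tukey", focal_species = NULL) {
  if (is.null(paths) == is.null(scenario)) {
    abort("Supply exactly one of `paths` or `scenario`.")
  }
  if (!is.null(scenario)) {
    cfg <- if (inherits(scenario, "karst_config")) scenario
           else scenario_config(scenario)
    inform(sprintf("Simulating landscape (seed %d).", as.integer(seed)))
    bundle <- generate_landscape(cfg, seed)
  } else {
    inform("Loading dataset.")
    bundle <- load_dataset(paths$plots, paths$cover, paths$phenology,
                           paths$temperature)
  }
  inform(sprintf("Loaded %d plots, %d phenophase records.",
                 nrow(bundle$plots), nrow(bundle$phenology)))
  bundle <- filter_flooded(bundle)
  results <- analyze_bundle(bundle, sqrt_ilg = sqrt_ilg, ln_tdd = ln_tdd,
                            adjust = adjust, focal_species = focal_species)
  if (!is.null(out_dir)) {
    meta <- list(
      package = "phenokarst",
      version = as.character(utils::packageVersion("phenokarst")),
      seed = as.integer(seed),
      sqrt_ilg = sqrt_ilg, ln_tdd = ln_tdd, adjust = adjust,
      n_plots_analyzed = nrow(bundle$plots),
      scenario = if (!is.null(scenario) && is.character(scenario)) scenario
                 else NULL
    )
    write_results(results, out_dir, metadata = meta)
    inform(sprintf("Results written to %s.", out_dir))
  }
  invisible(c(results, list(bundle = bundle)))
}

#' Analyze a (filtered) dataset bundle
#'
#' The computational core of [run_pipeline()], operating on an in-memory
#' bundle. See that function for the stages.
#'
#' @inheritParams run_pipeline
#' @param bundle A validated, flooded-filtered `karst_bundle`.
#' @return Named list of tidy result tables.
#' @export
analyze_bundle <- function(bundle, sqrt_ilg = TRUE, ln_tdd = TRUE,
                           adjust = "tukey", focal_species = NULL) {
  plots <- bundle$plots
  results <- list()

  ## Thermal: seasonal TDD, its ANOVA and EMMs --------------------------
  daily <- daily_means(bundle$temperature)
  tdd <- thaw_degree_days(daily)
  tdd_df <- left_join(tdd, plots, by = "plot_id") %>%
    rename(value = "tdd")
  tdd_fit <- fit_two_way_type2(tdd_df, response = "tdd")
  tdd_emm <- estimated_marginal_means(tdd_fit, adjust = adjust)
  inform(sprintf("Thermal summary: %d plots.", nrow(tdd)))

  has_cover <- !is.null(bundle$cover)
  if (!has_cover) {
    warn("No cover census: skipping CWM, decomposition and ANCOVA stages.")
  }

  cwm <- NULL
  anova_tab <- emm_cells <- emm_contrasts <- NULL
  ancova_tab <- ancova_contrasts <- regression <- aic_tab <- decomp <- NULL
  ctdd_all <- NULL
  if (has_cover) {
    cwm <- cwm_table(bundle)
    inform(sprintf("CWM table: %d rows.", nrow(cwm)))
    spec <- filter(cwm, .data$variant == "specific") %>%
      left_join(plots, by = "plot_id")

    fits <- list(); emms <- list()
    for (ph in intersect(.phenophases, as.character(unique(spec$phenophase)))) {
      tr <- if (sqrt_ilg && ph == "initial_leaf_growth") "sqrt" else "none"
      df <- filter(spec, .data$phenophase == ph)
      fits[[ph]] <- fit_two_way_type2(df, transform = tr, response = ph)
      emms[[ph]] <- estimated_marginal_means(fits[[ph]], adjust = adjust)
    }
    anova_tab <- bind_rows(lapply(fits, function(f) f$table))
    emm_cells <- bind_rows(lapply(names(emms), function(ph)
      mutate(emms[[ph]]$cells, response = ph, .before = 1)))
    emm_contrasts <- bind_rows(lapply(names(emms), function(ph)
      mutate(emms[[ph]]$cell_contrasts, response = ph, .before = 1)))

    ## Cumulative TDD at the specific CWM date, per plot and phenophase
    ctdd_all <- phenophase_tdd(
      daily, select(spec, "plot_id", "phenophase", cwm_date = "value")
    ) %>%
      left_join(select(spec, "plot_id", "phenophase", "value",
                       "ground_state", "polygon_feature"),
                by = c("plot_id", "phenophase"))

    reg_l <- list(); anc_l <- list(); ancc_l <- list(); aic_l <- list()
    for (ph in intersect(.phenophases, as.character(unique(ctdd_all$phenophase)))) {
      tr <- if (sqrt_ilg && ph == "initial_leaf_growth") "sqrt" else "none"
      df <- filter(ctdd_all, .data$phenophase == ph, .data$cum_tdd > 0)
      if (nrow(df) < 8) next
      reg_l[[ph]] <- regress_on_tdd(df, ln_covariate = ln_tdd,
                                    transform = tr, response = ph)
      anc <- fit_ancova_type2(df, transform = tr, ln_covariate = ln_tdd,
                              response = ph)
      anc_l[[ph]] <- anc$table
      ancc_l[[ph]] <- mutate(
        estimated_marginal_means(anc, adjust = adjust)$cell_contrasts,
        response = ph, covariate_at = anc$covariate$at, .before = 1)
    }
    for (ph in names(fits)) {
      tr <- if (sqrt_ilg && ph == "initial_leaf_growth") "sqrt" else "none"
      df <- filter(spec, .data$phenophase == ph)
      aic_l[[ph]] <- compare_random_effect(df, transform = tr, response = ph)
    }
    regression <- bind_rows(reg_l)
    ancova_tab <- bind_rows(anc_l)
    ancova_contrasts <- bind_rows(ancc_l)
    aic_tab <- bind_rows(aic_l)
    decomp <- decompose_variance(cwm, plots, sqrt_ilg = sqrt_ilg)
    inform("ANOVA, ANCOVA, regression, AIC and decomposition stages complete.")
  }

  ## Single-species analyses --------------------------------------------
  if (is.null(focal_species)) {
    focal_species <- if (has_cover) {
      occ <- colSums(as.matrix(bundle$cover[, -1, drop = FALSE]) > 0)
      names(which.max(occ))
    } else {
      names(which.max(table(bundle$phenology$species_id)))
    }
  }
  sp_anova_l <- list(); sp_contr_l <- list()
  for (ph in .phenophases) {
    df <- tryCatch(extract_species_phenology(bundle, focal_species, ph),
                   error = function(e) NULL)
    if (is.null(df) || nrow(df) < 12) next
    f <- tryCatch(fit_two_way_type2(df, response = paste0(focal_species, ":", ph)),
                  error = function(e) NULL)
    if (is.null(f)) next
    sp_anova_l[[ph]] <- f$table
    sp_contr_l[[ph]] <- mutate(
      estimated_marginal_means(f, adjust = adjust)$cell_contrasts,
      response = paste0(focal_species, ":", ph), .before = 1)
  }
  inform(sprintf("Single-species analyses for %s: %d phenophase(s).",
                 focal_species, length(sp_anova_l)))

  thermal_sum <- if (has_cover && !is.null(cwm)) {
    thermal_summary(bundle$temperature,
                    cwm_dates = filter(cwm, .data$variant == "specific") %>%
                      select("plot_id", "phenophase", cwm_date = "value"))
  } else {
    thermal_summary(bundle$temperature)
  }

  compact <- function(x) if (is.null(x)) NULL else x
  res <- list(
    thermal_summary = thermal_sum,
    tdd_anova = tdd_fit$table,
    tdd_emmeans = bind_rows(
      mutate(tdd_emm$ground_state, factor = "ground_state",
             level = as.character(.data$ground_state), .before = 1),
      mutate(tdd_emm$polygon_feature, factor = "polygon_feature",
             level = as.character(.data$polygon_feature), .before = 1)
    ) %>% select("factor", "level", "emmean", "SE", "df"),
    tdd_contrasts = bind_rows(
      mutate(tdd_emm$ground_state_contrast, factor = "ground_state", .before = 1),
      mutate(tdd_emm$polygon_feature_contrast, factor = "polygon_feature", .before = 1)
    ),
    cwm = compact(cwm),
    anova = compact(anova_tab),
    emmeans = compact(emm_cells),
    contrasts = compact(emm_contrasts),
    ancova = compact(ancova_tab),
    ancova_contrasts = compact(ancova_contrasts),
    regression = compact(regression),
    aic = compact(aic_tab),
    decomposition = compact(decomp),
    species_anova = if (length(sp_anova_l)) bind_rows(sp_anova_l) else NULL,
    species_contrasts = if (length(sp_contr_l)) bind_rows(sp_contr_l) else NULL,
    cumulative_tdd = compact(ctdd_all)
  )
  res[!vapply(res, is.null, logical(1))]
}
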