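#' Apply a response transform
#'
#' The square-root transform is used for the community-weighted
#' initial-leaf-growth response; the natural log for the cumulative-TDD
#' predictor. Domain violations name the offending plot.
#'
#' @param x Numeric vector.
#' @param kind `"none"`, `"sqrt"` or `"ln"`.
#' @param ids Optional identifiers (e.g. plot ids) used in error messages.
#' @return Transformed vector.
#' @export
apply_transform <- function(x, kind = c("none", "sqrt", "ln"), ids = NULL) {
  kind <- match.arg(kind)
  if (kind == "none") return(x)
  bad <- if (kind == "sqrt") x < 0 else x <= 0
  if (any(bad, na.rm = TRUE)) {
    lab <- if (is.null(ids)) which(bad)[1] else ids[bad][1]
    abort(sprintf("%s transform undefined for value %g (plot %s).",
                  kind, x[bad][1], lab))
  }
  switch(kind, sqrt = sqrt(x), ln = log(x))
}

.check_two_way <- function(df) {
  for (f in c("ground_state", "polygon_feature")) {
    if (length(unique(df[[f]])) < 2L) {
      abort(sprintf("Factor %s does not vary; two-way model is degenerate.", f))
    }
  }
  cells <- table(df$ground_state, df$polygon_feature)
  if (any(cells == 0)) {
    abort("Empty design cell(s): the interaction is inestimable (rank deficient).")
  }
  if (any(cells < 2)) {
    abort("Each represented design cell needs at least 2 plots.")
  }
  if (isTRUE(all.equal(var(df$value), 0))) {
    abort("Response is constant; nothing to test.")
  }
  invisible(df)
}

.prep_factors <- function(df) {
  df$ground_state <- factor(as.character(df$ground_state),
                            levels = .ground_states)
  df$polygon_feature <- factor(as.character(df$polygon_feature),
                               levels = .polygon_features)
  df
}

.tidy_anova <- function(a2, fit, response, transform) {
  tab <- as.data.frame(a2)
  term_map <- c(ground_state = "ground_state",
                polygon_feature = "polygon_feature",
                `ground_state:polygon_feature` = "interaction",
                cum_tdd = "cum_tdd",
                Residuals = "residuals")
  rn <- rownames(tab)
  tibble(
    response = response,
    term = unname(term_map[rn]),
    ss = tab[["Sum Sq"]],
    df = tab[["Df"]],
    statistic = tab[["F value"]],
    p_value = tab[["Pr(>F)"]],
    transform = transform
  )
}

#' Two-way type II ANOVA on plot-level responses
#'
#' Fits `value ~ ground_state * polygon_feature` by least squares and
#' reports type II sums of squares (each main effect adjusted for the other,
#' the interaction adjusted for both), the appropriate partition for this
#' unbalanced sampling design. F statistics use the full model's residual
#' mean square.
#'
#' @param df Tibble with columns `value`, `ground_state`, `polygon_feature`
#'   (and optionally `plot_id` for error messages).
#' @param transform Response transform, `"none"` or `"sqrt"`.
#' @param response Label recorded in the result table.
#' @return A `karst_fit`: list with `table` (term, ss, df, statistic,
#'   p_value), the underlying `fit`, `transform` and `data`.
#' @export
fit_two_way_type2 <- function(df, transform = c("none", "sqrt"),
                              response = "response") {
  transform <- match.arg(transform)
  df <- .prep_factors(as.data.frame(df))
  df$value <- apply_transform(df$value, transform, ids = df$plot_id)
  .check_two_way(df)
  fit <- lm(value ~ ground_state * polygon_feature, data = df)
  a2 <- car::Anova(fit, type = 2)
  structure(
    list(table = .tidy_anova(a2, fit, response, transform), fit = fit,
         transform = transform, data = df, covariate = NULL),
    class = "karst_fit"
  )
}

#' Type II ANCOVA with cumulative TDD as the first covariate
#'
#' Fits `value ~ cum_tdd + ground_state * polygon_feature`, testing whether
#' ground state and polygon feature explain residual variation once the
#' thermal driver is accounted for. Type II sums of squares; the covariate
#' may be ln-transformed.
#'
#' @param df Tibble with `value`, `cum_tdd`, `ground_state`,
#'   `polygon_feature`.
#' @param transform Response transform (`"none"`/`"sqrt"`).
#' @param ln_covariate Ln-transform the covariate before fitting?
#' @param response Label recorded in the result table.
#' @return A `karst_fit` whose table includes the `cum_tdd` term.
#' @export
fit_ancova_type2 <- function(df, transform = c("none", "sqrt"),
                             ln_covariate = TRUE, response = "response") {
  transform <- match.arg(transform)
  df <- .prep_factors(as.data.frame(df))
  df$value <- apply_transform(df$value, transform, ids = df$plot_id)
  if (ln_covariate) {
    df$cum_tdd <- apply_transform(df$cum_tdd, "ln", ids = df$plot_id)
  }
  .check_two_way(df)
  if (isTRUE(all.equal(var(df$cum_tdd), 0))) {
    abort("Covariate cum_tdd is constant; ANCOVA is degenerate.")
  }
  fit <- lm(value ~ cum_tdd + ground_state * polygon_feature, data = df)
  a2 <- car::Anova(fit, type = 2)
  structure(
    list(table = .tidy_anova(a2, fit, response, transform), fit = fit,
         transform = transform, data = df,
         covariate = list(name = "cum_tdd", ln = ln_covariate,
                          at = mean(df$cum_tdd))),
    class = "karst_fit"
  )
}

#' @export
print.karst_fit <- function(x, ...) {
  print(x$table)
  invisible(x)
}

.tidy_emm <- function(em) {
  as_tibble(as.data.frame(summary(em)))
}

.tidy_contrast <- function(ct) {
  s <- as.data.frame(summary(ct))
  tibble(
    contrast = as.character(s$contrast),
    estimate = s$estimate, se = s$SE, df = s$df,
    t_ratio = s$t.ratio, p_value = s$p.value
  )
}

#' Estimated marginal means with Tukey-adjusted pairwise contrasts
#'
#' Cell EMMs are model predictions per ground-state x feature cell (any
#' covariate held at its grand mean over the analyzed plots); main-effect
#' EMMs average cell EMMs with equal weight per level of the other factor.
#' All pairwise cell contrasts (6 for the 2x2) use the coefficient
#' covariance for their SEs, with p-values adjusted by the Tukey-Kramer
#' studentized-range method (k = number of cells, residual df from the full
#' model). With only two means the adjustment collapses to the unadjusted
#' two-sided t-test.
#'
#' @param fit_obj A `karst_fit` from [fit_two_way_type2()] or
#'   [fit_ancova_type2()].
#' @param adjust `"tukey"` or `"none"`.
#' @return List of class `karst_emm`: `cells`, `cell_contrasts`,
#'   `ground_state`, `ground_state_contrast`, `polygon_feature`,
#'   `polygon_feature_contrast`, `covariate_at`, `adjust`.
#' @export
estimated_marginal_means <- function(fit_obj, adjust = c("tukey", "none")) {
  adjust <- match.arg(adjust)
  fit <- fit_obj$fit
  em_cells <- emmeans::emmeans(fit, ~ ground_state * polygon_feature)
  em_gs <- emmeans::emmeans(fit, ~ ground_state)
  em_pf <- emmeans::emmeans(fit, ~ polygon_feature)
  structure(
    list(
      cells = .tidy_emm(em_cells),
      cell_contrasts = .tidy_contrast(emmeans::contrast(
        em_cells, method = "pairwise", adjust = adjust)),
      ground_state = .tidy_emm(em_gs),
      ground_state_contrast = .tidy_contrast(emmeans::contrast(
        em_gs, method = "pairwise", adjust = adjust)),
      polygon_feature = .tidy_emm(em_pf),
      polygon_feature_contrast = .tidy_contrast(emmeans::contrast(
        em_pf, method = "pairwise", adjust = adjust)),
      covariate_at = if (is.null(fit_obj$covariate)) NA_real_ else
        fit_obj$covariate$at,
      adjust = adjust
    ),
    class = "karst_emm"
  )
}

#' @export
print.karst_emm <- function(x, ...) {
  cat("Cell estimated marginal means:\n")
  print(x$cells)
  cat("\nPairwise cell contrasts (", x$adjust, " adjustment):\n", sep = "")
  print(x$cell_contrasts)
  invisible(x)
}

#' Simple regression of a phenophase response on cumulative TDD
#'
#' Ordinary least squares of the community-weighted date (or any plot-level
#' response) on cumulative TDD, optionally ln-transformed.
#'
#' @param df Tibble with `value` and `cum_tdd`.
#' @param ln_covariate Ln-transform the predictor?
#' @param transform Response transform.
#' @param response Label for the result row.
#' @return One-row tibble: response, predictor, slope, intercept,
#'   r_squared, df (= n - 2), p_value, n.
#' @export
regress_on_tdd <- function(df, ln_covariate = TRUE,
                           transform = c("none", "sqrt"),
                           response = "response") {
  transform <- match.arg(transform)
  df <- as.data.frame(df)
  if (nrow(df) < 3) abort("Regression needs at least 3 plots.")
  df$value <- apply_transform(df$value, transform, ids = df$plot_id)
  x <- if (ln_covariate) apply_transform(df$cum_tdd, "ln", ids = df$plot_id)
       else df$cum_tdd
  if (isTRUE(all.equal(var(x), 0))) {
    abort("Covariate cum_tdd has zero variance.")
  }
  fit <- lm(df$value ~ x)
  s <- summary(fit)
  n_obs <- nrow(df)
  tibble(
    response = response,
    predictor = if (ln_covariate) "ln_cum_tdd" else "cum_tdd",
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = s$r.squared,
    df = fit$df.residual,
    p_value = s$coefficients[2, 4],
    n = n_obs
  )
}

#' AIC check for a transect random intercept
#'
#' Fits the fixed-effects two-way model and the same model with a transect
#' random intercept, both by maximum likelihood (so the AICs are
#' comparable), and reports which is supported (lower AIC). A singular
#' random-effect fit is flagged, not raised.
#'
#' @param df Tibble with `value`, `ground_state`, `polygon_feature`,
#'   `transect_id`.
#' @param transform Response transform.
#' @param REML Use REML instead of ML for the mixed model (not comparable
#'   to the fixed-model AIC; default `FALSE`).
#' @param response Label for the result row.
#' @return One-row tibble: response, aic_fixed, aic_mixed, delta_aic
#'   (mixed - fixed), supported (`"fixed"`/`"mixed"`), singular.
#' @export
compare_random_effect <- function(df, transform = c("none", "sqrt"),
                                  REML = FALSE, response = "response") {
  transform <- match.arg(transform)
  df <- .prep_factors(as.data.frame(df))
  df$value <- apply_transform(df$value, transform, ids = df$plot_id)
  if (length(unique(df$transect_id)) < 2L) {
    abort("Need at least 2 transects for the random-effect comparison.")
  }
  fit_fixed <- lm(value ~ ground_state * polygon_feature, data = df)
  fit_mixed <- suppressMessages(lme4::lmer(
    value ~ ground_state * polygon_feature + (1 | transect_id),
    data = df, REML = REML
  ))
  aic_f <- AIC(fit_fixed)
  aic_m <- AIC(fit_mixed)
  tibble(
    response = response,
    aic_fixed = aic_f,
    aic_mixed = aic_m,
    delta_aic = aic_m - aic_f,
    supported = if (aic_f <= aic_m) "fixed" else "mixed",
    singular = lme4::isSingular(fit_mixed)
  )
}
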