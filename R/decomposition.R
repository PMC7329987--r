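#' Decompose ANOVA sums of squares into turnover, intraspecific and
#' covariation components
#'
#' For each phenophase, the identical two-way type II ANOVA is fitted three
#' times: on the specific CWM (its SS per term is the *total*), on the fixed
#' CWM (SS attributable to species *turnover*, since fixed averages can only
#' change through composition), and on the per-plot intraspecific response
#' (specific - fixed; SS attributable to within-species variation). The
#' *covariation* component is the signed remainder, total - turnover -
#' intraspecific per term, negative when compositional and within-species
#' shifts oppose each other. Each type II SS is a quadratic form in the
#' response with a term-specific projection fixed by the design, so the
#' additivity identity holds exactly for every term, including residuals.
#'
#' When a transform is applied (e.g. sqrt for initial leaf growth) the
#' specific and fixed responses are transformed first and the intraspecific
#' response is their transformed difference, keeping the identity exact on
#' the analyzed scale.
#'
#' A `total` row (column sums over the model and residual terms) mirrors the
#' conventional presentation of these partitions.
#'
#' @param cwm Long CWM tibble from [cwm_table()] (all three variants).
#' @param plots Plot factor table (`plot_id`, `ground_state`,
#'   `polygon_feature`).
#' @param sqrt_ilg Apply the sqrt transform to the initial-leaf-growth
#'   response?
#' @param phenophases Phenophases to decompose (default: all present).
#' @return Tibble `phenophase`, `term` (ground_state, polygon_feature,
#'   interaction, residuals, total), `turnover`, `intraspecific`,
#'   `covariation`, `total`, `transform`.
#' @export
decompose_variance <- function(cwm, plots, sqrt_ilg = TRUE,
                               phenophases = NULL) {
  if (is.null(phenophases)) {
    phenophases <- intersect(.phenophases, as.character(unique(cwm$phenophase)))
  }
  out <- vector("list", length(phenophases))
  for (k in seq_along(phenophases)) {
    ph <- phenophases[k]
    sub <- filter(cwm, .data$phenophase == ph)
    wide <- tidyr::pivot_wider(
      select(sub, "plot_id", "variant", "value"),
      names_from = "variant", values_from = "value"
    )
    missing_var <- setdiff(c("specific", "fixed", "intraspecific"),
                           names(wide))
    if (length(missing_var) > 0) {
      abort(sprintf("Phenophase %s: missing CWM variant(s): %s.",
                    ph, paste(missing_var, collapse = ", ")))
    }
    if (anyNA(wide$specific) || anyNA(wide$fixed) || anyNA(wide$intraspecific)) {
      abort(sprintf(
        "Phenophase %s: specific, fixed and intraspecific CWMs must cover a common plot set.",
        ph))
    }
    transform <- if (sqrt_ilg && ph == "initial_leaf_growth") "sqrt" else "none"
    df <- left_join(wide, plots, by = "plot_id")
    spec_t <- apply_transform(df$specific, transform, ids = df$plot_id)
    fixd_t <- apply_transform(df$fixed, transform, ids = df$plot_id)
    base <- select(df, "plot_id", "ground_state", "polygon_feature")

    terms4 <- c("ground_state", "polygon_feature", "interaction", "residuals")
    # A constant response (e.g. the fixed CWM when composition is identical
    # everywhere, or an identically-zero intraspecific component) carries no
    # variation: every SS in its column is exactly 0.
    ss_of <- function(v) {
      if (isTRUE(all.equal(var(v), 0))) return(setNames(rep(0, 4), terms4))
      f <- fit_two_way_type2(mutate(base, value = v), transform = "none")
      setNames(f$table$ss, f$table$term)
    }
    ss_total <- ss_of(spec_t)
    ss_turn <- ss_of(fixd_t)
    ss_intra <- ss_of(spec_t - fixd_t)

    terms <- terms4
    tab <- tibble(
      phenophase = ph,
      term = c(terms, "total"),
      turnover = unname(c(ss_turn[terms], sum(ss_turn[terms]))),
      intraspecific = unname(c(ss_intra[terms], sum(ss_intra[terms]))),
      total = unname(c(ss_total[terms], sum(ss_total[terms])))
    )
    tab$covariation <- tab$total - tab$turnover - tab$intraspecific
    tab$transform <- transform
    out[[k]] <- select(tab, "phenophase", "term", "turnover",
                       "intraspecific", "covariation", "total", "transform")
  }
  bind_rows(out)
}
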