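#' Relative-abundance weights from percent cover
#'
#' Total standardization (each plot's covers divided by their sum, via
#' `vegan::decostand(method = "total")`), so weights within a plot sum to 1
#' and zero-cover species keep weight 0.
#'
#' @param cover Wide cover tibble (`plot_id` + species columns) or a numeric
#'   matrix with plots as rows.
#' @return Object of the same shape with covers replaced by weights.
#' @export
relative_abundance <- function(cover) {
  is_df <- is.data.frame(cover)
  mat <- if (is_df) as.matrix(cover[, -1, drop = FALSE]) else as.matrix(cover)
  if (any(rowSums(mat) == 0)) {
    abort("relative_abundance: plot(s) with all-zero cover.")
  }
  w <- vegan::decostand(mat, method = "total")
  if (!is_df) return(w)
  bind_cols(cover[, 1, drop = FALSE], as_tibble(as.data.frame(w)))
}

#' Specific community-weighted mean for one plot and phenophase
#'
#' Weights are restricted to species with an observation and renormalized to
#' sum 1; the result is the weighted mean of the observed dates. Species
#' with cover but no record for this phenophase drop out of the weighting.
#'
#' @param weights Named numeric vector of relative-abundance weights for the
#'   plot (full censused row).
#' @param dates Named numeric vector of observed dates, names = species.
#' @return The weighted mean date, or `NA` if no weighted species was
#'   observed.
#' @export
specific_cwm <- function(weights, dates) {
  sp <- intersect(names(dates)[!is.na(dates)], names(weights)[weights > 0])
  if (length(sp) == 0) return(NA_real_)
  w <- weights[sp] / sum(weights[sp])
  sum(w * dates[sp])
}

#' Site-wide fixed species means for each phenophase
#'
#' The fixed average of a species is its unweighted arithmetic mean date
#' over all plots where that phenophase was recorded: a single site-level
#' trait value per species.
#'
#' @param phenology Observation tibble (`plot_id`, `species_id`,
#'   `phenophase`, `julian_date`).
#' @param phenophase Optional single phenophase to restrict to.
#' @return Tibble `species_id`, `phenophase`, `fixed_mean`.
#' @export
fixed_species_means <- function(phenology, phenophase = NULL) {
  if (!is.null(phenophase)) {
    phenology <- filter(phenology, .data$phenophase == !!phenophase)
  }
  phenology %>%
    group_by(.data$species_id, .data$phenophase) %>%
    summarise(fixed_mean = mean(.data$julian_date), .groups = "drop")
}

#' Fixed community-weighted mean over the observed species set
#'
#' Weighted mean of site-wide fixed species means over exactly the species
#' set (and renormalized weights) used by [specific_cwm()] for the same plot
#' and phenophase, so that specific minus fixed isolates within-species
#' deviation from compositional turnover.
#'
#' @param weights Named relative-abundance weights (full censused row).
#' @param fixed_means Named numeric vector of site-wide species means.
#' @param observed Character vector: species observed for this plot and
#'   phenophase.
#' @return The weighted mean of fixed means, or `NA`.
#' @export
fixed_cwm <- function(weights, fixed_means, observed) {
  sp <- intersect(observed, names(weights)[weights > 0])
  sp <- intersect(sp, names(fixed_means)[!is.na(fixed_means)])
  if (length(sp) == 0) return(NA_real_)
  w <- weights[sp] / sum(weights[sp])
  sum(w * fixed_means[sp])
}

#' Intraspecific component of a community-weighted mean
#'
#' The difference between the specific and fixed CWM removes the effect of
#' species compositional change, leaving the contribution of within-species
#' variation in timing.
#'
#' @param specific,fixed Numeric vectors (specific and fixed CWMs).
#' @return `specific - fixed`.
#' @export
intraspecific_component <- function(specific, fixed) specific - fixed

#' Community-weighted mean table for all plots and phenophases
#'
#' Computes, for every plot and phenophase with at least one weighted
#' observation, the specific CWM (plot-level observations), fixed CWM
#' (site-wide species means over the same renormalized species set) and the
#' intraspecific component (specific - fixed). Plots lacking any
#' observation for a phenophase are absent for that phenophase and are
#' thereby excluded from downstream analyses of it.
#'
#' @param bundle A `karst_bundle` with a cover census.
#' @return Long tibble `plot_id`, `phenophase`, `variant`
#'   (specific/fixed/intraspecific), `value`, `n_species_used`.
#' @export
cwm_table <- function(bundle) {
  if (is.null(bundle$cover)) {
    abort("cwm_table requires a cover census (bundle$cover is NULL).")
  }
  cover <- bundle$cover
  w_wide <- relative_abundance(cover)
  w_mat <- as.matrix(w_wide[, -1, drop = FALSE])
  rownames(w_mat) <- w_wide$plot_id
  species <- colnames(w_mat)

  out <- vector("list", length(.phenophases))
  for (k in seq_along(.phenophases)) {
    ph <- .phenophases[k]
    obs <- filter(bundle$phenology, .data$phenophase == ph,
                  .data$plot_id %in% rownames(w_mat),
                  .data$species_id %in% species)
    if (nrow(obs) == 0) next
    d_mat <- matrix(NA_real_, nrow(w_mat), length(species),
                    dimnames = list(rownames(w_mat), species))
    d_mat[cbind(obs$plot_id, obs$species_id)] <- obs$julian_date
    fixed_vec <- colMeans(d_mat, na.rm = TRUE)      # site-wide species means
    used <- !is.na(d_mat) & w_mat > 0
    wsum <- rowSums(w_mat * used)
    keep <- wsum > 0
    if (!any(keep)) next
    wn <- (w_mat * used) / wsum                     # renormalized weights
    spec <- rowSums(wn * ifelse(used, d_mat, 0))
    fixd <- rowSums(wn * ifelse(used, rep(fixed_vec, each = nrow(w_mat)), 0))
    n_used <- rowSums(used)
    out[[k]] <- tibble(
      plot_id = rep(rownames(w_mat)[keep], 3L),
      phenophase = ph,
      variant = rep(c("specific", "fixed", "intraspecific"), each = sum(keep)),
      value = c(spec[keep], fixd[keep], spec[keep] - fixd[keep]),
      n_species_used = rep(as.integer(n_used[keep]), 3L)
    )
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) abort("No phenophase observations overlap the cover census.")
  res$phenophase <- factor(res$phenophase, levels = .phenophases)
  arrange(res, .data$phenophase, .data$variant, .data$plot_id)
}

#' Plot-level phenophase dates for one focal species
#'
#' Unweighted dates of a single species (e.g. the dominant *Salix arctica*),
#' joined to the plot factor table, for single-species ANOVA/EMM analyses.
#'
#' @param bundle A `karst_bundle`.
#' @param species_id Focal species identifier.
#' @param phenophase Single phenophase.
#' @return Tibble `plot_id`, `ground_state`, `polygon_feature`,
#'   `transect_id`, `value` (Julian date).
#' @export
extract_species_phenology <- function(bundle, species_id, phenophase) {
  if (!species_id %in% bundle$phenology$species_id) {
    abort(sprintf("Species '%s' has no phenophase observations.", species_id))
  }
  obs <- filter(bundle$phenology, .data$species_id == !!species_id,
                .data$phenophase == !!phenophase)
  obs %>%
    mutate(value = as.numeric(.data$julian_date)) %>%
    select("plot_id", "value") %>%
    left_join(select(bundle$plots, "plot_id", "ground_state",
                     "polygon_feature", "transect_id"),
              by = "plot_id") %>%
    select("plot_id", "ground_state", "polygon_feature", "transect_id",
           "value")
}
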