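#' Construct a dataset bundle from in-memory tables
#'
#' Assembles the four analysis tables into a `karst_bundle` without
#' validation; use [validate_bundle()] (or [load_dataset()], which calls it)
#' to enforce the data model.
#'
#' @param plots Tibble: `plot_id`, `ground_state`, `polygon_feature`,
#'   `transect_id`, `flooded`.
#' @param cover Wide tibble: `plot_id` plus one percent-cover column per
#'   species, or `NULL` when no cover census is available.
#' @param phenology Tibble: `plot_id`, `species_id`, `phenophase`,
#'   `julian_date`.
#' @param temperature Tibble: `plot_id`, `julian_day`, `hour`, `temp_c`.
#' @param ground_truth Optional list of generator ground truth.
#' @return A `karst_bundle` list.
#' @export
new_bundle <- function(plots, cover, phenology, temperature,
                       ground_truth = NULL) {
  structure(
    list(plots = plots, cover = cover, phenology = phenology,
         temperature = temperature, ground_truth = ground_truth),
    class = "karst_bundle"
  )
}

#' @export
print.karst_bundle <- function(x, ...) {
  n_sp <- if (is.null(x$cover)) 0L else ncol(x$cover) - 1L
  cat(sprintf(
    "<karst_bundle> %d plots (%d flooded), %d species, %d phenophase records, %d temperature readings\n",
    nrow(x$plots), sum(x$plots$flooded), n_sp, nrow(x$phenology),
    nrow(x$temperature)
  ))
  invisible(x)
}

.require_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing required column(s): %s.",
                  file, paste(missing, collapse = ", ")))
  }
}

#' Read and validate the four input tables
#'
#' Reads the plot metadata, species percent-cover matrix, phenophase
#' observations and hourly soil-temperature series from CSV, normalizes
#' categorical levels (case-insensitive match to the canonical labels) and
#' enforces the data model via [validate_bundle()].
#'
#' Expected headers: `plots.csv` =
#' `plot_id,ground_state,polygon_feature,transect_id,flooded`; `cover.csv` =
#' wide with first column `plot_id`; `phenology.csv` =
#' `plot_id,species_id,phenophase,julian_date`; `temperature.csv` =
#' `plot_id,julian_day,hour,temp_c`.
#'
#' @param plots,phenology,temperature File paths.
#' @param cover File path, or `NULL` if no cover census exists (abundance
#'   weighting is then unavailable and CWM stages degrade gracefully).
#' @return A validated `karst_bundle`.
#' @export
load_dataset <- function(plots, cover, phenology, temperature) {
  read1 <- function(path) {
    if (!file.exists(path)) abort(sprintf("File not found: %s", path))
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  plots_df <- read1(plots)
  .require_columns(plots_df, c("plot_id", "ground_state", "polygon_feature",
                               "transect_id", "flooded"), "plots")
  plots_df <- plots_df %>%
    mutate(
      plot_id = as.character(.data$plot_id),
      ground_state = .canonical_factor(.data$ground_state, .ground_states,
                                       "ground_state"),
      polygon_feature = .canonical_factor(.data$polygon_feature,
                                          .polygon_features, "polygon_feature"),
      transect_id = as.character(.data$transect_id),
      flooded = .parse_flag(.data$flooded)
    )

  cover_df <- NULL
  if (!is.null(cover)) {
    cover_df <- read1(cover)
    .require_columns(cover_df, "plot_id", "cover")
    cover_df$plot_id <- as.character(cover_df$plot_id)
  }

  pheno_df <- read1(phenology)
  .require_columns(pheno_df, c("plot_id", "species_id", "phenophase",
                               "julian_date"), "phenology")
  pheno_df <- pheno_df %>%
    mutate(
      plot_id = as.character(.data$plot_id),
      species_id = as.character(.data$species_id),
      phenophase = as.character(.canonical_factor(.data$phenophase,
                                                  .phenophases, "phenophase")),
      julian_date = as.integer(.data$julian_date)
    )

  temp_df <- read1(temperature)
  .require_columns(temp_df, c("plot_id", "julian_day", "hour", "temp_c"),
                   "temperature")
  temp_df <- temp_df %>%
    mutate(plot_id = as.character(.data$plot_id),
           julian_day = as.integer(.data$julian_day),
           hour = as.integer(.data$hour))

  validate_bundle(new_bundle(plots_df, cover_df, pheno_df, temp_df))
}

.parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  xc <- tolower(trimws(as.character(x)))
  out <- xc %in% c("true", "t", "1", "yes")
  bad <- !xc %in% c("true", "t", "1", "yes", "false", "f", "0", "no")
  if (any(bad)) abort("flooded must be logical (TRUE/FALSE/1/0).")
  out
}

#' Validate a dataset bundle against the data model
#'
#' Checks plot-id uniqueness, non-missing factors, cover nonnegativity,
#' at least one positive cover per censused plot, cross-table referential
#' integrity (every child row's `plot_id` exists in the plot table; every
#' phenophase record's species has positive cover in that plot when a cover
#' census is present), uniqueness of (plot, species, phenophase), and
#' strictly increasing timestamps per plot. Phenophase dates outside the
#' logged temperature window raise a warning (their cumulative TDD is
#' ill-defined), not an error.
#'
#' @param bundle A `karst_bundle`.
#' @return The bundle, invisibly usable downstream.
#' @export
validate_bundle <- function(bundle) {
  plots <- bundle$plots
  if (anyDuplicated(plots$plot_id)) abort("plot_id values must be unique.")
  if (anyNA(plots$ground_state) || anyNA(plots$polygon_feature)) {
    abort("ground_state and polygon_feature must be non-missing for every plot.")
  }
  ids <- plots$plot_id

  if (!is.null(bundle$cover)) {
    cov <- bundle$cover
    orphan <- setdiff(cov$plot_id, ids)
    if (length(orphan) > 0) {
      abort(sprintf("cover: plot_id(s) not in plot table: %s.",
                    paste(orphan, collapse = ", ")))
    }
    vals <- as.matrix(cov[, -1, drop = FALSE])
    if (anyNA(vals) || any(vals < 0)) {
      abort("cover: percent cover values must be nonnegative and non-missing.")
    }
    if (any(rowSums(vals) == 0)) {
      abort("cover: every censused plot must have at least one positive cover value.")
    }
  }

  ph <- bundle$phenology
  orphan <- setdiff(ph$plot_id, ids)
  if (length(orphan) > 0) {
    abort(sprintf("phenology: plot_id(s) not in plot table: %s.",
                  paste(orphan, collapse = ", ")))
  }
  if (anyDuplicated(ph[c("plot_id", "species_id", "phenophase")])) {
    abort("phenology: at most one record per (plot, species, phenophase).")
  }
  if (!is.null(bundle$cover)) {
    cov_long <- tidyr::pivot_longer(bundle$cover, -"plot_id",
                                    names_to = "species_id",
                                    values_to = "cover")
    chk <- ph %>%
      left_join(cov_long, by = c("plot_id", "species_id"))
    bad <- is.na(chk$cover) | chk$cover <= 0
    if (any(bad)) {
      abort(sprintf(
        "phenology: %d record(s) for species with zero cover in their plot (first: %s / %s).",
        sum(bad), chk$plot_id[bad][1], chk$species_id[bad][1]
      ))
    }
  }

  tmp <- bundle$temperature
  orphan <- setdiff(tmp$plot_id, ids)
  if (length(orphan) > 0) {
    abort(sprintf("temperature: plot_id(s) not in plot table: %s.",
                  paste(orphan, collapse = ", ")))
  }
  ts_key <- tmp$julian_day * 24L + tmp$hour
  if (any(unlist(tapply(ts_key, tmp$plot_id, function(k) diff(k) <= 0)))) {
    abort("temperature: timestamps must be strictly increasing within each plot.")
  }
  if (nrow(tmp) > 0 && nrow(ph) > 0) {
    rng <- range(tmp$julian_day)
    out <- ph$julian_date < rng[1] | ph$julian_date > rng[2]
    if (any(out)) {
      warn(sprintf(
        "%d phenophase date(s) fall outside the logged window %d-%d.",
        sum(out), rng[1], rng[2]
      ))
    }
  }
  bundle
}

#' Drop plots flagged as flooded from every table
#'
#' Flooded plots (thermokarst troughs submerged through the season) carry no
#' usable phenology; they are removed from the plot, cover, phenology and
#' temperature tables. Idempotent. The number of removed plots is reported
#' via `message()`.
#'
#' @param bundle A `karst_bundle`.
#' @return The filtered bundle.
#' @export
filter_flooded <- function(bundle) {
  keep <- bundle$plots$plot_id[!bundle$plots$flooded]
  n_removed <- nrow(bundle$plots) - length(keep)
  if (length(keep) == 0) abort("All plots are flooded; nothing to analyze.")
  inform(sprintf("Removed %d flooded plot(s); %d retained.",
                 n_removed, length(keep)))
  bundle$plots <- filter(bundle$plots, .data$plot_id %in% keep)
  if (!is.null(bundle$cover)) {
    bundle$cover <- filter(bundle$cover, .data$plot_id %in% keep)
  }
  bundle$phenology <- filter(bundle$phenology, .data$plot_id %in% keep)
  bundle$temperature <- filter(bundle$temperature, .data$plot_id %in% keep)
  bundle
}

#' Write a dataset bundle to CSV files
#'
#' Writes `plots.csv`, `cover.csv` (if present), `phenology.csv`,
#' `temperature.csv` and, when generator ground truth is attached,
#' `ground_truth.json`, into `dir`. [load_dataset()] on the written files
#' reproduces the bundle exactly (dates as integers, reals at full
#' precision).
#'
#' @param bundle A `karst_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(bundle$plots, file.path(dir, "plots.csv"))
  if (!is.null(bundle$cover)) {
    readr::write_csv(bundle$cover, file.path(dir, "cover.csv"))
  }
  readr::write_csv(bundle$phenology, file.path(dir, "phenology.csv"))
  readr::write_csv(bundle$temperature, file.path(dir, "temperature.csv"))
  if (!is.null(bundle$ground_truth)) {
    gt <- bundle$ground_truth
    gt$cell_thermal_shift_c <- as.data.frame(as.table(gt$cell_thermal_shift_c))
    gt$habitat_shift_days <- as.data.frame(as.table(gt$habitat_shift_days))
    gt$config <- unclass(gt$config)
    gt$config$habitat_shift_days <-
      as.data.frame(as.table(gt$config$habitat_shift_days))
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(dir)
}

#' Write tidy result tables to an output directory
#'
#' One CSV per element of `results` (element name + `.csv`), with a
#' `run_metadata.json` sidecar carrying the seed, configuration and package
#' version when supplied. Reruns on identical inputs produce byte-identical
#' files.
#'
#' @param results Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param metadata Optional named list written to the sidecar.
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(results, out_dir, metadata = NULL) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok) abort(sprintf("Cannot create output directory: %s", out_dir))
  is_df <- vapply(results, is.data.frame, logical(1))
  for (nm in names(results)[is_df]) {
    readr::write_csv(results[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  }
  if (!is.null(metadata)) {
    jsonlite::write_json(metadata, file.path(out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}
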