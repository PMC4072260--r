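#' Study configuration
#'
#' Collects every setting of the desk-scale fibrosis study in one object.
#' Defaults reproduce the synthetic study conditions: 116 slides with true
#' fibrosis spanning 0-90%, 256 x 256 px tiles at 0.5 um/pixel, OD camera
#' noise 0.02, a stereology grid dense enough to place well over 500 points
#' on every tile, a 1000-iteration classifier budget, and a pathologist
#' with 4-point reading noise and 5-point score rounding.
#'
#' @param mode `"synthetic"` (generate the cohort) or `"tiles"` (read tiles
#'   and label maps listed in a manifest CSV).
#' @param n_slides number of synthetic slides.
#' @param fibrosis_range percent range of true fibrosis, `c(lo, hi)`.
#' @param tile_size tile dimensions in pixels.
#' @param noise_sd per-pixel OD noise SD.
#' @param amount_jitter_sd per-slide staining jitter SD.
#' @param od_vectors stain OD directions (default trichrome constants).
#' @param background_intensity per-channel white level.
#' @param thresholds colocalization per-stain OD thresholds.
#' @param grid_interval stereology sampling interval in pixels. The
#'   whole-slide setting is 200 px; on 256 px tiles the default 9 px keeps
#'   the effective (tissue) point count above the 500-point floor used for
#'   the smallest biopsies (see [recommended_sampling_interval()]).
#' @param grid_pattern_size marker extent for overlays.
#' @param classifier_iterations training iteration budget.
#' @param classifier_window feature window (odd, pixels).
#' @param pathologist_noise_sd,pathologist_rounding_step visual-score model.
#' @param friedman_columns the four matched columns compared by the
#'   Friedman test.
#' @param reference reference method name for agreement analyses.
#' @param tiles_dir,manifest tiles-mode input location (`manifest` is a CSV
#'   with columns slide_id, tile_path, label_path and optionally
#'   true_fibrosis_pct, pathologist_week0, pathologist_week2).
#' @param write_plots write Bland-Altman and regression PNGs.
#' @param write_markups write per-slide markup images (off by default).
#' @param seed master seed for the whole study.
#' @return Object of class `study_config`.
#' @export
study_config <- function(mode = c("synthetic", "tiles"),
                         n_slides = 116L,
                         fibrosis_range = c(0, 90),
                         tile_size = c(256L, 256L),
                         noise_sd = 0.02,
                         amount_jitter_sd = 0.05,
                         od_vectors = trichrome_od_vectors(),
                         background_intensity = c(255, 255, 255),
                         thresholds = c(0.15, 0.15, 0.15),
                         grid_interval = 9L,
                         grid_pattern_size = 2L,
                         classifier_iterations = 1000L,
                         classifier_window = 7L,
                         pathologist_noise_sd = 4,
                         pathologist_rounding_step = 5,
                         friedman_columns = c("stereology", "colocalization",
                                              "genie", "pathologist_mean"),
                         reference = "stereology",
                         tiles_dir = NULL, manifest = NULL,
                         write_plots = TRUE, write_markups = FALSE,
                         seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "tiles" && (is.null(tiles_dir) || is.null(manifest))) {
    fq_stop("tiles mode requires `tiles_dir` and `manifest`", "fq_parameter_error")
  }
  structure(as.list(environment()), class = "study_config")
}

#' Load a study configuration from YAML or JSON
#'
#' Reads a flat configuration file and passes the recognised fields to
#' [study_config()].
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON configuration file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    fq_stop("configuration must be YAML or JSON", "fq_parameter_error")
  }
  known <- names(formals(study_config))
  do.call(study_config, vals[intersect(names(vals), known)])
}

#' Run the full comparison study
#'
#' Generates (or loads) the cohort, quantifies every slide with the three
#' routes — colocalization, trainable classifier, stereology — simulates
#' the two pathologist readings (synthetic mode), assembles the per-slide
#' measurement table and emits the complete agreement report: summary
#' statistics, Pearson correlations, Friedman test with Wilcoxon post-hoc
#' pairs under Bonferroni, Bland-Altman objects and raw/ln regressions
#' against the reference, plus run metadata. Identical configuration and
#' seed give byte-identical CSV outputs.
#'
#' @param config a [study_config()].
#' @param out_dir output directory (created if missing).
#' @return Object of class `fq_study` with the measurements, every
#'   statistical result and the output paths. Files written:
#'   `measurements.csv`, `summary.csv`, `correlations.csv`,
#'   `correlation_p.csv`, `pairs.csv`, `friedman.csv`, `regressions.csv`,
#'   `run_meta.json` and (optionally) plot PNGs.
#' @export
run_study <- function(config, out_dir) {
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  done <- character(0)
  stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e) {
      jsonlite::write_json(
        list(completed_stages = done, failed_stage = name,
             error = conditionMessage(e)),
        file.path(out_dir, "partial_results.json"), auto_unbox = TRUE)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    done <<- c(done, name)
    res
  }

  seed <- check_seed(config$seed)
  model <- stain_model(config$od_vectors, config$background_intensity)
  sm <- stain_matrix(config$od_vectors)

  cohort <- stage("cohort", load_or_generate_cohort(config, model, seed))

  trained <- stage("training", {
    mont <- build_training_montage(model, noise_sd = config$noise_sd,
                                   seed = seed + 1L)
    train_classifier(mont, iteration_budget = config$classifier_iterations,
                     window = config$classifier_window,
                     background_intensity = config$background_intensity,
                     seed = seed + 2L)
  })

  per_slide <- stage("quantification", {
    grid_seeds <- withr::with_seed(seed + 3L,
                                   sample.int(2147483646L, length(cohort$slides)))
    rows <- vector("list", length(cohort$slides))
    for (i in seq_along(cohort$slides)) {
      sl <- cohort$slides[[i]]
      rows[[i]] <- tryCatch(
        quantify_slide(sl, sm, trained$model, config, grid_seeds[i], out_dir),
        error = function(e) stop(sprintf("slide %s: %s", sl$slide_id,
                                         conditionMessage(e)), call. = FALSE))
    }
    do.call(rbind, rows)
  })

  measurements <- stage("measurements", {
    m <- per_slide[c("slide_id", "stereology", "colocalization", "genie")]
    if (!is.null(cohort$pathologist)) {
      m$pathologist_week0 <- cohort$pathologist$week0
      m$pathologist_week2 <- cohort$pathologist$week2
    }
    method_measurements(m)
  })

  report <- stage("statistics", {
    compare_methods(measurements, reference = config$reference,
                    friedman_columns = config$friedman_columns)
  })

  stage("report", {
    out <- per_slide
    if (!is.null(measurements$pathologist_mean)) {
      out$pathologist_week0 <- measurements$pathologist_week0
      out$pathologist_week2 <- measurements$pathologist_week2
      out$pathologist_mean <- measurements$pathologist_mean
    }
    utils::write.csv(out, file.path(out_dir, "measurements.csv"),
                     row.names = FALSE, quote = FALSE)
    write_comparison_report(report, out_dir, write_plots = config$write_plots)
    meta <- list(package = "fibroquant",
                 version = as.character(utils::packageVersion("fibroquant")),
                 mode = config$mode, seed = seed,
                 n_slides = length(cohort$slides),
                 grid_interval = config$grid_interval,
                 classifier_iterations = config$classifier_iterations,
                 training_accuracy = trained$report$training_accuracy,
                 reference = config$reference,
                 csv_schema_version = 1L)
    jsonlite::write_json(meta, file.path(out_dir, "run_meta.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  structure(list(out_dir = out_dir,
                 measurements = measurements,
                 per_slide = per_slide,
                 report = report,
                 training_report = trained$report),
            class = "fq_study")
}

load_or_generate_cohort <- function(config, model, seed) {
  if (config$mode == "synthetic") {
    cohort <- generate_cohort(config$n_slides, config$fibrosis_range,
                              model = model, noise_sd = config$noise_sd,
                              tile_size = config$tile_size,
                              amount_jitter_sd = config$amount_jitter_sd,
                              seed = seed)
    truths <- vapply(cohort, `[[`, numeric(1), "true_fibrosis_pct")
    path <- list(
      week0 = simulate_pathologist(truths, config$pathologist_noise_sd,
                                   config$pathologist_rounding_step,
                                   seed = seed + 4L),
      week2 = simulate_pathologist(truths, config$pathologist_noise_sd,
                                   config$pathologist_rounding_step,
                                   seed = seed + 5L))
    list(slides = unclass(cohort), pathologist = path)
  } else {
    man <- utils::read.csv(file.path(config$tiles_dir, config$manifest),
                           stringsAsFactors = FALSE)
    need <- c("slide_id", "tile_path", "label_path")
    if (!all(need %in% names(man))) {
      fq_stop("manifest needs columns slide_id, tile_path, label_path",
              "fq_validation_error")
    }
    slides <- lapply(seq_len(nrow(man)), function(i) {
      tp <- file.path(config$tiles_dir, man$tile_path[i])
      lp <- file.path(config$tiles_dir, man$label_path[i])
      if (!file.exists(tp)) {
        fq_stop(sprintf("slide %s: tile file missing (%s)",
                        man$slide_id[i], tp), "fq_validation_error")
      }
      ph <- read_phantom(lp)
      list(slide_id = man$slide_id[i],
           true_fibrosis_pct = if ("true_fibrosis_pct" %in% names(man))
             man$true_fibrosis_pct[i] else ph$true_fibrosis_pct,
           phantom = ph, tile = read_tile(tp))
    })
    path <- if (all(c("pathologist_week0", "pathologist_week2") %in% names(man))) {
      list(week0 = man$pathologist_week0, week2 = man$pathologist_week2)
    }
    list(slides = slides, pathologist = path)
  }
}

quantify_slide <- function(sl, sm, genie_model, config, grid_seed, out_dir) {
  coloc <- quantify_colocalization(sl$tile, sm,
                                   config$background_intensity,
                                   config$thresholds)
  cmap <- classify_tile(sl$tile, genie_model)
  dims <- dim(sl$phantom$label_map)
  grid <- build_grid(c(0, 0, dims[1], dims[2]),
                     sampling_interval = config$grid_interval,
                     pattern_size = config$grid_pattern_size,
                     offset = "random", seed = grid_seed)
  pc <- estimate_area_fraction(auto_label_points(grid, sl$phantom))
  if (isTRUE(config$write_markups)) {
    write_tile(coloc$markup,
               file.path(out_dir, paste0(sl$slide_id, "_coloc_markup.png")))
    write_tile(render_class_markup(cmap),
               file.path(out_dir, paste0(sl$slide_id, "_genie_markup.png")))
  }
  data.frame(slide_id = sl$slide_id,
             true_fibrosis_pct = sl$true_fibrosis_pct,
             stereology = pc$pct,
             stereology_points = pc$n_effective,
             stereology_rse = pc$uncertainty_rse,
             colocalization = coloc$fibrosis_pct,
             genie = genie_fibrosis_fraction(cmap))
}

#' Full agreement-statistics battery on a measurement table
#'
#' Computes everything the comparison report contains: summary statistics,
#' the Pearson matrix, the Friedman test over the four matched methods,
#' the four Wilcoxon post-hoc pairs at the Bonferroni-adjusted level, and
#' Bland-Altman plus raw/ln regressions of each non-reference method
#' against the reference.
#'
#' @param measurements a [method_measurements()] data frame.
#' @param reference reference column name (default `"stereology"`).
#' @param friedman_columns the matched columns for the Friedman test.
#' @return List of class `method_comparison`.
#' @export
compare_methods <- function(measurements, reference = "stereology",
                            friedman_columns = c("stereology", "colocalization",
                                                 "genie", "pathologist_mean")) {
  cols <- method_columns(measurements)
  if (!reference %in% cols) {
    fq_stop(sprintf("reference column '%s' not present", reference),
            "fq_validation_error")
  }
  friedman_columns <- intersect(friedman_columns, cols)
  tests <- setdiff(intersect(c("colocalization", "genie", "pathologist_mean"),
                             cols), reference)
  pair_list <- c(lapply(tests, function(m) c(m, reference)),
                 if (all(c("colocalization", "genie") %in% cols))
                   list(c("colocalization", "genie")))
  ref_v <- measurements[[reference]]
  structure(list(
    summary = summarize_methods(measurements),
    correlations = pearson_matrix(measurements),
    friedman = if (length(friedman_columns) >= 3)
      friedman_test(measurements, friedman_columns),
    pairs = wilcoxon_pairs(measurements, pair_list),
    bland_altman = stats::setNames(lapply(tests, function(m)
      bland_altman(ref_v, measurements[[m]])), tests),
    regressions = stats::setNames(lapply(tests, function(m) list(
      raw = fit_regression(ref_v, measurements[[m]], "raw"),
      ln = fit_regression(ref_v, measurements[[m]], "ln")
    )), tests),
    reference = reference
  ), class = "method_comparison")
}

write_comparison_report <- function(report, out_dir, write_plots = TRUE) {
  utils::write.csv(report$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(report$correlations$r),
                   file.path(out_dir, "correlations.csv"), quote = FALSE)
  utils::write.csv(as.data.frame(report$correlations$p_value),
                   file.path(out_dir, "correlation_p.csv"), quote = FALSE)
  pairs_out <- report$pairs
  pairs_out$adjusted_alpha <- attr(report$pairs, "adjusted_alpha")
  utils::write.csv(pairs_out, file.path(out_dir, "pairs.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(report$friedman)) {
    utils::write.csv(data.frame(chi_square = report$friedman$chi_square,
                                df = report$friedman$df,
                                p_value = report$friedman$p_value,
                                n = report$friedman$n),
                     file.path(out_dir, "friedman.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  regs <- do.call(rbind, lapply(names(report$regressions), function(m) {
    do.call(rbind, lapply(c("raw", "ln"), function(tr) {
      rg <- report$regressions[[m]][[tr]]
      data.frame(method = m, transform = tr, slope = rg$slope,
                 intercept = rg$intercept, r_squared = rg$r_squared)
    }))
  }))
  utils::write.csv(regs, file.path(out_dir, "regressions.csv"),
                   row.names = FALSE, quote = FALSE)
  if (write_plots) {
    for (m in names(report$bland_altman)) {
      ggplot2::ggsave(file.path(out_dir, sprintf("bland_altman_%s.png", m)),
                      plot_bland_altman(report$bland_altman[[m]],
                                        title = sprintf("%s vs %s", m, report$reference)),
                      width = 5, height = 4, dpi = 120)
      for (tr in c("raw", "ln")) {
        ggplot2::ggsave(file.path(out_dir, sprintf("regression_%s_%s.png", m, tr)),
                        plot_regression(report$regressions[[m]][[tr]],
                                        title = sprintf("%s vs %s (%s)", m,
                                                        report$reference, tr)),
                        width = 5, height = 4, dpi = 120)
      }
    }
  }
  invisible(out_dir)
}

#' @export
print.fq_study <- function(x, ...) {
  cat(sprintf("fibroquant study: %d slides, outputs in %s\n",
              nrow(x$measurements), x$out_dir))
  if (!is.null(x$report$friedman)) print(x$report$friedman)
  invisible(x)
}
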