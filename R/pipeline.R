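# End-to-end orchestration: synthetic study -> preprocessing -> feature
# selection -> SPXY partitioning -> PLSR / PLS-DA -> metrics -> chemical
# maps -> JSON + Markdown report. Every stochastic stage consumes a seed
# derived from the master seed by a fixed counter scheme, so the whole
# report is a pure function of the configuration.

#' Pipeline configuration
#'
#' All tunables of [run_pipeline()] in one serializable list. Defaults
#' are the package's desk-scale study conditions: the full 412-band axis,
#' 216 retained samples split 2:1 for regression, 3:1 per-day splits for
#' discrimination, SPA chains up to 20 members inside the pipeline,
#' random frog at 1500 iterations with the 0.4 probability threshold,
#' and the (0.5, 1.5], (1.5, 2.5] PLS-DA decision bounds.
#'
#' @param seed master integer seed.
#' @param n_samples spectra retained from the 240-plant design
#'   (default 216).
#' @param link a [link_params()] (use [null_link_params()] for the
#'   no-signal control).
#' @param noise a [noise_params()].
#' @param preprocess character vector of spectral preprocessing steps
#'   (see [preprocess_matrix()]).
#' @param spa_k_min,spa_k_max SPA chain-length bounds inside the pipeline.
#' @param refine_r2_floor backward-refinement cross-validated R2 floor;
#'   the default `NA` uses a relative floor, the initial selection's
#'   cross-validated R2 minus `refine_q2_slack` (an absolute floor does
#'   not transfer across data scales: on easy data it lets refinement
#'   prune into underfitting, on hard data it blocks any pruning).
#' @param refine_q2_slack tolerated cross-validated R2 loss during
#'   refinement when `refine_r2_floor` is `NA` (default 0.03).
#' @param refine_max_drop cap on refinement removals.
#' @param rf_iterations,rf_init_size,rf_size_jitter,rf_accept_damp,rf_threshold
#'   random-frog settings for the ChlF branch.
#' @param split_fraction regression calibration fraction (default 2/3).
#' @param plsda_fraction per-day discriminant calibration fraction
#'   (default 3/4).
#' @param max_lv,plsda_max_lv latent-variable caps.
#' @param outlier_k_sd residual screening threshold in sd units.
#' @param stages subset of `c("spectral", "chlf", "discriminant", "maps")`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_samples = 216,
                            link = link_params(), noise = noise_params(),
                            preprocess = "wavelet_denoise",
                            spa_k_min = 1, spa_k_max = 20,
                            refine_r2_floor = NA, refine_q2_slack = 0.03,
                            refine_max_drop = 999,
                            rf_iterations = 1500, rf_init_size = 10,
                            rf_size_jitter = 0.3, rf_accept_damp = 0.1,
                            rf_threshold = 0.4,
                            split_fraction = 2 / 3, plsda_fraction = 3 / 4,
                            max_lv = 15, plsda_max_lv = 8,
                            outlier_k_sd = 3,
                            stages = c("spectral", "chlf", "discriminant",
                                       "maps")) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields in the YAML override [pipeline_config()] defaults; the
#' `link` and `noise` blocks override the corresponding parameter lists
#' field by field.
#'
#' @param path YAML file.
#' @param seed optional seed override.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in names(raw)) {
    if (nm %in% c("link", "noise")) {
      for (k in names(raw[[nm]])) cfg[[nm]][[k]] <- raw[[nm]][[k]]
    } else cfg[[nm]] <- raw[[nm]]
  }
  if (!is.null(seed)) cfg$seed <- seed
  cfg
}

# fixed counter scheme for per-stage seeds (recorded in the report)
stage_seed <- function(master, counter) {
  (as.integer(master) * 97L + counter * 131L) %% 2000000011L
}

#' Run the full study pipeline
#'
#' Executes, per the configured stages: synthetic experiment generation;
#' spectral preprocessing; SPA + backward refinement, SPXY 2:1 split and
#' PLSR on both the full axis and the refined sensitive wavelengths;
#' random frog + 0.4 threshold and PLSR on the ChlF panel; per-day 3:1
#' PLS-DA for both data sources (the per-day accuracy table); and
#' pixel-wise prediction maps of a stressed-WT and a TG plant from the
#' selected-wavelength model. A stage failure aborts with the stage name;
#' partial results are written to `outdir` when one is given.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory for report.json, report.md and
#'   map PNGs.
#' @return The report, an invisible list; also written as JSON/Markdown
#'   when `outdir` is set.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  seeds <- list(design = stage_seed(config$seed, 1L),
                subset = stage_seed(config$seed, 2L),
                frog = stage_seed(config$seed, 3L),
                maps = stage_seed(config$seed, 4L))
  report <- list(
    config = unclass(config),
    seeds = seeds,
    versions = list(shikimap = as.character(utils::packageVersion("shikimap")),
                    R = paste(R.version$major, R.version$minor, sep = ".")))
  report$config$link <- unclass(report$config$link)
  report$config$noise <- unclass(report$config$noise)

  finish <- function(report, failed_stage = NULL, err = NULL) {
    if (!is.null(outdir)) {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(report, file.path(outdir, "report.json"),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           force = TRUE)
      writeLines(render_report_md(report), file.path(outdir, "report.md"))
    }
    if (!is.null(failed_stage))
      stop(sprintf("pipeline stage '%s' failed: %s", failed_stage,
                   conditionMessage(err)), call. = FALSE)
    report
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) finish(report, name, e))
  }

  # ---- synth ----
  sim <- run_stage("synth", {
    design <- design_spec(seed = seeds$design)
    lib <- spectral_library(seeds$design)
    out <- simulate_experiment(design, lib, config$link, config$noise)
    out$lib <- lib
    out
  })
  n_total <- nrow(sim$spectra$X)
  keep <- with_seed(seeds$subset,
                    sort(sample.int(n_total, min(config$n_samples, n_total))))
  sub <- function(tab) sample_table(tab$X[keep, , drop = FALSE],
                                    y = tab$y[keep],
                                    meta = tab$meta[keep, , drop = FALSE])
  spec_tab <- sub(sim$spectra)
  chlf_tab <- sub(sim$chlf)
  report$data <- list(n_simulated = n_total, n_retained = length(keep))

  wl <- sim$lib$wavelengths
  spectral_model <- NULL

  # ---- spectral regression branch ----
  if ("spectral" %in% config$stages) {
    res <- run_stage("spectral", {
      X <- preprocess_matrix(spec_tab$X, wl, config$preprocess)
      y <- spec_tab$y
      out_idx <- detect_outliers(X, y, n_lv = min(10, config$max_lv),
                                 k_sd = config$outlier_k_sd)
      if (length(out_idx)) {
        X <- X[-out_idx, , drop = FALSE]; y <- y[-out_idx]
      }
      split <- spxy_split(X, y, config$split_fraction)
      ical <- split$calibration_indices; ipred <- split$prediction_indices
      Xc <- X[ical, , drop = FALSE]; yc <- y[ical]
      Xp <- X[ipred, , drop = FALSE]; yp <- y[ipred]

      inner <- spxy_split(Xc, yc, 2 / 3)
      sel <- spa_select(Xc[inner$calibration_indices, , drop = FALSE],
                        yc[inner$calibration_indices],
                        Xc[inner$prediction_indices, , drop = FALSE],
                        yc[inner$prediction_indices],
                        k_min = config$spa_k_min, k_max = config$spa_k_max)
      floor <- if (is.finite(config$refine_r2_floor))
        config$refine_r2_floor
      else loo_press(Xc[, sel$selected_indices, drop = FALSE], yc,
                     10)$q2 - config$refine_q2_slack
      ref <- backward_refine(sel, Xc, yc,
                             max_drop = config$refine_max_drop,
                             r2_floor = floor)
      idx <- ref$selected_indices
      corr <- if (length(idx) >= 2)
        correlation_matrix(Xc[, idx, drop = FALSE]) else NULL

      lv_full <- select_lv_loocv(Xc, yc, config$max_lv)
      m_full <- fit_plsr(Xc, yc, lv_full$n_lv)
      met_full <- model_metrics(yc, predict(m_full, Xc),
                                yp, predict(m_full, Xp))

      lv_sel <- select_lv_loocv(Xc[, idx, drop = FALSE], yc, config$max_lv)
      m_sel <- fit_plsr(Xc[, idx, drop = FALSE], yc, lv_sel$n_lv)
      met_sel <- model_metrics(yc, predict(m_sel, Xc[, idx, drop = FALSE]),
                               yp, predict(m_sel, Xp[, idx, drop = FALSE]))
      list(model = m_sel,
           report = list(
             n_outliers = length(out_idx),
             n_cal = length(ical), n_pred = length(ipred),
             spa = list(selected = sel$selected_names,
                        rmse = sel$rmse,
                        trace = as.list(sel$criterion_trace)),
             refined = list(selected = ref$selected_names,
                            trace = ref$criterion_trace),
             max_abs_corr = if (is.null(corr)) NA else
                              max(abs(corr[upper.tri(corr)])),
             full_spectrum = c(list(n_lv = lv_full$n_lv),
                               unclass(met_full)),
             sensitive_wavelengths = c(list(n_lv = lv_sel$n_lv),
                                       unclass(met_sel))))
    })
    spectral_model <- res$model
    report$spectral <- res$report
  }

  # ---- ChlF regression branch ----
  chlf_selected <- NULL
  if ("chlf" %in% config$stages) {
    res <- run_stage("chlf", {
      X <- chlf_tab$X; y <- chlf_tab$y
      out_idx <- detect_outliers(X, y, n_lv = 3, k_sd = config$outlier_k_sd,
                                 scale = TRUE)
      if (length(out_idx)) {
        X <- X[-out_idx, , drop = FALSE]; y <- y[-out_idx]
      }
      split <- spxy_split(scale(X), y, config$split_fraction)
      ical <- split$calibration_indices; ipred <- split$prediction_indices
      Xc <- X[ical, , drop = FALSE]; yc <- y[ical]
      Xp <- X[ipred, , drop = FALSE]; yp <- y[ipred]

      frog <- random_frog(Xc, yc, n_iterations = config$rf_iterations,
                          init_size = config$rf_init_size,
                          size_jitter = config$rf_size_jitter,
                          accept_damp = config$rf_accept_damp,
                          seed = seeds$frog)
      thr <- threshold_features(frog, config$rf_threshold)
      sel_names <- if (length(thr$selected_indices)) thr$selected_names
                   else utils::head(frog$selected_names, 3)

      lv_all <- select_lv_loocv(Xc, yc, config$max_lv, scale = TRUE)
      m_all <- fit_plsr(Xc, yc, lv_all$n_lv, scale = TRUE)
      met_all <- model_metrics(yc, predict(m_all, Xc), yp, predict(m_all, Xp))

      Xcs <- Xc[, sel_names, drop = FALSE]
      lv_sel <- select_lv_loocv(Xcs, yc, config$max_lv, scale = TRUE)
      m_sel <- fit_plsr(Xcs, yc, lv_sel$n_lv, scale = TRUE)
      met_sel <- model_metrics(yc, predict(m_sel, Xcs),
                               yp, predict(m_sel, Xp[, sel_names,
                                                     drop = FALSE]))
      list(selected = sel_names,
           report = list(
             n_outliers = length(out_idx),
             selection_probabilities =
               as.list(frog$criterion_trace[frog$selected_names]),
             selected = sel_names,
             threshold = config$rf_threshold,
             threshold_empty = isTRUE(thr$empty),
             all_parameters = c(list(n_lv = lv_all$n_lv), unclass(met_all)),
             sensitive_parameters = c(list(n_lv = lv_sel$n_lv),
                                      unclass(met_sel))))
    })
    chlf_selected <- res$selected
    report$chlf <- res$report
  }

  # ---- per-day discrimination ----
  if ("discriminant" %in% config$stages) {
    report$discriminant <- run_stage("discriminant", {
      sources <- list()
      if (!is.null(spectral_model))
        sources$spectral <- list(tab = spec_tab,
                                 feats = spectral_model$feature_names,
                                 X_all = preprocess_matrix(spec_tab$X, wl,
                                                           config$preprocess),
                                 scale = FALSE)
      if (!is.null(chlf_selected))
        sources$chlf <- list(tab = chlf_tab, feats = chlf_selected,
                             X_all = chlf_tab$X, scale = TRUE)
      lapply(sources, function(src) {
        meta <- src$tab$meta
        labels <- ifelse(meta$genotype == "WT" &
                           meta$treatment == "glyphosate", 2L, 1L)
        days <- sort(unique(meta$day))
        rows <- lapply(days, function(d) {
          id <- which(meta$day == d)
          Xd <- src$X_all[id, src$feats, drop = FALSE]
          ld <- labels[id]
          sp <- spxy_split(if (src$scale) scale(Xd) else Xd, ld,
                           config$plsda_fraction)
          ic <- sp$calibration_indices; ip <- sp$prediction_indices
          lv <- select_lv_loocv(Xd[ic, , drop = FALSE], ld[ic],
                                config$plsda_max_lv, scale = src$scale)
          m <- fit_plsda(Xd[ic, , drop = FALSE], ld[ic], lv$n_lv,
                         scale = src$scale)
          acc_c <- classification_accuracy(
            ld[ic], classify_plsda(m, Xd[ic, , drop = FALSE])$class)
          acc_p <- classification_accuracy(
            ld[ip], classify_plsda(m, Xd[ip, , drop = FALSE])$class)
          list(day = d, n_lv = lv$n_lv, n_cal = length(ic),
               n_pred = length(ip),
               accuracy_cal = acc_c, accuracy_pred = acc_p)
        })
        rows
      })
    })
  }

  # ---- chemical maps ----
  if ("maps" %in% config$stages && !is.null(spectral_model)) {
    report$maps <- run_stage("maps", {
      plants <- list(
        WT_glyphosate_day8 = config$link$shik_base +
          config$link$shik_day_slope * 8,
        TG_glyphosate_day8 = config$link$healthy_mean)
      prep_fun <- if (identical(config$preprocess, "none")) NULL else
        function(s) {
          for (st in config$preprocess)
            s <- switch(st,
                        wavelet_denoise = wavelet_detrend(s, mode = "denoise"),
                        wavelet_debaseline = wavelet_detrend(s,
                                                             mode = "debaseline"),
                        snv = snv(s), savgol = savgol(s), s)
          s
        }
      out <- lapply(seq_along(plants), function(i) {
        sim_c <- simulate_cube(sim$lib, plants[[i]],
                               link = config$link,
                               seed = stage_seed(seeds$maps, i))
        mask <- segment_plant(sim_c$cube)
        pm <- predict_map(sim_c$cube, spectral_model, mask,
                          preprocess = prep_fun)
        if (!is.null(outdir)) {
          dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
          render_map(pm, file.path(outdir,
                                   paste0("map_", names(plants)[i], ".png")))
        }
        list(plant = names(plants)[i],
             true_concentration = plants[[i]],
             foreground_mean = mean(pm$values[pm$mask]),
             foreground_px = sum(pm$mask))
      })
      names(out) <- names(plants)
      out
    })
  }

  invisible(finish(report))
}

# plain-text Table-1-style summary
render_report_md <- function(report) {
  lines <- c("# shikimap pipeline report", "",
             sprintf("Master seed: %s", report$config$seed),
             sprintf("Samples: %s simulated, %s retained",
                     report$data$n_simulated, report$data$n_retained), "")
  fmt_met <- function(m)
    sprintf("n_lv = %d, R2c = %.3f (RMSEC = %.2f), R2p = %.3f (RMSEP = %.2f)",
            m$n_lv, m$r2_cal, m$rmse_cal, m$r2_pred, m$rmse_pred)
  if (!is.null(report$spectral)) {
    s <- report$spectral
    lines <- c(lines, "## Spectral branch",
               sprintf("- SPA selected %d wavelengths (val RMSE %.2f)",
                       length(s$spa$selected), s$spa$rmse),
               sprintf("- refined to %d sensitive wavelengths: %s",
                       length(s$refined$selected),
                       paste(s$refined$selected, collapse = ", ")),
               paste("- full spectrum:", fmt_met(s$full_spectrum)),
               paste("- sensitive wavelengths:",
                     fmt_met(s$sensitive_wavelengths)), "")
  }
  if (!is.null(report$chlf)) {
    c_ <- report$chlf
    lines <- c(lines, "## ChlF branch",
               sprintf("- random frog selected (> %.2f): %s",
                       c_$threshold, paste(c_$selected, collapse = ", ")),
               paste("- all parameters:", fmt_met(c_$all_parameters)),
               paste("- sensitive parameters:",
                     fmt_met(c_$sensitive_parameters)), "")
  }
  if (!is.null(report$discriminant)) {
    lines <- c(lines, "## Per-day discrimination",
               "| source | day | LVs | calibration | prediction |",
               "|---|---|---|---|---|")
    for (src in names(report$discriminant))
      for (row in report$discriminant[[src]])
        lines <- c(lines, sprintf("| %s | %d | %d | %.2f%% | %.2f%% |",
                                  src, row$day, row$n_lv,
                                  100 * row$accuracy_cal,
                                  100 * row$accuracy_pred))
    lines <- c(lines, "")
  }
  if (!is.null(report$maps)) {
    lines <- c(lines, "## Chemical maps")
    for (m in report$maps)
      lines <- c(lines, sprintf("- %s: truth %.1f, map mean %.1f (%d px)",
                                m$plant, m$true_concentration,
                                m$foreground_mean, m$foreground_px))
  }
  lines
}
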