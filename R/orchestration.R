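# End-to-end workflow: preprocess -> register -> fuse/classify ->
# co-inertia -> correlate -> predict -> enhance, driven by one declarative
# configuration, with a structured report of the standard tables.

#' Default run configuration
#'
#' Builds the configuration consumed by [run_pipeline()]. Defaults match
#' the package's standard settings: Savitzky-Golay window 15 / order 3,
#' ten PCs per modality for mid-level fusion, ten denoising PCs, 0.85
#' correlation threshold.
#'
#' @param input Either `list(preset = "phantom", ...)` (extra entries are
#'   passed to [phantom_spec()]) or `list(cube_a = , cube_b = )` with ENVI
#'   or CSV cube paths (`labels` may name a CSV class-map matrix).
#' @param stages Stages to run, in order, from `c("classify", "coinertia",
#'   "correlate", "predict", "enhance")`. Registration runs whenever the
#'   two cubes are not already on the same grid.
#' @param preprocess List: `savgol` (logical), `window`, `polyorder`.
#' @param registration List: `pc_a`, `pc_b`, `threshold`, `rot90`, `flips`,
#'   `search_orientation`.
#' @param fusion_levels Subset of `c("a_only", "b_only", "low", "mid",
#'   "high")` reported in the classification table.
#' @param max_lv,n_pcs,coinertia_components,correlation_threshold,denoise_pcs
#'   Numeric options for the respective stages.
#' @param predict_targets Optional band positions to report predicted
#'   images for.
#' @param seed RNG seed stamped on the run.
#' @param out_dir Optional output directory for artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(input = list(preset = "phantom"),
                       stages = c("classify", "coinertia", "correlate",
                                  "predict"),
                       preprocess = list(savgol = FALSE, window = 15L,
                                         polyorder = 3L),
                       registration = list(pc_a = 1L, pc_b = 1L,
                                           threshold = "otsu", rot90 = 0L,
                                           flips = character(),
                                           search_orientation = FALSE),
                       fusion_levels = c("a_only", "b_only", "low", "mid", "high"),
                       max_lv = 12L, n_pcs = c(10L, 10L),
                       coinertia_components = 4L,
                       correlation_threshold = 0.85,
                       denoise_pcs = 10L,
                       predict_targets = NULL,
                       seed = 1L, out_dir = NULL) {
  cfg <- list(input = input, stages = stages, preprocess = preprocess,
              registration = registration, fusion_levels = fusion_levels,
              max_lv = max_lv, n_pcs = n_pcs,
              coinertia_components = coinertia_components,
              correlation_threshold = correlation_threshold,
              denoise_pcs = denoise_pcs, predict_targets = predict_targets,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  known <- c("classify", "coinertia", "correlate", "predict", "enhance")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!is.null(cfg$input$cube_a) && !file.exists(cfg$input$cube_a))
    stop("input cube A not found: ", cfg$input$cube_a)
  if (!is.null(cfg$input$cube_b) && !file.exists(cfg$input$cube_b))
    stop("input cube B not found: ", cfg$input$cube_b)
  if (is.null(cfg$input$preset) && is.null(cfg$input$cube_a))
    stop("input must name a phantom preset or cube paths")
  if ("classify" %in% cfg$stages && is.null(cfg$input$preset) &&
      is.null(cfg$input$labels))
    stop("classification requested but no class labels provided")
  if (cfg$correlation_threshold <= 0 || cfg$correlation_threshold > 1)
    stop("'correlation_threshold' must be in (0, 1]")
  if (cfg$max_lv < 1 || cfg$coinertia_components < 1 || cfg$denoise_pcs < 1)
    stop("numeric options must be positive")
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML path; entries override the [run_config()] defaults.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

read_any_cube <- function(path) {
  if (grepl("\\.csv$", path)) read_csv_spectra(path) else read_envi(path)
}

#' Run the full multivariate fusion workflow
#'
#' Loads or generates the paired cubes, registers the high-resolution cube
#' onto the low-resolution grid when needed, then executes the requested
#' stages in order. Every stage's key numbers are collected into a report;
#' artifacts (registered cube, tables, report JSON) are written when the
#' configuration names an output directory. A stage failure halts the run
#' with the stage name; completed results are kept on the error object.
#'
#' @param config A [run_config()] (or a YAML path accepted by
#'   [read_run_config()]).
#' @return A `run_report` list with one entry per executed stage plus
#'   provenance (`seed`, `config`, timing).
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  set.seed(config$seed)
  report <- list(seed = config$seed, started = format(Sys.time()),
                 config = unclass(config))
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    res$elapsed_s <- round(proc.time()[3] - t0, 2)
    res
  }

  # --- inputs ------------------------------------------------------------
  if (!is.null(config$input$preset)) {
    extra <- config$input[setdiff(names(config$input), "preset")]
    spec <- do.call(phantom_spec, c(extra, list(seed = config$seed)))
    ph <- make_phantom_pair(spec)
    cube_a <- ph$a_lr; cube_b_hr <- ph$b_hr_misaligned
    labels <- ph$truth$class_lr
    config$registration$rot90 <- spec$rot90_quarter_turns
    config$registration$flips <- spec$flip_axes
  } else {
    cube_a <- read_any_cube(config$input$cube_a)
    cube_b_hr <- read_any_cube(config$input$cube_b)
    labels <- if (!is.null(config$input$labels))
      as.matrix(utils::read.csv(config$input$labels, header = FALSE)) else NULL
  }

  # --- registration ------------------------------------------------------
  if (!all(dim(cube_a$data)[1:2] == dim(cube_b_hr$data)[1:2])) {
    reg <- stage("register", {
      r <- register_cubes(cube_a, cube_b_hr,
                          pc_low = config$registration$pc_a,
                          pc_high = config$registration$pc_b,
                          threshold = config$registration$threshold,
                          rot90_quarter_turns = config$registration$rot90,
                          flip_axes = config$registration$flips,
                          search_orientation = isTRUE(config$registration$search_orientation))
      list(final_msd = r$pipeline$final_msd, pipeline = r$pipeline,
           cube = r$registered)
    })
    cube_b <- reg$cube
    report$register <- reg[c("final_msd", "pipeline", "elapsed_s")]
  } else cube_b <- cube_b_hr

  # --- preprocessing for the analysis stages ----------------------------
  prep <- function(cube) {
    if (!isTRUE(config$preprocess$savgol)) return(cube)
    um <- savgol_second_derivative(unfold(cube), config$preprocess$window,
                                   config$preprocess$polyorder)
    refold(um)
  }
  pa <- prep(cube_a); pb <- prep(cube_b)

  # --- classification ----------------------------------------------------
  if ("classify" %in% config$stages) {
    report$classification <- stage("classify", {
      res <- list()
      acc <- c(); nlv <- c()
      run_one <- function(cube) classify_cube(cube, labels, config$max_lv)
      single <- list()
      if (any(c("a_only", "high") %in% config$fusion_levels))
        single$a <- run_one(pa)
      if (any(c("b_only", "high") %in% config$fusion_levels))
        single$b <- run_one(pb)
      if ("a_only" %in% config$fusion_levels) {
        acc["a_only"] <- single$a$accuracy; nlv["a_only"] <- single$a$n_lv }
      if ("b_only" %in% config$fusion_levels) {
        acc["b_only"] <- single$b$accuracy; nlv["b_only"] <- single$b$n_lv }
      if ("low" %in% config$fusion_levels) {
        r <- run_one(low_level_fuse(pa, pb))
        acc["low"] <- r$accuracy; nlv["low"] <- r$n_lv }
      if ("mid" %in% config$fusion_levels) {
        r <- run_one(mid_level_fuse(pa, pb, config$n_pcs))
        acc["mid"] <- r$accuracy; nlv["mid"] <- r$n_lv }
      if ("high" %in% config$fusion_levels) {
        cons <- consensus_fuse(single$a$class_map, single$b$class_map)
        acc["high"] <- classification_accuracy(cons, single$a$truth)
        nlv["high"] <- max(single$a$n_lv, single$b$n_lv) }
      list(accuracy = acc, n_lv = nlv)
    })
  }

  # --- co-inertia --------------------------------------------------------
  if ("coinertia" %in% config$stages) {
    report$coinertia <- stage("coinertia", {
      sc <- scale_blocks(list(unfold(pa), unfold(pb)))
      fit <- coinertia_fit(sc$blocks, config$coinertia_components)
      list(metrics = coinertia_metrics(fit, c(pa$modality, pb$modality)),
           eigenvalues = fit$eigenvalues)
    })
  }

  # --- correlation -------------------------------------------------------
  if ("correlate" %in% config$stages) {
    report$correlation <- stage("correlate", {
      cm <- correlation_map(unfold(pa), unfold(pb))
      pairs <- high_correlation_pairs(cm, config$correlation_threshold)
      list(n_pairs = nrow(pairs),
           ranges_a = attr(pairs, "ranges_a"),
           ranges_b = attr(pairs, "ranges_b"),
           max_abs_r = max(abs(cm$r), na.rm = TRUE), map = cm)
    })
  }

  # --- prediction --------------------------------------------------------
  if ("predict" %in% config$stages || "enhance" %in% config$stages) {
    report$prediction <- stage("predict", {
      ua <- unfold(pa); ub <- unfold(pb)
      m_ab <- plsr_fit(ua, ub, config$max_lv)   # predict B from A
      m_ba <- plsr_fit(ub, ua, config$max_lv)   # predict A from B
      pred_b <- refold(plsr_predict(m_ab, ua))
      pred_a <- refold(plsr_predict(m_ba, ub))
      list(model_ab = m_ab, model_ba = m_ba,
           rel_err_b = relative_error_spectrum(pb, pred_b),
           rel_err_a = relative_error_spectrum(pa, pred_a),
           test_r2_ab = m_ab$test_r2, test_r2_ba = m_ba$test_r2)
    })
  }

  # --- enhancement -------------------------------------------------------
  if ("enhance" %in% config$stages) {
    report$enhancement <- stage("enhance", {
      hr_src <- cube_b_hr
      pipe <- report$register$pipeline
      if (!is.null(pipe)) {
        # predictor must enter on the oriented high-resolution grid
        arr <- hr_src$data
        nb <- dim(arr)[3]
        o1 <- orient_and_resize(arr[, , 1], pipe$rot90_quarter_turns, pipe$flip_axes)
        out <- array(0, c(dim(o1), nb))
        out[, , 1] <- o1
        if (nb > 1) for (b in 2:nb)
          out[, , b] <- orient_and_resize(arr[, , b], pipe$rot90_quarter_turns,
                                          pipe$flip_axes)
        hr_src <- chem_cube(out, hr_src$axis, hr_src$pixel_size_um,
                            modality = hr_src$modality)
      }
      dn <- min(config$denoise_pcs, dim(hr_src$data)[3],
                prod(dim(hr_src$data)[1:2]))
      enhanced <- enhance_resolution(report$prediction$model_ba, hr_src,
                                     denoise_components = dn,
                                     targets = config$predict_targets)
      list(shape = dim(enhanced$data), cube = enhanced)
    })
  }

  report$finished <- format(Sys.time())
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) write_run_outputs(report, config)
  report
}

write_run_outputs <- function(report, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  for (w in c("classification", "coinertia", "correlation", "error")) {
    tab <- tryCatch(report_table(report, w), error = function(e) NULL)
    if (!is.null(tab)) writeLines(tab, p(paste0(w, ".csv")))
  }
  slim <- report
  slim$correlation$map <- NULL
  slim$prediction$model_ab <- slim$prediction$model_ba <- NULL
  slim$enhancement$cube <- NULL
  slim$register$pipeline <- NULL
  jsonlite::write_json(slim, p("report.json"), auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  if (!is.null(report$register$pipeline))
    write_pipeline(report$register$pipeline, p("pipeline.json"))
  if (!is.null(report$enhancement$cube))
    write_envi(report$enhancement$cube, p("enhanced.envi"))
  invisible(config$out_dir)
}

#' Render a report table as CSV text
#'
#' @param report A [run_pipeline()] report.
#' @param which `"classification"` (accuracy and LV count per fusion
#'   level), `"coinertia"` (the six-row block metric table),
#'   `"correlation"` (high-correlation band ranges) or `"error"`
#'   (relative-error spectra).
#' @return Character vector of CSV lines.
#' @export
report_table <- function(report, which = c("classification", "coinertia",
                                           "correlation", "error")) {
  which <- match.arg(which)
  part <- switch(which, classification = report$classification,
                 coinertia = report$coinertia,
                 correlation = report$correlation,
                 error = report$prediction)
  if (is.null(part)) stop("stage '", which, "' was not run")
  fmt <- function(df) {
    c(paste(c("", names(df)), collapse = ","),
      vapply(seq_len(nrow(df)), function(i)
        paste(c(rownames(df)[i], unlist(df[i, ])), collapse = ","), character(1)))
  }
  switch(which,
    classification = {
      df <- data.frame(rbind(`% Correct Class` = round(part$accuracy, 2),
                             `#LV` = part$n_lv), check.names = FALSE)
      names(df) <- names(part$accuracy)
      fmt(df)
    },
    coinertia = fmt(round(part$metrics, 4)),
    correlation = c("modality,ranges",
                    paste0("a,\"", paste(part$ranges_a, collapse = "; "), "\""),
                    paste0("b,\"", paste(part$ranges_b, collapse = "; "), "\"")),
    error = {
      df <- data.frame(band = seq_along(part$rel_err_a),
                       rel_err_a_pct = part$rel_err_a)
      c("band,rel_err_a_pct",
        vapply(seq_len(nrow(df)), function(i)
          paste(df$band[i], df$rel_err_a_pct[i], sep = ","), character(1)))
    })
}
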