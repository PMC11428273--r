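#' Default pipeline configuration
#'
#' The full nested configuration with every tunable of the pipeline, ready
#' to be overridden (see [run_pipeline()]). Printed defaults of the method
#' are wired in: K = 4 modes, low-frequency cutoff 0.05 Hz, loss weights
#' (50, 3, 1, 1), initial learning rate 0.01, batch size 128, hidden width
#' 96, split 7:2:1.
#'
#' @return Nested named list of configuration sections.
#' @export
default_run_config <- function() {
  list(
    paths = list(input_dir = NULL, out_dir = "boldcast-run", force = FALSE),
    simulate = list(n_subjects = 2L, m = 4L, T = 300L, tr_seconds = 0.72,
                    noise_sigma = 0.2, ar_coeff = 0.3,
                    coupling_strength = 0.5, seed = 1L),
    vmd = list(K = 4L, alpha = 2000, tau = 0, tol = 1e-7, max_iter = 500L,
               init_mode = "uniform", seed = 1L, f_max_hz = 0.05),
    window = list(D = 20L, H = 10L, stride = 1L),
    split = list(fractions = c(0.7, 0.2, 0.1)),
    model = list(gru_hidden = 96L, fc_nodes = 96L, attn_channels = 16L,
                 cbam_reduction = 8L, spatial_kernel = 7L,
                 enc_conv_channels = 16L),
    loss = list(lambda_ae = 50, lambda_t = 3, lambda_dis = 1, lambda_g = 1,
                trend_epsilon = 0.01),
    train = list(lr_init = 0.01, decay_rate = 1, decay_steps = 50L,
                 batch_size = 128L, supervised_epochs = 50L,
                 joint_epochs = 50L, d_steps_per_g_step = 1L,
                 grad_clip = NULL, seed = 1L),
    targets = NULL,
    extend = list(length = 0L),
    reliability = list(run = TRUE))
}

# strict recursive merge: every user key must exist in the defaults
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) return(user)
  extra <- setdiff(names(user), names(defaults))
  if (length(extra))
    stop("unknown config key", if (length(extra) > 1L) "s", ": ",
         paste0(sub("^\\.", "", paste0(path, ".", extra)), collapse = ", "))
  for (nm in names(user)) {
    defaults[[nm]] <- if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
                          !is.null(names(defaults[[nm]])))
      merge_config(defaults[[nm]], user[[nm]], paste0(path, ".", nm))
    else user[[nm]]
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Merges a user configuration (a nested list, or the path of a YAML file
#' with the same structure) over [default_run_config()]. Unknown keys are
#' rejected by name.
#'
#' @param config nested list, YAML file path, or `NULL` for pure defaults.
#' @return Validated full configuration list.
#' @export
load_run_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  merge_config(default_run_config(), config)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full forecasting pipeline
#'
#' Executes decompose -> window -> train -> evaluate (-> extend ->
#' reliability) for every subject of a cohort, writing all artifacts under
#' the configured output directory:
#' `cohort/` (the input tables, when simulated), `decomposition.json`
#' (center frequencies in Hz and selected modes), `evaluation.json`
#' (per-task test metrics on the normalized scale, with the persistence
#' baseline), `extended/` (prolonged tables, when `extend$length > 0`),
#' `reliability.json`, and `manifest.json` (package version, seeds, config).
#' A run is a pure function of its configuration: rerunning with the same
#' seeds reproduces the reports.
#'
#' @param config see [load_run_config()].
#' @return Invisibly, a list with the cohort, per-subject models, the
#'   evaluation data frame, the reliability summary, and the output paths.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- load_run_config(config)
  out_dir <- cfg$paths$out_dir
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !isTRUE(cfg$paths$force))
    stop("output directory ", out_dir,
         " already holds a run (use paths$force = TRUE to overwrite)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- stage("input", {
    if (!is.null(cfg$paths$input_dir)) {
      read_cohort(cfg$paths$input_dir)
    } else {
      sc <- cfg$simulate
      co <- generate_cohort(synthetic_config(
        n_subjects = sc$n_subjects, m = sc$m, T = sc$T,
        tr_seconds = sc$tr_seconds, noise_sigma = sc$noise_sigma,
        ar_coeff = sc$ar_coeff,
        coupling = if (sc$coupling_strength > 0)
          coupling_matrix(sc$m, sc$coupling_strength) else NULL,
        seed = sc$seed))
      write_cohort(co, file.path(out_dir, "cohort"), force = TRUE)
      co
    }
  })

  vmd_cfg <- vmd_config(K = cfg$vmd$K, alpha = cfg$vmd$alpha,
                        tau = cfg$vmd$tau, tol = cfg$vmd$tol,
                        max_iter = cfg$vmd$max_iter,
                        init_mode = cfg$vmd$init_mode, seed = cfg$vmd$seed)
  wspec <- window_spec(cfg$window$D, cfg$window$H, cfg$window$stride)
  weights <- loss_weights(cfg$loss$lambda_ae, cfg$loss$lambda_t,
                          cfg$loss$lambda_dis, cfg$loss$lambda_g)
  tcfg <- train_config(
    lr_init = cfg$train$lr_init, decay_rate = cfg$train$decay_rate,
    decay_steps = cfg$train$decay_steps, batch_size = cfg$train$batch_size,
    supervised_epochs = cfg$train$supervised_epochs,
    joint_epochs = cfg$train$joint_epochs,
    d_steps_per_g_step = cfg$train$d_steps_per_g_step,
    grad_clip = cfg$train$grad_clip, trend_epsilon = cfg$loss$trend_epsilon,
    seed = cfg$train$seed)
  gen_args <- cfg$model

  all_models <- list()
  eval_rows <- list()
  dec_report <- list()
  for (subject in cohort$subjects) {
    sm <- stage(paste0("train[", subject$subject_id, "]"),
      train_subject_models(subject, wspec, targets = cfg$targets,
                           vmd_cfg = vmd_cfg, f_max_hz = cfg$vmd$f_max_hz,
                           weights = weights, config = tcfg,
                           fractions = cfg$split$fractions,
                           gen_args = gen_args))
    all_models[[subject$subject_id]] <- sm
    for (mm in sm$models) {
      te <- mm$splits$test
      yhat <- predict_batched(mm$state, te$inputs)
      dtws <- vapply(seq_len(nrow(yhat)),
                     function(i) dtw_distance(te$targets[i, ], yhat[i, ]),
                     numeric(1))
      eval_rows[[length(eval_rows) + 1L]] <- data.frame(
        subject = subject$subject_id,
        region = subject$region_labels[mm$region],
        imf = mm$imf_rank,
        rmse = rmse(te$targets, yhat),
        mae = mae(te$targets, yhat),
        dtw = mean(dtws),
        persistence_rmse = rmse(te$targets, persistence_forecast(te)))
    }
    dec_report[[subject$subject_id]] <- lapply(
      seq_along(subject$region_labels), function(r) {
        res <- vmd_decompose(subject$data[r, ], vmd_cfg)
        list(region = subject$region_labels[r],
             center_freqs_hz = center_freqs_hz(res, subject$tr_seconds),
             selected = select_low_modes(res, subject$tr_seconds,
                                         cfg$vmd$f_max_hz))
      })
  }
  evaluation <- do.call(rbind, eval_rows)
  jsonlite::write_json(dec_report, file.path(out_dir, "decomposition.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(evaluation, file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)

  if (cfg$extend$length > 0L) {
    ext_dir <- file.path(out_dir, "extended")
    dir.create(ext_dir, showWarnings = FALSE)
    stage("extend", for (subject in cohort$subjects) {
      ext <- extend_series(all_models[[subject$subject_id]], subject,
                           cfg$extend$length)
      write_roi_table(ext, file.path(ext_dir,
                                     paste0(subject$subject_id, ".tsv")))
    })
  }

  reliability <- NULL
  if (isTRUE(cfg$reliability$run)) {
    reliability <- stage("reliability", {
      H <- wspec$H
      predicted <- lapply(cohort$subjects, function(subject) {
        sm <- all_models[[subject$subject_id]]
        T <- ncol(subject$data)
        seg <- matrix(0, nrow(subject$data), H)
        for (k in seq_len(sm$n_sel)) {
          blk <- sm$blocks[[k]]
          hist_win <- blk[, (T - H - sm$wspec$D + 1L):(T - H), drop = FALSE]
          for (r in seq_len(nrow(blk))) {
            st <- sm$models[[paste0("r", r, ".imf", k)]]$state
            seg[r, ] <- seg[r, ] +
              denormalize_minmax(predict(st, hist_win), sm$norm_params[[k]][[r]])
          }
        }
        pred_data <- subject$data
        pred_data[, (T - H + 1L):T] <- seg
        list(series = roi_series(subject$subject_id, pred_data,
                                 subject$region_labels, subject$tr_seconds),
             segment = seg,
             true_segment = subject$data[, (T - H + 1L):T, drop = FALSE])
      })
      rel <- list(n_subjects = length(cohort$subjects))
      if (length(cohort$subjects) >= 3L) {
        fc_p <- lapply(predicted, function(p) fc_matrix(p$series))
        fc_t <- lapply(cohort$subjects, fc_matrix)
        edges <- withCallingHandlers(icc_edges(fc_p, fc_t),
          warning = function(w) invokeRestart("muffleWarning"))
        rel$edges <- edges
        rel$mean_icc <- mean(edges$icc, na.rm = TRUE)
        rel$grade_counts <- as.list(table(factor(edges$grade,
          levels = c("poor", "fair", "good", "excellent"))))
      }
      rel$per_subject_pearson <- lapply(seq_along(predicted), function(i) {
        p <- predicted[[i]]
        r <- vapply(seq_len(nrow(p$segment)), function(rr) {
          stats::cor(p$segment[rr, ], p$true_segment[rr, ])
        }, numeric(1))
        list(subject = cohort$subjects[[i]]$subject_id,
             pearson = stats::setNames(r, cohort$subjects[[i]]$region_labels))
      })
      rel
    })
    jsonlite::write_json(reliability, file.path(out_dir, "reliability.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }

  manifest <- list(
    package = "boldcast",
    version = tryCatch(as.character(utils::packageVersion("boldcast")),
                       error = function(e) "unknown"),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = list(simulate = cfg$simulate$seed, vmd = cfg$vmd$seed,
                 train = cfg$train$seed),
    config = cfg)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)

  invisible(list(cohort = cohort, models = all_models,
                 evaluation = evaluation, reliability = reliability,
                 out_dir = out_dir))
}
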