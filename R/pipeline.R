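#' Build a pipeline run configuration
#'
#' Collects every tunable of the analysis with defaults fixed to the
#' reference protocol: 55-min (11-frame) zero-phase smoothing, a 600-min
#' analysis window, fit constraints `t0` in `[-30, tau - 30]` min and `k` in
#' `[0, 0.01]`, an F-test cutoff of 0.05 with floor rate `1e-7`, an `r2`
#' retry cutoff of 0.5, an early-death discard cutoff of 70 min, and a
#' 10-ng/ml minimum dose for pooled threshold estimation.
#'
#' @param generator `NULL`, or a list describing synthetic input:
#'   `scenarios` (list of [scenario()] objects, or a single one), `n` cells
#'   per scenario, and optionally `params` (a [population_params()]; default
#'   [calibrate_population()]).
#' @param input `NULL`, or a list of paths: `trajectories`, `cells`,
#'   optionally `control` (two-column CSV `time_min`, `fret_ratio`).
#' @param window smoothing window, frames.
#' @param horizon analysis window, min.
#' @param k_max,t0_min,t0_margin fit constraints.
#' @param alpha F-test cutoff.
#' @param r2_retry secondary-maximum retry cutoff.
#' @param k_floor fallback activation rate.
#' @param early_death early-death discard cutoff, min.
#' @param theta_dose_min minimum dose (as numeric condition label) entering
#'   the pooled threshold estimate.
#' @param t0_bar population mean lag used by the fate boundary, min.
#' @param n_boot bootstrap replicates for the threshold accuracy SEM.
#' @param seed integer seed for generation and bootstrap.
#' @param out_dir output directory (`NULL`: nothing written).
#' @return A validated list of class `c8_config`.
#' @export
c8_config <- function(generator = NULL, input = NULL, window = 11L,
                      horizon = 600, k_max = 0.01, t0_min = -30,
                      t0_margin = 30, alpha = 0.05, r2_retry = 0.5,
                      k_floor = 1e-7, early_death = 70, theta_dose_min = 10,
                      t0_bar = 20, n_boot = 200, seed = 1L,
                      out_dir = NULL) {
  cfg <- list(generator = generator, input = input, window = window,
              horizon = horizon, k_max = k_max, t0_min = t0_min,
              t0_margin = t0_margin, alpha = alpha, r2_retry = r2_retry,
              k_floor = k_floor, early_death = early_death,
              theta_dose_min = theta_dose_min, t0_bar = t0_bar,
              n_boot = n_boot, seed = seed, out_dir = out_dir)
  stopifnot(
    "alpha must be in (0,1)" = alpha > 0 && alpha < 1,
    "cutoffs must be positive" =
      all(c(window, horizon, k_max, t0_margin, r2_retry, k_floor,
            early_death) > 0),
    "exactly one of generator/input" = is.null(generator) != is.null(input)
  )
  class(cfg) <- "c8_config"
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' @param path configuration file; YAML (JSON is valid YAML) describing the
#'   arguments of [c8_config()]. Generator scenarios are given as lists of
#'   [scenario()] arguments.
#' @return A `c8_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$generator)) {
    g <- raw$generator
    # YAML 1.1 reads a bare `n:` key as the boolean FALSE; undo that, and
    # accept the unambiguous alias `n_cells`
    names(g)[names(g) %in% c("FALSE", "n_cells")] <- "n"
    if (!is.null(g$scenarios))
      g$scenarios <- lapply(g$scenarios, function(s) do.call(scenario, s))
    if (!is.null(g$params)) g$params <- do.call(calibrate_population,
                                                g$params)
    raw$generator <- g
  }
  do.call(c8_config, raw)
}

#' Validate input tables against the trajectory schema
#'
#' Structural checks on the long trajectory table and the per-cell table:
#' required columns, duplicate cell ids, fate domain, death-time
#' consistency (dying cells need a death time no earlier than their first
#' frame; survivors must not have one), uniform time grids, and cells
#' without trajectories.
#'
#' @param trajectories data frame `cell_id`, `time_min`, `fret_ratio`.
#' @param cells data frame `cell_id`, `fate`, optionally `death_time`.
#' @return Data frame of violations (`check`, `detail`); zero rows when
#'   clean.
#' @export
validate_input <- function(trajectories, cells) {
  v <- list()
  add <- function(check, detail)
    v[[length(v) + 1]] <<- data.frame(check = check, detail = detail,
                                      stringsAsFactors = FALSE)
  need_t <- setdiff(c("cell_id", "time_min", "fret_ratio"),
                    names(trajectories))
  if (length(need_t))
    add("missing_column", paste("trajectories:", paste(need_t,
                                                       collapse = ", ")))
  need_c <- setdiff(c("cell_id", "fate"), names(cells))
  if (length(need_c))
    add("missing_column", paste("cells:", paste(need_c, collapse = ", ")))
  if (length(need_t) || length(need_c))
    return(do.call(rbind, v))

  dup <- cells$cell_id[duplicated(cells$cell_id)]
  if (length(dup)) add("duplicate_cell_id", paste(unique(dup),
                                                  collapse = ", "))
  bad_fate <- !cells$fate %in% c("died", "survived")
  if (any(bad_fate))
    add("fate_domain", paste("cells:",
                             paste(cells$cell_id[bad_fate], collapse = ", ")))
  dt_col <- if ("death_time" %in% names(cells)) cells$death_time
            else rep(NA_real_, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    id <- cells$cell_id[i]
    tt <- trajectories$time_min[trajectories$cell_id == id]
    if (!length(tt)) { add("missing_trajectory", id); next }
    tt <- sort(tt)
    if (length(tt) > 2) {
      d <- diff(tt)
      off <- which(abs(d - d[1]) > 1e-6)
      if (length(off))
        add("non_uniform_grid",
            sprintf("%s: first offending time %g", id, tt[off[1] + 1]))
    }
    if (identical(cells$fate[i], "died")) {
      if (is.na(dt_col[i]))
        add("death_time_missing", id)
      else if (dt_col[i] < tt[1])
        add("death_time_before_first_frame", id)
    } else if (!is.na(dt_col[i])) {
      add("death_time_on_survivor", id)
    }
  }
  if (!length(v))
    return(data.frame(check = character(), detail = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, v)
}

#' Run the full analysis pipeline
#'
#' Executes generate (optional) -> validate -> preprocess + fit -> threshold
#' -> classify -> summarise, logging per-stage timing and cell counts to
#' stderr, and (with `out_dir`) writing `trajectories.csv`, `cells.csv`,
#' `fits.csv`, `classification.csv`, `threshold.json`, `summaries.csv`,
#' `dose_response.json` (when at least four conditions are present) and a
#' JSON run `manifest.json`. Identical configuration and seed give
#' identical outputs.
#'
#' @param config a [c8_config()], or a path passed to [read_config()].
#' @return Invisibly, a list: `fit` (the [c8_fit()] object), `threshold`,
#'   `classification`, `summaries`, `logistic` (or `NULL`), `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "c8_config"))
  manifest <- list(config = config_echo(config), seed = config$seed,
                   package_version = as.character(utils::packageVersion("c8fate")),
                   stages = list())
  t_start <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      manifest$failed_stage <<- name
      manifest$error <<- conditionMessage(e)
      if (!is.null(config$out_dir)) write_manifest(manifest, config$out_dir)
      stop(e)
    })
    manifest$stages[[name]] <<- list(seconds =
      round(proc.time()[["elapsed"]] - t0, 2))
    message(sprintf("[c8fate] %-10s %6.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  dat <- stage("load", {
    if (!is.null(config$generator)) {
      g <- config$generator
      params <- if (is.null(g$params)) calibrate_population() else g$params
      scns <- g$scenarios
      if (inherits(scns, "c8_scenario")) scns <- list(scns)
      set.seed(config$seed)
      sets <- lapply(scns, function(s)
        generate_dataset(params, s, g$n, seed = NULL))
      cells <- do.call(rbind, lapply(seq_along(sets), function(i) {
        cc <- sets[[i]]$cells
        cc$cell_id <- paste0("s", i, "_", cc$cell_id)
        cc
      }))
      trajs <- do.call(rbind, lapply(seq_along(sets), function(i) {
        tr <- sets[[i]]$trajectories
        tr$cell_id <- paste0("s", i, "_", tr$cell_id)
        tr
      }))
      list(trajectories = trajs, cells = cells, control = NULL)
    } else {
      tr <- utils::read.csv(config$input$trajectories,
                            stringsAsFactors = FALSE)
      cc <- utils::read.csv(config$input$cells, stringsAsFactors = FALSE)
      names(cc)[names(cc) == "death_time_min"] <- "death_time"
      ctl <- if (!is.null(config$input$control))
        utils::read.csv(config$input$control, stringsAsFactors = FALSE)
      list(trajectories = tr, cells = cc, control = ctl)
    }
  })

  stage("validate", {
    viol <- validate_input(dat$trajectories, dat$cells)
    if (nrow(viol)) {
      msg <- paste(apply(viol, 1, paste, collapse = ": "), collapse = "; ")
      stop(structure(class = c("c8_schema_error", "error", "condition"),
                     list(message = paste("input schema violations:", msg),
                          call = NULL)))
    }
    NULL
  })

  fit <- stage("fit", c8_fit(dat$trajectories, dat$cells,
                             control = dat$control,
                             window = config$window,
                             horizon = config$horizon,
                             k_max = config$k_max, t0_min = config$t0_min,
                             t0_margin = config$t0_margin,
                             r2_retry = config$r2_retry,
                             alpha = config$alpha,
                             k_floor = config$k_floor,
                             early_death = config$early_death,
                             keep_prep = FALSE))
  kept <- fit$fits[!fit$fits$discarded, ]
  manifest$cell_counts <- list(input = nrow(fit$fits),
                               fitted = nrow(kept),
                               discarded = sum(fit$fits$discarded),
                               fallback = sum(kept$fallback))

  thr <- stage("threshold", {
    pool <- kept
    dose <- suppressWarnings(as.numeric(gsub("[^0-9.]+", "",
                                             pool$condition)))
    if (any(is.finite(dose)))
      pool <- pool[is.finite(dose) & dose >= config$theta_dose_min, ,
                   drop = FALSE]
    if (nrow(pool) < 2) pool <- kept
    estimate_theta(pool$max_c8, pool$fate, n_boot = config$n_boot,
                   seed = config$seed)
  })

  cls <- stage("classify", {
    svm_pred <- tryCatch(
      fit_linear_margin_classifier(kept$k, kept$tau, kept$fate)$predicted,
      error = function(e) rep(NA_character_, nrow(kept)))
    data.frame(cell_id = kept$cell_id, max_c8 = kept$max_c8,
               fate = kept$fate,
               predicted_threshold = ifelse(kept$max_c8 >= thr$theta_hat,
                                            "died", "survived"),
               predicted_boundary = classify_by_boundary(
                 kept$k, kept$tau, thr$theta_hat, config$t0_bar),
               predicted_svm = svm_pred, stringsAsFactors = FALSE)
  })

  sums <- stage("summarize", {
    do.call(rbind, lapply(unique(kept$condition), function(cond)
      summarize_condition(fit$fits, cond)))
  })
  logi <- if (nrow(sums) >= 4)
    tryCatch(fit_logistic_survival(sums), error = function(e) NULL)

  if (!is.null(config$out_dir)) {
    stage("write", {
      d <- config$out_dir
      dir.create(d, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(dat$trajectories, file.path(d, "trajectories.csv"),
                       row.names = FALSE)
      cells_out <- dat$cells
      names(cells_out)[names(cells_out) == "death_time"] <- "death_time_min"
      utils::write.csv(cells_out, file.path(d, "cells.csv"),
                       row.names = FALSE)
      utils::write.csv(fit$fits, file.path(d, "fits.csv"),
                       row.names = FALSE)
      utils::write.csv(cls, file.path(d, "classification.csv"),
                       row.names = FALSE)
      utils::write.csv(sums, file.path(d, "summaries.csv"),
                       row.names = FALSE)
      jsonlite::write_json(list(theta_hat = thr$theta_hat,
                                accuracy = thr$accuracy,
                                sem = thr$sem_accuracy,
                                n_cells = thr$n_cells,
                                n_candidates = length(thr$candidate_grid),
                                dose_filter = config$theta_dose_min),
                           file.path(d, "threshold.json"),
                           auto_unbox = TRUE, digits = NA)
      if (!is.null(logi))
        jsonlite::write_json(list(midpoint = logi$midpoint,
                                  slope = logi$slope, r2 = logi$r2,
                                  identifiable = logi$identifiable),
                             file.path(d, "dose_response.json"),
                             auto_unbox = TRUE, digits = NA)
      NULL
    })
  }
  manifest$total_seconds <- round(proc.time()[["elapsed"]] - t_start, 2)
  if (!is.null(config$out_dir)) write_manifest(manifest, config$out_dir)

  invisible(list(fit = fit, threshold = thr, classification = cls,
                 summaries = sums, logistic = logi, manifest = manifest))
}

config_echo <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$generator)) {
    g <- cfg$generator
    cfg$generator <- list(
      n = g$n,
      scenarios = lapply(if (inherits(g$scenarios, "c8_scenario"))
        list(g$scenarios) else g$scenarios, unclass),
      params = if (!is.null(g$params)) unclass(g$params))
  }
  cfg
}

write_manifest <- function(manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
}
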