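#' Preprocess a cohort end to end
#'
#' Convenience glue: bins gaze samples ([bin_trials()]) and aggregates them
#' to participant-level timecourses ([aggregate_participant()]).
#'
#' @param samples,trials Cohort tables (see [read_sample_report()],
#'   [read_trial_metadata()]).
#' @param layout A [roi_layout()].
#' @param grid A [bin_grid()].
#' @param keep_only_correct Drop incorrectly answered trials (default TRUE).
#' @return Participant-level timecourses (see [aggregate_participant()]).
#' @export
preprocess_cohort <- function(samples, trials, layout = roi_layout(),
                              grid, keep_only_correct = TRUE) {
  tb <- bin_trials(samples, trials, layout, grid)
  aggregate_participant(tb, keep_only_correct = keep_only_correct)
}

default_config <- function() {
  list(
    timeline = list(
      durations = list(the1 = 93.58, agent = 612.72, verb = 602.05,
                       the2 = 130.27, object = 464.45),
      post_delay_ms = 2000
    ),
    grid = list(bin_ms = 20, window_start_ms = 0, window_end_ms = NULL),
    filters = list(intelligibility = "intelligibility_pct >= 50"),
    keep_only_correct = TRUE,
    contrasts = list(
      list(label = "sub1_prediction", sub_experiment = "1", condition = "CP",
           role_a = "target", role_b = "cu_target"),
      list(label = "sub1_cost", sub_experiment = "1", condition = "CU",
           role_a = "cu_target", role_b = "distractor1"),
      list(label = "sub2_early", sub_experiment = "2", condition = "CP",
           role_a = "target", role_b = "verb_distractor"),
      list(label = "sub2_late", sub_experiment = "2", condition = "CP",
           role_a = "target", role_b = "agent_competitor"),
      list(label = "fillers", sub_experiment = "filler", condition = "neutral",
           role_a = "target", role_b = "distractor1")
    ),
    dpa = list(n_boot = 2000, alpha = 0.05, tail = "one_sided",
               consec_bins = 10, ci = c(0.025, 0.975), baseline = "PwNH"),
    seed = 1,
    out_dir = "vwpdpa_results"
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a pipeline run configuration
#'
#' Reads a YAML configuration and fills unspecified settings with defaults.
#' The configuration names the input files (`inputs: samples/trials/
#' participants`), the timeline, the bin grid, participant filter rules, the
#' contrast list, and the DPA settings (`n_boot`, `alpha`, `tail`,
#' `consec_bins`, `ci`, `baseline`). Referenced input files must exist.
#'
#' @param path Path to a YAML file.
#' @return A configuration list for [run_pipeline()].
#' @export
run_config <- function(path) {
  cfg <- merge_config(default_config(), yaml::read_yaml(path))
  for (f in unlist(cfg$inputs)) {
    if (!file.exists(f)) {
      stop("config error: input file does not exist: ", f, call. = FALSE)
    }
  }
  cfg
}

log_line <- function(con, stage, ...) {
  rec <- c(list(stage = stage), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

#' Run the full analysis pipeline
#'
#' Orchestrates load (or use in-memory cohort) -> preprocess -> divergence
#' point analysis -> report. Writes, under `config$out_dir`: the accuracy
#' summary (`accuracy_summary.csv`), participant filter log
#' (`filter_log.json`), per-group DPA results (`dpa_results.csv`),
#' between-group differences with CI classifications
#' (`group_differences.csv`), a verbatim configuration echo
#' (`config_echo.json`), a JSON-lines stage log (`log.jsonl`), and one
#' timecourse figure per contrast.
#'
#' @param config Configuration list (see [run_config()]); may carry an
#'   in-memory `cohort` (as from [simulate_cohort()]) instead of `inputs`.
#' @param write_figures Write one PNG per contrast (default TRUE).
#' @return Invisibly, a result bundle: `series`, `group_map`,
#'   `accuracy`, `dpa` (per-contrast [dpa_by_group()] results), `tables`
#'   (combined result tibbles), `figures` (ggplot objects), `out_dir`.
#' @export
run_pipeline <- function(config, write_figures = TRUE) {
  cfg <- merge_config(default_config(), config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out_dir, "log.jsonl"), open = "wt")
  on.exit(close(log_con), add = TRUE)

  # --- load ---------------------------------------------------------------
  if (!is.null(cfg$cohort)) {
    samples <- cfg$cohort$samples
    trials <- recompute_accuracy(cfg$cohort$trials)
    participants <- cfg$cohort$participants
  } else if (!is.null(cfg$inputs)) {
    samples <- read_sample_report(cfg$inputs$samples)
    trials <- read_trial_metadata(cfg$inputs$trials)
    participants <- read_participant_metadata(cfg$inputs$participants)
  } else {
    stop("config error: provide either `cohort` or `inputs`", call. = FALSE)
  }

  timeline <- build_timeline(unlist(cfg$timeline$durations),
                             cfg$timeline$post_delay_ms)
  end_ms <- cfg$grid$window_end_ms
  if (is.null(end_ms)) end_ms <- timeline$selection_cue_ms
  grid <- bin_grid(end_ms, bin_ms = cfg$grid$bin_ms,
                   window_start_ms = cfg$grid$window_start_ms)

  # validate contrasts against the roles that actually occur, before any
  # heavy computation
  known_roles <- unique(unlist(trials[paste0("q", 1:4, "_role")]))
  for (cs in cfg$contrasts) {
    bad <- setdiff(c(cs$role_a, cs$role_b), known_roles)
    if (length(bad) > 0L) {
      stop("config error: contrast '", cs$label, "' references unknown role(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }

  cfg_echo <- cfg
  cfg_echo$cohort <- NULL  # tables are inputs, not configuration
  jsonlite::write_json(cfg_echo, file.path(out_dir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)

  # --- filter participants ------------------------------------------------
  filt <- filter_participants(participants, unlist(cfg$filters))
  meta_in <- participants[participants$participant_id %in% filt$included, ,
                          drop = FALSE]
  if (!is.null(cfg$regroup)) {
    group_map <- regroup_by_metadata(meta_in, unlist(cfg$regroup))
  } else {
    group_map <- meta_in[, c("participant_id", "group")]
  }
  jsonlite::write_json(
    list(rules = as.list(unlist(cfg$filters)),
         n_before = nrow(participants), n_after = nrow(meta_in),
         excluded_per_criterion = stats::setNames(
           as.list(filt$log$n_excluded), filt$log$criterion)),
    file.path(out_dir, "filter_log.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  log_line(log_con, "filter", n_participants = nrow(meta_in),
           n_excluded = nrow(participants) - nrow(meta_in))

  trials <- trials[trials$participant_id %in% group_map$participant_id, ,
                   drop = FALSE]
  samples <- samples[samples$participant_id %in% group_map$participant_id, ,
                     drop = FALSE]

  # --- accuracy + preprocess ----------------------------------------------
  acc <- accuracy_summary(trials, meta = group_map)
  fwrite(acc, file.path(out_dir, "accuracy_summary.csv"))

  series <- preprocess_cohort(samples, trials, roi_layout(), grid,
                              keep_only_correct = cfg$keep_only_correct)
  log_line(log_con, "preprocess", n_trials = nrow(trials),
           n_removed_incorrect = sum(trials$accuracy == 0))

  # --- DPA ----------------------------------------------------------------
  results <- list()
  figures <- list()
  for (cs in cfg$contrasts) {
    contrast <- contrast_spec(
      condition = cs$condition, role_a = cs$role_a, role_b = cs$role_b,
      grid = grid, sub_experiment = cs$sub_experiment,
      tail = cfg$dpa$tail, alpha = cfg$dpa$alpha,
      consec_bins = cfg$dpa$consec_bins, label = cs$label
    )
    res <- dpa_by_group(series, group_map, contrast,
                        baseline = cfg$dpa$baseline,
                        n_boot = cfg$dpa$n_boot, seed = cfg$seed,
                        ci_probs = cfg$dpa$ci)
    results[[cs$label]] <- res
    nonconv <- sum(res$table$n_boot - res$table$n_convergent)
    log_line(log_con, "dpa", contrast = cs$label,
             n_nonconvergent_resamples = nonconv)
    fig <- plot_timecourse(
      series[series$participant_id %in% group_map$participant_id, ],
      estimate = res$estimates[[cfg$dpa$baseline]], timeline = timeline,
      contrast = contrast
    )
    figures[[cs$label]] <- fig
    if (write_figures) {
      ggplot2::ggsave(
        file.path(out_dir, paste0("timecourse_", cs$label, ".png")),
        fig, width = 7, height = 4.5, dpi = 120
      )
    }
  }

  dpa_tab <- dplyr::bind_rows(lapply(results, function(r) r$table))
  diff_tab <- dplyr::bind_rows(lapply(results, function(r) r$diff_table))
  fwrite(dpa_tab, file.path(out_dir, "dpa_results.csv"))
  fwrite(diff_tab, file.path(out_dir, "group_differences.csv"))
  log_line(log_con, "report", n_contrasts = length(results))

  invisible(list(
    series = series, group_map = group_map, accuracy = acc,
    dpa = results, tables = list(dpa = dpa_tab, differences = diff_tab,
                                 filter_log = filt$log),
    figures = figures, out_dir = out_dir
  ))
}

#' Plot a fixation-proportion timecourse
#'
#' Grand-average fixation proportions per image role over time, with dashed
#' vertical lines at the word onsets of the normalized sentence frame and,
#' when a convergent divergence estimate is supplied, a divergence-point
#' marker with its bootstrap CI drawn as a horizontal whisker on the time
#' axis. If the estimate has no convergent resamples the figure carries an
#' annotation instead of a marker.
#'
#' @param series Participant-level timecourses (from
#'   [aggregate_participant()]); averaged over participants per role here.
#' @param estimate Optional [bootstrap_dp()] result to mark.
#' @param timeline Optional [build_timeline()] for word-onset lines.
#' @param contrast Optional [contrast_spec()] used to subset `series` to the
#'   contrast's sub-experiment/condition.
#' @return A ggplot object (the bin-level plot data is in `$data`).
#' @export
plot_timecourse <- function(series, estimate = NULL, timeline = NULL,
                            contrast = NULL) {
  df <- series
  if (!is.null(contrast)) {
    df <- df[df$condition %in% contrast$condition, , drop = FALSE]
    if (!is.null(contrast$sub_experiment)) {
      df <- df[df$sub_experiment %in% contrast$sub_experiment, , drop = FALSE]
    }
  }
  if (nrow(df) == 0L) {
    stop("no series rows to plot", call. = FALSE)
  }
  avg <- df |>
    dplyr::group_by(.data$role, .data$bin_start_ms) |>
    dplyr::summarise(prop = mean(.data$prop, na.rm = TRUE), .groups = "drop")
  p <- ggplot2::ggplot(avg, ggplot2::aes(.data$bin_start_ms, .data$prop,
                                         colour = .data$role)) +
    ggplot2::geom_line(linewidth = 0.7, na.rm = TRUE) +
    ggplot2::labs(x = "Time from audio onset (ms)", y = "Fixation proportion",
                  colour = "Image") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
  if (!is.null(timeline)) {
    p <- p + ggplot2::geom_vline(xintercept = unname(timeline$word_onsets_ms),
                                 linetype = "dashed", colour = "grey55")
  }
  if (!is.null(estimate)) {
    if (estimate$n_convergent > 0L) {
      marker <- tibble::tibble(x = estimate$boot_mean_ms,
                               xmin = estimate$ci_low_ms,
                               xmax = estimate$ci_high_ms, y = 0)
      p <- p +
        ggplot2::geom_segment(
          data = marker,
          ggplot2::aes(x = .data$xmin, xend = .data$xmax,
                       y = .data$y, yend = .data$y),
          inherit.aes = FALSE, linewidth = 1.1
        ) +
        ggplot2::geom_point(
          data = marker, ggplot2::aes(.data$x, .data$y),
          inherit.aes = FALSE, shape = 17, size = 3
        )
    } else {
      p <- p + ggplot2::annotate(
        "text", x = mean(range(avg$bin_start_ms)), y = 0.95,
        label = "no convergent divergence point"
      )
    }
  }
  p
}
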