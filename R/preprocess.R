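#' @importFrom data.table := .N .SD as.data.table data.table CJ melt setnames setorderv fread fwrite
#' @importFrom stats quantile rbinom rgamma runif sd setNames
#' @importFrom utils head
NULL

# quiet R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", "participant_id", "trial_id", "t_ms", "x", "y", "valid", "bin",
  "quadrant", "role", "n_valid", "n_hits", "prop", "accuracy", "condition",
  "sub_experiment", "bin_start_ms", "n_trials", "item_id", "clicked_role",
  "fix_start_ms", "fix_end_ms", "group"
))

required_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(
      what, " is missing required column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
}

#' Read a tab-delimited gaze sample report
#'
#' Expects a header with columns `participant_id`, `trial_id`, `t_ms`, `x`,
#' `y`, and optionally `valid` (logical/0-1; missing means all samples valid).
#' `t_ms` is time relative to audio onset (the 2000 ms image preview is
#' negative time). Extra columns are ignored.
#'
#' @param path Path to the tab-delimited file.
#' @return A tibble of gaze samples.
#' @export
read_sample_report <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  required_cols(dt, c("participant_id", "trial_id", "t_ms", "x", "y"), "sample report")
  if (!"valid" %in% names(dt)) dt[, valid := TRUE]
  dt[, valid := as.logical(valid)]
  tibble::as_tibble(dt[, .(
    participant_id = as.character(participant_id),
    trial_id = as.character(trial_id), t_ms, x, y, valid
  )])
}

#' Read a tab-delimited fixation-event report
#'
#' Expects columns `participant_id`, `trial_id`, `fix_start_ms`,
#' `fix_end_ms`, `x`, `y`. Events are expanded to the sample grid at
#' `sample_rate_hz` (one internal representation for both input kinds); time
#' between fixations is simply absent, so it never contributes to bins.
#'
#' @param path Path to the tab-delimited file.
#' @param sample_rate_hz Sampling rate used for the expansion (default 1000).
#' @return A tibble of gaze samples as from [read_sample_report()].
#' @export
read_fixation_report <- function(path, sample_rate_hz = 1000) {
  dt <- fread(path, sep = "\t", header = TRUE)
  required_cols(
    dt, c("participant_id", "trial_id", "fix_start_ms", "fix_end_ms", "x", "y"),
    "fixation report"
  )
  if (any(dt$fix_end_ms <= dt$fix_start_ms)) {
    stop("fixation report contains events with fix_end_ms <= fix_start_ms", call. = FALSE)
  }
  step <- 1000 / sample_rate_hz
  expand_fixations(
    as.character(dt$participant_id), as.character(dt$trial_id),
    dt$fix_start_ms, dt$fix_end_ms, dt$x, dt$y, step
  )
}

# Expand fixation events into per-sample rows on a regular grid.
# A fixation [s, e) contributes samples at the grid times s', s'+step, ...
# where s' is s rounded up to the grid.
expand_fixations <- function(pid, trial, s, e, x, y, step,
                             valid = rep(TRUE, length(s))) {
  s_grid <- ceiling(s / step) * step
  n <- pmax(0L, as.integer(floor((e - s_grid) / step - 1e-9)) + 1L)
  keep <- n > 0L
  n <- n[keep]
  idx <- rep.int(which(keep), n)
  offs <- sequence(n) - 1
  tibble::tibble(
    participant_id = pid[idx],
    trial_id = trial[idx],
    t_ms = s_grid[keep][rep.int(seq_along(n), n)] + offs * step,
    x = x[idx], y = y[idx], valid = valid[idx]
  )
}

#' Read trial metadata
#'
#' CSV with one row per trial: `participant_id`, `trial_id`, `item_id`,
#' `sub_experiment` (1, 2 or "filler"), `condition` (CP, CU or neutral),
#' `q1_role`..`q4_role` (quadrant-to-role map), `clicked_role`, `accuracy`
#' (0/1), `block`. Accuracy is recomputed from `clicked_role` against the
#' condition's correct role; mismatches with the stored column are reported.
#'
#' @param path Path to the CSV file.
#' @return A tibble of trial records with recomputed accuracy.
#' @export
read_trial_metadata <- function(path) {
  dt <- fread(path, sep = ",", header = TRUE)
  required_cols(dt, c(
    "participant_id", "trial_id", "sub_experiment", "condition",
    "q1_role", "q2_role", "q3_role", "q4_role", "clicked_role"
  ), "trial metadata")
  tr <- tibble::as_tibble(dt)
  tr$participant_id <- as.character(tr$participant_id)
  tr$trial_id <- as.character(tr$trial_id)
  recompute_accuracy(tr)
}

#' The correct (clickable) role for a condition
#'
#' CP and neutral sentences culminate in the predictable/named target; CU
#' sentences culminate in the unpredictable-but-plausible alternative, so
#' their correct answer is the `cu_target` image.
#'
#' @param condition Character vector of conditions (`CP`, `CU`, `neutral`).
#' @return Character vector of role names.
#' @export
correct_role <- function(condition) {
  out <- ifelse(condition == "CU", "cu_target", "target")
  out[!condition %in% c("CP", "CU", "neutral")] <- NA_character_
  out
}

#' Recompute trial accuracy from the clicked image
#'
#' @param trials Trial metadata as from [read_trial_metadata()].
#' @return `trials` with `accuracy` set to 1 when `clicked_role` equals the
#'   condition's correct role; if a stored `accuracy` column disagrees, a
#'   warning reports the number of mismatching rows.
#' @export
recompute_accuracy <- function(trials) {
  acc <- as.integer(trials$clicked_role == correct_role(trials$condition))
  if ("accuracy" %in% names(trials)) {
    mism <- sum(trials$accuracy != acc, na.rm = TRUE)
    if (mism > 0L) {
      warning(
        mism, " trial(s) had a stored accuracy inconsistent with clicked_role; ",
        "using the recomputed value", call. = FALSE
      )
    }
  }
  trials$accuracy <- acc
  trials
}

#' Read participant metadata
#'
#' CSV with columns `participant_id`, `group`, `intelligibility_pct`,
#' `effort_rating`, `age`, `hearing_level`.
#'
#' @param path Path to the CSV file.
#' @return A tibble of participant metadata.
#' @export
read_participant_metadata <- function(path) {
  dt <- fread(path, sep = ",", header = TRUE)
  required_cols(dt, c("participant_id", "group"), "participant metadata")
  meta <- tibble::as_tibble(dt)
  meta$participant_id <- as.character(meta$participant_id)
  if ("intelligibility_pct" %in% names(meta)) {
    bad <- meta$intelligibility_pct < 0 | meta$intelligibility_pct > 100
    if (any(bad, na.rm = TRUE)) {
      stop("intelligibility_pct outside [0, 100] for participant(s): ",
           paste(meta$participant_id[which(bad)], collapse = ", "),
           call. = FALSE)
    }
  }
  meta
}

# long quadrant -> role map, one row per trial x quadrant
trial_role_map <- function(trials) {
  tr <- as.data.table(trials)
  long <- melt(
    tr[, .(participant_id, trial_id, q1_role, q2_role, q3_role, q4_role)],
    id.vars = c("participant_id", "trial_id"),
    variable.name = "quadrant", value.name = "role"
  )
  long[, quadrant := as.integer(sub("q(\\d)_role", "\\1", quadrant))]
  dup <- long[, .(distinct = data.table::uniqueN(role)), by = .(participant_id, trial_id)]
  if (any(dup$distinct != 4L)) {
    bad <- dup[distinct != 4L]
    stop(
      "trial(s) do not map the four quadrants to four distinct roles, e.g. ",
      bad$participant_id[1], "/", bad$trial_id[1],
      call. = FALSE
    )
  }
  long
}

#' Bin gaze samples into per-trial fixation proportions
#'
#' Assigns every valid sample to the image role whose padded region of
#' interest contains it, then computes, per trial and 20 ms bin, the
#' proportion of valid samples on each of the trial's four roles. Invalid
#' samples (blinks, track loss) are removed from both numerator and
#' denominator; a bin with no valid samples is missing (`NA`), not zero.
#'
#' @param samples Gaze samples (as from [read_sample_report()]); may span the
#'   whole cohort.
#' @param trials Trial metadata (as from [read_trial_metadata()]).
#' @param layout A [roi_layout()].
#' @param grid A [bin_grid()].
#' @return A tibble with one row per trial x bin x role: `participant_id`,
#'   `trial_id`, `sub_experiment`, `condition`, `accuracy`, `bin_start_ms`,
#'   `role`, `prop` (in \[0,1\] or `NA`), `n_valid` (valid samples in bin).
#' @export
bin_trials <- function(samples, trials, layout, grid) {
  stopifnot(inherits(layout, "roi_layout"), inherits(grid, "bin_grid"))
  required_cols(samples, c("participant_id", "trial_id", "t_ms", "x", "y"), "samples")
  dt <- as.data.table(samples)
  if (!"valid" %in% names(dt)) dt[, valid := TRUE]
  win_end <- grid$window_start_ms + grid$n_bins * grid$bin_ms
  dt <- dt[t_ms >= grid$window_start_ms & t_ms < win_end]

  roles_long <- trial_role_map(trials)

  if (nrow(dt) > 0L) {
    dt[, bin := as.integer(floor((t_ms - grid$window_start_ms) / grid$bin_ms))]
    dt[, quadrant := roi_quadrant(x, y, layout)]
    dtv <- dt[valid == TRUE]
    totals <- dtv[, .(n_valid = .N), by = .(participant_id, trial_id, bin)]
    hits <- dtv[!is.na(quadrant),
                .(n_hits = .N),
                by = .(participant_id, trial_id, bin, quadrant)]
    hits <- merge(hits, roles_long, by = c("participant_id", "trial_id", "quadrant"))
  } else {
    totals <- data.table(participant_id = character(), trial_id = character(),
                         bin = integer(), n_valid = integer())
    hits <- data.table(participant_id = character(), trial_id = character(),
                       bin = integer(), quadrant = integer(),
                       n_hits = integer(), role = character())
  }

  # complete frame: every trial x bin x that trial's four roles
  bins <- data.table(bin = seq_len(grid$n_bins) - 1L)
  frame <- roles_long[, .(participant_id, trial_id, role)][
    , c(.SD, list(dummy = 1L))][bins[, c(.SD, list(dummy = 1L))],
                                on = "dummy", allow.cartesian = TRUE]
  frame[, dummy := NULL]

  out <- merge(frame, hits[, .(participant_id, trial_id, bin, role, n_hits)],
               by = c("participant_id", "trial_id", "bin", "role"), all.x = TRUE)
  out <- merge(out, totals, by = c("participant_id", "trial_id", "bin"), all.x = TRUE)
  out[is.na(n_valid), n_valid := 0L]
  out[is.na(n_hits), n_hits := 0L]
  out[, prop := ifelse(n_valid > 0L, n_hits / n_valid, NA_real_)]
  out[, bin_start_ms := grid$window_start_ms + bin * grid$bin_ms]

  empty_trials <- out[, .(any_valid = any(n_valid > 0L)),
                      by = .(participant_id, trial_id)][any_valid == FALSE]
  if (nrow(empty_trials) > 0L) {
    warning(
      nrow(empty_trials),
      " trial(s) had no valid samples in the analysis window; all bins missing",
      call. = FALSE
    )
  }

  tr_meta <- as.data.table(trials)[, .(participant_id, trial_id, sub_experiment,
                                       condition, accuracy)]
  out <- merge(out, tr_meta, by = c("participant_id", "trial_id"))
  setorderv(out, c("participant_id", "trial_id", "bin", "role"))
  tibble::as_tibble(out[, .(participant_id, trial_id, sub_experiment, condition,
                            accuracy, bin_start_ms, role, prop, n_valid)])
}

#' Bin a single trial
#'
#' Convenience wrapper around [bin_trials()] for one trial's samples.
#'
#' @param samples Gaze samples for one trial.
#' @param layout A [roi_layout()].
#' @param trial A one-row trial metadata data frame.
#' @param grid A [bin_grid()].
#' @return Per-bin per-role proportions for the trial (see [bin_trials()]).
#' @export
bin_trial <- function(samples, layout, trial, grid) {
  stopifnot(nrow(trial) == 1L)
  bin_trials(samples, trial, layout, grid)
}

#' Aggregate trial-level bins to participant timecourses
#'
#' Averages trial-level bin proportions into one fixation-proportion
#' timecourse per participant x sub-experiment x condition x role (an
#' unweighted mean over trials, giving each trial equal weight). Missing
#' trial-bins are excluded from the mean; a bin missing in every contributing
#' trial stays missing. With `keep_only_correct = TRUE` (the default),
#' incorrectly answered trials are removed before averaging.
#'
#' @param trial_bins Output of [bin_trials()].
#' @param keep_only_correct Drop trials with `accuracy == 0` (default TRUE).
#' @return A tibble with columns `participant_id`, `sub_experiment`,
#'   `condition`, `role`, `bin_start_ms`, `prop`, `n_trials` (trials
#'   contributing a non-missing value to the bin).
#' @export
aggregate_participant <- function(trial_bins, keep_only_correct = TRUE) {
  dt <- as.data.table(trial_bins)
  if (keep_only_correct) {
    dt <- dt[accuracy == 1]
  }
  if (nrow(dt) == 0L) {
    stop("no trials remain after accuracy filtering", call. = FALSE)
  }
  agg <- dt[, .(
    prop = {
      v <- prop[!is.na(prop)]
      if (length(v) == 0L) NA_real_ else mean(v)
    },
    n_trials = sum(!is.na(prop))
  ), by = .(participant_id, sub_experiment, condition, role, bin_start_ms)]
  setorderv(agg, c("participant_id", "sub_experiment", "condition", "role",
                   "bin_start_ms"))
  tibble::as_tibble(agg)
}

parse_rule <- function(rule, fields, context) {
  expr <- tryCatch(
    str2lang(rule),
    error = function(e) stop(context, ": cannot parse rule '", rule, "'", call. = FALSE)
  )
  vars <- all.vars(expr)
  unknown <- setdiff(vars, fields)
  if (length(unknown) > 0L) {
    stop(
      context, ": rule '", rule, "' references unknown field(s): ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  expr
}

#' Filter participants by metadata predicates
#'
#' Applies one or more predicate rules (R expressions over metadata columns,
#' e.g. `"intelligibility_pct >= 50"`) and returns the participants that
#' satisfy all of them, plus a log of how many participants each criterion
#' excluded. A rule mentioning a column absent from `meta` is a
#' configuration error. `NA` predicate values count as exclusion.
#'
#' @param meta Participant metadata (as from [read_participant_metadata()]).
#' @param rules Character vector of predicate expressions; names (optional)
#'   label the criteria in the log.
#' @return A list with `included` (character vector of participant ids) and
#'   `log` (tibble: criterion, n_excluded).
#' @export
filter_participants <- function(meta, rules) {
  required_cols(meta, "participant_id", "participant metadata")
  if (length(rules) == 0L) {
    return(list(
      included = meta$participant_id,
      log = tibble::tibble(criterion = character(), n_excluded = integer())
    ))
  }
  labels <- names(rules)
  if (is.null(labels)) labels <- unname(rules)
  labels[!nzchar(labels)] <- unname(rules)[!nzchar(labels)]
  keep <- rep(TRUE, nrow(meta))
  n_excl <- integer(length(rules))
  for (i in seq_along(rules)) {
    expr <- parse_rule(rules[[i]], names(meta), "filter_participants")
    ok <- eval(expr, envir = meta, enclos = baseenv())
    ok[is.na(ok)] <- FALSE
    n_excl[i] <- sum(!ok)
    keep <- keep & ok
  }
  list(
    included = meta$participant_id[keep],
    log = tibble::tibble(criterion = labels, n_excluded = n_excl)
  )
}

#' Regroup participants by metadata predicates
#'
#' Maps each participant to a new group label according to a set of mutually
#' exclusive predicate rules (e.g. splitting hearing-loss participants into
#' low- and high-effort groups at a subjective-effort cutoff). A participant
#' matching more than one rule is a configuration error; participants
#' matching none are dropped with a warning (e.g. a rating exactly at a
#' strict cutoff boundary).
#'
#' @param meta Participant metadata.
#' @param rules Named character vector or list: new group label -> predicate
#'   expression over metadata columns.
#' @return A tibble with columns `participant_id`, `group`.
#' @export
regroup_by_metadata <- function(meta, rules) {
  required_cols(meta, "participant_id", "participant metadata")
  labels <- names(rules)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("regroup_by_metadata: every rule must be named with its group label",
         call. = FALSE)
  }
  hit <- matrix(FALSE, nrow(meta), length(rules))
  for (i in seq_along(rules)) {
    expr <- parse_rule(rules[[i]], names(meta), "regroup_by_metadata")
    ok <- eval(expr, envir = meta, enclos = baseenv())
    ok[is.na(ok)] <- FALSE
    hit[, i] <- ok
  }
  n_hit <- rowSums(hit)
  if (any(n_hit > 1L)) {
    bad <- meta$participant_id[which(n_hit > 1L)]
    stop(
      "regroup_by_metadata: overlapping rules; participant(s) match more than one group: ",
      paste(head(bad, 5), collapse = ", "),
      call. = FALSE
    )
  }
  if (any(n_hit == 0L)) {
    warning(
      sum(n_hit == 0L),
      " participant(s) matched no regrouping rule and were dropped",
      call. = FALSE
    )
  }
  idx <- which(n_hit == 1L)
  tibble::tibble(
    participant_id = meta$participant_id[idx],
    group = labels[apply(hit[idx, , drop = FALSE], 1L, which)]
  )
}

#' Accuracy summary table
#'
#' Mean selection accuracy and trial counts by group, sub-experiment and
#' condition. If `meta` is supplied, its `group` column is joined onto the
#' trials; otherwise trials must already carry a `group` column.
#'
#' @param trials Trial metadata with 0/1 `accuracy`.
#' @param meta Optional participant metadata providing `group`.
#' @return A tibble: group, sub_experiment, condition, n_trials, accuracy.
#' @export
accuracy_summary <- function(trials, meta = NULL) {
  required_cols(trials, c("accuracy", "sub_experiment", "condition"), "trials")
  if (!is.null(meta)) {
    trials <- dplyr::left_join(
      trials, dplyr::select(meta, "participant_id", "group"),
      by = "participant_id"
    )
  }
  required_cols(trials, "group", "trials (after metadata join)")
  trials |>
    dplyr::group_by(.data$group, .data$sub_experiment, .data$condition) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      accuracy = mean(.data$accuracy),
      .groups = "drop"
    )
}

#' @importFrom rlang .data
NULL
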