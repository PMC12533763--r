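#' Parametric looking curve
#'
#' The probability that gaze lands on a given image as a function of time: a
#' logistic rise from `baseline_p` to `asymptote_p` with midpoint
#' `latency_ms` and scale `slope_ms`. The generator uses such curves to give
#' synthetic cohorts a known ground-truth divergence structure.
#'
#' @param baseline_p Pre-divergence landing probability, in \[0,1\].
#' @param asymptote_p Post-divergence landing probability; must exceed
#'   `baseline_p`.
#' @param latency_ms Logistic midpoint in ms.
#' @param slope_ms Logistic scale in ms (> 0); the rise spans roughly
#'   `latency_ms` +/- 3 * `slope_ms`.
#' @return An object of class `looking_curve`.
#' @export
looking_curve <- function(baseline_p, asymptote_p, latency_ms, slope_ms) {
  if (!(baseline_p >= 0 && baseline_p <= 1 && asymptote_p >= 0 && asymptote_p <= 1)) {
    stop("`baseline_p` and `asymptote_p` must lie in [0, 1]", call. = FALSE)
  }
  if (baseline_p >= asymptote_p) {
    stop("`baseline_p` must be smaller than `asymptote_p`", call. = FALSE)
  }
  if (slope_ms <= 0) {
    stop("`slope_ms` must be positive", call. = FALSE)
  }
  structure(
    list(baseline_p = baseline_p, asymptote_p = asymptote_p,
         latency_ms = latency_ms, slope_ms = slope_ms),
    class = "looking_curve"
  )
}

#' Evaluate a looking curve
#'
#' @param t_ms Numeric vector of times in ms.
#' @param params A [looking_curve()].
#' @return `baseline_p + (asymptote_p - baseline_p) * logistic((t - latency) / slope)`.
#' @export
looking_probability <- function(t_ms, params) {
  stopifnot(inherits(params, "looking_curve"))
  params$baseline_p + (params$asymptote_p - params$baseline_p) *
    stats::plogis((t_ms - params$latency_ms) / params$slope_ms)
}

# Role-probability model for one condition. Two of the four roles form a
# "pair" whose combined probability mass q(t) rises logistically at
# `pair_latency_ms`; the primary role's share of that mass follows a sum of
# logistic transitions (`share_points`, each a c(latency, share) step). The
# two remaining roles split 1 - q(t) equally. Probabilities sum to 1 at
# every t by construction.
condition_curves <- function(roles, baseline_p, pair_asym, pair_latency_ms,
                             share_points, slope_ms) {
  stopifnot(length(roles) == 4L, !anyDuplicated(roles))
  if (2 * baseline_p >= pair_asym) {
    stop("`pair_asym` must exceed twice the per-role baseline", call. = FALSE)
  }
  cc <- structure(
    list(roles = roles, baseline_p = baseline_p, pair_asym = pair_asym,
         pair_latency_ms = pair_latency_ms, share_points = share_points,
         slope_ms = slope_ms),
    class = "condition_curves"
  )
  probe <- role_probabilities(seq(-3000, 8000, by = 50), cc)
  if (any(probe < -1e-9) || any(abs(rowSums(probe) - 1) > 1e-9)) {
    stop("condition curve parameters yield invalid role probabilities",
         call. = FALSE)
  }
  cc
}

#' Role landing probabilities at given times
#'
#' @param t_ms Numeric vector of times in ms.
#' @param curves A `condition_curves` object (see [simulate_cohort()]).
#' @return Matrix with one row per time and one column per role; rows sum
#'   to 1.
#' @export
role_probabilities <- function(t_ms, curves) {
  stopifnot(inherits(curves, "condition_curves"))
  q <- 2 * curves$baseline_p + (curves$pair_asym - 2 * curves$baseline_p) *
    stats::plogis((t_ms - curves$pair_latency_ms) / curves$slope_ms)
  share <- rep(0.5, length(t_ms))
  prev <- 0.5
  for (pt in curves$share_points) {
    share <- share + (pt[2] - prev) * stats::plogis((t_ms - pt[1]) / curves$slope_ms)
    prev <- pt[2]
  }
  p <- cbind(q * share, q * (1 - share), (1 - q) / 2, (1 - q) / 2)
  colnames(p) <- curves$roles
  p
}

# build the per-condition curve set for one group from its latencies
group_condition_curves <- function(latencies, baseline_p = 0.25,
                                   asymptote_p = 0.85, slope_ms = 10) {
  pair_asym <- asymptote_p + (1 - asymptote_p) / 3
  hi <- asymptote_p / pair_asym
  lo <- 1 - hi
  out <- list()
  if (!is.null(latencies$cp)) {
    out$CP <- condition_curves(
      c("target", "cu_target", "distractor1", "distractor2"),
      baseline_p, pair_asym, latencies$cp,
      list(c(latencies$cp, hi)), slope_ms
    )
  }
  if (!is.null(latencies$cu_cost)) {
    out$CU <- condition_curves(
      c("target", "cu_target", "distractor1", "distractor2"),
      baseline_p, pair_asym, latencies$cp,
      list(c(latencies$cp, hi), c(latencies$cu_cost, lo)), slope_ms
    )
  }
  if (!is.null(latencies$comp_stage2)) {
    out$competition <- condition_curves(
      c("target", "agent_competitor", "verb_distractor", "distractor2"),
      baseline_p, pair_asym, latencies$comp_stage1,
      list(c(latencies$comp_stage2, hi)), slope_ms
    )
  }
  if (!is.null(latencies$neutral)) {
    out$neutral <- condition_curves(
      c("target", "distractor1", "distractor2", "distractor3"),
      baseline_p, pair_asym, latencies$neutral,
      list(c(latencies$neutral, hi)), slope_ms
    )
  }
  out
}

#' Default group specifications for a synthetic cohort
#'
#' Three groups of older adults (normal hearing; hearing loss under low
#' listening demand; hearing loss under high demand). Divergence latencies
#' encode the qualitative result structure the generator emulates: identical
#' early (agent-based) latencies across groups, late (verb-based narrowing)
#' latencies offset by +115 and +190 ms in the two hearing-loss groups.
#' These offsets are generator defaults for producing realistic-looking
#' cohorts, not empirical claims.
#'
#' @return A list of group specifications for [cohort_spec()].
#' @export
default_groups <- function() {
  base_lat <- list(cp = 800, cu_cost = 1850, comp_stage1 = 800,
                   comp_stage2 = 1200, neutral = 1800)
  mk <- function(label, n, stage2_offset, meta) {
    lat <- base_lat
    lat$comp_stage2 <- lat$comp_stage2 + stage2_offset
    list(label = label, n_participants = n, latencies = lat, meta = meta)
  }
  list(
    mk("PwNH", 30L, 0,
       list(intelligibility = c(100, 0), effort = c(8, 4), age = c(68.9, 5.9),
            hearing = c(14.7, 6.2))),
    mk("PwHL_low_demand", 32L, 115,
       list(intelligibility = c(96.9, 3.5), effort = c(13, 6), age = c(72.3, 5.2),
            hearing = c(46.4, 7.8))),
    mk("PwHL_high_demand", 31L, 190,
       list(intelligibility = c(88.4, 8), effort = c(25, 10), age = c(72.5, 5.3),
            hearing = c(46.7, 10.6)))
  )
}

#' Specify a synthetic cohort
#'
#' Bundles everything [simulate_cohort()] needs: the groups (sizes, true
#' divergence latencies, metadata distributions), the item counts per
#' condition, the gaze-sampling model, and the sentence timeline. Defaults
#' follow the study design the generator emulates: 24 predictable (CP) + 24
#' unpredictable (CU) items, 16 competition items, 40 neutral fillers; 1000
#' Hz sampling; a 2000 ms image preview before audio onset; and
#' Gamma-distributed fixation durations (mean 250 ms, shape 4) with 30 ms
#' saccade gaps recorded as invalid samples, so that consecutive samples are
#' strongly autocorrelated as in real gaze data.
#'
#' @param groups List of group specs as produced by [default_groups()]:
#'   each a list with `label`, `n_participants`, `latencies` (named list:
#'   `cp`, `cu_cost`, `comp_stage1`, `comp_stage2`, `neutral`), and
#'   optionally `meta` (metadata means/sds) and `accuracy` overrides.
#' @param n_items Named integer vector: items per condition
#'   (`cp`, `cu`, `competition`, `neutral`). Zero drops a condition.
#' @param accuracy_p Named list of per-condition probabilities that a trial
#'   is answered correctly.
#' @param sample_rate_hz Gaze sampling rate (default 1000).
#' @param fixation_mean_ms,fixation_shape Gamma fixation-duration model.
#' @param saccade_gap_ms Gap between fixations, emitted as invalid samples
#'   (0 disables).
#' @param preview_ms Image preview before audio onset; simulated as negative
#'   time (default 2000).
#' @param baseline_p,asymptote_p,slope_ms Looking-curve parameters shared by
#'   all conditions: per-role baseline at preview (uniform 0.25), target
#'   asymptote, and logistic scale. The default scale (10 ms) keeps
#'   transitions sharp so the nominal latency is also where the curves begin
#'   to separate, which keeps the ground truth well defined.
#' @param timeline A [build_timeline()] result; default is the normalized
#'   five-word frame.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = default_groups(),
                        n_items = c(cp = 24L, cu = 24L, competition = 16L,
                                    neutral = 40L),
                        accuracy_p = list(cp = 0.99, cu = 0.92,
                                          competition = 0.974, neutral = 0.974),
                        sample_rate_hz = 1000, fixation_mean_ms = 250,
                        fixation_shape = 4, saccade_gap_ms = 30,
                        preview_ms = 2000, baseline_p = 0.25,
                        asymptote_p = 0.85, slope_ms = 10,
                        timeline = default_timeline(), seed = 1L) {
  stopifnot(inherits(timeline, "stimulus_timeline"))
  if (length(groups) == 0L) stop("at least one group required", call. = FALSE)
  for (g in groups) {
    if (is.null(g$n_participants) || g$n_participants < 2L) {
      stop("every group needs at least 2 participants", call. = FALSE)
    }
  }
  for (p in accuracy_p) {
    if (p <= 0 || p > 1) stop("accuracy probabilities must be in (0, 1]", call. = FALSE)
  }
  window_len <- timeline$selection_cue_ms + preview_ms
  if (window_len < fixation_mean_ms / fixation_shape) {
    stop("trial window shorter than one plausible fixation", call. = FALSE)
  }
  structure(
    list(groups = groups, n_items = n_items, accuracy_p = accuracy_p,
         sample_rate_hz = sample_rate_hz, fixation_mean_ms = fixation_mean_ms,
         fixation_shape = fixation_shape, saccade_gap_ms = saccade_gap_ms,
         preview_ms = preview_ms, baseline_p = baseline_p,
         asymptote_p = asymptote_p, slope_ms = slope_ms,
         timeline = timeline, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' The default duration-normalized sentence timeline
#'
#' Word durations of the normalized frame "The \[agent\] \[verb\] the
#' \[object\]" in ms, with the selection cue 2000 ms after audio offset.
#'
#' @return A [build_timeline()] object.
#' @export
default_timeline <- function() {
  build_timeline(
    c(the1 = 93.58, agent = 612.72, verb = 602.05, the2 = 130.27,
      object = 464.45),
    post_delay_ms = 2000
  )
}

cond_meta <- function() {
  data.frame(
    key = c("cp", "cu", "competition", "neutral"),
    condition = c("CP", "CU", "CP", "neutral"),
    sub_experiment = c("1", "1", "2", "filler"),
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete synthetic cohort
#'
#' Generates gaze samples, trial metadata and participant metadata with a
#' known ground-truth divergence structure, suitable as direct input to
#' [bin_trials()] and the rest of the pipeline. Per trial, fixations are
#' generated sequentially: each duration is Gamma-distributed, the landing
#' image is drawn from the condition's role probabilities evaluated at the
#' fixation's onset time, and each fixation is followed by a saccade gap of
#' invalid samples. Fixation events are then expanded to the sample grid.
#' Trial accuracy is Bernoulli, with `clicked_role` set to the correct role
#' or a random other image accordingly.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `samples`, `trials`, `participants` (tibbles in the
#'   formats of [read_sample_report()], [read_trial_metadata()] and
#'   [read_participant_metadata()]), and `ground_truth` (true latencies per
#'   group and condition, the seed, and the spec).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(substream_seed(spec$seed, "simulate_cohort"))

  step <- 1000 / spec$sample_rate_hz
  t_start <- -spec$preview_ms
  t_end <- spec$timeline$selection_cue_ms
  layout <- roi_layout()
  cm <- cond_meta()
  cm <- cm[cm$key %in% names(spec$n_items)[spec$n_items > 0], , drop = FALSE]

  samples_l <- list()
  trials_l <- list()
  parts_l <- list()
  truth <- list()

  for (g in spec$groups) {
    curves <- group_condition_curves(g$latencies, spec$baseline_p,
                                     spec$asymptote_p, spec$slope_ms)
    pids <- sprintf("%s_p%02d", g$label, seq_len(g$n_participants))
    meta <- g$meta
    meta_defaults <- list(intelligibility = c(100, 0), effort = c(10, 5),
                          age = c(70, 5), hearing = c(15, 5))
    draw_meta <- function(nm, lo = -Inf, hi = Inf) {
      par <- meta[[nm]]
      if (is.null(par)) par <- meta_defaults[[nm]]
      v <- stats::rnorm(length(pids), par[1], par[2])
      pmin(pmax(v, lo), hi)
    }
    parts_l[[g$label]] <- tibble::tibble(
      participant_id = pids, group = g$label,
      intelligibility_pct = round(draw_meta("intelligibility", 0, 100), 1),
      effort_rating = round(draw_meta("effort", 0, 100), 1),
      age = round(draw_meta("age", 50, 90)),
      hearing_level = round(draw_meta("hearing", -10, 120), 1)
    )
    truth[[g$label]] <- g$latencies

    for (ci in seq_len(nrow(cm))) {
      key <- cm$key[ci]
      cc <- curves[[cm$condition[ci]]]
      if (cm$key[ci] == "competition") cc <- curves[["competition"]]
      if (is.null(cc)) {
        stop("group '", g$label, "' lacks latencies for condition '", key, "'",
             call. = FALSE)
      }
      n_it <- spec$n_items[[key]]
      acc_p <- spec$accuracy_p[[key]]
      roles <- cc$roles

      n_tr <- length(pids) * n_it
      pid_v <- rep(pids, each = n_it)
      item_v <- sprintf("%s_%02d", key, rep(seq_len(n_it), times = length(pids)))
      trial_v <- paste0(pid_v, "_", item_v)

      # fixation sequence per trial, batched: draw enough Gamma durations,
      # cumulate onsets, drop fixations starting after the window end
      win <- t_end - t_start
      K <- ceiling(win / spec$fixation_mean_ms * 2) + 8
      repeat {
        dur <- matrix(
          stats::rgamma(n_tr * K, shape = spec$fixation_shape,
                        rate = spec$fixation_shape / spec$fixation_mean_ms),
          nrow = n_tr
        )
        stride <- dur + spec$saccade_gap_ms
        onset <- cbind(0, t(apply(stride, 1L, cumsum)))[, seq_len(K), drop = FALSE]
        if (all(onset[, K] + dur[, K] >= win)) break
        K <- K * 2  # extremely short draws; widen the batch and retry
      }
      keep <- onset < win
      fid <- which(keep)
      tr_i <- ((fid - 1L) %% n_tr) + 1L
      f_on <- t_start + onset[fid]
      f_dur <- dur[fid]
      f_end <- pmin(f_on + f_dur, t_end)

      p <- role_probabilities(f_on, cc)
      u <- stats::runif(length(fid))
      cum1 <- p[, 1]; cum2 <- cum1 + p[, 2]; cum3 <- cum2 + p[, 3]
      ridx <- 1L + (u > cum1) + (u > cum2) + (u > cum3)

      # counterbalanced placement: role -> quadrant rotates over items and
      # participants so each image appears in each location equally often
      rot <- (rep(seq_len(n_it), times = length(pids)) +
                rep(seq_along(pids), each = n_it) - 2L) %% 4L
      quad_of <- function(role_i, rot_i) ((role_i - 1L + rot_i) %% 4L) + 1L
      f_quad <- quad_of(ridx, rot[tr_i])
      ib <- layout$image_boxes
      jx <- stats::runif(length(fid), 0.15, 0.85)
      jy <- stats::runif(length(fid), 0.15, 0.85)
      f_x <- ib$x0[f_quad] + jx * (ib$x1[f_quad] - ib$x0[f_quad])
      f_y <- ib$y0[f_quad] + jy * (ib$y1[f_quad] - ib$y0[f_quad])

      fix_samp <- expand_fixations(pid_v[tr_i], trial_v[tr_i], f_on, f_end,
                                   f_x, f_y, step)
      if (spec$saccade_gap_ms > 0) {
        g_on <- f_on + f_dur
        g_end <- pmin(g_on + spec$saccade_gap_ms, t_end)
        ok <- g_on < t_end
        gap_samp <- expand_fixations(pid_v[tr_i][ok], trial_v[tr_i][ok],
                                     g_on[ok], g_end[ok],
                                     rep(NA_real_, sum(ok)),
                                     rep(NA_real_, sum(ok)), step,
                                     valid = rep(FALSE, sum(ok)))
        fix_samp <- dplyr::bind_rows(fix_samp, gap_samp)
      }
      fix_samp <- dplyr::arrange(fix_samp, .data$participant_id,
                                 .data$trial_id, .data$t_ms)
      samples_l[[paste(g$label, key)]] <- fix_samp

      corr <- correct_role(cm$condition[ci])
      acc <- stats::rbinom(n_tr, 1L, acc_p)
      clicked <- rep(corr, n_tr)
      wrong <- which(acc == 0L)
      if (length(wrong) > 0L) {
        alt <- setdiff(roles, corr)
        clicked[wrong] <- alt[sample.int(3L, length(wrong), replace = TRUE)]
      }
      qroles <- t(vapply(rot, function(r) {
        out <- character(4)
        out[quad_of(seq_len(4L), r)] <- roles
        out
      }, character(4)))
      trials_l[[paste(g$label, key)]] <- tibble::tibble(
        participant_id = pid_v, trial_id = trial_v, item_id = item_v,
        sub_experiment = cm$sub_experiment[ci], condition = cm$condition[ci],
        q1_role = qroles[, 1], q2_role = qroles[, 2],
        q3_role = qroles[, 3], q4_role = qroles[, 4],
        clicked_role = clicked, accuracy = acc,
        block = rep_len(c(1L, 2L), n_tr)
      )
    }
  }

  list(
    samples = dplyr::bind_rows(samples_l),
    trials = dplyr::bind_rows(trials_l),
    participants = dplyr::bind_rows(parts_l),
    ground_truth = list(latencies = truth, seed = spec$seed,
                        baseline_p = spec$baseline_p,
                        asymptote_p = spec$asymptote_p,
                        slope_ms = spec$slope_ms)
  )
}

#' Write a simulated cohort to disk
#'
#' Writes the three tabular inputs of the preprocessing stage (tab-delimited
#' sample report, trial CSV, participant CSV) plus a ground-truth JSON with
#' the true latencies and seed.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    samples = file.path(dir, "samples.tsv"),
    trials = file.path(dir, "trials.csv"),
    participants = file.path(dir, "participants.csv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  fwrite(cohort$samples, paths[["samples"]], sep = "\t")
  fwrite(cohort$trials, paths[["trials"]])
  fwrite(cohort$participants, paths[["participants"]])
  jsonlite::write_json(cohort$ground_truth, paths[["ground_truth"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
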