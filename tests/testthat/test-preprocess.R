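trial_row <- function(pid = "p1", trial = "t1", cond = "CP", sub = "1",
                      clicked = NULL) {
  if (is.null(clicked)) clicked <- correct_role(cond)
  tibble::tibble(
    participant_id = pid, trial_id = trial, item_id = "i1",
    sub_experiment = sub, condition = cond,
    q1_role = "target", q2_role = "cu_target", q3_role = "distractor1",
    q4_role = "distractor2", clicked_role = clicked,
    accuracy = as.integer(clicked == correct_role(cond)), block = 1L
  )
}

gaze_at <- function(pid, trial, t, quadrant, lay = roi_layout(),
                    valid = TRUE) {
  ib <- lay$image_boxes
  tibble::tibble(
    participant_id = pid, trial_id = trial, t_ms = t,
    x = (ib$x0[quadrant] + ib$x1[quadrant]) / 2,
    y = (ib$y0[quadrant] + ib$y1[quadrant]) / 2,
    valid = valid
  )
}

test_that("a trial fixating the target throughout gives proportion 1 everywhere", {
  g <- bin_grid(100, bin_ms = 20)
  tr <- trial_row()
  s <- gaze_at("p1", "t1", 0:99, quadrant = 1)
  tb <- bin_trial(s, roi_layout(), tr, g)
  expect_equal(nrow(tb), 5 * 4)
  expect_equal(unique(tb$n_valid), 20)  # 1000 Hz, 20 ms bins
  expect_equal(tb$prop[tb$role == "target"], rep(1, 5))
  expect_equal(tb$prop[tb$role != "target"], rep(0, 15))
})

test_that("samples alternating between two images split the bin evenly", {
  g <- bin_grid(100, bin_ms = 20)
  tr <- trial_row()
  s1 <- gaze_at("p1", "t1", seq(0, 98, by = 2), quadrant = 1)
  s2 <- gaze_at("p1", "t1", seq(1, 99, by = 2), quadrant = 2)
  tb <- bin_trial(dplyr::bind_rows(s1, s2), roi_layout(), tr, g)
  expect_equal(tb$prop[tb$role == "target"], rep(0.5, 5))
  expect_equal(tb$prop[tb$role == "cu_target"], rep(0.5, 5))
  # brute-force recount for every bin
  for (b in 0:4) {
    in_bin <- dplyr::bind_rows(s1, s2) |>
      dplyr::filter(t_ms >= b * 20, t_ms < (b + 1) * 20)
    expect_equal(
      tb$prop[tb$role == "target" & tb$bin_start_ms == b * 20],
      mean(in_bin$x < 500)
    )
  }
})

test_that("invalid samples drop out of numerator and denominator; empty bins are missing", {
  g <- bin_grid(60, bin_ms = 20)
  tr <- trial_row()
  s <- dplyr::bind_rows(
    gaze_at("p1", "t1", 0:19, quadrant = 1),            # bin 0: all target
    gaze_at("p1", "t1", 20:39, quadrant = 1, valid = FALSE)  # bin 1: blink
    # bin 2: no samples at all
  )
  tb <- bin_trial(s, roi_layout(), tr, g)
  tgt <- tb[tb$role == "target", ]
  expect_equal(tgt$prop, c(1, NA, NA))
  expect_equal(tgt$n_valid, c(20, 0, 0))
  # a trial with no valid samples anywhere warns
  expect_warning(
    bin_trial(gaze_at("p1", "t1", 0:59, 1, valid = FALSE),
              roi_layout(), tr, g),
    "no valid samples"
  )
})

test_that("role proportions sum to at most 1 in every bin", {
  coh <- tiny_cohort(n = 3, n_items = 3, seed = 3)
  g <- default_grid()
  tb <- bin_trials(coh$samples, coh$trials, roi_layout(), g)
  sums <- tb |>
    dplyr::group_by(participant_id, trial_id, bin_start_ms) |>
    dplyr::summarise(s = sum(prop), .groups = "drop")
  expect_true(all(is.na(sums$s) | sums$s <= 1 + 1e-9))
  expect_true(all(tb$prop >= 0 & tb$prop <= 1, na.rm = TRUE))
})

test_that("aggregation averages trials, honours accuracy and missingness, ignores order", {
  g <- bin_grid(40, bin_ms = 20)
  t1 <- trial_row(trial = "t1")
  t2 <- trial_row(trial = "t2")
  t3 <- trial_row(trial = "t3", clicked = "cu_target")  # incorrect
  s <- dplyr::bind_rows(
    gaze_at("p1", "t1", 0:39, 1),                 # target both bins
    gaze_at("p1", "t2", 0:19, 2),                 # cu_target bin 0, bin 1 empty
    gaze_at("p1", "t3", 0:39, 1)
  )
  trials <- dplyr::bind_rows(t1, t2, t3)
  tb <- bin_trials(s, trials, roi_layout(), g)
  agg <- aggregate_participant(tb, keep_only_correct = TRUE)
  tgt <- agg[agg$role == "target", ]
  # incorrect trial t3 excluded; bin 0 averages t1 (1) and t2 (0)
  expect_equal(tgt$prop[tgt$bin_start_ms == 0], 0.5)
  expect_equal(tgt$n_trials[tgt$bin_start_ms == 0], 2L)
  # t2 has no bin-1 samples: mean over the single contributing trial
  expect_equal(tgt$prop[tgt$bin_start_ms == 20], 1)
  expect_equal(tgt$n_trials[tgt$bin_start_ms == 20], 1L)
  # including incorrect trials changes the average
  agg_all <- aggregate_participant(tb, keep_only_correct = FALSE)
  expect_equal(agg_all$prop[agg_all$role == "target" &
                              agg_all$bin_start_ms == 0], 2 / 3)
  # trial order does not matter
  tb_rev <- tb[rev(seq_len(nrow(tb))), ]
  expect_equal(aggregate_participant(tb_rev), agg)
  # nothing left after filtering is an error
  tb_wrong <- tb[tb$accuracy == 0, ]
  expect_error(aggregate_participant(tb_wrong), "no trials")
})

meta6 <- tibble::tibble(
  participant_id = paste0("p", 1:6),
  group = c("PwNH", "PwNH", "PwHL", "PwHL", "PwHL", "PwHL"),
  intelligibility_pct = c(100, 100, 96, 40, 100, 88),
  effort_rating = c(8, 12, 10, 40, 15, 22)
)

test_that("participant filtering applies predicates and logs exclusions", {
  res <- filter_participants(meta6, c(intelligibility = "intelligibility_pct >= 50"))
  expect_false("p4" %in% res$included)
  expect_length(res$included, 5)
  expect_equal(res$log$n_excluded, 1L)
  # the 100%-intelligibility sensitivity subset
  res100 <- filter_participants(meta6, c(perfect = "intelligibility_pct == 100"))
  expect_setequal(res100$included, c("p1", "p2", "p5"))
  # an always-true rule is the identity
  expect_equal(filter_participants(meta6, "intelligibility_pct >= 0")$included,
               meta6$participant_id)
  expect_error(filter_participants(meta6, "wpm > 10"), "unknown field")
})

test_that("tightening an intelligibility threshold never grows the included set", {
  prev <- meta6$participant_id
  for (thr in c(0, 40, 50, 88, 96, 100)) {
    cur <- filter_participants(
      meta6, sprintf("intelligibility_pct >= %d", thr)
    )$included
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("metadata regrouping is exclusive, exhaustive-or-dropped", {
  rules <- c(
    PwNH_low_effort = "group == 'PwNH' & effort_rating < 15",
    PwHL_low_effort = "group == 'PwHL' & effort_rating < 15",
    PwHL_high_effort = "group == 'PwHL' & effort_rating > 15"
  )
  expect_warning(map <- regroup_by_metadata(meta6, rules), "dropped")
  expect_equal(map$group[map$participant_id == "p3"], "PwHL_low_effort")
  expect_equal(map$group[map$participant_id == "p4"], "PwHL_high_effort")
  expect_false("p5" %in% map$participant_id)  # effort exactly 15
  expect_error(
    regroup_by_metadata(meta6, c(a = "effort_rating < 20",
                                 b = "effort_rating < 30")),
    "overlapping"
  )
})

test_that("accuracy summaries are plain proportions with counts", {
  trials <- dplyr::bind_rows(lapply(1:100, function(i) {
    trial_row(pid = ifelse(i <= 50, "p1", "p2"), trial = paste0("t", i),
              clicked = ifelse(i <= 92, "target", "cu_target"))
  }))
  meta <- tibble::tibble(participant_id = c("p1", "p2"), group = "G")
  acc <- accuracy_summary(trials, meta)
  expect_equal(acc$accuracy, 0.92)
  expect_equal(acc$n_trials, 100L)
})

test_that("simulated cohort accuracy matches its generating probability", {
  coh <- tiny_cohort(n = 12, n_items = 20, seed = 21)
  acc <- accuracy_summary(coh$trials, coh$participants)
  n <- acc$n_trials
  # binomial 99.9% band around the generating p = 0.99
  expect_gt(acc$accuracy, 0.99 - 3.3 * sqrt(0.99 * 0.01 / n))
  # accuracy recomputation flags doctored labels
  bad <- coh$trials
  bad$accuracy[1] <- 1L - bad$accuracy[1]
  expect_warning(recompute_accuracy(bad), "inconsistent")
})

test_that("fixation reports expand to the same bins as sample reports", {
  g <- bin_grid(100, bin_ms = 20)
  lay <- roi_layout()
  ib <- lay$image_boxes
  tmp <- withr::local_tempdir()
  fx <- tibble::tibble(
    participant_id = "p1", trial_id = "t1",
    fix_start_ms = c(0, 50), fix_end_ms = c(50, 100),
    x = (ib$x0[c(1, 2)] + ib$x1[c(1, 2)]) / 2,
    y = (ib$y0[c(1, 2)] + ib$y1[c(1, 2)]) / 2
  )
  fp <- file.path(tmp, "fix.tsv")
  data.table::fwrite(fx, fp, sep = "\t")
  s <- read_fixation_report(fp)
  expect_equal(nrow(s), 100)
  tb <- bin_trial(s, lay, trial_row(), g)
  expect_equal(tb$prop[tb$role == "target"], c(1, 1, 0.5, 0, 0))
  expect_equal(tb$prop[tb$role == "cu_target"], c(0, 0, 0.5, 1, 1))
})

test_that("cohort files round-trip through the readers", {
  coh <- tiny_cohort(n = 3, n_items = 2, seed = 5)
  tmp <- withr::local_tempdir()
  paths <- write_cohort(coh, tmp)
  s <- read_sample_report(paths[["samples"]])
  expect_equal(nrow(s), nrow(coh$samples))
  expect_equal(s$t_ms, coh$samples$t_ms)
  tr <- suppressWarnings(read_trial_metadata(paths[["trials"]]))
  expect_equal(tr$accuracy, coh$trials$accuracy)
  meta <- read_participant_metadata(paths[["participants"]])
  expect_equal(meta$participant_id, coh$participants$participant_id)
})
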