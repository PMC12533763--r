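#' Specify a divergence-point contrast
#'
#' A contrast names the two image roles whose fixation-proportion
#' timecourses are compared (e.g. target vs. agent-related competitor on the
#' predictable items), the item subset they are evaluated on, and the
#' detection parameters: per-bin test tail and alpha, and the number of
#' consecutive significant bins required to call a divergence (default 10
#' bins of 20 ms, i.e. a sustained 200 ms difference).
#'
#' @param condition Condition subset (character vector, e.g. `"CP"`).
#' @param role_a,role_b The two roles compared; the divergence of interest is
#'   `role_a` above `role_b`.
#' @param sub_experiment Optional sub-experiment subset (e.g. `1`, `2`,
#'   `"filler"`); `NULL` means no restriction.
#' @param tail `"one_sided"` (default; tests `role_a > role_b`, the
#'   directional prediction every contrast encodes) or `"two_sided"`.
#' @param alpha Per-bin significance level (default 0.05).
#' @param consec_bins Required run length of significant bins (default 10).
#' @param grid A [bin_grid()] defining the analysis window.
#' @param label Optional short name used in result tables.
#' @return An object of class `contrast_spec`.
#' @export
contrast_spec <- function(condition, role_a, role_b, grid,
                          sub_experiment = NULL,
                          tail = c("one_sided", "two_sided"),
                          alpha = 0.05, consec_bins = 10L, label = NULL) {
  tail <- match.arg(tail)
  stopifnot(inherits(grid, "bin_grid"))
  if (identical(role_a, role_b)) {
    stop("`role_a` and `role_b` must differ", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  if (consec_bins < 1L || consec_bins != round(consec_bins)) {
    stop("`consec_bins` must be a positive integer", call. = FALSE)
  }
  if (is.null(label)) {
    label <- paste0(paste(condition, collapse = "+"), ":", role_a, ">", role_b)
  }
  structure(
    list(
      condition = condition, role_a = role_a, role_b = role_b,
      sub_experiment = sub_experiment, tail = tail, alpha = alpha,
      consec_bins = as.integer(consec_bins), grid = grid, label = label
    ),
    class = "contrast_spec"
  )
}

#' @export
print.contrast_spec <- function(x, ...) {
  cat(sprintf(
    "<contrast_spec> %s: %s > %s (%s, alpha %g, %d consecutive bins)\n",
    paste(x$condition, collapse = "+"), x$role_a, x$role_b, x$tail,
    x$alpha, x$consec_bins
  ))
  invisible(x)
}

# same contrast definition (window included), ignoring the label
same_contrast <- function(a, b) {
  identical(a[c("condition", "role_a", "role_b", "sub_experiment", "tail",
                "alpha", "consec_bins")],
            b[c("condition", "role_a", "role_b", "sub_experiment", "tail",
                "alpha", "consec_bins")]) &&
    identical(unclass(a$grid), unclass(b$grid))
}

# Participant x bin difference matrix (role_a - role_b) for one contrast.
# Rows are participants, columns the grid's bins; entries NA where either
# role's proportion is missing.
diff_matrix <- function(series, contrast) {
  dt <- as.data.table(series)
  dt <- dt[condition %in% contrast$condition]
  if (!is.null(contrast$sub_experiment)) {
    dt <- dt[sub_experiment %in% contrast$sub_experiment]
  }
  dt <- dt[role %in% c(contrast$role_a, contrast$role_b)]
  if (nrow(dt) == 0L) {
    stop("no series rows match the contrast (condition/roles)", call. = FALSE)
  }
  starts <- bin_starts(contrast$grid)
  pids <- sort(unique(dt$participant_id))
  mat_for <- function(r) {
    sub <- dt[role == r]
    m <- matrix(NA_real_, length(pids), length(starts),
                dimnames = list(pids, NULL))
    ri <- match(sub$participant_id, pids)
    ci <- match(sub$bin_start_ms, starts)
    ok <- !is.na(ci)
    m[cbind(ri[ok], ci[ok])] <- sub$prop[ok]
    m
  }
  mat_for(contrast$role_a) - mat_for(contrast$role_b)
}

# Vectorized per-bin one-sample t-test of the column means of D against 0.
# Zero-variance columns take the limiting verdict of the t statistic:
# constant positive difference is significant (one-sided), constant zero or
# negative is not. Columns with fewer than 2 non-missing rows are never
# significant.
bin_tests_matrix <- function(D, alpha, tail) {
  n <- colSums(!is.na(D))
  m <- colMeans(D, na.rm = TRUE)
  m[n == 0L] <- NA_real_
  ss <- colSums(D * D, na.rm = TRUE) - ifelse(n > 0L, n * m * m, 0)
  v <- ifelse(n > 1L, pmax(ss, 0) / (n - 1L), NA_real_)
  se <- sqrt(v / n)
  t_stat <- ifelse(n > 1L & se > 0, m / se, NA_real_)
  if (tail == "one_sided") {
    p <- stats::pt(t_stat, df = n - 1L, lower.tail = FALSE)
  } else {
    p <- 2 * stats::pt(abs(t_stat), df = n - 1L, lower.tail = FALSE)
  }
  sig <- !is.na(p) & p < alpha
  if (tail == "one_sided") {
    sig <- sig & !is.na(m) & m > 0
  }
  degen <- n > 1L & !is.na(se) & se == 0
  if (any(degen)) {
    pos <- if (tail == "one_sided") m > 0 else m != 0
    sig[degen] <- pos[degen]
    t_stat[degen] <- ifelse(pos[degen], Inf, NaN)
    p[degen] <- ifelse(pos[degen], 0, 1)
  }
  sig[n < 2L] <- FALSE
  list(n = n, mean_diff = m, t = t_stat, p = p, significant = sig)
}

#' Per-bin t-tests for a contrast
#'
#' Runs, in every bin of the analysis window, a paired one-sample t-test of
#' the participant-level fixation-proportion differences
#' (`role_a - role_b`) against zero. With the default one-sided tail a bin
#' is significant when `p < alpha` and the mean difference is positive.
#' Bins with fewer than two contributing participants, or zero variance at a
#' non-positive mean, are not significant.
#'
#' @param series Participant-level timecourses (from
#'   [aggregate_participant()]) for one group.
#' @param contrast A [contrast_spec()].
#' @return A tibble with one row per bin: `bin_start_ms`, `n`, `mean_diff`,
#'   `t`, `p`, `significant`.
#' @export
bin_tests <- function(series, contrast) {
  stopifnot(inherits(contrast, "contrast_spec"))
  D <- diff_matrix(series, contrast)
  if (nrow(D) == 0L) {
    stop("no participants in group for contrast ", contrast$label, call. = FALSE)
  }
  res <- bin_tests_matrix(D, contrast$alpha, contrast$tail)
  tibble::tibble(
    bin_start_ms = bin_starts(contrast$grid),
    n = res$n, mean_diff = res$mean_diff, t = res$t, p = res$p,
    significant = res$significant
  )
}

#' Detect a divergence onset from per-bin significance flags
#'
#' Returns the start time of the first bin that begins a run of at least
#' `consec_bins` consecutive significant bins, or `NA` when no such
#' sustained run exists (a valid outcome: the resample is nonconvergent).
#'
#' @param flags Logical vector of per-bin significance over the full
#'   analysis window (`NA` treated as not significant).
#' @param grid The [bin_grid()] the flags are defined on.
#' @param consec_bins Required run length (default 10).
#' @return Onset time in ms (a bin start) or `NA_real_`.
#' @export
detect_onset <- function(flags, grid, consec_bins = 10L) {
  stopifnot(inherits(grid, "bin_grid"))
  if (length(flags) != grid$n_bins) {
    stop("`flags` must cover the full analysis window (", grid$n_bins,
         " bins)", call. = FALSE)
  }
  flags <- as.logical(flags)
  flags[is.na(flags)] <- FALSE
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= consec_bins)
  if (length(hit) == 0L) {
    return(NA_real_)
  }
  first <- ends[hit[1]] - r$lengths[hit[1]] + 1L
  bin_starts(grid)[first]
}

# deterministic 31-bit substream seed from the master seed plus a string
# tag, so that adding a group or contrast never perturbs another's resamples
substream_seed <- function(seed, tag) {
  bytes <- utf8ToInt(tag)
  h <- 0
  for (b in bytes) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Bootstrap the divergence point for one group
#'
#' Estimates the sampling distribution of a group's divergence point by
#' resampling participants with replacement within the group (`n_boot`
#' resamples of the same size; a participant drawn twice counts twice). Each
#' resample's group timecourse is re-tested bin by bin ([bin_tests()]) and
#' the divergence onset re-detected ([detect_onset()]). Resamples with no
#' qualifying run are nonconvergent: they are counted and excluded from the
#' mean and percentile confidence interval rather than assigned a sentinel
#' time, which would bias the mean.
#'
#' @param series Participant-level timecourses for one group.
#' @param contrast A [contrast_spec()].
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed Master seed; the group's resampling stream is derived
#'   deterministically from `(seed, group, contrast)`.
#' @param group Group label (used for the substream and in reports).
#' @param ci_probs Percentile CI probabilities (default 2.5% and 97.5%).
#'   Endpoints are order statistics of the bootstrap distribution, so they
#'   lie on the bin grid.
#' @return An object of class `divergence_estimate`: list with `group`,
#'   `contrast`, `observed_dp_ms`, `boot_all_ms` (per-resample onsets, `NA`
#'   where nonconvergent), `boot_dps_ms` (convergent onsets), `boot_mean_ms`,
#'   `ci_low_ms`, `ci_high_ms`, `n_boot`, `n_convergent`, `seed`.
#' @export
bootstrap_dp <- function(series, contrast, n_boot = 2000L, seed = 1L,
                         group = "group", ci_probs = c(0.025, 0.975)) {
  stopifnot(inherits(contrast, "contrast_spec"))
  D <- diff_matrix(series, contrast)
  n_p <- nrow(D)
  if (n_p < 2L) {
    stop("group '", group, "' has fewer than 2 participants for contrast ",
         contrast$label, call. = FALSE)
  }
  obs <- bin_tests_matrix(D, contrast$alpha, contrast$tail)
  observed_dp <- detect_onset(obs$significant, contrast$grid, contrast$consec_bins)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(substream_seed(seed, paste("dpa", group, contrast$label, sep = "|")))
  idx <- matrix(sample.int(n_p, n_p * n_boot, replace = TRUE), nrow = n_p)

  boot_all <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    Db <- D[idx[, b], , drop = FALSE]
    res <- bin_tests_matrix(Db, contrast$alpha, contrast$tail)
    boot_all[b] <- detect_onset(res$significant, contrast$grid,
                                contrast$consec_bins)
  }
  boot_dps <- boot_all[!is.na(boot_all)]
  n_conv <- length(boot_dps)
  if (n_conv == 0L) {
    warning("bootstrap for group '", group, "', contrast ", contrast$label,
            ": no convergent resamples; estimate is undefined", call. = FALSE)
    boot_mean <- NA_real_
    ci <- c(NA_real_, NA_real_)
  } else {
    if (1 - n_conv / n_boot > 0.2) {
      warning(sprintf(
        "bootstrap for group '%s', contrast %s: %.1f%% of resamples nonconvergent",
        group, contrast$label, 100 * (1 - n_conv / n_boot)
      ), call. = FALSE)
    }
    boot_mean <- mean(boot_dps)
    ci <- unname(stats::quantile(boot_dps, ci_probs, type = 1))
  }
  structure(
    list(
      group = group, contrast = contrast,
      observed_dp_ms = observed_dp,
      boot_all_ms = boot_all, boot_dps_ms = boot_dps,
      boot_mean_ms = boot_mean, ci_low_ms = ci[1], ci_high_ms = ci[2],
      n_boot = as.integer(n_boot), n_convergent = n_conv,
      ci_probs = ci_probs, seed = seed
    ),
    class = "divergence_estimate"
  )
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf(
    "<divergence_estimate> %s, %s\n  observed DP: %s ms; bootstrap mean %s ms (CI: %s to %s), %d/%d convergent\n",
    x$group, x$contrast$label,
    format(x$observed_dp_ms), format(round(x$boot_mean_ms, 2)),
    format(x$ci_low_ms), format(x$ci_high_ms), x$n_convergent, x$n_boot
  ))
  invisible(x)
}

#' Classify a group-difference confidence interval
#'
#' Reporting convention for bootstrap difference CIs: the groups are
#' `"not_different"` when the CI strictly contains 0, `"marginal"` when a CI
#' bound equals 0 exactly, and `"different"` when 0 lies outside the CI.
#'
#' @param ci_low,ci_high CI bounds in ms (`ci_low <= ci_high`).
#' @return One of `"not_different"`, `"marginal"`, `"different"`.
#' @export
classify_difference <- function(ci_low, ci_high) {
  if (is.na(ci_low) || is.na(ci_high)) {
    return(NA_character_)
  }
  if (ci_low > ci_high) {
    stop("`ci_low` must not exceed `ci_high`", call. = FALSE)
  }
  if (ci_low < 0 && ci_high > 0) {
    "not_different"
  } else if (ci_low == 0 || ci_high == 0) {
    "marginal"
  } else {
    "different"
  }
}

#' Compare two groups' divergence points
#'
#' Builds the bootstrap distribution of latency differences
#' (`comparison - reference`) by pairing resample b of the comparison group
#' with resample b of the reference group (groups are bootstrapped
#' independently; index pairing is an arbitrary but valid coupling). Pairs
#' where either resample was nonconvergent are dropped. Reports the mean
#' difference, its percentile CI, and the categorical verdict of
#' [classify_difference()]. Under full convergence the mean of paired
#' differences equals the difference of bootstrap means; both are reported.
#'
#' @param est_ref Reference group's [bootstrap_dp()] estimate (baseline).
#' @param est_cmp Comparison group's estimate (same contrast and `n_boot`).
#' @param ci_probs Percentile CI probabilities (default 2.5% and 97.5%).
#' @return An object of class `group_difference`: list with `group_ref`,
#'   `group_cmp`, `mean_diff_ms`, `diff_of_means_ms`, `ci_low_ms`,
#'   `ci_high_ms`, `classification`, `n_pairs`, `diffs_ms`.
#' @export
compare_groups <- function(est_ref, est_cmp, ci_probs = c(0.025, 0.975)) {
  stopifnot(inherits(est_ref, "divergence_estimate"),
            inherits(est_cmp, "divergence_estimate"))
  if (!same_contrast(est_ref$contrast, est_cmp$contrast)) {
    stop("estimates were built with different contrasts", call. = FALSE)
  }
  if (est_ref$n_boot != est_cmp$n_boot) {
    stop("estimates were built with different n_boot", call. = FALSE)
  }
  diffs <- est_cmp$boot_all_ms - est_ref$boot_all_ms
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) == 0L) {
    stop("no resample pairs where both groups converged", call. = FALSE)
  }
  ci <- unname(stats::quantile(diffs, ci_probs, type = 1))
  structure(
    list(
      group_ref = est_ref$group, group_cmp = est_cmp$group,
      contrast = est_ref$contrast,
      mean_diff_ms = mean(diffs),
      diff_of_means_ms = est_cmp$boot_mean_ms - est_ref$boot_mean_ms,
      ci_low_ms = ci[1], ci_high_ms = ci[2],
      classification = classify_difference(ci[1], ci[2]),
      n_pairs = length(diffs), diffs_ms = diffs
    ),
    class = "group_difference"
  )
}

#' @export
print.group_difference <- function(x, ...) {
  cat(sprintf(
    "<group_difference> %s - %s (%s)\n  mean difference %.2f ms (CI: %g to %g): %s [%d pairs]\n",
    x$group_cmp, x$group_ref, x$contrast$label,
    x$mean_diff_ms, x$ci_low_ms, x$ci_high_ms, x$classification, x$n_pairs
  ))
  invisible(x)
}

#' Run a contrast's DPA across groups
#'
#' Bootstraps the divergence point separately for every group and compares
#' each non-baseline group against the baseline. Each group's resampling
#' stream is derived from the master seed and the group/contrast labels, so
#' results for one group are unaffected by which other groups are analysed.
#'
#' @param series Participant-level timecourses for all groups (from
#'   [aggregate_participant()]).
#' @param group_map Data frame with columns `participant_id`, `group`.
#' @param contrast A [contrast_spec()].
#' @param baseline Baseline group label (reference for differences).
#' @param n_boot,seed,ci_probs Passed to [bootstrap_dp()].
#' @return A list with `estimates` (named list of `divergence_estimate`),
#'   `differences` (named list of `group_difference`), and `table` (tibble
#'   summary, one row per group).
#' @export
dpa_by_group <- function(series, group_map, contrast, baseline,
                         n_boot = 2000L, seed = 1L,
                         ci_probs = c(0.025, 0.975)) {
  required_cols(group_map, c("participant_id", "group"), "group map")
  groups <- unique(group_map$group)
  if (!baseline %in% groups) {
    stop("baseline group '", baseline, "' not present in group map", call. = FALSE)
  }
  estimates <- list()
  for (g in groups) {
    ids <- group_map$participant_id[group_map$group == g]
    sub <- series[series$participant_id %in% ids, , drop = FALSE]
    estimates[[g]] <- bootstrap_dp(sub, contrast, n_boot = n_boot, seed = seed,
                                   group = g, ci_probs = ci_probs)
  }
  differences <- list()
  for (g in setdiff(groups, baseline)) {
    differences[[g]] <- compare_groups(estimates[[baseline]], estimates[[g]],
                                       ci_probs = ci_probs)
  }
  tab <- dplyr::bind_rows(lapply(estimates, function(e) {
    tibble::tibble(
      contrast = e$contrast$label, group = e$group,
      observed_dp_ms = e$observed_dp_ms, boot_mean_ms = e$boot_mean_ms,
      ci_low_ms = e$ci_low_ms, ci_high_ms = e$ci_high_ms,
      n_convergent = e$n_convergent, n_boot = e$n_boot
    )
  }))
  diff_tab <- dplyr::bind_rows(lapply(differences, function(d) {
    tibble::tibble(
      contrast = d$contrast$label, group_ref = d$group_ref,
      group_cmp = d$group_cmp, mean_diff_ms = d$mean_diff_ms,
      ci_low_ms = d$ci_low_ms, ci_high_ms = d$ci_high_ms,
      classification = d$classification, n_pairs = d$n_pairs
    )
  }))
  list(estimates = estimates, differences = differences,
       table = tab, diff_table = diff_tab)
}
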