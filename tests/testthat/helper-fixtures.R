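# Shared fixtures: everything is built in code at test time.

default_grid <- function() bin_grid(default_timeline())

# Participant-level series for two roles from participant x bin matrices.
series_from_matrices <- function(A, B, grid,
                                 roles = c("target", "cu_target"),
                                 condition = "CP", sub_experiment = "1") {
  stopifnot(identical(dim(A), dim(B)), ncol(A) == grid$n_bins)
  pids <- sprintf("p%02d", seq_len(nrow(A)))
  starts <- bin_starts(grid)
  long <- function(M, role) {
    tibble::tibble(
      participant_id = rep(pids, each = ncol(M)),
      sub_experiment = sub_experiment, condition = condition, role = role,
      bin_start_ms = rep(starts, times = nrow(M)),
      prop = as.vector(t(M)), n_trials = 1L
    )
  }
  dplyr::bind_rows(long(A, roles[1]), long(B, roles[2]))
}

# Deterministic two-role series: both roles at 0.25 before `onset_bin`,
# then role_a jumps to a participant-specific positive level. Every
# bootstrap resample detects the same onset.
deterministic_series <- function(n_participants, grid, onset_bin,
                                 jump = 0.3) {
  nb <- grid$n_bins
  A <- matrix(0.25, n_participants, nb)
  B <- matrix(0.25, n_participants, nb)
  lev <- 0.25 + jump + 0.002 * seq_len(n_participants)
  A[, (onset_bin + 1):nb] <- matrix(rep(lev, nb - onset_bin), n_participants)
  B[, (onset_bin + 1):nb] <- 0.15
  series_from_matrices(A, B, grid)
}

# A bin-aligned bootstrap distribution with an exact (possibly fractional)
# mean, wrapped as a divergence_estimate. Mixes the two neighbouring bin
# multiples of the mean in the proportion that reproduces it exactly.
synthetic_estimate <- function(mean_ms, contrast, group, n_boot = 2000L) {
  base <- floor(mean_ms / contrast$grid$bin_ms) * contrast$grid$bin_ms
  k <- round((mean_ms - base) / contrast$grid$bin_ms * n_boot)
  dps <- c(rep(base, n_boot - k), rep(base + contrast$grid$bin_ms, k))
  stopifnot(abs(mean(dps) - mean_ms) < 1e-9)
  structure(
    list(group = group, contrast = contrast, observed_dp_ms = NA_real_,
         boot_all_ms = dps, boot_dps_ms = dps, boot_mean_ms = mean(dps),
         ci_low_ms = unname(quantile(dps, 0.025, type = 1)),
         ci_high_ms = unname(quantile(dps, 0.975, type = 1)),
         n_boot = n_boot, n_convergent = n_boot,
         ci_probs = c(0.025, 0.975), seed = NA_integer_),
    class = "divergence_estimate"
  )
}

# Small single-group cohort on the predictable-item condition.
tiny_cohort <- function(n = 6L, n_items = 4L, latency = 800, seed = 7L, ...) {
  simulate_cohort(cohort_spec(
    groups = list(list(label = "G1", n_participants = n,
                       latencies = list(cp = latency))),
    n_items = c(cp = n_items), seed = seed, ...
  ))
}

# Brute-force onset scan: first window of k consecutive TRUE flags.
onset_scan <- function(flags, starts, k) {
  flags[is.na(flags)] <- FALSE
  n <- length(flags)
  if (n >= k) {
    for (i in seq_len(n - k + 1)) {
      if (all(flags[i:(i + k - 1)])) return(starts[i])
    }
  }
  NA_real_
}
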