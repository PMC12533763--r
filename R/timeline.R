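#' Duration-normalized sentence timelines
#'
#' A `stimulus_timeline` represents the word-level timing of the normalized
#' sentence frame "The \[agent\] \[verb\] the \[object\]". Every item in a
#' sub-experiment shares the same frame because each word position was
#' normalized to a common duration across items, so a single timeline defines
#' the word onsets (relative to audio onset, t = 0), the audio offset, and the
#' time at which the selection cue (green border + mouse pointer) appears.
#'
#' @param durations Named numeric vector of word durations in ms, in sentence
#'   order. Names are word labels (e.g. `the1`, `agent`, `verb`, `the2`,
#'   `object`). All durations must be positive.
#' @param post_delay_ms Delay in ms between audio offset and the selection
#'   cue. Default 2000.
#'
#' @return An object of class `stimulus_timeline`: a list with elements
#'   `word_labels`, `word_durations_ms`, `word_onsets_ms` (first onset = 0),
#'   `audio_end_ms` (sum of durations), and `selection_cue_ms`
#'   (`audio_end_ms + post_delay_ms`).
#'
#' @examples
#' tl <- build_timeline(c(
#'   the1 = 93.58, agent = 612.72, verb = 602.05,
#'   the2 = 130.27, object = 464.45
#' ))
#' word_onset(tl, "verb")
#' @export
build_timeline <- function(durations, post_delay_ms = 2000) {
  if (length(durations) == 0L) {
    stop("`durations` must contain at least one word", call. = FALSE)
  }
  labels <- names(durations)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("`durations` must be a named vector of word durations", call. = FALSE)
  }
  bad <- labels[is.na(durations) | durations <= 0]
  if (length(bad) > 0L) {
    stop(
      "word duration must be a positive number; offending label(s): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.numeric(post_delay_ms) || length(post_delay_ms) != 1L ||
      is.na(post_delay_ms) || post_delay_ms < 0) {
    stop("`post_delay_ms` must be a single non-negative number", call. = FALSE)
  }
  durations <- as.numeric(durations)
  onsets <- cumsum(c(0, durations[-length(durations)]))
  names(onsets) <- labels
  names(durations) <- labels
  structure(
    list(
      word_labels = labels,
      word_durations_ms = durations,
      word_onsets_ms = onsets,
      audio_end_ms = sum(durations),
      selection_cue_ms = sum(durations) + post_delay_ms
    ),
    class = "stimulus_timeline"
  )
}

#' @export
print.stimulus_timeline <- function(x, ...) {
  cat("<stimulus_timeline>\n")
  print(data.frame(
    word = x$word_labels,
    onset_ms = round(x$word_onsets_ms, 2),
    duration_ms = round(x$word_durations_ms, 2),
    row.names = NULL
  ))
  cat(sprintf(
    "audio end: %.2f ms; selection cue: %.2f ms\n",
    x$audio_end_ms, x$selection_cue_ms
  ))
  invisible(x)
}

#' Word onset lookup
#'
#' @param timeline A `stimulus_timeline`.
#' @param label Word label present in the timeline.
#' @return Onset in ms relative to audio onset.
#' @export
word_onset <- function(timeline, label) {
  stopifnot(inherits(timeline, "stimulus_timeline"))
  if (!label %in% timeline$word_labels) {
    stop("unknown word label: ", label, call. = FALSE)
  }
  unname(timeline$word_onsets_ms[[label]])
}

#' Analysis bin grid
#'
#' Defines the half-open 20 ms bins `[start, start + bin_ms)` into which gaze
#' samples are aggregated. Time 0 is audio onset; the 2000 ms image preview
#' lives at negative times and is excluded by the default window.
#'
#' @param window_end_ms End of the analysis window in ms, or a
#'   `stimulus_timeline`, in which case the window runs from 0 through the
#'   selection cue (`audio_end_ms + 2000`).
#' @param bin_ms Bin width in ms (positive integer, default 20).
#' @param window_start_ms Window start in ms (default 0 = audio onset).
#' @return An object of class `bin_grid` with `bin_ms`, `window_start_ms`,
#'   `window_end_ms` and `n_bins = floor((end - start) / bin_ms)`.
#' @export
bin_grid <- function(window_end_ms, bin_ms = 20, window_start_ms = 0) {
  if (inherits(window_end_ms, "stimulus_timeline")) {
    window_end_ms <- window_end_ms$selection_cue_ms
  }
  if (!is.numeric(bin_ms) || length(bin_ms) != 1L || is.na(bin_ms) ||
      bin_ms <= 0 || bin_ms != round(bin_ms)) {
    stop("`bin_ms` must be a positive integer", call. = FALSE)
  }
  if (window_end_ms <= window_start_ms) {
    stop("`window_end_ms` must be greater than `window_start_ms`", call. = FALSE)
  }
  n_bins <- floor((window_end_ms - window_start_ms) / bin_ms)
  if (n_bins < 1L) {
    stop("analysis window shorter than one bin", call. = FALSE)
  }
  structure(
    list(
      bin_ms = as.numeric(bin_ms),
      window_start_ms = as.numeric(window_start_ms),
      window_end_ms = as.numeric(window_end_ms),
      n_bins = as.integer(n_bins)
    ),
    class = "bin_grid"
  )
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf(
    "<bin_grid> %d bins of %g ms over [%g, %g) ms\n",
    x$n_bins, x$bin_ms, x$window_start_ms,
    x$window_start_ms + x$n_bins * x$bin_ms
  ))
  invisible(x)
}

#' Bin start times of a grid
#'
#' @param grid A `bin_grid`.
#' @return Numeric vector of the left edges of all bins, in ms.
#' @export
bin_starts <- function(grid) {
  stopifnot(inherits(grid, "bin_grid"))
  grid$window_start_ms + grid$bin_ms * (seq_len(grid$n_bins) - 1)
}

#' Round a time to the nearest bin boundary
#'
#' Rounds to the nearest multiple of the grid's bin width; exact ties round
#' up. Used to report word onsets on the analysis grid (e.g. a verb onset of
#' 706.30 ms reported as 700 ms on a 20 ms grid).
#'
#' @param t_ms Numeric vector of times in ms.
#' @param grid A `bin_grid` (only its `bin_ms` is used).
#' @return Times rounded to multiples of `bin_ms`.
#' @export
round_to_bin <- function(t_ms, grid) {
  stopifnot(inherits(grid, "bin_grid"))
  floor(t_ms / grid$bin_ms + 0.5) * grid$bin_ms
}
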