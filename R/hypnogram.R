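#' Epoch state alphabet
#'
#' Contactless sleep monitors score each 30-second epoch as one of five
#' states: `WAKE`, `LIGHT`, `DEEP`, `REM` (the three sleep stages), or
#' `ABSENCE` (the sleeper is not in bed).
#'
#' @return Character vector of the five canonical state tokens.
#' @export
epoch_states <- function() {
  c("WAKE", "LIGHT", "DEEP", "REM", "ABSENCE")
}

#' Duration of one scoring epoch, in minutes
#' @export
EPOCH_MIN <- 0.5

# internal integer codes: 1 WAKE, 2 LIGHT, 3 DEEP, 4 REM, 5 ABSENCE
.state_code <- function(states) {
  if (is.numeric(states)) {
    code <- as.integer(states)
    if (any(is.na(code)) || any(code < 1L) || any(code > 5L))
      stop("numeric epoch states must be integer codes in 1..5")
    return(code)
  }
  code <- match(toupper(as.character(states)), epoch_states())
  if (any(is.na(code)))
    stop("unknown epoch state(s): ",
         paste(unique(states[is.na(code)]), collapse = ", "))
  code
}

.is_sleep_code <- function(code) code >= 2L & code <= 4L

#' Locate the analysis window of a night
#'
#' The analysis window begins at the first epoch following the last absence
#' bout that precedes sleep onset (or at the first epoch of the recording if
#' the sleeper never left the bed before falling asleep), and ends at the
#' epoch just before the first absence following the final sleep epoch (or at
#' the end of the recording, whichever comes first).
#'
#' @param states Character vector of epoch states (see [epoch_states()]),
#'   or the equivalent integer codes 1..5. One element per 30-s epoch.
#' @return A list of class `"analysis_window"` with elements `start` and
#'   `end` (1-based, inclusive epoch indices) and `has_sleep`. When no epoch
#'   is a sleep stage, `has_sleep` is `FALSE` and the window is undefined
#'   (`start`/`end` are `NA`).
#' @export
#' @examples
#' analysis_window(c("ABSENCE", "WAKE", "LIGHT", "WAKE", "LIGHT", "ABSENCE"))
analysis_window <- function(states) {
  code <- .state_code(states)
  if (length(code) == 0L) stop("epoch sequence is empty")
  sleep <- which(.is_sleep_code(code))
  if (length(sleep) == 0L) {
    out <- list(start = NA_integer_, end = NA_integer_, has_sleep = FALSE)
    class(out) <- "analysis_window"
    return(out)
  }
  first_sleep <- sleep[1L]
  last_sleep <- sleep[length(sleep)]
  pre_abs <- which(code[seq_len(first_sleep - 1L)] == 5L)
  start <- if (length(pre_abs)) pre_abs[length(pre_abs)] + 1L else 1L
  n <- length(code)
  post <- if (last_sleep < n) which(code[(last_sleep + 1L):n] == 5L) else integer(0)
  end <- if (length(post)) last_sleep + post[1L] - 1L else n
  out <- list(start = start, end = end, has_sleep = TRUE)
  class(out) <- "analysis_window"
  out
}

.check_window <- function(window) {
  if (!isTRUE(window$has_sleep))
    stop("analysis window undefined: night contains no sleep epoch")
}

#' Adjusted sleep latency (minutes)
#'
#' When an absence bout occurs before the first sleep epoch, latency is the
#' time from the end of the last pre-sleep absence (the window start) to the
#' first sleep epoch. Otherwise the recording was started in bed and latency
#' is the time from the start of the recording to the first sleep epoch.
#'
#' @inheritParams analysis_window
#' @param window The night's [analysis_window()].
#' @return Minutes, a multiple of 0.5.
#' @export
adjusted_sleep_latency <- function(states, window = analysis_window(states)) {
  .check_window(window)
  code <- .state_code(states)
  first_sleep <- which(.is_sleep_code(code))[1L]
  has_pre_absence <- any(code[seq_len(first_sleep - 1L)] == 5L)
  origin <- if (has_pre_absence) window$start else 1L
  EPOCH_MIN * (first_sleep - origin)
}

#' Total sleep time (minutes)
#'
#' Summed duration of LIGHT, DEEP, and REM epochs within the analysis window.
#'
#' @inheritParams adjusted_sleep_latency
#' @export
total_sleep_time <- function(states, window = analysis_window(states)) {
  .check_window(window)
  code <- .state_code(states)
  idx <- window$start:window$end
  EPOCH_MIN * sum(.is_sleep_code(code[idx]))
}

#' Wake after sleep onset (minutes)
#'
#' Wake time strictly between the first and the last sleep epoch; absence
#' epochs in that span are excluded.
#'
#' @inheritParams adjusted_sleep_latency
#' @export
wake_after_sleep_onset <- function(states, window = analysis_window(states)) {
  .check_window(window)
  code <- .state_code(states)
  sleep <- which(.is_sleep_code(code))
  first_sleep <- sleep[1L]
  last_sleep <- sleep[length(sleep)]
  if (last_sleep - first_sleep < 2L) return(0)
  span <- code[(first_sleep + 1L):(last_sleep - 1L)]
  EPOCH_MIN * sum(span == 1L)
}

#' Final awakening duration (minutes)
#'
#' Time from the last sleep epoch to the window end boundary (the first
#' absence after sleep, or the end of the recording).
#'
#' @inheritParams adjusted_sleep_latency
#' @export
final_awakening_duration <- function(states, window = analysis_window(states)) {
  .check_window(window)
  code <- .state_code(states)
  sleep <- which(.is_sleep_code(code))
  last_sleep <- sleep[length(sleep)]
  EPOCH_MIN * (window$end - last_sleep)
}

#' Time in bed (minutes)
#'
#' Presence-based time in bed: the number of non-absence epochs inside the
#' analysis window, times 0.5 min. Scoping TIB to the window keeps sleep
#' efficiency (TST/TIB) and the nightly partition identity internally
#' consistent and excludes pre-window lounging.
#'
#' @inheritParams adjusted_sleep_latency
#' @export
time_in_bed <- function(states, window = analysis_window(states)) {
  .check_window(window)
  code <- .state_code(states)
  idx <- window$start:window$end
  EPOCH_MIN * sum(code[idx] != 5L)
}

#' Derive all nightly sleep parameters from one hypnogram
#'
#' Composes the window location and the five parameter derivations. All
#' values are unrounded epoch totals (0.5-minute granularity); whole-minute
#' rounding is a display concern only (see [display_round()]). Nights with
#' no sleep epoch are flagged `valid = FALSE` with all parameters `NA`
#' rather than raising an error.
#'
#' @inheritParams analysis_window
#' @return A one-row `data.frame` with columns `valid`, `sl_adj_min`,
#'   `tst_min`, `waso_min`, `final_awakening_min`, `tib_min`,
#'   `sleep_efficiency_pct`.
#' @export
#' @examples
#' derive_night(c("ABSENCE", "WAKE", "LIGHT", "WAKE", "WAKE",
#'                "LIGHT", "REM", "WAKE", "ABSENCE"))
derive_night <- function(states) {
  code <- .state_code(states)
  window <- analysis_window(code)
  if (!window$has_sleep) {
    return(data.frame(valid = FALSE, sl_adj_min = NA_real_, tst_min = NA_real_,
                      waso_min = NA_real_, final_awakening_min = NA_real_,
                      tib_min = NA_real_, sleep_efficiency_pct = NA_real_))
  }
  tst <- total_sleep_time(code, window)
  tib <- time_in_bed(code, window)
  data.frame(
    valid = TRUE,
    sl_adj_min = adjusted_sleep_latency(code, window),
    tst_min = tst,
    waso_min = wake_after_sleep_onset(code, window),
    final_awakening_min = final_awakening_duration(code, window),
    tib_min = tib,
    sleep_efficiency_pct = 100 * tst / tib
  )
}

#' Derive nightly summaries for a long-format epoch table
#'
#' @param epochs A `data.frame` with columns `subject_id`, `night_index`,
#'   `epoch_index`, `state` (as written by [write_epochs()] or read by
#'   [read_epochs()]). Epochs are ordered by `epoch_index` within night.
#' @return A `data.frame` with one row per (subject, night):
#'   `subject_id`, `night_index`, `valid`, and the six parameter columns of
#'   [derive_night()]. Invalid nights (no sleep epoch) are retained and
#'   flagged, never dropped silently.
#' @export
derive_nights <- function(epochs) {
  stopifnot(all(c("subject_id", "night_index", "epoch_index", "state") %in%
                  names(epochs)))
  code <- .state_code(epochs$state)
  sid_f <- factor(epochs$subject_id)
  o <- order(sid_f, epochs$night_index, epochs$epoch_index)
  code <- code[o]
  key <- as.numeric(sid_f[o]) * (max(epochs$night_index) + 1) +
    epochs$night_index[o]
  runs <- rle(key)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  first <- starts  # index of first row of each night in the ordered table
  sid <- epochs$subject_id[o][first]
  nid <- epochs$night_index[o][first]
  m <- length(starts)
  res <- matrix(NA_real_, m, 7L)
  for (i in seq_len(m)) {
    res[i, ] <- .derive_night_vec(code[starts[i]:ends[i]])
  }
  data.frame(subject_id = sid, night_index = nid,
             valid = res[, 1L] > 0,
             sl_adj_min = res[, 2L], tst_min = res[, 3L],
             waso_min = res[, 4L], final_awakening_min = res[, 5L],
             tib_min = res[, 6L], sleep_efficiency_pct = res[, 7L])
}

# lean single-pass derivation on integer codes; returns
# c(valid, sl_adj, tst, waso, final_awakening, tib, se)
.derive_night_vec <- function(code) {
  sleep <- which(.is_sleep_code(code))
  if (length(sleep) == 0L) return(c(0, rep(NA_real_, 6L)))
  first_sleep <- sleep[1L]
  last_sleep <- sleep[length(sleep)]
  n <- length(code)
  pre <- which(code[seq_len(first_sleep - 1L)] == 5L)
  start <- if (length(pre)) pre[length(pre)] + 1L else 1L
  post <- if (last_sleep < n) which(code[(last_sleep + 1L):n] == 5L) else integer(0)
  end <- if (length(post)) last_sleep + post[1L] - 1L else n
  sl <- EPOCH_MIN * (first_sleep - if (length(pre)) start else 1L)
  tst <- EPOCH_MIN * length(sleep)
  waso <- if (last_sleep - first_sleep >= 2L)
    EPOCH_MIN * sum(code[(first_sleep + 1L):(last_sleep - 1L)] == 1L) else 0
  fa <- EPOCH_MIN * (end - last_sleep)
  tib <- EPOCH_MIN * sum(code[start:end] != 5L)
  c(1, sl, tst, waso, fa, tib, 100 * tst / tib)
}

#' Read / write long-format epoch tables
#'
#' Epoch CSVs have header `subject_id,night_index,epoch_index,state`; state
#' tokens are matched case-insensitively on read and written in canonical
#' uppercase.
#'
#' @param path Path to a CSV file.
#' @return `read_epochs()` returns the epoch `data.frame`.
#' @export
read_epochs <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "night_index", "epoch_index", "state") %in% names(x)))
  x$state <- epoch_states()[.state_code(x$state)]
  x
}

#' @rdname read_epochs
#' @param epochs Epoch `data.frame` to write.
#' @export
write_epochs <- function(epochs, path) {
  epochs$state <- epoch_states()[.state_code(epochs$state)]
  utils::write.csv(epochs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write nightly summary tables
#'
#' Night CSVs have header
#' `subject_id,night_index,valid,sl_adj_min,tst_min,waso_min,final_awakening_min,tib_min,sleep_efficiency_pct`.
#'
#' @param path Path to a CSV file.
#' @export
read_nights <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_nights
#' @param nights Nightly summary `data.frame` (from [derive_nights()]).
#' @export
write_nights <- function(nights, path) {
  utils::write.csv(nights, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
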