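# Per-recording feature extraction: each kinematic signal is reduced to its
# range of movement (ROM); an extended mode adds min/max/median/mean.

#' Range of movement of a signal
#'
#' Maximum minus minimum of the signal over its valid frames — the single
#' summary used as a classification feature for each catalogue signal.
#'
#' @param signal A `kin_signal` (see [compute_signal()]) or a plain numeric
#'   vector (`NA`s treated as invalid frames).
#' @return Non-negative scalar in the signal's units.
#' @export
range_of_movement <- function(signal) {
  v <- valid_values(signal)
  max(v) - min(v)
}

#' Summary statistics of a signal
#'
#' @param signal A `kin_signal` or numeric vector.
#' @return Named numeric vector `c(min, max, median, mean)` over valid frames.
#' @export
signal_statistics <- function(signal) {
  v <- valid_values(signal)
  c(min = min(v), max = max(v),
    median = stats::median(v), mean = mean(v))
}

valid_values <- function(signal) {
  v <- if (inherits(signal, "kin_signal")) signal$values[signal$valid]
       else signal[!is.na(signal)]
  if (length(v) < 1)
    ms_stop("empty_signal", "signal has no valid frames")
  v
}

#' Build the recordings-by-features table for classification
#'
#' Computes the catalogue signals for every recording and reduces each to
#' features. In `"rom"` mode (the default) each recording yields one ROM per
#' catalogue signal — 15 features under the default catalogue. In
#' `"extended"` mode each signal additionally contributes its min, max,
#' median and mean (five columns per signal). Recordings in which any
#' catalogue signal has no valid frame are excluded and listed in
#' `attr(, "excluded")`.
#'
#' @param sequences List of `pose_sequence` objects.
#' @param catalogue Named list of [signal_def()]s.
#' @param mode `"rom"` or `"extended"`.
#' @return A data frame of class `feature_table`: columns `recording_id`,
#'   `test_id`, then features in catalogue order (`<signal>_rom`, and in
#'   extended mode `<signal>_{min,max,median,mean}`).
#' @export
build_feature_table <- function(sequences, catalogue = default_catalogue(),
                                mode = c("rom", "extended")) {
  mode <- match.arg(mode)
  if (length(sequences) < 1)
    ms_stop("bad_argument", "build_feature_table needs >= 1 sequence")
  rows <- list(); excluded <- character(0)
  for (seq in sequences) {
    feats <- tryCatch({
      sigs <- compute_signals(seq, catalogue)
      unlist(lapply(sigs, function(s) {
        rom <- c(rom = range_of_movement(s))
        if (mode == "extended") c(rom, signal_statistics(s)) else rom
      }))
    }, motionscreen_error = function(e) NULL)
    if (is.null(feats)) {
      excluded <- c(excluded, seq$subject_id)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      recording_id = seq$subject_id, test_id = seq$test_id,
      as.list(feats), check.names = FALSE)
  }
  if (length(rows) == 0)
    ms_stop("empty_signal", "all recordings excluded: no valid signals")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(out) <- sub("\\.", "_", names(out))
  class(out) <- c("feature_table", "data.frame")
  attr(out, "excluded") <- excluded
  attr(out, "mode") <- mode
  out
}

#' Extract the numeric feature matrix from a feature table
#'
#' @param table A `feature_table`.
#' @return Numeric matrix (recordings x features).
#' @export
feature_matrix <- function(table) {
  cols <- setdiff(names(table), c("recording_id", "test_id"))
  as.matrix(as.data.frame(table)[, cols, drop = FALSE])
}
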