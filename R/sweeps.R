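# Sweep extraction and steady-state averaging.

#' Extract complete sweeps from a trace bundle
#'
#' Returns one row per (sweep, step) pair with its sample slice. Sweeps cut
#' off at the recording edges are dropped (with a message). When the bundle
#' carries no sweep annotations, sweeps are reconstructed from the command
#' voltage: runs of constant command matching the protocol's 11-step ladder
#' are identified; on annotated synthetic data the two routes agree
#' exactly.
#'
#' @param bundle A `"trace_bundle"`.
#' @param protocol A [protocol_spec()]; defaults to the bundle's metadata.
#' @return A `"sweep_set"`: data.frame with columns `sweep`, `step_mV`,
#'   `t_start_s`, `i_start`, `i_end` (inclusive sample indices, 1-based
#'   into the bundle arrays). Zero rows (with a warning) when no complete
#'   sweep exists.
#' @export
extract_sweeps <- function(bundle, protocol = bundle$meta$protocol) {
  fs <- protocol$sample_rate_Hz
  n_step <- round(protocol$step_duration_ms / 1000 * fs)
  levels <- protocol$step_levels_mV
  if (!is.null(bundle$sweep) && !all(is.na(bundle$sweep))) {
    rows <- .sweeps_from_annotations(bundle, levels, n_step)
  } else {
    rows <- .sweeps_from_edges(bundle, levels, n_step, protocol$holding_mV)
  }
  if (nrow(rows) == 0) {
    warning("no complete sweep found in bundle")
  }
  structure(rows, class = c("sweep_set", "data.frame"))
}

.sweeps_from_annotations <- function(bundle, levels, n_step) {
  out <- list()
  dropped <- 0L
  for (sw in unique(bundle$sweep[!is.na(bundle$sweep)])) {
    rows <- lapply(seq_along(levels), function(k) {
      idx <- which(bundle$sweep == sw & bundle$step_mV == levels[k])
      if (length(idx) < n_step) return(NULL)
      data.frame(sweep = sw, step_mV = levels[k],
                 t_start_s = bundle$time_s[idx[1]],
                 i_start = idx[1], i_end = idx[1] + n_step - 1L)
    })
    if (any(vapply(rows, is.null, logical(1)))) {
      dropped <- dropped + 1L
      next
    }
    out[[length(out) + 1L]] <- do.call(rbind, rows)
  }
  if (dropped > 0)
    message(dropped, " incomplete sweep(s) dropped at recording edges")
  if (length(out) == 0)
    return(data.frame(sweep = integer(0), step_mV = numeric(0),
                      t_start_s = numeric(0), i_start = integer(0),
                      i_end = integer(0)))
  do.call(rbind, out)
}

.sweeps_from_edges <- function(bundle, levels, n_step, holding) {
  r <- rle(bundle$command_mV)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  sw <- 0L
  k <- 1
  while (k <= length(r$values) - length(levels) + 1) {
    vals <- r$values[k:(k + length(levels) - 1)]
    lens <- r$lengths[k:(k + length(levels) - 1)]
    if (all(vals == levels) && all(lens >= n_step)) {
      sw <- sw + 1L
      out[[sw]] <- data.frame(
        sweep = sw, step_mV = levels,
        t_start_s = bundle$time_s[starts[k:(k + length(levels) - 1)]],
        i_start = starts[k:(k + length(levels) - 1)],
        i_end = starts[k:(k + length(levels) - 1)] + n_step - 1L)
      k <- k + length(levels)
    } else {
      k <- k + 1
    }
  }
  if (length(out) == 0)
    return(data.frame(sweep = integer(0), step_mV = numeric(0),
                      t_start_s = numeric(0), i_start = integer(0),
                      i_end = integer(0)))
  do.call(rbind, out)
}

#' Steady-state mean over the end of a voltage step
#'
#' Averages a window near the end of a step: `[end - window - guard,
#' end - guard]` (default 30 ms window with a 2 ms guard excluding the
#' off-edge capacitive transient). On a 200 ms step the default window is
#' 168-198 ms.
#'
#' @param step_slice Numeric vector: the current samples of one step.
#' @param sample_rate_Hz Sampling rate of the slice.
#' @param window_ms Averaging window length (ms).
#' @param guard_ms Guard interval excluded at the step end (ms).
#' @return A list with `I_mean_pA`, `I_sd_pA`, `n_samples`.
#' @export
steady_state_mean <- function(step_slice, sample_rate_Hz, window_ms = 30,
                              guard_ms = 2) {
  n <- length(step_slice)
  n_win <- round(window_ms / 1000 * sample_rate_Hz)
  n_guard <- round(guard_ms / 1000 * sample_rate_Hz)
  if (n <= n_win + n_guard)
    stop("step slice shorter than steady-state window plus guard")
  idx <- (n - n_guard - n_win + 1L):(n - n_guard)
  list(I_mean_pA = mean(step_slice[idx]),
       I_sd_pA = stats::sd(step_slice[idx]),
       n_samples = n_win)
}
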