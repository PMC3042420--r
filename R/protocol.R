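# Voltage-step protocols and bath-exchange timelines.

#' Episodic voltage-step protocol
#'
#' Eleven consecutive steps from +100 to -100 mV in 20 mV decrements from a
#' 0 mV holding potential, repeated at a fixed interval. Two canonical
#' presets are provided: preset 1 uses 300 ms steps repeated every 16.7 s,
#' preset 2 uses 200 ms steps repeated every 5.3 s. Custom durations,
#' repeat intervals and sample rates are allowed (e.g. for fast test
#' fixtures); the step ladder itself is fixed at 11 levels decreasing by
#' 20 mV.
#'
#' @param preset 1 or 2 to select a canonical preset, or `NULL` with
#'   explicit arguments.
#' @param step_levels_mV Step levels, strictly decreasing by 20 mV,
#'   11 values.
#' @param step_duration_ms Duration of each step.
#' @param repeat_interval_s Sweep repetition interval; must exceed the sweep
#'   duration.
#' @param sample_rate_Hz Sampling rate (canonical recordings: 5 kHz).
#' @param holding_mV Holding potential between sweeps.
#' @return An object of class `"protocol_spec"`.
#' @export
protocol_spec <- function(preset = 1, step_levels_mV = seq(100, -100, by = -20),
                          step_duration_ms = NULL, repeat_interval_s = NULL,
                          sample_rate_Hz = 5000, holding_mV = 0) {
  if (!is.null(preset)) {
    if (!preset %in% c(1, 2)) stop("preset must be 1 or 2")
    if (is.null(step_duration_ms))
      step_duration_ms <- if (preset == 1) 300 else 200
    if (is.null(repeat_interval_s))
      repeat_interval_s <- if (preset == 1) 16.7 else 5.3
  }
  if (length(step_levels_mV) != 11)
    stop("protocol requires 11 step levels")
  if (any(diff(step_levels_mV) != -20))
    stop("step levels must decrease by 20 mV")
  stopifnot(step_duration_ms > 0, repeat_interval_s > 0, sample_rate_Hz > 0)
  sweep_s <- length(step_levels_mV) * step_duration_ms / 1000
  if (repeat_interval_s <= sweep_s)
    stop("repeat_interval_s must exceed the sweep duration (",
         sweep_s, " s)")
  structure(list(holding_mV = holding_mV, step_levels_mV = step_levels_mV,
                 step_duration_ms = step_duration_ms,
                 repeat_interval_s = repeat_interval_s,
                 sample_rate_Hz = sample_rate_Hz,
                 sweep_duration_s = sweep_s),
            class = "protocol_spec")
}

#' One bath epoch
#'
#' @param start_s Epoch start time (s).
#' @param bath Bath `"solution"`.
#' @param benzamil_uM Blocker concentration in this epoch, >= 0.
#' @param exchange_tau_s First-order bath-exchange time constant (s).
#' @param label Optional condition label (defaults to the bath label, with
#'   "+benz" appended when the blocker is present).
#' @return A list describing the epoch.
#' @export
bath_epoch <- function(start_s, bath, benzamil_uM = 0, exchange_tau_s = 2,
                       label = NULL) {
  stopifnot(inherits(bath, "solution"), benzamil_uM >= 0, exchange_tau_s > 0)
  if (is.null(label))
    label <- paste0(bath$label, if (benzamil_uM > 0) "+benz" else "")
  list(start_s = start_s, bath = bath, benzamil_uM = benzamil_uM,
       exchange_tau_s = exchange_tau_s, label = label)
}

#' Bath-exchange timeline
#'
#' An ordered sequence of [bath_epoch()]s covering `duration_s` of
#' recording. Epochs must start at increasing times and the first epoch
#' must start at 0 (the cell is assumed equilibrated in the first bath).
#'
#' @param epochs List of [bath_epoch()]s.
#' @param duration_s Total recording duration (s).
#' @return An object of class `"bath_timeline"`.
#' @export
bath_timeline <- function(epochs, duration_s) {
  starts <- vapply(epochs, `[[`, numeric(1), "start_s")
  if (length(starts) == 0) stop("timeline needs at least one epoch")
  if (starts[1] != 0) stop("first epoch must start at t = 0")
  if (any(diff(starts) <= 0)) stop("epoch start times must be increasing")
  if (duration_s <= max(starts))
    stop("duration_s must exceed the last epoch start")
  labels <- vapply(epochs, `[[`, character(1), "label")
  labels <- make.unique(labels, sep = ".")
  for (i in seq_along(epochs)) epochs[[i]]$label <- labels[i]
  structure(list(epochs = epochs, duration_s = duration_s),
            class = "bath_timeline")
}

# epoch boundaries: start and end time of each epoch
.epoch_bounds <- function(timeline) {
  starts <- vapply(timeline$epochs, `[[`, numeric(1), "start_s")
  data.frame(label = vapply(timeline$epochs, `[[`, character(1), "label"),
             start_s = starts,
             end_s = c(starts[-1], timeline$duration_s),
             benzamil_uM = vapply(timeline$epochs, `[[`, numeric(1),
                                  "benzamil_uM"),
             exchange_tau_s = vapply(timeline$epochs, `[[`, numeric(1),
                                     "exchange_tau_s"),
             stringsAsFactors = FALSE)
}
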