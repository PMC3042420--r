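# Plain-text persistence for trace bundles: a CSV table of samples plus a
# JSON sidecar carrying protocol, timeline, solutions, cell parameters and
# the seed — enough to re-simulate or re-analyze the bundle.

.sol_to_list <- function(s)
  list(label = s$label, ions = as.list(s$ions),
       neutrals = as.list(s$neutrals), pH = s$pH,
       temperature_C = s$temperature_C)

.sol_from_list <- function(x)
  make_solution(x$label, unlist(x$ions), unlist(x$neutrals), x$pH,
                x$temperature_C)

#' Write a trace bundle as CSV + JSON sidecar
#'
#' Samples go to `<path>.csv` (columns `time_s`, `sweep`, `step_mV`,
#' `command_mV`, `current_pA`); metadata to `<path>.json`.
#'
#' @param bundle A `"trace_bundle"` from [simulate_experiment()].
#' @param path Path stem (without extension).
#' @return `path`, invisibly.
#' @export
write_trace_bundle <- function(bundle, path) {
  df <- data.frame(time_s = bundle$time_s, sweep = bundle$sweep,
                   step_mV = bundle$step_mV, command_mV = bundle$command_mV,
                   current_pA = bundle$current_pA)
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  m <- bundle$meta
  cellp <- m$cell
  chan <- unclass(cellp$channels)
  chan$ratios <- as.list(chan$ratios)   # keep names through JSON
  meta <- list(
    protocol = m$protocol[c("holding_mV", "step_levels_mV",
                            "step_duration_ms", "repeat_interval_s",
                            "sample_rate_Hz")],
    timeline = list(duration_s = m$timeline$duration_s,
                    epochs = lapply(m$timeline$epochs, function(e)
                      list(start_s = e$start_s, bath = .sol_to_list(e$bath),
                           benzamil_uM = e$benzamil_uM,
                           exchange_tau_s = e$exchange_tau_s,
                           label = e$label))),
    pipette = .sol_to_list(m$pipette),
    cell = list(channels = chan,
                leak_nS = cellp$leak_nS,
                leak_reversal_mV = cellp$leak_reversal_mV,
                capacitance_pF = cellp$capacitance_pF,
                series_resistance_MOhm = cellp$series_resistance_MOhm,
                drift_sd_pA = cellp$drift_sd_pA,
                drift_tau_s = cellp$drift_tau_s,
                temperature_C = cellp$temperature_C),
    ljp_by_epoch = as.list(m$ljp_by_epoch),
    noise_sd_pA = m$noise_sd_pA,
    seed = m$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trace bundle written by [write_trace_bundle()]
#'
#' @param path Path stem (without extension). The sidecar `<path>.json`
#'   must exist; a missing sidecar is an error naming the file.
#' @return A `"trace_bundle"`.
#' @export
read_trace_bundle <- function(path) {
  csv <- paste0(path, ".csv"); side <- paste0(path, ".json")
  if (!file.exists(csv)) stop("trace file not found: ", csv)
  if (!file.exists(side)) stop("metadata sidecar not found: ", side)
  df <- utils::read.csv(csv)
  m <- jsonlite::read_json(side, simplifyVector = TRUE)
  protocol <- protocol_spec(preset = NULL,
                            step_levels_mV = m$protocol$step_levels_mV,
                            step_duration_ms = m$protocol$step_duration_ms,
                            repeat_interval_s = m$protocol$repeat_interval_s,
                            sample_rate_Hz = m$protocol$sample_rate_Hz,
                            holding_mV = m$protocol$holding_mV)
  # jsonlite may simplify the epoch list; rebuild it defensively
  raw_epochs <- m$timeline$epochs
  if (is.data.frame(raw_epochs))
    raw_epochs <- lapply(seq_len(nrow(raw_epochs)), function(i)
      lapply(raw_epochs, function(col) if (is.data.frame(col)) col[i, ]
             else col[[i]]))
  epochs <- lapply(raw_epochs, function(e)
    bath_epoch(e$start_s, .sol_from_list(as.list(e$bath)), e$benzamil_uM,
               e$exchange_tau_s, e$label))
  timeline <- bath_timeline(epochs, m$timeline$duration_s)
  ch <- m$cell$channels
  cell <- cell_model(
    channels = channel_population(P_Na = ch$P_Na,
                                  ratio_Li = ch$ratios[["Li"]],
                                  ratio_K = ch$ratios[["K"]],
                                  ratio_NMDG = ch$ratios[["NMDG"]],
                                  Kd0 = ch$Kd0, delta = ch$delta,
                                  z_blocker = ch$z_blocker,
                                  tau_on = ch$tau_on, tau_off = ch$tau_off,
                                  rundown_tau = ch$rundown_tau,
                                  rundown_floor = ch$rundown_floor),
    pipette = .sol_from_list(m$pipette),
    leak_nS = m$cell$leak_nS, leak_reversal_mV = m$cell$leak_reversal_mV,
    capacitance_pF = m$cell$capacitance_pF,
    series_resistance_MOhm = m$cell$series_resistance_MOhm,
    drift_sd_pA = m$cell$drift_sd_pA, drift_tau_s = m$cell$drift_tau_s,
    temperature_C = m$cell$temperature_C)
  structure(list(time_s = df$time_s, current_pA = df$current_pA,
                 command_mV = df$command_mV, sweep = df$sweep,
                 step_mV = df$step_mV,
                 meta = list(protocol = protocol, timeline = timeline,
                             pipette = cell$pipette, cell = cell,
                             ljp_by_epoch = unlist(m$ljp_by_epoch),
                             noise_sd_pA = m$noise_sd_pA, seed = m$seed)),
            class = "trace_bundle")
}
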