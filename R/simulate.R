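# Whole-cell voltage-clamp simulator.
#
# Quasi-static membrane model: at every sample the membrane potential
# satisfies V_m = V_cmd - LJP(bath) - I_total(V_m) * Rs, with
# I_total = sum over permeant cations of GHK current x (1 - block) x
# rundown + ohmic leak. Capacitive transients (single exponential with time
# constant Rs*Cm at every command edge), a slow Ornstein-Uhlenbeck baseline
# drift, and white recording noise are added on top. Bath exchanges blend
# ion concentrations (and the junction offset) exponentially with the
# epoch's exchange tau; the blocker washes in/out with its own first-order
# kinetics.

.channel_ions <- c("Na", "Li", "K", "NMDG")

# per-sample exponential blending of a per-epoch target value
.blend_epochs <- function(t, bounds, targets, taus) {
  out <- numeric(length(t))
  v_start <- targets[1]
  for (j in seq_len(nrow(bounds))) {
    idx <- t >= bounds$start_s[j] & t < bounds$end_s[j]
    if (j == nrow(bounds)) idx <- t >= bounds$start_s[j]  # include t == end
    dtj <- t[idx] - bounds$start_s[j]
    out[idx] <- targets[j] + (v_start - targets[j]) * exp(-dtj / taus[j])
    v_end <- targets[j] +
      (v_start - targets[j]) * exp(-(bounds$end_s[j] - bounds$start_s[j]) /
                                     taus[j])
    v_start <- v_end
  }
  out
}

# total ionic steady-state current (pA) at membrane potential Vm (mV);
# all arguments vectorized over samples
.ionic_current <- function(Vm, cell, co, benz, rund, T_K) {
  ch <- cell$channels
  fb <- block_fraction(Vm, benz, ch$Kd0, ch$delta, ch$z_blocker, T_K)
  I <- cell$leak_nS * (Vm - cell$leak_reversal_mV)
  open_scale <- rund * (1 - fb)
  for (ion in .channel_ions) {
    P <- ch$P_Na * ch$ratios[[ion]]
    if (P <= 0) next
    ci <- ion_conc(cell$pipette, ion)
    coi <- co[[ion]]
    if (ci == 0 && all(coi == 0)) next
    I <- I + open_scale * ghk_current(Vm, P, ci, coi, 1L, T_K)
  }
  I
}

#' Analytic steady-state operating point of the simulated cell
#'
#' Solves the series-resistance fixed point
#' V_m = V_cmd - ljp - I(V_m) Rs for one command potential, returning the
#' membrane potential and the current decomposed into channel and leak
#' components. This closed-form oracle is what the simulator converges to
#' at steady state and is used to validate the analysis pipeline.
#'
#' @param cell A [cell_model()].
#' @param V_cmd_mV Command potential (mV).
#' @param bath Bath `"solution"`.
#' @param benzamil_uM Blocker concentration (uM).
#' @param t_s Time since whole-cell access (s), for the rundown factor.
#' @param ljp_mV Junction offset; `NULL` computes it with
#'   [henderson_ljp()] from the cell's pipette and `bath`.
#' @return A list with `Vm_mV`, `I_total_pA`, `I_channel_pA`, `I_leak_pA`.
#' @export
steady_state_current <- function(cell, V_cmd_mV, bath, benzamil_uM = 0,
                                 t_s = 0, ljp_mV = NULL) {
  T_K <- cell$temperature_C + phys_constants()$zero_celsius
  if (is.null(ljp_mV)) ljp_mV <- henderson_ljp(cell$pipette, bath,
                                               temperature_K = T_K)
  co <- lapply(stats::setNames(.channel_ions, .channel_ions),
               function(i) ion_conc(bath, i))
  rund <- rundown_factor(t_s, cell$channels$rundown_tau,
                         cell$channels$rundown_floor)
  rs <- cell$series_resistance_MOhm * 1e-3   # pA -> mV
  veff <- V_cmd_mV - ljp_mV
  vapply_one <- function(vc) {
    f <- function(vm) vm - (vc - .ionic_current(vm, cell, co, benzamil_uM,
                                                rund, T_K) * rs)
    stats::uniroot(f, interval = c(vc - 500, vc + 500), tol = 1e-10)$root
  }
  Vm <- vapply(veff, vapply_one, numeric(1))
  I_leak <- cell$leak_nS * (Vm - cell$leak_reversal_mV)
  I_tot <- .ionic_current(Vm, cell, co, benzamil_uM, rund, T_K)
  list(Vm_mV = Vm, I_total_pA = I_tot, I_channel_pA = I_tot - I_leak,
       I_leak_pA = I_leak)
}

# command waveform + annotations for a protocol over N samples; all
# boundaries are computed in integer sample counts so that every step owns
# exactly step_duration x sample_rate samples
.command_waveform <- function(protocol, t) {
  fs <- protocol$sample_rate_Hz
  n_rep <- round(protocol$repeat_interval_s * fs)
  n_step <- round(protocol$step_duration_ms / 1000 * fs)
  n_sweep <- length(protocol$step_levels_mV) * n_step
  n <- seq_along(t) - 1L
  pos <- n %% n_rep
  in_sweep <- pos < n_sweep
  step_idx <- pos %/% n_step + 1L
  command <- rep(protocol$holding_mV, length(t))
  command[in_sweep] <- protocol$step_levels_mV[step_idx[in_sweep]]
  sweep <- ifelse(in_sweep, n %/% n_rep + 1L, NA_integer_)
  step_mV <- rep(NA_real_, length(t))
  step_mV[in_sweep] <- protocol$step_levels_mV[step_idx[in_sweep]]
  list(command = command, sweep = as.integer(sweep), step_mV = step_mV)
}

#' Simulate an episodic whole-cell voltage-clamp recording
#'
#' Generates a complete recording — sampled current, command voltage and
#' sweep annotations — for one cell under a voltage-step protocol and a
#' bath-exchange timeline. Identical inputs and seed reproduce the bundle
#' bit-identically.
#'
#' @param cell A [cell_model()].
#' @param protocol A [protocol_spec()].
#' @param timeline A [bath_timeline()]; its duration must allow at least
#'   one complete sweep.
#' @param noise_sd_pA White recording-noise standard deviation (pA).
#' @param seed Integer seed controlling all randomness (noise and drift).
#' @return An object of class `"trace_bundle"`: a list with `time_s`,
#'   `current_pA`, `command_mV`, `sweep`, `step_mV` and a `meta` list
#'   (protocol, timeline, pipette, cell, per-epoch junction offsets, seed).
#' @export
simulate_experiment <- function(cell, protocol, timeline, noise_sd_pA = 20,
                                seed = 1L) {
  stopifnot(inherits(cell, "cell_model"), inherits(protocol, "protocol_spec"),
            inherits(timeline, "bath_timeline"))
  if (timeline$duration_s < protocol$sweep_duration_s)
    stop("timeline shorter than one protocol sweep")
  T_K <- cell$temperature_C + phys_constants()$zero_celsius
  fs <- protocol$sample_rate_Hz
  N <- round(timeline$duration_s * fs)
  t <- (seq_len(N) - 1L) / fs
  wav <- .command_waveform(protocol, t)
  bounds <- .epoch_bounds(timeline)

  # per-epoch targets: bath ion concentrations and junction offsets
  ljp_by_epoch <- vapply(timeline$epochs, function(e)
    henderson_ljp(cell$pipette, e$bath, temperature_K = T_K), numeric(1))
  names(ljp_by_epoch) <- bounds$label
  co <- lapply(stats::setNames(.channel_ions, .channel_ions), function(ion) {
    targets <- vapply(timeline$epochs, function(e) ion_conc(e$bath, ion),
                      numeric(1))
    .blend_epochs(t, bounds, targets, bounds$exchange_tau_s)
  })
  ljp_t <- .blend_epochs(t, bounds, ljp_by_epoch, bounds$exchange_tau_s)
  benz_tau <- ifelse(diff(c(0, bounds$benzamil_uM)) >= 0,
                     cell$channels$tau_on, cell$channels$tau_off)
  benz <- .blend_epochs(t, bounds, bounds$benzamil_uM, benz_tau)
  rund <- rundown_factor(t, cell$channels$rundown_tau,
                         cell$channels$rundown_floor)

  # quasi-static fixed point V_m = V_cmd - ljp - I(V_m) Rs
  rs <- cell$series_resistance_MOhm * 1e-3
  veff <- wav$command - ljp_t
  Vm <- veff
  for (iter in 1:40) {
    Vm_new <- veff - .ionic_current(Vm, cell, co, benz, rund, T_K) * rs
    delta <- max(abs(Vm_new - Vm))
    Vm <- Vm_new
    if (delta < 1e-7) break
  }
  I <- .ionic_current(Vm, cell, co, benz, rund, T_K)

  # capacitive transients at command edges
  tau_c <- cell$series_resistance_MOhm * cell$capacitance_pF * 1e-6  # s
  L <- max(1L, ceiling(8 * tau_c * fs))
  decay <- exp(-(seq_len(L) - 1L) / (tau_c * fs))
  edges <- which(diff(wav$command) != 0) + 1L
  for (e in edges) {
    amp <- (wav$command[e] - wav$command[e - 1L]) /
      cell$series_resistance_MOhm * 1e3              # pA
    span <- e:min(N, e + L - 1L)
    I[span] <- I[span] + amp * decay[seq_along(span)]
  }

  withr::with_seed(seed, {
    if (cell$drift_sd_pA > 0) {
      a <- exp(-1 / (fs * cell$drift_tau_s))
      innov <- stats::rnorm(N, 0, cell$drift_sd_pA * sqrt(1 - a^2))
      innov[1] <- stats::rnorm(1, 0, cell$drift_sd_pA)
      I <- I + as.numeric(stats::filter(innov, a, method = "recursive"))
    }
    if (noise_sd_pA > 0) I <- I + stats::rnorm(N, 0, noise_sd_pA)
  })

  structure(list(time_s = t, current_pA = I, command_mV = wav$command,
                 sweep = wav$sweep, step_mV = wav$step_mV,
                 meta = list(protocol = protocol, timeline = timeline,
                             pipette = cell$pipette, cell = cell,
                             ljp_by_epoch = ljp_by_epoch,
                             noise_sd_pA = noise_sd_pA, seed = seed)),
            class = "trace_bundle")
}

#' @export
print.trace_bundle <- function(x, ...) {
  cat(sprintf(
    "<trace_bundle> %d samples @ %g Hz (%.1f s), %d sweeps, %d epochs\n",
    length(x$time_s), x$meta$protocol$sample_rate_Hz,
    x$meta$timeline$duration_s, max(x$sweep, na.rm = TRUE),
    length(x$meta$timeline$epochs)))
  invisible(x)
}
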