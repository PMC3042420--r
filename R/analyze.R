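# Bundle-level analysis: from a raw trace to per-condition I-V curves and
# metrics, and paired before/after analysis across a bath transition.

# per-(sweep, step) steady-state means for a bundle
.step_means <- function(bundle, sweeps, window_ms = 30, guard_ms = 2) {
  fs <- bundle$meta$protocol$sample_rate_Hz
  out <- sweeps
  res <- lapply(seq_len(nrow(sweeps)), function(i) {
    sl <- bundle$current_pA[sweeps$i_start[i]:sweeps$i_end[i]]
    steady_state_mean(sl, fs, window_ms, guard_ms)
  })
  out$I_mean_pA <- vapply(res, `[[`, numeric(1), "I_mean_pA")
  out$I_sd_pA <- vapply(res, `[[`, numeric(1), "I_sd_pA")
  out$n_samples <- vapply(res, `[[`, numeric(1), "n_samples")
  out
}

# sweep-level table: start/end, epoch assignment, settled flag.  A sweep
# belongs to an epoch when it lies entirely inside it; it is "settled" when
# it also starts at least settle_factor exchange time constants after the
# epoch's solution change (the first epoch is settled from t = 0).
.sweep_epochs <- function(bundle, sweeps, settle_factor = 3) {
  bounds <- .epoch_bounds(bundle$meta$timeline)
  sw <- unique(sweeps[c("sweep")])
  agg <- stats::aggregate(cbind(t_start_s = sweeps$t_start_s),
                          by = list(sweep = sweeps$sweep), FUN = min)
  step_s <- bundle$meta$protocol$step_duration_ms / 1000
  agg$t_end_s <- stats::aggregate(sweeps$t_start_s,
                                  by = list(sweep = sweeps$sweep),
                                  FUN = max)$x + step_s
  agg$epoch <- NA_character_
  agg$settled <- FALSE
  for (j in seq_len(nrow(bounds))) {
    inside <- agg$t_start_s >= bounds$start_s[j] & agg$t_end_s <= bounds$end_s[j]
    agg$epoch[inside] <- bounds$label[j]
    ready <- if (j == 1) bounds$start_s[j] else
      bounds$start_s[j] + settle_factor * bounds$exchange_tau_s[j]
    agg$settled[inside] <- agg$t_start_s[inside] >= ready
  }
  agg
}

# ljp per epoch according to `ljp`: "metadata", "auto", or numeric
.epoch_ljps <- function(bundle, ljp = "metadata") {
  bounds <- .epoch_bounds(bundle$meta$timeline)
  if (is.numeric(ljp)) {
    return(stats::setNames(rep_len(ljp, nrow(bounds)), bounds$label))
  }
  if (identical(ljp, "metadata")) {
    v <- bundle$meta$ljp_by_epoch
    if (is.null(v)) stop("bundle metadata carries no junction potentials")
    return(v)
  }
  if (identical(ljp, "auto")) {
    T_K <- bundle$meta$cell$temperature_C + phys_constants()$zero_celsius
    v <- vapply(bundle$meta$timeline$epochs, function(e)
      henderson_ljp(bundle$meta$pipette, e$bath, temperature_K = T_K),
      numeric(1))
    return(stats::setNames(v, bounds$label))
  }
  if (identical(ljp, "none")) {
    return(stats::setNames(rep(0, nrow(bounds)), bounds$label))
  }
  stop("ljp must be 'metadata', 'auto', 'none' or numeric")
}

#' Analyze a trace bundle into per-condition I-V curves and metrics
#'
#' Extracts complete sweeps, averages the steady-state window of each step,
#' assigns sweeps to bath epochs (only sweeps entirely inside a settled
#' epoch contribute to that condition), averages across the epoch's sweeps,
#' corrects voltages for the epoch's junction potential and the pipette
#' voltage drop, and computes reversal voltage, terminal conductances and
#' currents at +/-100 mV per condition.
#'
#' @param bundle A `"trace_bundle"`.
#' @param window_ms,guard_ms Steady-state window, see [steady_state_mean()].
#' @param Rp_MOhm Pipette resistance used for the voltage-drop correction;
#'   defaults to the nominal value in the bundle metadata.
#' @param ljp Junction-potential source: `"metadata"` (offsets recorded at
#'   simulation time), `"auto"` (recompute with [henderson_ljp()] from the
#'   sidecar solutions), `"none"`, or a numeric vector per epoch.
#' @param settle_factor Number of exchange time constants after a solution
#'   change before sweeps count as settled.
#' @return An `"iv_analysis"` list: `conditions` (per settled epoch: curve,
#'   metrics, number of sweeps), `sweep_table`, `step_means`.
#' @export
analyze_bundle <- function(bundle, window_ms = 30, guard_ms = 2,
                           Rp_MOhm = NULL, ljp = "metadata",
                           settle_factor = 3) {
  if (is.null(Rp_MOhm))
    Rp_MOhm <- bundle$meta$cell$series_resistance_MOhm
  sweeps <- extract_sweeps(bundle)
  if (nrow(sweeps) == 0) {
    return(structure(list(conditions = list(),
                          sweep_table = data.frame(),
                          step_means = data.frame()),
                     class = "iv_analysis"))
  }
  sm <- .step_means(bundle, sweeps, window_ms, guard_ms)
  info <- .sweep_epochs(bundle, sweeps, settle_factor)
  ljps <- .epoch_ljps(bundle, ljp)
  conditions <- list()
  for (lab in unique(info$epoch[info$settled & !is.na(info$epoch)])) {
    ids <- info$sweep[info$settled & !is.na(info$epoch) & info$epoch == lab]
    rows <- sm[sm$sweep %in% ids, ]
    agg <- stats::aggregate(cbind(I_pA = rows$I_mean_pA),
                            by = list(V_cmd_mV = rows$step_mV), FUN = mean)
    sdagg <- stats::aggregate(rows$I_mean_pA,
                              by = list(V_cmd_mV = rows$step_mV),
                              FUN = function(x)
                                if (length(x) > 1) stats::sd(x) else NA_real_)
    pts <- correct_voltages(agg, ljps[[lab]], Rp_MOhm)
    curve <- iv_curve(pts$V_mV, pts$I_pA, sdagg$x,
                      n_samples = length(ids) * rows$n_samples[1],
                      condition = lab,
                      time_s = mean(info$t_start_s[info$sweep %in% ids]))
    conditions[[lab]] <- list(curve = curve, metrics = iv_metrics(curve),
                              n_sweeps = length(ids),
                              ljp_mV = unname(ljps[[lab]]))
  }
  structure(list(conditions = conditions, sweep_table = info,
                 step_means = sm, Rp_MOhm = Rp_MOhm),
            class = "iv_analysis")
}

#' @export
print.iv_analysis <- function(x, ...) {
  cat("<iv_analysis>", length(x$conditions), "condition(s)\n")
  for (lab in names(x$conditions)) {
    m <- x$conditions[[lab]]$metrics
    cat(sprintf(
      "  %-12s n=%d  I(-100)=%8.0f pA  g(-)=%5.1f nS  Vr=%6.1f mV  I(+100)=%7.0f pA  g(+)=%5.1f nS\n",
      lab, x$conditions[[lab]]$n_sweeps, m$I_m100_pA, m$g_minus_nS,
      m$Vr_mV, m$I_p100_pA, m$g_plus_nS))
  }
  invisible(x)
}

#' Paired metrics immediately before and after a bath transition
#'
#' Single-sweep I-V metrics from the last complete sweep ending before the
#' transition and the first complete sweep starting after the exchange has
#' settled (`settle_factor` exchange time constants). Used for bi-ionic
#' substitutions where rundown must not contaminate the comparison.
#'
#' @param bundle A `"trace_bundle"`.
#' @param transition_time_s Time of the solution change (s). Must coincide
#'   with an epoch boundary of the bundle's timeline.
#' @param window_ms,guard_ms,Rp_MOhm,ljp,settle_factor See
#'   [analyze_bundle()].
#' @return A list with `before` and `after` (each `metrics` + `curve` +
#'   `sweep_time_s`) and `delta_Vr_mV`.
#' @export
paired_transition_metrics <- function(bundle, transition_time_s,
                                      window_ms = 30, guard_ms = 2,
                                      Rp_MOhm = NULL, ljp = "metadata",
                                      settle_factor = 3) {
  if (is.null(Rp_MOhm))
    Rp_MOhm <- bundle$meta$cell$series_resistance_MOhm
  bounds <- .epoch_bounds(bundle$meta$timeline)
  j <- which(abs(bounds$start_s - transition_time_s) < 1e-9)
  if (length(j) != 1 || j == 1)
    stop("transition_time_s must match an epoch boundary after the first epoch")
  sweeps <- extract_sweeps(bundle)
  if (nrow(sweeps) == 0) stop("no complete sweep in bundle")
  sm <- .step_means(bundle, sweeps, window_ms, guard_ms)
  info <- .sweep_epochs(bundle, sweeps, settle_factor)
  ljps <- .epoch_ljps(bundle, ljp)
  before_ids <- info$sweep[info$t_end_s <= transition_time_s]
  after_ok <- info$t_start_s >=
    transition_time_s + settle_factor * bounds$exchange_tau_s[j] &
    info$t_end_s <= bounds$end_s[j]
  after_ids <- info$sweep[after_ok]
  if (length(before_ids) == 0)
    stop("no complete sweep before the transition")
  if (length(after_ids) == 0)
    stop("no settled complete sweep after the transition")
  pick <- function(id, lab) {
    rows <- sm[sm$sweep == id, ]
    pts <- correct_voltages(data.frame(V_cmd_mV = rows$step_mV,
                                       I_pA = rows$I_mean_pA),
                            ljps[[lab]], Rp_MOhm)
    curve <- iv_curve(pts$V_mV, pts$I_pA, rows$I_sd_pA, rows$n_samples[1],
                      condition = lab,
                      time_s = min(rows$t_start_s))
    list(metrics = iv_metrics(curve), curve = curve,
         sweep_time_s = min(rows$t_start_s))
  }
  before <- pick(max(before_ids), bounds$label[j - 1])
  after <- pick(min(after_ids), bounds$label[j])
  list(before = before, after = after,
       delta_Vr_mV = after$metrics$Vr_mV - before$metrics$Vr_mV)
}
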