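# Closed-loop lumped-parameter circulation: activation law, elemental laws,
# the full right-hand side (R mirror of the compiled core), and the
# beat-by-beat integrator.

#' Ventricular activation waveform
#'
#' Smooth unimodal activation driving the time-varying elastance of both
#' ventricles: a raised-cosine rise over the contraction phase
#' \code{sys_split * T_sys}, a raised-cosine fall over the remaining
#' relaxation phase, and zero for the rest of the beat, with systolic
#' duration \code{T_sys = k_sys * rr^alpha_sys} (capped at 90\% of the
#' beat). The sublinear law (\code{alpha_sys < 1}, square root by default)
#' shortens systole less than the beat itself at fast rates, so the systolic
#' fraction of the cycle grows and diastolic filling time shrinks as heart
#' rate rises; \code{sys_split < 0.5} gives the slower relaxation typical of
#' measured elastance curves.
#'
#' @param t_in_beat time since beat onset (s); vectorised. Must lie in
#'   \code{[0, rr)}.
#' @param rr duration of the current beat (s).
#' @param k_sys systolic-duration coefficient (s^(1-alpha)).
#' @param alpha_sys exponent of the systolic-duration law, in (0, 1].
#' @param sys_split fraction of \code{T_sys} spent contracting, in (0, 1).
#' @return activation in \code{[0, 1]}.
#' @examples
#' ventricular_activation(0, 1.2)        # 0 at onset
#' @export
ventricular_activation <- function(t_in_beat, rr, k_sys = 0.42,
                                   alpha_sys = 0.5, sys_split = 0.5) {
  if (!is.numeric(rr) || length(rr) != 1L || rr <= 0)
    stop("`rr` must be a single positive duration (s)")
  if (any(t_in_beat < 0 | t_in_beat >= rr))
    stop("`t_in_beat` must lie in [0, rr)")
  if (sys_split <= 0 || sys_split >= 1) stop("`sys_split` must be in (0, 1)")
  if (alpha_sys <= 0 || alpha_sys > 1) stop("`alpha_sys` must be in (0, 1]")
  t_sys <- min(k_sys * rr^alpha_sys, 0.9 * rr)
  .activation(t_in_beat, t_sys, sys_split)
}

.t_sys <- function(params, rr) min(params$k_sys * rr^params$alpha_sys, 0.9 * rr)

.activation <- function(t, t_sys, split) {
  tc <- split * t_sys
  ifelse(t < tc,
         0.5 * (1 - cos(pi * t / tc)),
         ifelse(t < t_sys,
                0.5 * (1 + cos(pi * (t - tc) / (t_sys - tc))),
                0))
}

#' Chamber pressure from the linear state equation
#'
#' \code{P = [E_min + activation (E_max - E_min)] (V - V_un)}. Atrial
#' chambers are passive (activation forced to zero at all times), mimicking
#' the loss of the atrial kick during atrial fibrillation.
#'
#' @param V chamber volume (mL), vectorised.
#' @param activation activation level in \code{[0, 1]}, vectorised.
#' @param chamber list with \code{E_max}, \code{E_min} (mmHg/mL),
#'   \code{V_un} (mL) and logical \code{passive}.
#' @return pressure (mmHg); negative transmural pressures are allowed.
#' @examples
#' lv <- list(E_max = 2.5, E_min = 0.1, V_un = 5, passive = FALSE)
#' chamber_pressure(55, 1, lv)   # 125 mmHg
#' @export
chamber_pressure <- function(V, activation, chamber) {
  stopifnot(is.list(chamber),
            all(c("E_max", "E_min", "V_un", "passive") %in% names(chamber)))
  if (any(V < 0)) stop("`V` must be >= 0")
  act <- if (isTRUE(chamber$passive)) 0 else activation
  (chamber$E_min + act * (chamber$E_max - chamber$E_min)) * (V - chamber$V_un)
}

#' Flow through an ideal pressure-gated valve
#'
#' Resistive diode: forward Ohmic flow when the upstream pressure exceeds the
#' downstream pressure, zero otherwise. No regurgitation is possible.
#'
#' @param P_up,P_down pressures (mmHg), vectorised.
#' @param R_open open-state resistance (mmHg s/mL).
#' @return flow (mL/s), always >= 0.
#' @examples
#' valve_flow(81, 80, 0.01)  # 100 mL/s
#' valve_flow(10, 80, 0.01)  # closed valve, 0
#' @export
valve_flow <- function(P_up, P_down, R_open) {
  if (!is.numeric(R_open) || length(R_open) != 1L || R_open <= 0)
    stop("`R_open` must be a single positive resistance")
  if (any(!is.finite(P_up)) || any(!is.finite(P_down)))
    stop("pressures must be finite")
  pmax(P_up - P_down, 0) / R_open
}

#' Time derivatives of the circulation state
#'
#' R reference implementation of the model equations (the integrator uses a
#' compiled equivalent): mass conservation for every chamber and vascular
#' compartment, equations of motion on the two inertial arterial branches,
#' and linear state equations mapping volumes to pressures. By construction
#' the compartment volume derivatives sum to zero, so total blood volume is
#' conserved exactly.
#'
#' @param t time (s) on the global clock.
#' @param state named state vector (see [initial_state()]).
#' @param params a \code{cv_params} parameter set.
#' @param current_rr duration of the current beat (s).
#' @param t_beat_start onset time of the current beat on the clock of
#'   \code{t} (s).
#' @return list with \code{derivatives} (named, same layout as the state) and
#'   \code{aux} (pressures, flows, activation, valve states).
#' @export
cv_derivatives <- function(t, state, params, current_rr, t_beat_start = 0) {
  params <- validate_parameters(params)
  if (any(!is.finite(state))) {
    nm <- names(state)
    if (is.null(nm)) nm <- .state_names
    stop("non-finite state component(s): ",
         paste(nm[!is.finite(state)], collapse = ", "))
  }
  s <- stats::setNames(as.numeric(state), .state_names)
  tb <- t - t_beat_start
  if (tb < 0)
    stop("`t` must not precede the current beat onset")
  # adaptive solvers may evaluate slightly beyond the beat boundary; the
  # activation is zero past T_sys, so no upper clamp is needed
  act <- .activation(tb, .t_sys(params, current_rr), params$sys_split)

  P <- c(
    P_la  = params$E_la * (s[["V_la"]] - params$V0_la),
    P_lv  = (params$Emin_lv + act * (params$Emax_lv - params$Emin_lv)) *
            (s[["V_lv"]] - params$V0_lv),
    P_ra  = params$E_ra * (s[["V_ra"]] - params$V0_ra),
    P_rv  = (params$Emin_rv + act * (params$Emax_rv - params$Emin_rv)) *
            (s[["V_rv"]] - params$V0_rv),
    P_sas = (s[["V_sas"]] - params$V0_sas) / params$C_sas,
    P_svn = (s[["V_svn"]] - params$V0_svn) / params$C_svn,
    P_pas = (s[["V_pas"]] - params$V0_pas) / params$C_pas,
    P_pvn = (s[["V_pvn"]] - params$V0_pvn) / params$C_pvn)

  Q <- c(
    Q_mi  = max(s[["Q_mi"]], 0),
    Q_ao  = valve_flow(P[["P_lv"]], P[["P_sas"]], params$R_ao),
    Q_ti  = valve_flow(P[["P_ra"]], P[["P_rv"]], params$R_ti),
    Q_po  = valve_flow(P[["P_rv"]], P[["P_pas"]], params$R_po),
    Q_svn = (P[["P_svn"]] - P[["P_ra"]]) / params$R_svn,
    Q_pvn = (P[["P_pvn"]] - P[["P_la"]]) / params$R_pvn,
    Q_sys = s[["Q_sys"]],
    Q_pul = s[["Q_pul"]])

  d <- c(
    V_la  = Q[["Q_pvn"]] - Q[["Q_mi"]],
    V_lv  = Q[["Q_mi"]]  - Q[["Q_ao"]],
    V_ra  = Q[["Q_svn"]] - Q[["Q_ti"]],
    V_rv  = Q[["Q_ti"]]  - Q[["Q_po"]],
    V_sas = Q[["Q_ao"]]  - Q[["Q_sys"]],
    V_svn = Q[["Q_sys"]] - Q[["Q_svn"]],
    V_pas = Q[["Q_po"]]  - Q[["Q_pul"]],
    V_pvn = Q[["Q_pul"]] - Q[["Q_pvn"]],
    Q_sys = (P[["P_sas"]] - P[["P_svn"]] - params$R_sys * s[["Q_sys"]]) / params$L_sys,
    Q_pul = (P[["P_pas"]] - P[["P_pvn"]] - params$R_pul * s[["Q_pul"]]) / params$L_pul,
    Q_mi = (P[["P_la"]] - P[["P_lv"]] - params$R_mi * s[["Q_mi"]]) / params$L_mi -
      if (s[["Q_mi"]] < 0) 1e5 * s[["Q_mi"]] else 0)

  list(derivatives = d,
       aux = list(pressures = P, flows = Q, activation = act,
                  valves_open = c(mitral = Q[["Q_mi"]] > 0,
                                  aortic = Q[["Q_ao"]] > 0,
                                  tricuspid = Q[["Q_ti"]] > 0,
                                  pulmonary = Q[["Q_po"]] > 0)))
}

# dense per-beat frame with algebraic pressures/flows/valve states,
# vectorised over the solver output of one beat
.beat_frame <- function(out, params, rr, t_offset, beat) {
  tb <- out[, 1L]
  y <- out[, -1L, drop = FALSE]
  t_sys <- .t_sys(params, rr)
  act <- .activation(tb, t_sys, params$sys_split)

  P_la  <- params$E_la * (y[, 1] - params$V0_la)
  P_lv  <- (params$Emin_lv + act * (params$Emax_lv - params$Emin_lv)) * (y[, 2] - params$V0_lv)
  P_ra  <- params$E_ra * (y[, 3] - params$V0_ra)
  P_rv  <- (params$Emin_rv + act * (params$Emax_rv - params$Emin_rv)) * (y[, 4] - params$V0_rv)
  P_sas <- (y[, 5] - params$V0_sas) / params$C_sas
  P_svn <- (y[, 6] - params$V0_svn) / params$C_svn
  P_pas <- (y[, 7] - params$V0_pas) / params$C_pas
  P_pvn <- (y[, 8] - params$V0_pvn) / params$C_pvn

  Q_mi <- pmax(y[, 11], 0)
  Q_ao <- pmax(P_lv - P_sas, 0) / params$R_ao
  Q_ti <- pmax(P_ra - P_rv, 0) / params$R_ti
  Q_po <- pmax(P_rv - P_pas, 0) / params$R_po

  data.frame(
    t = t_offset + tb, t_beat = tb, beat = beat, activation = act,
    P_la = P_la, P_lv = P_lv, P_ra = P_ra, P_rv = P_rv,
    P_sas = P_sas, P_svn = P_svn, P_pas = P_pas, P_pvn = P_pvn,
    V_la = y[, 1], V_lv = y[, 2], V_ra = y[, 3], V_rv = y[, 4],
    V_sas = y[, 5], V_svn = y[, 6], V_pas = y[, 7], V_pvn = y[, 8],
    Q_mi = Q_mi, Q_ao = Q_ao, Q_ti = Q_ti, Q_po = Q_po,
    Q_sys = y[, 9], Q_pul = y[, 10],
    mitral_open = y[, 11] > 0, aortic_open = Q_ao > 0,
    tricuspid_open = Q_ti > 0, pulmonary_open = Q_po > 0)
}

#' Integrate the closed loop over an RR sequence
#'
#' Beat-by-beat integration with a stiff adaptive multistep solver
#' (\code{deSolve::lsoda}): the activation clock is reset at every beat
#' onset, each beat is sampled on a dense uniform grid, and the final state
#' of a beat seeds the next. The first \code{warmup} beats flush the initial
#' condition and are excluded from analysis. Per-beat summaries (see
#' [summarize_beats()]) are computed on the fly, so long runs do not need to
#' retain the dense trace.
#'
#' @param rr an \code{rr_sequence} from [sample_rr()] or a numeric vector of
#'   beat durations (s); includes the warm-up beats.
#' @param params a \code{cv_params} parameter set.
#' @param init named initial state; default [initial_state()].
#' @param warmup number of initial beats excluded from analysis.
#' @param samples_per_beat dense-output samples per beat (>= 200 recommended
#'   for event location and loop areas).
#' @param rtol,atol solver relative/absolute tolerances.
#' @param keep_trace \code{TRUE} to retain the dense trace for every beat,
#'   \code{FALSE} for none, or an integer vector of beat indices to retain.
#' @param conservation_tol maximum admissible relative drift of total blood
#'   volume; larger drift is an error (the loop is closed).
#' @return an object of class \code{cv_sim}: list with \code{trace} (dense
#'   data frame or \code{NULL}), \code{summaries} (one row per analyzed
#'   beat), \code{beats} (onset table), \code{params}, \code{solver},
#'   \code{conservation}.
#' @examples
#' \donttest{
#' rr <- sample_rr(60, hr = 70, cv = 0, seed = 1)
#' sim <- simulate_beats(rr, warmup = 20, keep_trace = FALSE)
#' colMeans(sim$summaries[c("SV", "EF", "P_sas_syst")])
#' }
#' @export
simulate_beats <- function(rr, params = default_parameters(), init = NULL,
                           warmup = 20, samples_per_beat = 200,
                           rtol = 1e-6, atol = 1e-8, keep_trace = TRUE,
                           conservation_tol = 1e-6) {
  intervals <- if (inherits(rr, "rr_sequence")) rr$intervals else as.numeric(rr)
  n <- length(intervals)
  if (n < 1L) stop("`rr` must contain at least one beat")
  if (any(!is.finite(intervals)) || any(intervals <= 0))
    stop("all RR intervals must be positive and finite")
  if (warmup < 0 || warmup >= n)
    stop("`warmup` must be in [0, n_beats)")
  params <- validate_parameters(params)
  if (is.null(init)) init <- initial_state(params)
  if (length(init) != 11L) stop("`init` must have 11 components")
  state <- stats::setNames(as.numeric(init), .state_names)

  keep <- if (isTRUE(keep_trace)) seq_len(n)
          else if (isFALSE(keep_trace)) integer(0)
          else as.integer(keep_trace)

  spb <- as.integer(samples_per_beat)
  if (spb < 20L) stop("`samples_per_beat` must be >= 20")

  v_idx <- 1:8
  vol0 <- sum(state[v_idx])
  max_drift <- 0
  t_offset <- 0
  trace_parts <- vector("list", length(keep))
  summary_rows <- vector("list", n - warmup)
  onsets <- numeric(n)

  for (b in seq_len(n)) {
    rr_b <- intervals[b]
    onsets[b] <- t_offset
    t_sys <- .t_sys(params, rr_b)
    times <- seq(0, rr_b, length.out = spb + 1L)
    out <- deSolve::lsoda(
      y = state, times = times, func = "cv_rhs", parms = .parms_vector(params, rr_b, t_sys),
      dllname = "afsim", initfunc = "cv_init",
      rtol = rtol, atol = atol, maxsteps = 50000)
    istate <- attr(out, "istate")
    if (!is.null(istate) && istate[1L] < 0)
      stop("solver failure (istate = ", istate[1L], ") in beat ", b)
    if (nrow(out) != spb + 1L)
      stop("solver returned an incomplete beat at index ", b)
    y_end <- out[nrow(out), -1L]
    if (any(!is.finite(y_end)))
      stop("non-finite state after beat ", b, ": ",
           paste(.state_names[!is.finite(y_end)], collapse = ", "))

    drift <- max(abs(rowSums(out[, 1L + v_idx, drop = FALSE]) - vol0)) / vol0
    if (drift > max_drift) max_drift <- drift
    if (max_drift > conservation_tol)
      stop("blood-volume drift ", signif(max_drift, 3),
           " exceeds `conservation_tol` at beat ", b)

    analyzed <- b > warmup
    if (analyzed || b %in% keep) {
      bf <- .beat_frame(out, params, rr_b, t_offset, b)
      # stored trace samples [0, rr) so that time is strictly increasing
      # across beats; the in-loop summary uses the full grid incl. endpoint
      if (b %in% keep) trace_parts[[match(b, keep)]] <- bf[-nrow(bf), ]
      if (analyzed)
        summary_rows[[b - warmup]] <- .summarize_beat(bf, rr_b, params$V0_lv)
    }

    state <- stats::setNames(as.numeric(y_end), .state_names)
    t_offset <- t_offset + rr_b
  }

  summaries <- as.data.frame(do.call(rbind, summary_rows))
  summaries$ejecting <- summaries$ejecting > 0
  trace <- if (length(trace_parts)) do.call(rbind, trace_parts) else NULL

  structure(list(
    trace = trace,
    summaries = summaries,
    beats = data.frame(beat = seq_len(n), t_onset = onsets, rr = intervals,
                       analyzed = seq_len(n) > warmup),
    params = params,
    solver = list(rtol = rtol, atol = atol, samples_per_beat = spb,
                  warmup = warmup),
    conservation = list(max_rel_drift = max_drift, tol = conservation_tol)),
    class = "cv_sim")
}

#' @export
print.cv_sim <- function(x, ...) {
  n <- nrow(x$beats)
  cat(sprintf("Closed-loop simulation: %d beats (%d analyzed), %.1f s\n",
              n, sum(x$beats$analyzed), sum(x$beats$rr)))
  cat(sprintf("  max relative volume drift %.2e\n", x$conservation$max_rel_drift))
  if (!is.null(x$summaries) && nrow(x$summaries)) {
    cat(sprintf("  mean SV %.1f mL, EF %.1f%%, P_sas %.1f/%.1f mmHg\n",
                mean(x$summaries$SV, na.rm = TRUE),
                mean(x$summaries$EF, na.rm = TRUE),
                mean(x$summaries$P_sas_syst), mean(x$summaries$P_sas_dias)))
  }
  invisible(x)
}

#' Write a dense trace to CSV
#'
#' One row per sample: time, pressures, volumes, flows and valve flags
#' (flags written as 0/1).
#'
#' @param x a \code{cv_sim} with a retained trace, or a trace data frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  df <- if (inherits(x, "cv_sim")) x$trace else x
  if (is.null(df)) stop("no trace retained in this simulation")
  flags <- c("mitral_open", "aortic_open", "tricuspid_open", "pulmonary_open")
  for (f in intersect(flags, names(df))) df[[f]] <- as.integer(df[[f]])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trace CSV written by [write_trace_csv()]
#'
#' @param path CSV file.
#' @return a trace data frame with logical valve flags.
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path)
  flags <- c("mitral_open", "aortic_open", "tricuspid_open", "pulmonary_open")
  for (f in intersect(flags, names(df))) df[[f]] <- df[[f]] > 0
  df
}
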