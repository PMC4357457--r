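# Per-beat segmentation, end-systole/end-diastole location and
# hemodynamic / mechano-energetic indices.

# linear interpolation of trace columns at a query time
.sample_at <- function(bf, tq, cols, tcol = "t_beat") {
  vapply(cols, function(cl)
    stats::approx(bf[[tcol]], bf[[cl]], xout = tq, rule = 2)$y, numeric(1))
}

# refine an event time between bracketing samples by the zero crossing of a
# pressure difference; falls back to the first post-transition sample time
.refine_crossing <- function(tt, d, k) {
  if (is.finite(d[k]) && is.finite(d[k + 1L]) && d[k] != d[k + 1L] &&
      d[k] >= 0 && d[k + 1L] <= 0)
    tt[k] + (tt[k + 1L] - tt[k]) * d[k] / (d[k] - d[k + 1L])
  else
    tt[k + 1L]
}

#' Locate end-systole and end-diastole within one beat
#'
#' End-systole is the instant of aortic-valve closure; end-diastole the
#' instant of mitral-valve closure that begins the beat's systole. Valve
#' transitions are taken from the trace's open/closed flags and refined by
#' linear interpolation of the driving pressure difference between the
#' bracketing samples. A beat whose aortic valve never opens is flagged
#' non-ejecting (\code{t_es = NA}).
#'
#' @param beat one-beat trace slice (data frame) with valve flags; event
#'   refinement uses \code{P_la}, \code{P_lv} and \code{P_sas} when present.
#' @return list with \code{t_es}, \code{t_ed} (s, on the beat clock) and
#'   logical \code{ejecting}.
#' @export
locate_es_ed <- function(beat) {
  req <- c("mitral_open", "aortic_open")
  if (!all(req %in% names(beat)))
    stop("beat slice lacks valve state flags (mitral_open / aortic_open)")
  tt <- if ("t_beat" %in% names(beat)) beat$t_beat else beat$t
  if (is.null(tt)) stop("beat slice lacks a time column")
  n <- length(tt)
  has_p <- all(c("P_la", "P_lv", "P_sas") %in% names(beat))

  # mitral closure: first open -> closed transition (or already closed at
  # onset); refined by extrapolating the decelerating mitral flow to zero
  mo <- beat$mitral_open
  if (!mo[1L]) {
    t_ed <- tt[1L]
  } else {
    k <- which(mo[-n] & !mo[-1L])[1L]
    if (is.na(k)) {
      t_ed <- NA_real_
    } else if ("Q_mi" %in% names(beat) && k >= 2L &&
               beat$Q_mi[k - 1L] > beat$Q_mi[k] && beat$Q_mi[k] > 0) {
      q1 <- beat$Q_mi[k - 1L]; q2 <- beat$Q_mi[k]
      t_ed <- min(tt[k] + q2 * (tt[k] - tt[k - 1L]) / (q1 - q2), tt[k + 1L])
    } else if (has_p) {
      t_ed <- .refine_crossing(tt, beat$P_la - beat$P_lv, k)
    } else {
      t_ed <- tt[k + 1L]
    }
  }

  # aortic closure: first open -> closed transition after the valve opens
  ao <- beat$aortic_open
  if (!any(ao)) {
    return(list(t_es = NA_real_, t_ed = t_ed, ejecting = FALSE))
  }
  first_open <- which(ao)[1L]
  k <- which(ao[-n] & !ao[-1L])
  k <- k[k >= first_open][1L]
  if (is.na(k)) {
    t_es <- tt[n]   # still ejecting at beat end
  } else if (has_p) {
    t_es <- .refine_crossing(tt, beat$P_lv - beat$P_sas, k)
  } else {
    t_es <- tt[k + 1L]
  }
  list(t_es = t_es, t_ed = t_ed, ejecting = TRUE)
}

#' Pressure-volume loop area (stroke work)
#'
#' Absolute shoelace area of the closed loop traced by one beat in the
#' (volume, pressure) plane; the first point is appended as the last to close
#' the loop. The raw area in mmHg mL is converted to joules
#' (1 mmHg mL = 1.33322e-4 J).
#'
#' @param P_series pressures (mmHg).
#' @param V_series volumes (mL), same length, at least 3 points.
#' @param units \code{"J"} (default) or \code{"mmHg_mL"}.
#' @return loop area, orientation-independent.
#' @examples
#' # rectangular loop 90 mmHg x 80 mL = 7200 mmHg mL = 0.960 J
#' pv_loop_area(c(10, 100, 100, 10), c(130, 130, 50, 50))
#' @export
pv_loop_area <- function(P_series, V_series, units = c("J", "mmHg_mL")) {
  units <- match.arg(units)
  if (length(P_series) != length(V_series))
    stop("`P_series` and `V_series` must have the same length")
  if (length(P_series) < 3L)
    stop("a loop needs at least 3 points")
  x <- c(V_series, V_series[1L])
  y <- c(P_series, P_series[1L])
  n <- length(x)
  area <- 0.5 * abs(sum(x[-n] * y[-1L] - x[-1L] * y[-n]))
  if (units == "J") area * MMHG_ML_TO_J else area
}

#' Per-beat mechano-energetic indices
#'
#' Derives the left-ventricular performance and oxygen-consumption surrogate
#' indices from end-systolic/end-diastolic values and the loop area:
#' \itemize{
#'   \item \code{SV = V_lved - V_lves} (mL), \code{EF = SV / V_lved * 100} (\%)
#'   \item \code{CO = SV * 60/rr} (L/min), using the beat's instantaneous rate
#'   \item \code{RPP = P_sas_syst * 60/rr} (mmHg/min)
#'   \item \code{TTI = P_lv_mean * rr} (mmHg s); \code{TTI_min = TTI * 60/rr}
#'   \item \code{PE = P_lves (V_lves - V_un)/2 - P_lved (V_lved - V_un)/4}
#'     (converted to J), the end-systolic elastic potential energy
#'   \item \code{PVA = PE + SW} (J); \code{PVA_min = PVA * 60/rr} (J/min)
#'   \item \code{efficiency = SW / PVA * 100} (\%)
#' }
#' All per-minute indices use the beat's instantaneous heart rate
#' \code{60/rr}; sweep-level values are means of these per-beat quantities.
#'
#' @param V_lved,V_lves end-diastolic/end-systolic LV volume (mL).
#' @param P_lved,P_lves end-diastolic/end-systolic LV pressure (mmHg).
#' @param SW stroke work (J), from [pv_loop_area()].
#' @param P_lv_mean beat-mean LV pressure (mmHg) over the whole cycle.
#' @param P_sas_syst systolic systemic arterial pressure of the beat (mmHg).
#' @param rr beat duration (s).
#' @param V_lv_un unstressed LV volume for the potential-energy term (mL).
#' @return named list with SV, EF, SW, PE, PVA, CO, RPP, TTI, TTI_min,
#'   PVA_min, efficiency.
#' @examples
#' beat_energetics(V_lved = 126.4, V_lves = 48.94, P_lved = 15.46,
#'                 P_lves = 91.75, SW = 0.88, P_lv_mean = 33.92,
#'                 P_sas_syst = 103.8, rr = 1.2)
#' @export
beat_energetics <- function(V_lved, V_lves, P_lved, P_lves, SW, P_lv_mean,
                            P_sas_syst, rr, V_lv_un = 5) {
  if (any(V_lved <= 0)) stop("`V_lved` must be positive")
  if (any(rr <= 0)) stop("`rr` must be positive")
  hr_inst <- 60 / rr
  SV <- V_lved - V_lves
  EF <- SV / V_lved * 100
  PE <- (P_lves * (V_lves - V_lv_un) / 2 -
         P_lved * (V_lved - V_lv_un) / 4) * MMHG_ML_TO_J
  PVA <- PE + SW
  efficiency <- ifelse(PVA > 0, SW / PVA * 100, NA_real_)
  list(SV = SV, EF = EF, SW = SW, PE = PE, PVA = PVA,
       CO = SV * hr_inst / 1000, RPP = P_sas_syst * hr_inst,
       TTI = P_lv_mean * rr, TTI_min = P_lv_mean * 60,
       PVA_min = PVA * hr_inst, efficiency = efficiency)
}

# time average over a uniform grid including both endpoints (trapezoid)
.trap_mean <- function(x) {
  n <- length(x)
  (sum(x) - (x[1L] + x[n]) / 2) / (n - 1L)
}

# one-beat summary as a named numeric vector (fast path for long runs)
.summarize_beat <- function(bf, rr, v_un = 5) {
  ev <- locate_es_ed(bf)
  hr_inst <- 60 / rr

  means <- vapply(c("P_la", "P_lv", "P_sas", "P_pas", "P_pvn", "V_la", "V_lv"),
                  function(cl) .trap_mean(bf[[cl]]), numeric(1))

  ed <- if (is.finite(ev$t_ed))
    unname(.sample_at(bf, ev$t_ed, c("P_la", "V_la", "P_lv", "V_lv")))
  else rep(NA_real_, 4)
  es <- if (isTRUE(ev$ejecting) && is.finite(ev$t_es))
    unname(.sample_at(bf, ev$t_es, c("P_la", "V_la", "P_lv", "V_lv")))
  else rep(NA_real_, 4)

  P_sas_syst <- max(bf$P_sas)
  out <- c(
    beat = bf$beat[1L], t_onset = bf$t[1L], rr = rr, hr_inst = hr_inst,
    ejecting = as.numeric(ev$ejecting),
    t_es = if (is.finite(ev$t_es)) ev$t_es else NA_real_,
    t_ed = if (is.finite(ev$t_ed)) ev$t_ed else NA_real_,
    P_laes = es[1L], V_laes = es[2L], P_lves = es[3L], V_lves = es[4L],
    P_laed = ed[1L], V_laed = ed[2L], P_lved = ed[3L], V_lved = ed[4L],
    P_lv_max = max(bf$P_lv), P_lv_min = min(bf$P_lv),
    P_sas_syst = P_sas_syst, P_sas_dias = min(bf$P_sas),
    P_pas_syst = max(bf$P_pas), P_pas_dias = min(bf$P_pas),
    P_la = means[["P_la"]], P_lv = means[["P_lv"]], P_sas = means[["P_sas"]],
    P_pas = means[["P_pas"]], P_pvn = means[["P_pvn"]],
    V_la = means[["V_la"]], V_lv = means[["V_lv"]],
    SV = NA_real_, EF = NA_real_, SW = NA_real_, PE = NA_real_,
    PVA = NA_real_, CO = NA_real_, RPP = P_sas_syst * hr_inst,
    TTI = means[["P_lv"]] * rr, TTI_min = means[["P_lv"]] * 60,
    PVA_min = NA_real_, SW_PVA = NA_real_)

  if (isTRUE(ev$ejecting) && is.finite(ed[4L]) && ed[4L] > 0) {
    sw <- pv_loop_area(bf$P_lv, bf$V_lv)
    en <- beat_energetics(V_lved = ed[4L], V_lves = es[4L],
                          P_lved = ed[3L], P_lves = es[3L], SW = sw,
                          P_lv_mean = means[["P_lv"]],
                          P_sas_syst = P_sas_syst, rr = rr, V_lv_un = v_un)
    out[c("SV", "EF", "SW", "PE", "PVA", "CO", "PVA_min", "SW_PVA")] <-
      c(en$SV, en$EF, en$SW, en$PE, en$PVA, en$CO, en$PVA_min, en$efficiency)
  }
  out
}

#' Split a trace into per-beat slices
#'
#' One slice per RR interval, with boundaries exactly at the activation-clock
#' resets recorded by the simulator (the \code{beat} column). For a
#' \code{cv_sim}, warm-up beats are excluded.
#'
#' @param x a \code{cv_sim} with a retained trace, or a trace data frame with
#'   a \code{beat} column.
#' @return named list of one-beat data frames.
#' @export
segment_beats <- function(x) {
  if (inherits(x, "cv_sim")) {
    if (is.null(x$trace)) stop("no trace retained in this simulation")
    df <- x$trace
    analyzed <- x$beats$beat[x$beats$analyzed]
    df <- df[df$beat %in% analyzed, , drop = FALSE]
  } else {
    df <- x
  }
  if (is.null(df$beat)) stop("trace lacks beat-onset markers (`beat` column)")
  split(df, df$beat)
}

#' Per-beat summaries from a trace or simulation
#'
#' For a \code{cv_sim} the summaries computed during integration are
#' returned; otherwise the trace is segmented with [segment_beats()] and each
#' slice is summarized (events, extrema, beat means, loop area, energetics).
#'
#' @param x a \code{cv_sim} or a trace data frame with a \code{beat} column.
#' @param v_un unstressed LV volume (mL) for the potential-energy term.
#' @return data frame, one row per beat.
#' @export
summarize_beats <- function(x, v_un = 5) {
  if (inherits(x, "cv_sim") && !is.null(x$summaries)) return(x$summaries)
  slices <- segment_beats(x)
  rows <- lapply(slices, function(bf) {
    tt <- if ("t_beat" %in% names(bf)) bf$t_beat else bf$t - bf$t[1L]
    # slices sample [0, rr): the grid step past the last sample closes the beat
    rr <- if ("rr" %in% names(bf)) bf$rr[1L] else max(tt) + (tt[2L] - tt[1L])
    bf2 <- bf
    if (!"t_beat" %in% names(bf2)) bf2$t_beat <- tt
    .summarize_beat(bf2, rr, v_un)
  })
  out <- as.data.frame(do.call(rbind, rows))
  out$ejecting <- out$ejecting > 0
  rownames(out) <- NULL
  out
}

#' Aggregate per-beat summaries to means and SDs
#'
#' Arithmetic mean and sample standard deviation of every index over the
#' analyzed beats. Indices that require an ejection (SV, EF, SW, PE, PVA,
#' CO, PVA/min, SW/PVA and end-systolic values) are \code{NA} on
#' non-ejecting beats and are excluded from their statistics only; the count
#' of non-ejecting beats is reported as an attribute.
#'
#' @param summaries data frame from [summarize_beats()] (or a compatible
#'   synthetic stream).
#' @return data frame with columns \code{index}, \code{mean}, \code{sd},
#'   \code{n}; attributes \code{n_beats} and \code{n_nonejecting}.
#' @export
aggregate_summaries <- function(summaries) {
  if (is.null(summaries) || nrow(summaries) == 0L)
    stop("no beat summaries to aggregate")
  if (nrow(summaries) < 2L)
    stop("at least 2 analyzed beats are required")
  skip <- c("beat", "t_onset", "t_es", "t_ed", "ejecting")
  idx <- setdiff(names(summaries)[vapply(summaries, is.numeric, logical(1))], skip)
  agg <- data.frame(
    index = idx,
    mean = vapply(idx, function(cl) mean(summaries[[cl]], na.rm = TRUE), numeric(1)),
    sd = vapply(idx, function(cl) sd(summaries[[cl]], na.rm = TRUE), numeric(1)),
    n = vapply(idx, function(cl) sum(is.finite(summaries[[cl]])), numeric(1)),
    row.names = NULL)
  attr(agg, "n_beats") <- nrow(summaries)
  attr(agg, "n_nonejecting") <-
    if ("ejecting" %in% names(summaries)) sum(!summaries$ejecting) else 0L
  agg
}

#' Write per-beat summaries to CSV
#'
#' @param summaries data frame from [summarize_beats()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_summary_csv <- function(summaries, path) {
  write.csv(summaries, path, row.names = FALSE)
  invisible(path)
}
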