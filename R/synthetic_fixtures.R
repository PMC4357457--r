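# Analytic test-beat generators: traces with known loop areas and planted
# valve events, plus Gaussian summary streams with planted moments. These
# pin the arithmetic of the index pipeline without the ODE model; they make
# no attempt at physiological realism.

#' Analytic one-beat trace with closed-form index values
#'
#' Builds a single-beat trace in the simulator's schema whose
#' left-ventricular pressure-volume loop has an exactly known area
#' (rectangle, ellipse, or arbitrary tabulated polygon), with mitral and
#' aortic valve events planted at prescribed instants. The planted pressure
#' columns cross exactly at the event times, so event location can be checked
#' against ground truth.
#'
#' @param shape \code{"rectangle"}, \code{"ellipse"} or \code{"polygon"}.
#' @param p_range pressure range (mmHg) of the loop (for the ellipse, the
#'   full axis, i.e. twice the semi-axis).
#' @param v_range volume range (mL), likewise.
#' @param vertices for \code{shape = "polygon"}: data frame with columns
#'   \code{P} and \code{V} listing the vertices in traversal order.
#' @param rr beat duration (s).
#' @param samples samples on \code{[0, rr)}.
#' @param t_ed planted mitral-closure time (s), in \code{(0, rr)}.
#' @param t_es planted aortic-closure time (s), in \code{(0, rr)}.
#' @param t_open planted aortic-opening time (s), before \code{t_es}.
#' @return list with \code{trace} (data frame), \code{expected} (exact
#'   \code{SW_mmHg_mL}, \code{SW_J}, \code{SV}, \code{EF}) and
#'   \code{events}.
#' @examples
#' fx <- make_analytic_beat("rectangle", p_range = c(10, 100),
#'                          v_range = c(50, 130))
#' fx$expected$SW_J   # 0.960 J
#' @export
make_analytic_beat <- function(shape = c("rectangle", "ellipse", "polygon"),
                               p_range = c(10, 100), v_range = c(50, 130),
                               vertices = NULL, rr = 1.0, samples = 500,
                               t_ed = 0.1 * rr, t_es = 0.5 * rr,
                               t_open = t_es / 2) {
  shape <- match.arg(shape)
  if (rr <= 0) stop("`rr` must be positive")
  if (samples < 8) stop("`samples` must be >= 8")
  if (!(t_ed > 0 && t_ed < rr) || !(t_es > 0 && t_es < rr) ||
      !(t_open >= 0 && t_open < t_es))
    stop("planted events must lie inside [0, rr) with t_open < t_es")

  t <- seq(0, rr, length.out = samples + 1L)[seq_len(samples)]
  s <- t / rr  # loop traversal parameter in [0, 1)

  if (shape == "polygon") {
    if (is.null(vertices) || !all(c("P", "V") %in% names(vertices)) ||
        nrow(vertices) < 3L)
      stop("`vertices` must be a data frame with columns P, V and >= 3 rows")
    vp <- vertices$P; vv <- vertices$V
    sw_exact <- pv_loop_area(vp, vv, units = "mmHg_mL")
    # traverse the polygon edges at constant parameter speed
    kk <- nrow(vertices)
    edge <- pmin(floor(s * kk) + 1L, kk)
    frac <- s * kk - (edge - 1L)
    nxt <- ifelse(edge == kk, 1L, edge + 1L)
    P_lv <- vp[edge] + frac * (vp[nxt] - vp[edge])
    V_lv <- vv[edge] + frac * (vv[nxt] - vv[edge])
    v_min <- min(vv); v_max <- max(vv)
  } else {
    if (diff(p_range) <= 0 || diff(v_range) <= 0)
      stop("degenerate `p_range` or `v_range`")
    if (shape == "rectangle") {
      pts <- data.frame(P = c(p_range[1], p_range[2], p_range[2], p_range[1]),
                        V = c(v_range[2], v_range[2], v_range[1], v_range[1]))
      kk <- 4L
      edge <- pmin(floor(s * kk) + 1L, kk)
      frac <- s * kk - (edge - 1L)
      nxt <- ifelse(edge == kk, 1L, edge + 1L)
      P_lv <- pts$P[edge] + frac * (pts$P[nxt] - pts$P[edge])
      V_lv <- pts$V[edge] + frac * (pts$V[nxt] - pts$V[edge])
      sw_exact <- diff(p_range) * diff(v_range)
    } else {
      a <- diff(v_range) / 2; b <- diff(p_range) / 2
      P_lv <- mean(p_range) + b * sin(2 * pi * s)
      V_lv <- mean(v_range) + a * cos(2 * pi * s)
      sw_exact <- pi * a * b
    }
    v_min <- v_range[1]; v_max <- v_range[2]
  }

  # planted valve events: pressure differences cross zero exactly at the
  # planted instants, and the flags are consistent with the differences
  d_mi <- t_ed - t                      # > 0 while mitral open
  d_ao <- (t - t_open) * (t_es - t)     # > 0 while aortic open
  P_la <- P_lv + d_mi
  P_sas <- P_lv - d_ao

  trace <- data.frame(
    t = t, t_beat = t, beat = 1L, rr = rr, activation = 0,
    P_la = P_la, P_lv = P_lv, P_ra = 5, P_rv = 10,
    P_sas = P_sas, P_svn = 5, P_pas = 15, P_pvn = 10,
    V_la = 60, V_lv = V_lv, V_ra = 60, V_rv = 100,
    V_sas = 750, V_svn = 3500, V_pas = 200, V_pvn = 300,
    Q_mi = pmax(d_mi, 0), Q_ao = pmax(d_ao, 0), Q_ti = 0, Q_po = 0,
    Q_sys = 0, Q_pul = 0,
    mitral_open = d_mi > 0, aortic_open = d_ao > 0,
    tricuspid_open = FALSE, pulmonary_open = FALSE)

  sv <- v_max - v_min
  list(trace = trace,
       expected = list(SW_mmHg_mL = sw_exact,
                       SW_J = sw_exact * MMHG_ML_TO_J,
                       SV = sv, EF = sv / v_max * 100),
       events = list(t_open = t_open, t_es = t_es, t_ed = t_ed),
       rr = rr)
}

#' Synthetic beat-summary stream with planted moments
#'
#' Gaussian per-beat summaries with specified means and standard deviations,
#' for testing aggregation and the stationarity check against known truth.
#'
#' @param n number of beats (>= 2).
#' @param index_means named numeric vector of planted means.
#' @param index_sds named numeric vector of planted SDs (>= 0); defaults to
#'   zero for all indices.
#' @param seed integer seed.
#' @return data frame with one column per index plus \code{beat} and
#'   \code{ejecting}.
#' @examples
#' st <- make_summary_stream(5000, c(SV = 77.45), c(SV = 8.5), seed = 3)
#' mean(st$SV); sd(st$SV)
#' @export
make_summary_stream <- function(n, index_means, index_sds = NULL, seed = NULL) {
  if (n < 2) stop("`n` must be >= 2")
  if (is.null(names(index_means)) || any(!nzchar(names(index_means))))
    stop("`index_means` must be a named vector")
  if (is.null(index_sds))
    index_sds <- stats::setNames(numeric(length(index_means)), names(index_means))
  if (any(index_sds < 0)) stop("`index_sds` must be >= 0")
  if (!setequal(names(index_sds), names(index_means)))
    stop("`index_sds` names must match `index_means`")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  out <- data.frame(beat = seq_len(n))
  for (nm in names(index_means))
    out[[nm]] <- rnorm(n, index_means[[nm]], index_sds[[nm]])
  out$ejecting <- TRUE
  out
}
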