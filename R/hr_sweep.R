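# Heart-rate sweep: the package's central in-silico experiment.

# Table layout: internal summary column -> display label and unit
.TABLE1 <- data.frame(
  key = c("P_la", "P_laes", "P_laed", "V_la", "V_laes", "V_laed",
          "P_lv", "P_lves", "P_lved", "P_lv_max", "P_lv_min",
          "V_lv", "V_lves", "V_lved",
          "P_sas", "P_sas_dias", "P_sas_syst",
          "P_pas", "P_pas_dias", "P_pas_syst", "P_pvn",
          "SV", "EF", "SW", "CO", "RPP", "TTI_min", "PVA_min", "SW_PVA"),
  unit = c("mmHg", "mmHg", "mmHg", "mL", "mL", "mL",
           "mmHg", "mmHg", "mmHg", "mmHg", "mmHg",
           "mL", "mL", "mL",
           "mmHg", "mmHg", "mmHg",
           "mmHg", "mmHg", "mmHg", "mmHg",
           "mL", "%", "J", "L/min", "mmHg/min", "mmHg s/min", "J/min", "%"),
  stringsAsFactors = FALSE)

# deterministic per-HR seed spawned from the master seed
.derive_seed <- function(seed, hr, i) {
  as.integer((as.numeric(seed) * 1009 + 97 * round(hr) + 31 * i) %%
               (.Machine$integer.max - 1) + 1)
}

#' Configuration of a heart-rate sweep
#'
#' Bundles every knob of the experiment: heart-rate list, beats per rate,
#' RR-distribution settings, solver options, circulation parameters and the
#' master seed from which per-rate seeds are spawned deterministically.
#'
#' @param hr_list mean heart rates to simulate (bpm).
#' @param beats analyzed beats per heart rate.
#' @param cv coefficient of variation of the RR distribution.
#' @param tau_fraction exGaussian variance split, see [exgauss_from_moments()].
#' @param rr_min physiological RR floor (s).
#' @param seed master seed (integer).
#' @param warmup warm-up beats discarded before analysis.
#' @param samples_per_beat dense-output samples per beat.
#' @param rtol,atol solver tolerances.
#' @param params circulation parameter set.
#' @param snippet_beats number of analyzed beats whose dense trace is kept
#'   per heart rate (for representative time-series figures).
#' @return an object of class \code{sweep_config}.
#' @export
sweep_config <- function(hr_list = c(50, 70, 90, 110, 130), beats = 5000,
                         cv = 0.24, tau_fraction = 0.5, rr_min = 0.25,
                         seed = 42, warmup = 20, samples_per_beat = 200,
                         rtol = 1e-6, atol = 1e-8,
                         params = default_parameters(), snippet_beats = 8) {
  if (length(hr_list) < 1L || any(hr_list <= 0))
    stop("`hr_list` must be nonempty and positive")
  if (beats < 100) stop("`beats` must be >= 100")
  structure(list(hr_list = hr_list, beats = as.integer(beats), cv = cv,
                 tau_fraction = tau_fraction, rr_min = rr_min,
                 seed = as.integer(seed), warmup = as.integer(warmup),
                 samples_per_beat = as.integer(samples_per_beat),
                 rtol = rtol, atol = atol,
                 params = validate_parameters(params),
                 snippet_beats = as.integer(snippet_beats)),
            class = "sweep_config")
}

#' Run the heart-rate sweep
#'
#' For each heart rate in the configuration: spawn a per-rate seed, sample an
#' AF-like RR sequence, integrate the closed loop, summarize every analyzed
#' beat, and aggregate to means and SDs. The per-rate columns are assembled
#' into an index table with the maximum percent variation of each index
#' relative to the first (reference) heart rate and a relevance flag at the
#' |variation| > 15\% threshold. A failure at one rate is logged and leaves
#' the other columns intact.
#'
#' @param config a \code{sweep_config}.
#' @param progress print one line per completed heart rate.
#' @return an object of class \code{cv_sweep}: list with \code{table} (one
#'   row per index), \code{aggregates}, \code{summaries} (per-rate per-beat
#'   data frames), \code{snippets} (short dense traces), \code{config},
#'   \code{manifest}, \code{errors}.
#' @export
run_sweep <- function(config = sweep_config(), progress = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  hrs <- config$hr_list
  seeds <- vapply(seq_along(hrs),
                  function(i) .derive_seed(config$seed, hrs[i], i), integer(1))

  summaries <- stats::setNames(vector("list", length(hrs)), as.character(hrs))
  snippets <- summaries
  aggregates <- summaries
  errors <- list()

  for (i in seq_along(hrs)) {
    hr <- hrs[i]
    res <- tryCatch({
      rr <- sample_rr(config$beats + config$warmup, hr = hr, cv = config$cv,
                      tau_fraction = config$tau_fraction,
                      rr_min = config$rr_min, seed = seeds[i])
      keep <- if (config$snippet_beats > 0)
        config$warmup + seq_len(min(config$snippet_beats, config$beats))
      else FALSE
      sim <- simulate_beats(rr, params = config$params,
                            warmup = config$warmup,
                            samples_per_beat = config$samples_per_beat,
                            rtol = config$rtol, atol = config$atol,
                            keep_trace = keep)
      list(summaries = sim$summaries, trace = sim$trace,
           agg = aggregate_summaries(sim$summaries))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[as.character(hr)]] <- conditionMessage(res)
      warning("heart rate ", hr, " bpm failed: ", conditionMessage(res))
      next
    }
    summaries[[i]] <- res$summaries
    snippets[[i]] <- res$trace
    aggregates[[i]] <- res$agg
    if (progress)
      message(sprintf("HR %g bpm: %d beats done", hr, nrow(res$summaries)))
  }

  ok <- !vapply(aggregates, is.null, logical(1))
  table <- .assemble_index_table(aggregates[ok], hrs[ok])

  manifest <- list(
    package = "afsim",
    version = as.character(utils::packageVersion("afsim")),
    master_seed = config$seed,
    hr_list = hrs, hr_seeds = seeds,
    beats = config$beats, warmup = config$warmup,
    cv = config$cv, tau_fraction = config$tau_fraction, rr_min = config$rr_min,
    solver = list(rtol = config$rtol, atol = config$atol,
                  samples_per_beat = config$samples_per_beat),
    parameters = unclass(config$params))

  structure(list(table = table, aggregates = aggregates,
                 summaries = summaries, snippets = snippets,
                 config = config, manifest = manifest, errors = errors),
            class = "cv_sweep")
}

.assemble_index_table <- function(aggregates, hrs) {
  tab <- .TABLE1
  for (j in seq_along(hrs)) {
    agg <- aggregates[[j]]
    m <- agg$mean[match(tab$key, agg$index)]
    s <- agg$sd[match(tab$key, agg$index)]
    tab[[paste0("mean_", hrs[j])]] <- m
    tab[[paste0("sd_", hrs[j])]] <- s
  }
  if (length(hrs) >= 2L) {
    ref <- tab[[paste0("mean_", hrs[1L])]]
    cmp <- as.matrix(tab[paste0("mean_", hrs[-1L])])
    worst <- apply(abs(cmp - ref), 1L, which.max)
    worst_val <- cmp[cbind(seq_len(nrow(tab)), worst)]
    pv <- 100 * (worst_val - ref) / ref
    tab$max_variation_pct <- round(pv)
    tab$relevant <- abs(pv) > 15
  }
  tab
}

#' @export
print.cv_sweep <- function(x, ...) {
  hrs <- x$config$hr_list
  cat(sprintf("Heart-rate sweep: %s bpm, %d beats each (cv = %g)\n",
              paste(hrs, collapse = ", "), x$config$beats, x$config$cv))
  if (length(x$errors))
    cat("  failed rates:", paste(names(x$errors), collapse = ", "), "\n")
  headline <- c("P_lv", "P_sas", "SV", "EF", "SW", "RPP", "TTI_min",
                "PVA_min", "SW_PVA")
  sub <- x$table[x$table$key %in% headline,
                 c("key", "unit", grep("^mean_", names(x$table), value = TRUE),
                   intersect("max_variation_pct", names(x$table)))]
  print(format(sub, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Percent variation relative to a reference value
#'
#' \code{100 (value_cmp - value_ref) / value_ref}, together with the
#' integer-rounded value used in tabulated reports and the relevance flag at
#' the |variation| > 15\% threshold.
#'
#' @param value_ref reference value (nonzero).
#' @param value_cmp comparison value.
#' @return list with \code{percent}, \code{percent_int}, \code{relevant}.
#' @examples
#' percent_variation(33.92, 53.15)  # about +57
#' @export
percent_variation <- function(value_ref, value_cmp) {
  if (any(value_ref == 0)) stop("`value_ref` must be nonzero")
  pv <- 100 * (value_cmp - value_ref) / value_ref
  list(percent = pv, percent_int = round(pv), relevant = abs(pv) > 15)
}

#' Split-half stationarity check of a beat-summary stream
#'
#' Splits the beat series into halves and reports, for every index, the
#' difference of the half means in units of its standard error
#' \code{sqrt(s1^2/n1 + s2^2/n2)}. Indices with |difference| > \code{z_limit}
#' standard errors are flagged as non-stationary.
#'
#' @param summaries per-beat summary data frame.
#' @param z_limit flagging threshold in standard-error units.
#' @param min_beats minimum number of beats required.
#' @return data frame with columns \code{index}, \code{mean_first},
#'   \code{mean_second}, \code{z}, \code{flagged}.
#' @export
stationarity_check <- function(summaries, z_limit = 3, min_beats = 1000) {
  n <- nrow(summaries)
  if (is.null(n) || n < min_beats)
    stop("stationarity check needs at least ", min_beats, " beats")
  half <- seq_len(n) <= n / 2
  skip <- c("beat", "t_onset", "t_es", "t_ed", "ejecting")
  idx <- setdiff(names(summaries)[vapply(summaries, is.numeric, logical(1))], skip)
  rows <- lapply(idx, function(cl) {
    x1 <- summaries[[cl]][half]; x2 <- summaries[[cl]][!half]
    x1 <- x1[is.finite(x1)]; x2 <- x2[is.finite(x2)]
    se <- sqrt(sd(x1)^2 / length(x1) + sd(x2)^2 / length(x2))
    z <- if (is.finite(se) && se > 0) (mean(x1) - mean(x2)) / se else 0
    data.frame(index = cl, mean_first = mean(x1), mean_second = mean(x2),
               z = z, flagged = abs(z) > z_limit)
  })
  do.call(rbind, rows)
}

#' Write the index table as CSV
#'
#' Rows are the tabulated indices, one column pair per heart rate formatted
#' as \code{mean +/- SD}, plus the maximum percent variation relative to the
#' reference rate and the relevance flag (|variation| > 15\%).
#'
#' @param result a \code{cv_sweep}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_index_table <- function(result, path) {
  stopifnot(inherits(result, "cv_sweep"))
  tab <- result$table
  hrs <- result$config$hr_list
  out <- data.frame(parameter = paste0(tab$key, " [", tab$unit, "]"))
  for (hr in hrs) {
    mc <- paste0("mean_", hr); sc <- paste0("sd_", hr)
    if (mc %in% names(tab))
      out[[paste0(hr, "_bpm")]] <-
        sprintf("%s ± %s", signif(tab[[mc]], 4), signif(tab[[sc]], 3))
  }
  if ("max_variation_pct" %in% names(tab)) {
    out$max_variation_pct <- tab$max_variation_pct
    out$relevant <- tab$relevant
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
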