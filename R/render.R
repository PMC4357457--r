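# File outputs of a sweep: index table, per-beat summaries, manifest and the
# four standard figures (RR densities, LV pressure, systemic pressure, and
# the seven-panel mechano-energetic overview).

.panel_mean_sd <- function(hrs, m, s, ylab, main = ylab, col = "black") {
  ylim <- range(m - s, m + s, na.rm = TRUE)
  plot(hrs, m, type = "b", pch = 19, col = col, xlab = "HR [bpm]",
       ylab = ylab, main = main, ylim = ylim)
  arrows_ok <- is.finite(s) & s > 0
  suppressWarnings(graphics::arrows(hrs[arrows_ok], (m - s)[arrows_ok],
                                    hrs[arrows_ok], (m + s)[arrows_ok],
                                    angle = 90, code = 3, length = 0.03,
                                    col = col))
}

.table_row <- function(result, key) {
  tab <- result$table
  hrs <- result$config$hr_list
  hrs <- hrs[paste0("mean_", hrs) %in% names(tab)]
  i <- match(key, tab$key)
  list(hrs = hrs,
       mean = as.numeric(tab[i, paste0("mean_", hrs)]),
       sd = as.numeric(tab[i, paste0("sd_", hrs)]))
}

#' Write all sweep outputs to a directory
#'
#' Emits \code{table1.csv} (index table), one \code{beats_<hr>.csv} per heart
#' rate, \code{manifest.yaml}, and four figures: RR-interval densities
#' (\code{fig1.png}), mean left-ventricular pressure with a representative
#' time series (\code{fig2.png}), systemic arterial pressure likewise
#' (\code{fig3.png}), and the seven mechano-energetic indices versus heart
#' rate (\code{fig4.png}).
#'
#' @param result a \code{cv_sweep}.
#' @param dir output directory (created if missing).
#' @return named character vector of the files written, invisibly.
#' @export
render_outputs <- function(result, dir) {
  stopifnot(inherits(result, "cv_sweep"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c()
  cfg <- result$config
  hrs <- cfg$hr_list

  p <- file.path(dir, "table1.csv")
  write_index_table(result, p)
  files["table"] <- p

  for (hr in names(result$summaries)) {
    if (is.null(result$summaries[[hr]])) next
    p <- file.path(dir, paste0("beats_", hr, ".csv"))
    write_summary_csv(result$summaries[[hr]], p)
    files[paste0("beats_", hr)] <- p
  }

  p <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(result$manifest, p)
  files["manifest"] <- p

  # fig 1: RR densities
  p <- file.path(dir, "fig1.png")
  png(p, width = 900, height = 650, res = 120)
  if (cfg$cv > 0) {
    tgrid <- seq(0.2, 2.0, length.out = 400)
    dens <- sapply(hrs, function(hr)
      exgauss_pdf(tgrid, exgauss_from_moments(60 / hr, cfg$cv, cfg$tau_fraction)))
    graphics::matplot(tgrid, dens, type = "l", lty = 1, lwd = 2,
                      xlab = "RR [s]", ylab = "pdf [1/s]",
                      main = "RR-interval distributions")
    legend("topright", legend = paste(hrs, "bpm"), lty = 1, lwd = 2,
           col = seq_along(hrs), bty = "n")
  } else {
    plot(60 / hrs, rep(1, length(hrs)), type = "h", lwd = 2,
         xlab = "RR [s]", ylab = "", main = "Regular rhythm (cv = 0)")
  }
  dev.off()
  files["fig1"] <- p

  # fig 2: LV pressure
  p <- file.path(dir, "fig2.png")
  png(p, width = 1200, height = 550, res = 120)
  par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  r1 <- .table_row(result, "P_lv")
  r2 <- .table_row(result, "P_lves")
  r3 <- .table_row(result, "P_lved")
  ylim <- range(0, r1$mean + r1$sd, r2$mean, na.rm = TRUE)
  plot(r1$hrs, r1$mean, type = "b", pch = 19, ylim = ylim, xlab = "HR [bpm]",
       ylab = "P [mmHg]", main = "Left ventricular pressure")
  lines(r2$hrs, r2$mean, type = "b", pch = 17, col = 2)
  lines(r3$hrs, r3$mean, type = "b", pch = 15, col = 4)
  legend("topleft", c("P_lv (mean)", "P_lves", "P_lved"), pch = c(19, 17, 15),
         col = c(1, 2, 4), bty = "n")
  .snippet_panel(result, "P_lv", "P_lv [mmHg]")
  dev.off()
  files["fig2"] <- p

  # fig 3: systemic arterial pressure
  p <- file.path(dir, "fig3.png")
  png(p, width = 1200, height = 550, res = 120)
  par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  r1 <- .table_row(result, "P_sas")
  r2 <- .table_row(result, "P_sas_syst")
  r3 <- .table_row(result, "P_sas_dias")
  ylim <- range(r3$mean, r2$mean, na.rm = TRUE)
  plot(r1$hrs, r1$mean, type = "b", pch = 19, ylim = ylim, xlab = "HR [bpm]",
       ylab = "P [mmHg]", main = "Systemic arterial pressure")
  lines(r2$hrs, r2$mean, type = "b", pch = 17, col = 2)
  lines(r3$hrs, r3$mean, type = "b", pch = 15, col = 4)
  legend("bottomright", c("P_sas (mean)", "P_sas,syst", "P_sas,dias"),
         pch = c(19, 17, 15), col = c(1, 2, 4), bty = "n")
  .snippet_panel(result, "P_sas", "P_sas [mmHg]")
  dev.off()
  files["fig3"] <- p

  # fig 4: the seven mechano-energetic indices
  p <- file.path(dir, "fig4.png")
  png(p, width = 1300, height = 1100, res = 120)
  par(mfrow = c(3, 3), mar = c(4, 4, 2, 1))
  panels <- c(SV = "SV [mL]", EF = "EF [%]", SW = "SW [J]",
              RPP = "RPP [mmHg/min]", TTI_min = "TTI/min [mmHg s/min]",
              PVA_min = "PVA/min [J/min]", SW_PVA = "SW/PVA [%]")
  for (k in names(panels)) {
    r <- .table_row(result, k)
    .panel_mean_sd(r$hrs, r$mean, r$sd, ylab = panels[[k]], main = panels[[k]])
  }
  dev.off()
  files["fig4"] <- p

  invisible(files)
}

.snippet_panel <- function(result, col, ylab) {
  sn <- result$snippets
  keep <- !vapply(sn, is.null, logical(1))
  sn <- sn[keep]
  if (!length(sn)) {
    plot.new(); return(invisible(NULL))
  }
  pick <- unique(c(1L, length(sn)))
  ylim <- range(unlist(lapply(sn[pick], function(df) range(df[[col]]))))
  first <- TRUE
  for (j in seq_along(pick)) {
    df <- sn[[pick[j]]]
    tt <- df$t - df$t[1L]
    if (first) {
      plot(tt, df[[col]], type = "l", col = j, xlab = "t [s]", ylab = ylab,
           ylim = ylim, main = "Representative time series")
      first <- FALSE
    } else lines(tt, df[[col]], col = j)
  }
  legend("topright", paste(names(sn)[pick], "bpm"), lty = 1,
         col = seq_along(pick), bty = "n")
}
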