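#' Exponentially modified Gaussian parameters from target moments
#'
#' During atrial fibrillation the RR-interval histogram is typically
#' right-skewed and well described by an exponentially modified Gaussian
#' (exGaussian): the sum of a Gaussian \code{N(mu_g, sigma_g^2)} and an
#' independent exponential with mean \code{tau}. Its mean is
#' \code{mu_g + tau} and its variance \code{sigma_g^2 + tau^2}. Only the
#' first two moments are pinned by a target mean RR and coefficient of
#' variation, so the split of the variance between the two components is a
#' free choice exposed as \code{tau_fraction}.
#'
#' @param mean_rr target mean RR interval (s), positive.
#' @param cv target coefficient of variation (SD/mean), in \code{[0, 1)}.
#' @param tau_fraction fraction of the total variance assigned to the
#'   exponential component, in \code{(0, 1)}. Default 0.5 (equal split).
#' @return an object of class \code{exgauss_params}: list with \code{mu_g},
#'   \code{sigma_g}, \code{tau} (all seconds).
#' @examples
#' p <- exgauss_from_moments(1.2, 0.24)
#' p$mu_g + p$tau                      # = 1.2
#' sqrt(p$sigma_g^2 + p$tau^2) / 1.2   # = 0.24
#' @export
exgauss_from_moments <- function(mean_rr, cv, tau_fraction = 0.5) {
  if (!is.numeric(mean_rr) || length(mean_rr) != 1L || !is.finite(mean_rr) || mean_rr <= 0)
    stop("`mean_rr` must be a single positive number (seconds)")
  if (!is.numeric(cv) || length(cv) != 1L || !is.finite(cv) || cv < 0 || cv >= 1)
    stop("`cv` must be in [0, 1)")
  if (!is.numeric(tau_fraction) || length(tau_fraction) != 1L ||
      tau_fraction <= 0 || tau_fraction >= 1)
    stop("`tau_fraction` must be in (0, 1)")

  sd_total <- cv * mean_rr
  tau     <- sqrt(tau_fraction) * sd_total
  sigma_g <- sqrt(1 - tau_fraction) * sd_total
  structure(list(mu_g = mean_rr - tau, sigma_g = sigma_g, tau = tau),
            class = "exgauss_params")
}

#' Sample an AF-like RR-interval sequence
#'
#' Draws \code{n} beat intervals from the exGaussian specified by the target
#' mean heart rate and coefficient of variation. Draws below the
#' physiological floor \code{rr_min} (ventricular refractoriness) are redrawn
#' from the same seeded stream, so the sequence is reproducible for a fixed
#' seed. \code{cv = 0} yields a strictly regular rhythm, useful as a sinus
#' baseline.
#'
#' @param n number of beats (>= 1).
#' @param hr target mean heart rate (bpm); mean RR is \code{60/hr}. Values
#'   outside 50-130 bpm are allowed with a warning.
#' @param cv coefficient of variation of the RR distribution; the AF-typical
#'   value is 0.24.
#' @param tau_fraction variance split, see [exgauss_from_moments()].
#' @param rr_min smallest admissible interval (s); rejection-resampled.
#' @param seed integer seed; \code{NULL} leaves the RNG state alone.
#' @return an object of class \code{rr_sequence}: list with \code{intervals}
#'   (s), \code{hr_nominal}, \code{cv_target}, \code{tau_fraction},
#'   \code{rr_min}, \code{seed}, \code{n_rejected}.
#' @examples
#' rr <- sample_rr(1000, hr = 70, cv = 0.24, seed = 1)
#' mean(rr$intervals)          # about 60/70
#' sd(rr$intervals) / mean(rr$intervals)  # about 0.24
#' @export
sample_rr <- function(n, hr, cv = 0.24, tau_fraction = 0.5, rr_min = 0.25,
                      seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a positive integer")
  if (!is.numeric(hr) || length(hr) != 1L || !is.finite(hr) || hr <= 0)
    stop("`hr` must be a single positive number (bpm)")
  if (hr < 50 || hr > 130)
    warning("`hr` outside the 50-130 bpm study range")
  if (!is.numeric(rr_min) || length(rr_min) != 1L || rr_min < 0)
    stop("`rr_min` must be >= 0")
  n <- as.integer(n)
  mean_rr <- 60 / hr

  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }

  n_rejected <- 0L
  if (cv == 0) {
    if (mean_rr < rr_min)
      stop("constant RR ", signif(mean_rr, 4), " s lies below `rr_min`")
    intervals <- rep(mean_rr, n)
  } else {
    par <- exgauss_from_moments(mean_rr, cv, tau_fraction)
    draw <- function(k) rnorm(k, par$mu_g, par$sigma_g) + rexp(k, rate = 1 / par$tau)
    intervals <- draw(n)
    bad <- which(intervals < rr_min)
    n_rejected <- length(bad)
    if (n_rejected > 0.5 * n)
      stop("rejection rate ", round(100 * n_rejected / n), "% > 50%: ",
           "exGaussian parameters incompatible with `rr_min`")
    it <- 0L
    while (length(bad) > 0L) {
      intervals[bad] <- draw(length(bad))
      bad <- bad[intervals[bad] < rr_min]
      n_rejected <- n_rejected + length(bad)
      it <- it + 1L
      if (it > 1000L) stop("rejection sampling did not terminate")
    }
  }

  structure(list(intervals = intervals, hr_nominal = hr, cv_target = cv,
                 tau_fraction = tau_fraction, rr_min = rr_min,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 n_rejected = n_rejected),
            class = "rr_sequence")
}

#' Exponentially modified Gaussian density
#'
#' Standard exGaussian density, used for the RR-distribution figure and for
#' checking the sampler's moments.
#'
#' @param t evaluation points (s), vectorised.
#' @param params an \code{exgauss_params} object with positive
#'   \code{sigma_g} and \code{tau}.
#' @return density values (1/s).
#' @export
exgauss_pdf <- function(t, params) {
  if (!inherits(params, "exgauss_params"))
    stop("`params` must be an `exgauss_params` object")
  if (params$sigma_g <= 0 || params$tau <= 0)
    stop("degenerate exGaussian (sigma_g or tau is zero) has no density")
  mu <- params$mu_g; s <- params$sigma_g; tau <- params$tau
  # f(t) = 1/tau exp(sigma^2/(2 tau^2) - (t-mu)/tau) Phi((t-mu)/sigma - sigma/tau)
  # evaluated on the log scale so the deep left tail does not overflow
  z <- (t - mu) / s - s / tau
  exp(-log(tau) + s^2 / (2 * tau^2) - (t - mu) / tau +
        pnorm(z, log.p = TRUE))
}

#' Write an RR sequence to CSV
#'
#' One interval per row (seconds, 6 decimal places); commented header lines
#' record the generating settings.
#'
#' @param rr an \code{rr_sequence}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_rr_csv <- function(rr, path) {
  stopifnot(inherits(rr, "rr_sequence"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hr=%g cv=%g tau_fraction=%g rr_min=%g seed=%s",
                     rr$hr_nominal, rr$cv_target, rr$tau_fraction, rr$rr_min,
                     ifelse(is.na(rr$seed), "NA", rr$seed)), con)
  writeLines("rr_s", con)
  writeLines(sprintf("%.6f", rr$intervals), con)
  invisible(path)
}

#' Read an RR sequence written by [write_rr_csv()]
#'
#' @param path CSV file with a commented settings line and an `rr_s` column.
#' @return an \code{rr_sequence}.
#' @export
read_rr_csv <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- list(hr = NA_real_, cv = NA_real_, tau_fraction = NA_real_,
               rr_min = NA_real_, seed = NA_integer_)
  if (startsWith(header, "#")) {
    kv <- regmatches(header, gregexpr("[a-z_]+=[-0-9.eNA]+", header))[[1]]
    for (item in kv) {
      parts <- strsplit(item, "=", fixed = TRUE)[[1]]
      meta[[parts[1]]] <- suppressWarnings(as.numeric(parts[2]))
    }
  }
  dat <- read.csv(path, comment.char = "#")
  structure(list(intervals = dat$rr_s, hr_nominal = meta$hr,
                 cv_target = meta$cv, tau_fraction = meta$tau_fraction,
                 rr_min = meta$rr_min,
                 seed = if (is.na(meta$seed)) NA_integer_ else as.integer(meta$seed),
                 n_rejected = NA_integer_),
            class = "rr_sequence")
}

#' @export
print.rr_sequence <- function(x, ...) {
  cat(sprintf("RR sequence: %d beats, nominal HR %g bpm (mean RR %.3f s)\n",
              length(x$intervals), x$hr_nominal, mean(x$intervals)))
  cat(sprintf("  target cv %.3f, sample cv %.3f, seed %s\n",
              x$cv_target, sd(x$intervals) / mean(x$intervals),
              ifelse(is.na(x$seed), "unset", x$seed)))
  invisible(x)
}
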