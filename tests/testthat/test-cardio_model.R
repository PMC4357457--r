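test_that("activation rises from zero, peaks at one, and vanishes in diastole", {
  expect_identical(ventricular_activation(0, 1.2), 0)
  grid <- seq(0, 1.2 - 1e-9, length.out = 20001)
  act <- ventricular_activation(grid, 1.2)
  expect_equal(max(act), 1, tolerance = 1e-6)
  expect_true(all(act >= 0 & act <= 1))
  # single maximum (unimodal): the sign of the increments changes once
  s <- sign(diff(act[act > 0 | c(act[-1], 0) > 0]))
  expect_lte(sum(diff(s[s != 0]) != 0), 1)
  expect_error(ventricular_activation(-0.1, 1.2), "t_in_beat")
  expect_error(ventricular_activation(1.2, 1.2), "t_in_beat")
})

test_that("systole occupies a larger fraction of short beats", {
  frac <- function(rr) {
    g <- seq(0, rr * (1 - 1e-9), length.out = 5000)
    mean(ventricular_activation(g, rr) > 0)
  }
  expect_gt(frac(0.46), frac(1.2))
})

test_that("the linear state equation maps volume to pressure", {
  lv <- list(E_max = 2.5, E_min = 0.1, V_un = 5, passive = FALSE)
  expect_equal(chamber_pressure(5, 0.7, lv), 0)      # unstressed volume
  expect_equal(chamber_pressure(55, 1, lv), 125)     # full activation
  expect_equal(chamber_pressure(55, 0, lv), 5)       # diastolic
  # passive atrium: pressure independent of activation at fixed volume
  la <- list(E_max = 0.3, E_min = 0.165, V_un = 4, passive = TRUE)
  expect_equal(chamber_pressure(60, 0, la), chamber_pressure(60, 1, la))
})

test_that("the ideal valve is an Ohmic diode", {
  expect_identical(valve_flow(10, 80, 0.01), 0)
  expect_equal(valve_flow(81, 80, 0.01), 100)
  set.seed(1)
  up <- runif(100, 0, 150); dn <- runif(100, 0, 150)
  expect_true(all(valve_flow(up, dn, 0.01) >= 0))
  expect_error(valve_flow(Inf, 80, 0.01), "finite")
})

test_that("derivatives conserve volume and respect valve phases", {
  p <- default_parameters()
  set.seed(2)
  for (i in 1:20) {
    st <- initial_state(p)
    st[1:8] <- st[1:8] * runif(8, 0.8, 1.2)
    st[9:10] <- runif(2, -50, 300)
    st[11] <- runif(1, 0, 300)
    d <- cv_derivatives(runif(1, 0, 0.9), st, p, 0.9)
    expect_equal(sum(d$derivatives[1:8]), 0, tolerance = 1e-10)
  }

  # all valves closed -> isovolumic left ventricle
  st <- initial_state(p)
  st["Q_mi"] <- 0
  d <- cv_derivatives(0.25, st, p, 0.9)   # mid-systole, P_lv between la and sas
  if (!d$aux$valves_open[["mitral"]] && !d$aux$valves_open[["aortic"]])
    expect_equal(d$derivatives[["V_lv"]], 0)

  # mitral open, aortic closed -> the ventricle fills
  st2 <- initial_state(p)
  st2["Q_mi"] <- 120
  d2 <- cv_derivatives(0.8, st2, p, 0.9)  # diastole
  expect_false(d2$aux$valves_open[["aortic"]])
  expect_gt(d2$derivatives[["V_lv"]], 0)

  st_bad <- initial_state(p); st_bad["V_lv"] <- NaN
  expect_error(cv_derivatives(0, st_bad, p, 0.9), "V_lv")
})

test_that("compiled and R derivatives produce the same trajectories", {
  p <- default_parameters()
  rrv <- c(0.9, 0.8, 1.0)
  tr_c <- simulate_beats(rrv, p, warmup = 0, samples_per_beat = 100)$trace
  y <- initial_state(p)
  vlv_r <- NULL
  for (b in seq_along(rrv)) {
    f <- function(t, y, parms) list(cv_derivatives(t, y, p, rrv[b], 0)$derivatives)
    o <- deSolve::lsoda(y, seq(0, rrv[b], length.out = 101), f, NULL,
                        rtol = 1e-6, atol = 1e-8)
    vlv_r <- c(vlv_r, o[-101, "V_lv"])
    y <- o[101, -1]
  }
  expect_lt(max(abs(vlv_r - tr_c$V_lv)) / mean(tr_c$V_lv), 1e-6)
})

test_that("a regular rhythm settles into a periodic steady state", {
  sim <- sinus_sim()
  sv <- sim$summaries$SV
  expect_lt(max(abs(diff(sv)) / sv[-1]), 1e-3)
})

test_that("total blood volume is conserved through long runs", {
  sim <- af_sim()
  expect_lt(sim$conservation$max_rel_drift, 1e-6)
  vols <- rowSums(sinus_sim()$trace[, c("V_la", "V_lv", "V_ra", "V_rv",
                                        "V_sas", "V_svn", "V_pas", "V_pvn")])
  expect_lt(max(abs(vols - vols[1])) / vols[1], 1e-6)
})

test_that("no valve regurgitates at any accepted step", {
  tr <- sinus_sim()$trace
  expect_true(all(tr$Q_mi >= 0))
  expect_true(all(tr$Q_ao >= 0))
  expect_true(all(tr$Q_ti >= 0))
  expect_true(all(tr$Q_po >= 0))
})

test_that("valve events are consistently ordered within beats", {
  s <- af_sim()$summaries
  ej <- s[s$ejecting, ]
  expect_gt(nrow(ej), 100)
  # end-diastole (mitral closure starting systole) precedes end-systole
  expect_true(all(ej$t_ed < ej$t_es))
  expect_true(all(ej$t_es < ej$rr))
})

test_that("the sinus baseline sits in textbook-normal ranges", {
  rr <- sample_rr(50, hr = 70, cv = 0, seed = 1)
  s <- simulate_beats(rr, warmup = 20, keep_trace = FALSE)$summaries
  expect_gt(mean(s$EF), 55); expect_lt(mean(s$EF), 70)
  expect_gt(mean(s$P_sas_syst), 100); expect_lt(mean(s$P_sas_syst), 130)
})

test_that("results are robust to halving the solver tolerances", {
  rr <- sample_rr(120, hr = 90, cv = 0.24, seed = 12)
  s1 <- simulate_beats(rr, warmup = 20, keep_trace = FALSE,
                       rtol = 1e-6, atol = 1e-8)$summaries
  s2 <- simulate_beats(rr, warmup = 20, keep_trace = FALSE,
                       rtol = 5e-7, atol = 5e-9)$summaries
  expect_lt(abs(mean(s1$SV) - mean(s2$SV)) / mean(s1$SV), 0.005)
})

test_that("simulation inputs are validated", {
  expect_error(simulate_beats(numeric(0)), "at least one")
  expect_error(simulate_beats(c(0.9, -1), warmup = 0), "positive")
  expect_error(simulate_beats(rep(0.9, 5), warmup = 5), "warmup")
})

test_that("parameter sets validate and round-trip through YAML", {
  p <- default_parameters()
  expect_error(default_parameters(nonsense = 1), "unknown")
  expect_error(validate_parameters(within(unclass(p), rm(R_mi))), "missing")
  expect_error(default_parameters(C_sas = -1), "positive")
  expect_error(default_parameters(Emin_lv = 5), "Emax")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_params_yaml(p, path)
  back <- read_params_yaml(path)
  expect_equal(unclass(back), unclass(p))
  # the shipped versioned config equals the built-in default set
  shipped <- read_params_yaml(system.file("extdata", "default_params.yaml",
                                          package = "afsim"))
  expect_equal(unclass(shipped), unclass(p))
})

test_that("traces round-trip through the CSV writer", {
  sim <- sinus_sim()
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(sim, path)
  back <- read_trace_csv(path)
  expect_equal(nrow(back), nrow(sim$trace))
  expect_equal(back$V_lv, sim$trace$V_lv, tolerance = 1e-12)
  expect_identical(back$aortic_open, sim$trace$aortic_open)
})
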