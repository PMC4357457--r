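test_that("traces segment into one slice per beat that tile the run", {
  sim <- sinus_sim()
  slices <- segment_beats(sim)
  analyzed <- sim$beats[sim$beats$analyzed, ]
  expect_length(slices, nrow(analyzed))
  # slice duration matches the RR draw to within one sample spacing
  for (i in c(1, 10, length(slices))) {
    sl <- slices[[i]]
    dt <- sl$t_beat[2] - sl$t_beat[1]
    expect_lt(abs((max(sl$t_beat) + dt) - analyzed$rr[i]), dt + 1e-12)
  }
  # concatenation reconstructs the analyzed trace
  recon <- do.call(rbind, unname(slices))
  orig <- sim$trace[sim$trace$beat %in% analyzed$beat, ]
  expect_equal(nrow(recon), nrow(orig))
  expect_equal(recon$t, orig$t)
  expect_equal(recon$V_lv, orig$V_lv)
  expect_error(segment_beats(data.frame(t = 1:3)), "beat")
})

test_that("planted valve events are recovered exactly", {
  fx <- make_analytic_beat("rectangle", rr = 1.2, t_es = 0.30, t_ed = 0.95)
  ev <- locate_es_ed(fx$trace)
  expect_true(ev$ejecting)
  expect_equal(ev$t_es, 0.30, tolerance = 1e-9)
  expect_equal(ev$t_ed, 0.95, tolerance = 1e-9)
})

test_that("end-systolic and end-diastolic volumes bracket the ejection", {
  s <- af_sim()$summaries
  ej <- s[s$ejecting, ]
  expect_true(all(ej$V_lved > ej$V_lves))
  expect_true(all(ej$EF > 0 & ej$EF < 100))
  expect_true(all(ej$SW > 0))
  expect_true(all(ej$PVA >= ej$SW))
  expect_true(all(ej$SW_PVA > 0 & ej$SW_PVA <= 100))
})

test_that("a beat with no aortic opening is flagged non-ejecting", {
  fx <- make_analytic_beat("rectangle", rr = 1.0, t_es = 0.5, t_ed = 0.9)
  tr <- fx$trace
  tr$aortic_open <- FALSE
  ev <- locate_es_ed(tr)
  expect_false(ev$ejecting)
  expect_true(is.na(ev$t_es))
})

test_that("loop areas match closed-form values", {
  # rectangle: 90 mmHg x 80 mL = 7200 mmHg mL = 0.960 J
  expect_equal(pv_loop_area(c(10, 100, 100, 10), c(130, 130, 50, 50)),
               7200 * 1.33322e-4, tolerance = 1e-12)
  expect_equal(pv_loop_area(c(10, 100, 100, 10), c(130, 130, 50, 50),
                            units = "mmHg_mL"), 7200)
  # orientation invariance
  expect_equal(pv_loop_area(rev(c(10, 100, 100, 10)), rev(c(130, 130, 50, 50))),
               pv_loop_area(c(10, 100, 100, 10), c(130, 130, 50, 50)))
  # degenerate loop
  expect_equal(pv_loop_area(rep(50, 5), rep(80, 5)), 0)
  expect_error(pv_loop_area(c(1, 2), c(1, 2)), "3 points")

  # sampled fixtures at 500 points per loop, < 0.1% of the analytic area
  for (shape in c("rectangle", "ellipse")) {
    fx <- make_analytic_beat(shape, p_range = c(10, 100), v_range = c(50, 130),
                             samples = 500)
    got <- pv_loop_area(fx$trace$P_lv, fx$trace$V_lv)
    expect_lt(abs(got - fx$expected$SW_J) / fx$expected$SW_J, 1e-3)
  }
  tri <- data.frame(P = c(10, 10, 100), V = c(50, 130, 50))
  fx <- make_analytic_beat("polygon", vertices = tri, samples = 600)
  expect_lt(abs(pv_loop_area(fx$trace$P_lv, fx$trace$V_lv, "mmHg_mL") -
                  0.5 * 90 * 80) / (0.5 * 90 * 80), 1e-3)
})

test_that("per-beat energetics reproduce the defining formulas", {
  en <- beat_energetics(V_lved = 126.4, V_lves = 48.94, P_lved = 15.46,
                        P_lves = 91.75, SW = 0.88, P_lv_mean = 33.92,
                        P_sas_syst = 103.8, rr = 1.2)
  expect_equal(en$SV, 77.46, tolerance = 1e-10)
  # potential energy: 91.75*43.94/2 - 15.46*121.4/4 = 1546.54 mmHg mL
  expect_equal(en$PE, 1546.5365 * 1.33322e-4, tolerance = 1e-6)
  expect_equal(en$PVA, en$PE + 0.88)
  expect_equal(en$efficiency, 100 * 0.88 / (0.88 + en$PE))
  expect_equal(en$CO, 77.46 * 50 / 1000)
  expect_equal(en$RPP, 103.8 * 50)
  expect_equal(en$TTI, 33.92 * 1.2)
  expect_equal(en$TTI_min, 33.92 * 60)

  expect_equal(beat_energetics(100, 50, 10, 90, 0.5, 30, 110, 1)$EF, 50)
  expect_error(beat_energetics(-1, 50, 10, 90, 0.5, 30, 110, 1), "V_lved")
})

test_that("aggregation computes two-point statistics and is linear/invariant", {
  st <- make_summary_stream(2, c(SV = 75), c(SV = 0))
  st$SV <- c(70, 80)
  agg <- aggregate_summaries(st)
  expect_equal(agg$mean[agg$index == "SV"], 75)
  expect_equal(agg$sd[agg$index == "SV"], sqrt(50), tolerance = 1e-12)

  s <- af_sim()$summaries
  a <- aggregate_summaries(s)
  g <- function(k) a$mean[a$index == k]
  # linearity: mean SV equals mean V_lved minus mean V_lves (ejecting beats)
  expect_equal(g("SV"), g("V_lved") - g("V_lves"), tolerance = 1e-10)
  # ratio of means differs from mean of ratios (per-beat EF convention)
  expect_false(isTRUE(all.equal(g("EF"), 100 * g("SV") / g("V_lved"),
                                tolerance = 1e-4)))
  # permutation invariance
  perm <- s[sample.int(nrow(s)), ]
  ap <- aggregate_summaries(perm)
  expect_equal(ap$mean[order(ap$index)], a$mean[order(a$index)])

  expect_error(aggregate_summaries(s[0, ]), "no beat")
  expect_error(aggregate_summaries(s[1, , drop = FALSE]), "2 analyzed")
})

test_that("per-beat rate weighting produces the Jensen gap in RPP", {
  s <- af_sim()$summaries
  expect_gt(mean(60 / s$rr), 60 / mean(s$rr))
  expect_gt(mean(s$RPP), mean(s$P_sas_syst) * 70)
})

test_that("summaries recomputed from a stored trace match the streaming path", {
  sim <- sinus_sim()
  analyzed <- sim$beats$beat[sim$beats$analyzed]
  from_trace <- summarize_beats(sim$trace[sim$trace$beat %in% analyzed, ])
  streaming <- sim$summaries
  expect_equal(nrow(from_trace), nrow(streaming))
  for (col in c("SV", "EF", "SW", "P_lv", "P_sas_syst", "TTI_min"))
    expect_equal(from_trace[[col]], streaming[[col]], tolerance = 0.01,
                 label = col)
})
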