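# Shared short simulations, computed once per test run.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# 40-beat regular-rhythm run with trace retained (events, segmentation)
sinus_sim <- function() cached("sinus", {
  rr <- sample_rr(40, hr = 70, cv = 0, seed = 5)
  simulate_beats(rr, warmup = 10, keep_trace = TRUE)
})

# 120-beat AF run at 70 bpm, summaries only
af_sim <- function() cached("af70", {
  rr <- sample_rr(140, hr = 70, cv = 0.24, seed = 7)
  simulate_beats(rr, warmup = 20, keep_trace = FALSE)
})

sample_skewness <- function(x) mean((x - mean(x))^3) / sd(x)^3
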