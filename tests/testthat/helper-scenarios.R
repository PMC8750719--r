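# Shared, lazily computed scenario runs (the model is deterministic, so a
# single run per scenario serves every test file).

cb <- cocoa_butter()

memo <- local({
  cache <- list()
  function(key, expr) {
    if (is.null(cache[[key]])) cache[[key]] <<- force(expr)
    cache[[key]]
  }
})

baseline_traj <- function() {
  memo("baseline", suppressWarnings(
    simulate_droplet(d = 2e-3, T_init = 318, mat = cb, Ta = 277,
                     Vdg = 0.83, p = 1e5)))
}

cold_traj <- function() {
  memo("cold", suppressWarnings(
    simulate_droplet(d = 2e-3, T_init = 318, mat = cb, Ta = 263,
                     Vdg = 0.83, p = 1e5)))
}

sweep_grid <- function() memo("sweep", run_sweep())
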