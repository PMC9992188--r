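# Shared helpers: parameter shortcuts and a memoised simulation cache so
# expensive runs (28-day scenarios, the full metabolic scan) are computed
# once per test session and reused across files.

params_with <- function(vmaxc = 1808, km = 15,
                        physiology = default_physiology(),
                        chemical = default_chemical()) {
  pbpk_params(physiology = physiology, chemical = chemical,
              metabolism = metabolic_params(vmaxc, km))
}

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# The five 28-day reference regimens as individual time courses (so tests
# can inspect per-run attributes as well as the metrics table).
reference_timecourses <- function() {
  cached("reference_tcs", {
    p <- params_with(1808, 15.0)
    list(
      gavage_25 = run_simulation("gavage", 25, 28, params = p),
      gavage_75 = run_simulation("gavage", 75, 28, params = p),
      dw_61.9 = run_simulation("drinking_water", 61.9, 28, params = p),
      dw_75 = run_simulation("drinking_water", 75, 28, params = p),
      dw_83.9 = run_simulation("drinking_water", 83.9, 28, params = p))
  })
}

reference_metrics <- function() {
  cached("reference_metrics",
         do.call(rbind, lapply(reference_timecourses(), dose_metrics)))
}

full_scan <- function() cached("full_scan", run_scan())

gavage10_7day <- function() {
  cached("g10_7", run_simulation("gavage", 10, 7, params = params_with()))
}
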