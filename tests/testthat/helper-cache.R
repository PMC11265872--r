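# Shared, lazily computed solutions. Expensive solves (the baseline
# continuum grid, the damaged cornea, the discrete refinement series) are
# reused across test files within one run.
.cm_cache <- new.env(parent = emptyenv())

cm_cached <- function(key, fn) {
  if (is.null(.cm_cache[[key]])) assign(key, fn(), envir = .cm_cache)
  get(key, envir = .cm_cache)
}

healthy_config <- function(...) cornea_config(Dmax = 0, ...)

healthy_coarse <- function() {
  cm_cached("healthy_16x320", function()
    solve_continuum(healthy_config(), n_R = 16, n_Phi = 320))
}

healthy_baseline <- function() {
  cm_cached("healthy_64x1280", function()
    solve_continuum(healthy_config(), n_R = 64, n_Phi = 1280))
}

damaged_baseline <- function() {
  cm_cached("damaged_64x1280_xi4", function()
    solve_continuum(cornea_config(Dmax = 0.99, xi = 4),
                    n_R = 64, n_Phi = 1280, warm_start = healthy_baseline()))
}

discrete_healthy <- function(N) {
  cm_cached(paste0("discrete_N", N), function()
    solve_discrete(healthy_config(), N = N))
}
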