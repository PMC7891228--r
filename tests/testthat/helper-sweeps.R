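# Desk-scale factorial sweeps shared by the acceptance tests: computed once
# per test run, on first use, under a fixed master seed.  Same problem sizes
# as scripts/acceptance.R: 500-year realisations, window over the final two
# fifths, 16 replicates per strategy x cost cell.
acceptance_sweep <- local({
    cache <- new.env(parent = emptyenv())
    function(variable = FALSE) {
        key <- if (variable) "variable" else "constant"
        if (!is.null(cache[[key]])) return(cache[[key]])
        sc <- scale_design(sim_config(), n_reps = 200, scale = 0.5,
                           window_frac = 0.4)
        cache[[key]] <- run_factorial(sc$config, costs = 26:35,
                                      n_reps = 16L, variable = variable,
                                      master_seed = 2026)
        cache[[key]]
    }
})
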