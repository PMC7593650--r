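# The desk-scale four-variant study, run once and shared by the acceptance
# blocks (matched-force comparison, equilibrium and qualitative findings).

study_config <- function(seed = 1L) run_config(seed = seed)

get_study <- function() {
  memo("study", {
    cfg <- study_config()
    prep <- prepare_geometry(cfg)
    runs <- list()
    for (v in VARIANTS) {
      runs[[v]] <- suppressWarnings(
        run_variant(cfg, v, prep = prep, keep_solution = TRUE))
    }
    list(cfg = cfg, prep = prep, runs = runs)
  })
}
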