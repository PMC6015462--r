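# The reference synthetic scenario (the simulation_config() defaults, master
# seed 1) run once per test session and cached; several test files interrogate
# different stages of the same run.
.scenario_cache <- new.env(parent = emptyenv())

reference_scenario <- function() {
  if (is.null(.scenario_cache$res)) {
    cfg <- simulation_config(seed = 1L)
    outdir <- file.path(tempdir(), "masterreg-reference-scenario")
    .scenario_cache$res <- suppressMessages(run_pipeline(cfg, outdir = outdir))
    .scenario_cache$config <- cfg
  }
  .scenario_cache$res
}

reference_config <- function() {
  reference_scenario()
  .scenario_cache$config
}
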