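# Memoized pipeline runs shared across test files (built once per session).

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

# the full study conditions: ~500 kb genome, 12 libraries, 50k reads each,
# 100 calibration rounds at 40:1
default_study <- function() {
  cached("default", {
    cfg <- sim_config(seed = 42)
    out <- file.path(tempdir(), "mirdisc-default-sim")
    sim <- run_simulate(cfg, out)
    pc <- pipeline_config(genome = sim$paths$genome,
                          manifest = sim$paths$manifest,
                          hairpin_db = sim$paths$hairpin_db,
                          screen_db = sim$paths$screen_db,
                          seed = 1)
    list(config = cfg, sim = sim, result = run_discovery(pc))
  })
}

# a reduced study for structural/determinism checks
small_study_config <- function(seed = 301) {
  sim_config(genome_size = 400000, n_contigs = 16, depth = 6000, seed = seed)
}

small_study <- function() {
  cached("small", {
    cfg <- small_study_config()
    out <- file.path(tempdir(), "mirdisc-small-sim")
    sim <- run_simulate(cfg, out)
    pc <- pipeline_config(genome = sim$paths$genome,
                          manifest = sim$paths$manifest,
                          hairpin_db = sim$paths$hairpin_db,
                          screen_db = sim$paths$screen_db,
                          n_rounds = 25, seed = 7)
    list(config = cfg, sim = sim, result = run_discovery(pc))
  })
}
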