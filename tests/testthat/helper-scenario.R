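# The default synthetic scenario is expensive (50k reads per library),
# so it is built lazily once and shared across test files.
.scenario_cache <- new.env(parent = emptyenv())

default_scenario <- function() {
  if (is.null(.scenario_cache$sim)) {
    params <- sim_params()
    sim <- build_references(params, seed = 1)
    libs <- simulate_libraries(sim, seed = 1)
    .scenario_cache$sim <- sim
    .scenario_cache$raw <- libs
    .scenario_cache$ct <- build_library(libs$ct, name = "ct")
    .scenario_cache$hs <- build_library(libs$hs, name = "hs")
  }
  .scenario_cache
}

# a small, fast scenario for module-level end-to-end tests
small_scenario_params <- function() {
  sim_params(genome_length = 20000L, reads_per_library = 4000L,
             n_novel = 3L, n_background_loci = 15L,
             repeat_tags_shared = 10L, repeat_tags_ct = 5L,
             repeat_tags_hs = 8L,
             hotspot_tags_ct = 55L, hotspot_tags_hs = 70L,
             n_cds = 3L, n_silenced = 1L, bystander_tags = 5L)
}
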