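# The default synthetic cohort and its pipeline run are expensive enough to
# share across test files; built lazily, once.

.cohort_cache <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.cohort_cache$cohort)) {
    .cohort_cache$cohort <- simulate_cohort(sim_config())
  }
  .cohort_cache$cohort
}

default_pipeline <- function() {
  if (is.null(.cohort_cache$pipeline)) {
    .cohort_cache$pipeline <- run_pipeline(default_cohort())
  }
  .cohort_cache$pipeline
}

# small, fast cohort for structural tests
small_config <- function(seed = 11L) {
  sim_config(seed = seed, n_chrom = 2L, chrom_length = 2e5,
             n_markers_per_chrom = 500L,
             deletion = list(chrom = 1L, start = 50001, end = 60000,
                             carrier = "IV/A"),
             shared_deletion = list(offset = 3000, length = 1500,
                                    n_control_carriers = 3L),
             n_candidate_genes = 4L, n_controls = 6L,
             depth = 30, read_flank = 5000,
             n_shared_variants = 60L, n_private_variants = 5L,
             n_nonpass_variants = 2L)
}
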