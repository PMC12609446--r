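# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

# A mid-size cohort (30 orthogroups, full species panel) reused by the
# feature, homology, conservation and pipeline tests.
fixture_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(
      cohort_config(n_orthogroups = 30L, seed = 2024L)
    )
  }
  .fixture_env$cohort
}

fixture_pipeline <- function() {
  if (is.null(.fixture_env$pipeline)) {
    .fixture_env$pipeline <- run_pipeline(cohort = fixture_cohort())
  }
  .fixture_env$pipeline
}

# The full-scale study-condition cohort used by the planted-truth recovery
# checks (5 species, 3 of them allotetraploid, 200 single-copy
# orthogroups, 5% per-branch divergence, depth 100 x 3 replicates).
acceptance_run <- function() {
  if (is.null(.fixture_env$acc)) {
    co <- generate_cohort(cohort_config(seed = 7L))
    .fixture_env$acc <- list(cohort = co, result = run_pipeline(cohort = co))
  }
  .fixture_env$acc
}

# Cluster member sets as canonical strings, for truth comparison.
cluster_member_sets <- function(members, key) {
  vapply(split(paste(members$unit, members$event_id), members[[key]]),
         function(x) paste(sort(x), collapse = ";"), character(1L))
}
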