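# one moderately sized synthetic cohort + pipeline run shared across test
# files (built lazily, cached for the session)
.test_cache <- new.env(parent = emptyenv())

test_cohort <- function(n_users = 200, seed = 42) {
  key <- sprintf("cohort_%d_%d", n_users, seed)
  if (is.null(.test_cache[[key]])) {
    .test_cache[[key]] <- generate_cohort(generator_config(n_users = n_users,
                                                           seed = seed))
  }
  .test_cache[[key]]
}

test_pipeline_result <- function(n_users = 200, seed = 42) {
  key <- sprintf("pipe_%d_%d", n_users, seed)
  if (is.null(.test_cache[[key]])) {
    coh <- test_cohort(n_users, seed)
    .test_cache[[key]] <- run_pipeline(coh$clicks, coh$activations, coh$survey)
  }
  .test_cache[[key]]
}
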