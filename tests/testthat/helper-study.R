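# Reduced replication study shared by the acceptance-level tests: three
# design cells at 50 replications, M = 2000 Monte-Carlo draws. Computed
# once per test run and memoized (it takes several minutes).
.study_cache <- new.env(parent = emptyenv())

acceptance_study <- function() {
  if (!is.null(.study_cache$study)) return(.study_cache$study)
  settings <- list(
    small_dif = sim_setting(500, "small", "small", "high"),
    large_dif = sim_setting(500, "small", "large", "high"),
    n1000 = sim_setting(1000, "small", "small", "high")
  )
  study_a <- run_study(settings$small_dif, n_reps = 50,
                       methods = c("proposed", "lrt-1"), M = 2000,
                       master_seed = 42)
  study_b <- run_study(settings$large_dif, n_reps = 50,
                       methods = "proposed", M = 2000, master_seed = 42)
  study_c <- run_study(settings$n1000, n_reps = 50,
                       methods = "proposed", M = 2000, master_seed = 42)
  .study_cache$study <- list(a = study_a, b = study_b, c = study_c)
  .study_cache$study
}
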