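# Shared fixtures built in code.
#
# The full-condition experiment (10 subjects per group, 1,000 training
# epochs, 100 test stimuli) is computed once and shared by the acceptance
# tests; module tests use much smaller problem sizes.

.fixture_env <- new.env(parent = emptyenv())

# full study-condition cohort, trained and tested, with history metrics
acceptance_cohort <- function(base_seed = 1) {
  key <- paste0("cohort_", base_seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  ex <- run_experiment(n_per_group = 10, base_seed = base_seed,
                       epochs = 1000, n_test = 100)
  .fixture_env[[key]] <- ex
  ex
}

# one quickly-trained control subject for behavioural unit tests
quick_trained_control <- function() {
  if (!is.null(.fixture_env$quick_control)) return(.fixture_env$quick_control)
  spec <- build_cohort(1, base_seed = 3)[[1]]
  rec <- train_subject(spec, epochs = 200)
  .fixture_env$quick_control <- list(spec = spec, rec = rec)
  .fixture_env$quick_control
}

subjects_of <- function(ex, group) {
  Filter(function(s) s$spec$group == group, ex$subjects)
}
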