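# Shared fixtures. Expensive artifacts (the trained policy, cohort
# normalisers) are computed once per test run and cached here.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

bm_params <- function() cell_params("bone_marrow")

# training protocol used throughout the suite: full learning
# hyperparameters, reduced episode budget
suite_training_config <- function(...) {
  training_config(max_resets = 3000, patience = 400,
                  buffer_capacity = 1e5, ...)
}

# micro protocol for cheap structural checks
micro_training_config <- function(...) {
  training_config(exploratory_steps = 100, eps_anneal_steps = 500,
                  max_resets = 25, patience = 25, runs = 2,
                  buffer_capacity = 2000, target_sync_period = 100, ...)
}

nominal_solution <- function() {
  fixture("nominal_solution", function()
    oc_solve(bm_params(), objective_config()))
}

# best-of-5 policy trained on the nominal patient
trained_policy <- function() {
  fixture("trained_policy", function()
    best_of_runs(bm_params(), objective_config(), suite_training_config(),
                 seed = 1))
}

test_cohort <- function(k, n = 50) {
  fixture(sprintf("cohort_%d_%d", n, round(1000 * k)), function()
    sample_cohort(n, k, seed = 100 + round(100 * k)))
}

cohort_maxima <- function(k, n = 50) {
  key <- sprintf("maxima_%d_%d", n, round(1000 * k))
  fixture(key, function() oc_max_scores(test_cohort(k, n),
                                        objective_config()))
}

random_schedules <- function(n, cfg, seed = 42) {
  set.seed(seed)
  matrix(sample(cfg$actions, n * cfg$n_steps, replace = TRUE),
         nrow = n)
}
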