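test_that("epsilon anneals linearly and clamps at the floor", {
  tc <- training_config()
  expect_equal(epsilon_schedule(0, tc), 1)
  expect_equal(epsilon_schedule(12500, tc), 0.505)
  expect_equal(epsilon_schedule(25000, tc), 0.01)
  expect_equal(epsilon_schedule(80000, tc), 0.01)
  expect_error(epsilon_schedule(-1, tc), "non-negative")
})

# deterministic toy MDP: states 1..3 (3 terminal), two actions
toy_mdp <- function() {
  nxt <- matrix(c(2, 3, 3, 1), 2, 2, byrow = TRUE)  # [state, action]
  rew <- matrix(c(1, 2, 3, 0), 2, 2, byrow = TRUE)
  list(nxt = nxt, rew = rew, discount = 0.9)
}

toy_qstar <- function(m) {
  # independent value-iteration oracle on the state values
  V <- c(0, 0, 0)
  for (i in 1:500) {
    for (s in 1:2) {
      V[s] <- max(m$rew[s, ] + m$discount * V[m$nxt[s, ]])
    }
  }
  Q <- matrix(0, 2, 2)
  for (s in 1:2) Q[s, ] <- m$rew[s, ] + m$discount * V[m$nxt[s, ]]
  Q
}

toy_batch <- function(m) {
  s <- rep(1:2, each = 2)
  a <- rep(1:2, times = 2)
  list(states = matrix(s, 1), actions = a,
       rewards = m$rew[cbind(s, a)],
       next_states = matrix(m$nxt[cbind(s, a)], 1),
       terminal = m$nxt[cbind(s, a)] == 3)
}

test_that("iterating the double-Q targets solves a toy MDP exactly", {
  m <- toy_mdp()
  batch <- toy_batch(m)
  Q <- matrix(0, 2, 3)                     # actions x states, col 3 terminal
  qfun <- function(X) Q[, as.integer(X[1, ]), drop = FALSE]
  for (i in 1:500) {
    y <- bellman_targets(batch, qfun, qfun, m$discount)
    Q[cbind(batch$actions, as.integer(batch$states[1, ]))] <- y
  }
  expect_lt(max(abs(t(Q[, 1:2]) - toy_qstar(m))), 1e-6)
})

test_that("target degeneracies: zero discount and shared networks", {
  m <- toy_mdp()
  batch <- toy_batch(m)
  Q <- matrix(rnorm(6), 2, 3)
  qfun <- function(X) Q[, as.integer(X[1, ]), drop = FALSE]
  expect_equal(bellman_targets(batch, qfun, qfun, 0), batch$rewards)
  # online == target reduces to the standard Q-learning target
  std <- batch$rewards + m$discount * ifelse(
    batch$terminal, 0,
    apply(Q[, as.integer(batch$next_states[1, ]), drop = FALSE], 2, max))
  expect_equal(bellman_targets(batch, qfun, qfun, m$discount), std)
  expect_error(bellman_targets(list(rewards = numeric(0)), qfun, qfun, 0.9),
               "empty")
})

test_that("training runs are reproducible under a fixed seed", {
  p <- bm_params()
  cfg <- objective_config()
  tc <- micro_training_config()
  a <- ddqn_train(p, cfg, tc, seed = 7)
  b <- ddqn_train(p, cfg, tc, seed = 7)
  expect_identical(a$log, b$log)
  expect_identical(a$W1, b$W1)
  expect_identical(a$W3, b$W3)
  c <- ddqn_train(p, cfg, tc, seed = 8)
  expect_false(identical(a$log$return, c$log$return))
})

test_that("policy evaluation is deterministic", {
  p <- bm_params()
  cfg <- objective_config()
  pol <- ddqn_train(p, cfg, micro_training_config(), seed = 3)
  obs <- observation(1, 0)
  expect_identical(policy_dose(pol, obs), policy_dose(pol, obs))
  r1 <- rollout_policy(pol, p, cfg)
  r2 <- rollout_policy(pol, p, cfg)
  expect_identical(r1, r2)
  expect_true(all(r1$schedule %in% cfg$actions))
})

test_that("a pure-exploration agent scores like the random baseline", {
  p <- bm_params()
  cfg <- objective_config()
  tc <- training_config(eps_start = 1, eps_end = 1,
                        exploratory_steps = 100, eps_anneal_steps = 1000,
                        max_resets = 400, patience = 400,
                        buffer_capacity = 10000)
  pol <- ddqn_train(p, cfg, tc, seed = 5)
  base <- random_baseline(p, cfg, n_sims = 20000, seed = 6)
  agent_mean <- mean(pol$log$return)
  agent_se <- sd(pol$log$return) / sqrt(nrow(pol$log))
  expect_lt(abs(agent_mean - base$mean),
            3 * sqrt(agent_se^2 + base$se^2))
})

test_that("best-of-runs selects on greedy objective value", {
  p <- bm_params()
  cfg <- objective_config()
  tc <- micro_training_config()
  best <- best_of_runs(p, cfg, tc, seed = 11)
  vals <- attr(best, "run_values")
  expect_length(vals, tc$runs)
  expect_equal(rollout_policy(best, p, cfg)$value, max(vals))
  # runs = 1 reduces to a single training run
  tc1 <- micro_training_config()
  tc1$runs <- 1
  one <- best_of_runs(p, cfg, tc1, seed = 11)
  expect_equal(rollout_policy(one, p, cfg)$value,
               rollout_policy(ddqn_train(p, cfg, tc1, seed = 11), p,
                              cfg)$value)
})

test_that("the trained policy clears the random baseline decisively", {
  p <- bm_params()
  cfg <- objective_config()
  pol <- trained_policy()
  base <- random_baseline(p, cfg, n_sims = 20000, seed = 2)
  expect_gt(rollout_policy(pol, p, cfg)$value,
            base$mean + 5 * base$sd / sqrt(base$n))
})

test_that("policies round-trip through the JSON format", {
  p <- bm_params()
  cfg <- objective_config()
  pol <- ddqn_train(p, cfg, micro_training_config(), seed = 13)
  path <- withr::local_tempfile(fileext = ".json")
  write_policy(pol, path)
  back <- read_policy(path)
  expect_equal(rollout_policy(back, p, cfg)$value,
               rollout_policy(pol, p, cfg)$value)
  expect_equal(back$actions, pol$actions)
})

test_that("hyperparameter search respects the stated ranges", {
  p <- bm_params()
  cfg <- objective_config()
  out <- hyperparameter_search(p, cfg, budget = 2, seed = 3,
                               base_tcfg = micro_training_config())
  expect_equal(nrow(out$trials), 2)
  expect_true(all(out$trials$hd1 %in% seq(64, 256, 32)))
  expect_true(all(out$trials$hd2 %in% seq(64, 256, 32)))
  expect_true(all(out$trials$batch %in% seq(32, 128, 32)))
  expect_true(all(out$trials$lr > 1e-4 & out$trials$lr < 1e-1))
  expect_true(all(out$trials$discount > 0 & out$trials$discount < 1))
  expect_equal(out$best$lr,
               out$trials$lr[which.max(out$trials$score)])
})
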