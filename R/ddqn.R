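#' Training configuration for the deep double Q-learning agent
#'
#' Defaults are the tuned learning hyperparameters of the dosing problem:
#' hidden widths 64 and 96, Bellman discount 0.9553, Adam learning rate
#' 0.003809, batch size 96, a 10-measurement observation window, 5000
#' random exploratory steps to seed the replay buffer, epsilon annealed
#' linearly from 1 to 0.01 over 25000 steps, episodes of 21 daily steps,
#' training stopped after 50000 environment resets or 500 episodes without
#' improvement of the best episode return, and 5 independent runs for
#' best-of selection.
#'
#' @param hd1,hd2 Hidden-layer widths.
#' @param discount Bellman discount factor in `[0, 1]` (distinct from the
#'   proliferation rate gamma).
#' @param lr Adam learning rate.
#' @param batch Replay batch size.
#' @param wl Observation window length.
#' @param exploratory_steps Random warm-up steps before learning starts.
#' @param eps_start,eps_end,eps_anneal_steps Linear epsilon annealing.
#' @param episode_length Steps per episode (must match the objective
#'   horizon).
#' @param max_resets Maximum number of environment resets (episodes).
#' @param patience Episodes without best-return improvement before stopping.
#' @param runs Independent training runs for [best_of_runs()].
#' @param buffer_capacity Replay buffer capacity (FIFO once full).
#' @param target_sync_period Environment steps between hard copies of the
#'   online network into the target network.
#' @return An object of class `training_config`.
#' @export
training_config <- function(hd1 = 64, hd2 = 96, discount = 0.9553,
                            lr = 0.003809, batch = 96, wl = 10,
                            exploratory_steps = 5000,
                            eps_start = 1, eps_end = 0.01,
                            eps_anneal_steps = 25000,
                            episode_length = 21, max_resets = 50000,
                            patience = 500, runs = 5,
                            buffer_capacity = 1e6,
                            target_sync_period = 500) {
  if (discount < 0 || discount > 1) stop("'discount' must lie in [0, 1]")
  if (eps_end > eps_start) stop("'eps_end' must not exceed 'eps_start'")
  if (lr <= 0 || batch < 1 || wl < 1) stop("invalid learning parameters")
  structure(as.list(environment()), class = "training_config")
}

#' Exploration rate schedule
#'
#' Linear annealing of the epsilon-greedy exploration rate from
#' `eps_start` to `eps_end` over `eps_anneal_steps` environment steps,
#' clamped at `eps_end` thereafter.
#'
#' @param step Environment step counter (0-based, counted once learning
#'   begins).
#' @param tcfg A [training_config()].
#' @return The exploration probability at `step`.
#' @export
#' @examples
#' epsilon_schedule(0, training_config())      # 1
#' epsilon_schedule(25000, training_config())  # 0.01
epsilon_schedule <- function(step, tcfg = training_config()) {
  if (any(step < 0)) stop("'step' must be non-negative")
  pmax(tcfg$eps_end,
       tcfg$eps_start - (tcfg$eps_start - tcfg$eps_end) *
         step / tcfg$eps_anneal_steps)
}

mlp_init <- function(sizes) {
  he <- function(nout, nin) matrix(rnorm(nout * nin, 0, sqrt(2 / nin)),
                                   nout, nin)
  list(W1 = he(sizes[2], sizes[1]), b1 = rep(0, sizes[2]),
       W2 = he(sizes[3], sizes[2]), b2 = rep(0, sizes[3]),
       W3 = he(sizes[4], sizes[3]), b3 = rep(0, sizes[4]))
}

mlp_forward <- function(w, X) {
  X <- as.matrix(X)
  H1 <- pmax(w$W1 %*% X + w$b1, 0)
  H2 <- pmax(w$W2 %*% H1 + w$b2, 0)
  w$W3 %*% H2 + w$b3
}

net_eval <- function(net, X) {
  if (is.function(net)) net(X) else mlp_forward(net, X)
}

#' Double-Q regression targets for a batch of transitions
#'
#' Implements the double Q-learning target: the online network selects the
#' best next action, the target network evaluates it,
#' `y = r + discount * Q_target(s', argmax_a Q_online(s', a))`. Terminal
#' transitions use the reward alone. The environment is deterministic, so
#' no transition-probability weighting is involved.
#'
#' @param batch A list with `states` (d x n matrix), `actions` (1-based
#'   action indices), `rewards`, `next_states` (d x n matrix) and
#'   `terminal` (logical).
#' @param online_net,target_net Either MLP weight lists (as produced by
#'   training) or functions mapping a d x n state matrix to an
#'   `n_actions` x n matrix of Q-values.
#' @param discount Discount factor.
#' @return Numeric vector of regression targets, one per transition.
#' @export
bellman_targets <- function(batch, online_net, target_net, discount) {
  n <- length(batch$rewards)
  if (n == 0) stop("empty batch")
  q2on <- net_eval(online_net, batch$next_states)
  q2t <- net_eval(target_net, batch$next_states)
  a2 <- max.col(t(q2on), ties.method = "first")
  boot <- q2t[cbind(a2, seq_len(n))]
  batch$rewards + discount * ifelse(batch$terminal, 0, boot)
}

# environment description consumed by the C++ training loop
build_env <- function(params, cfg, wl) {
  props <- propagator_set(params, cfg$actions, cfg$dt)
  na <- length(cfg$actions)
  A <- array(0, c(2, 2, na))
  rvec <- matrix(0, na, 2)
  for (i in seq_len(na)) {
    A[, , i] <- props[[i]]$A
    rvec[i, ] <- props[[i]]$r
  }
  list(A = A, rvec = rvec,
       kpen = -(cfg$b / 2) * (1 - cfg$actions)^2 * cfg$dt,
       x0 = as.vector(initial_state(params)),
       horizon = cfg$n_steps, wl = as.integer(wl))
}

#' Train a deep double Q-learning dosing agent
#'
#' Runs one training run on the environment defined by `params` (normally
#' the nominal patient): random warm-up, epsilon-greedy acting, uniform
#' replay sampling, double-Q Adam updates, an episode reset every
#' `episode_length` steps, and the stopping rules of the configuration.
#' Deterministic given `seed`.
#'
#' @param params Bone-marrow [compartment_params()] of the training
#'   environment.
#' @param cfg An [objective_config()].
#' @param tcfg A [training_config()].
#' @param seed Integer seed for weight initialisation, exploration and
#'   replay sampling.
#' @return An object of class `dosing_policy`: network weights, the action
#'   set, window length, training log (`episode`, `return`, `loss`) and
#'   stopping metadata. Signals an error if the run diverged (non-finite
#'   loss).
#' @export
ddqn_train <- function(params, cfg = objective_config(),
                       tcfg = training_config(), seed = 1) {
  if (tcfg$episode_length != cfg$n_steps)
    stop("training episode_length must equal the objective horizon steps")
  env <- build_env(params, cfg, tcfg$wl)
  na <- length(cfg$actions)
  set.seed(seed)
  w0 <- mlp_init(c(tcfg$wl + 1, tcfg$hd1, tcfg$hd2, na))
  ccfg <- tcfg
  ccfg$buffer_capacity <-
    as.integer(min(tcfg$buffer_capacity,
                   tcfg$max_resets * tcfg$episode_length + 1))
  res <- .ddqn_train_cpp(env, w0, ccfg)
  if (isTRUE(res$diverged))
    stop("DDQN training run diverged (non-finite loss)")
  log <- data.frame(episode = seq_len(res$episodes),
                    return = res$episode_returns,
                    loss = res$episode_losses)
  structure(list(W1 = res$W1, b1 = as.vector(res$b1),
                 W2 = res$W2, b2 = as.vector(res$b2),
                 W3 = res$W3, b3 = as.vector(res$b3),
                 actions = cfg$actions, wl = tcfg$wl,
                 seed = seed, log = log,
                 steps = res$steps,
                 best_return = res$best_return,
                 best_episode = res$best_episode),
            class = "dosing_policy")
}

#' @export
print.dosing_policy <- function(x, ...) {
  cat(sprintf("DDQN dosing policy: %d-%d-%d-%d network, wl = %d, seed = %d\n",
              ncol(x$W1), nrow(x$W1), nrow(x$W2), nrow(x$W3), x$wl, x$seed))
  cat(sprintf("  trained %d episodes (%g steps), best training return %.4f\n",
              nrow(x$log), x$steps, x$best_return))
  invisible(x)
}

#' Greedy dose for an observation
#'
#' Deterministic policy evaluation: the dose level whose Q-value is
#' maximal for the given observation vector (ties broken toward the lower
#' dose).
#'
#' @param policy A `dosing_policy`.
#' @param obs Observation vector from [observation()].
#' @return A dose level from the policy's action set.
#' @export
policy_dose <- function(policy, obs) {
  q <- mlp_forward(policy, matrix(obs, ncol = 1))
  policy$actions[which.max(q)]
}

#' Closed-loop greedy rollout of a policy
#'
#' Simulates a patient under the policy: at each day the policy observes
#' the day index and the window of relative bone-marrow totals (never the
#' patient's parameters) and selects a dose greedily.
#'
#' @param policy A `dosing_policy`.
#' @param params The simulated patient's [compartment_params()].
#' @param cfg An [objective_config()].
#' @return List with `schedule`, `value` (episode objective) and `totals`
#'   (daily relative bone-marrow totals).
#' @export
rollout_policy <- function(policy, params, cfg = objective_config()) {
  props <- propagator_set(params, cfg$actions, cfg$dt)
  kpen <- -(cfg$b / 2) * (1 - cfg$actions)^2 * cfg$dt
  x <- as.vector(initial_state(params))
  hist <- sum(x)
  schedule <- numeric(cfg$n_steps)
  value <- 0
  for (t in seq_len(cfg$n_steps)) {
    obs <- observation(hist, t - 1, policy$wl)
    ai <- which.max(mlp_forward(policy, matrix(obs, ncol = 1)))
    schedule[t] <- cfg$actions[ai]
    value <- value + sum(props[[ai]]$r * x) + kpen[ai]
    x <- as.vector(props[[ai]]$A %*% x)
    hist <- c(hist, sum(x))
  }
  list(schedule = schedule, value = value, totals = hist)
}

#' Best-of-several training runs
#'
#' Performs `tcfg$runs` independent training runs (seeds `seed`,
#' `seed + 1`, ...) and returns the policy whose greedy evaluation episode
#' on the training environment achieves the largest objective value.
#' Selection is on the objective value of the deterministic rollout, not
#' on training loss.
#'
#' @inheritParams ddqn_train
#' @return The winning `dosing_policy`, with the per-run greedy values in
#'   attribute `"run_values"`.
#' @export
best_of_runs <- function(params, cfg = objective_config(),
                         tcfg = training_config(), seed = 1) {
  if (tcfg$runs < 1) stop("'runs' must be at least 1")
  vals <- numeric(tcfg$runs)
  policies <- vector("list", tcfg$runs)
  for (i in seq_len(tcfg$runs)) {
    policies[[i]] <- ddqn_train(params, cfg, tcfg, seed = seed + i - 1)
    vals[i] <- rollout_policy(policies[[i]], params, cfg)$value
  }
  best <- policies[[which.max(vals)]]
  attr(best, "run_values") <- vals
  best
}

#' Save / load a trained policy
#'
#' Policies are stored as self-describing JSON: layer sizes, action set,
#' window length and flat weight arrays, loadable without the training
#' stack.
#'
#' @param policy A `dosing_policy`.
#' @param path File path.
#' @return `write_policy` returns `path` invisibly; `read_policy` returns
#'   the restored `dosing_policy`.
#' @export
write_policy <- function(policy, path) {
  obj <- list(sizes = c(ncol(policy$W1), nrow(policy$W1), nrow(policy$W2),
                        nrow(policy$W3)),
              actions = policy$actions, wl = policy$wl, seed = policy$seed,
              W1 = as.vector(policy$W1), b1 = policy$b1,
              W2 = as.vector(policy$W2), b2 = policy$b2,
              W3 = as.vector(policy$W3), b3 = policy$b3)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_policy
#' @export
read_policy <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- obj$sizes
  structure(list(W1 = matrix(obj$W1, s[2], s[1]), b1 = obj$b1,
                 W2 = matrix(obj$W2, s[3], s[2]), b2 = obj$b2,
                 W3 = matrix(obj$W3, s[4], s[3]), b3 = obj$b3,
                 actions = obj$actions, wl = obj$wl, seed = obj$seed,
                 log = NULL, steps = NA, best_return = NA,
                 best_episode = NA),
            class = "dosing_policy")
}

#' Sequential model-based hyperparameter search
#'
#' Explores the five-dimensional learning hyperparameter space (hidden
#' widths in 64..256 by 32, batch size in 32..128 by 32, learning rate
#' log-uniform in (1e-4, 1e-1), discount in (0, 1)). The first trials are
#' sampled at random; subsequent trials are proposed by a random-forest
#' surrogate fitted to the observed scores when the `randomForest` package
#' is available, and at random otherwise. Each trial runs one training run
#' and scores its greedy rollout on the training environment.
#'
#' @param params Training-environment [compartment_params()].
#' @param cfg An [objective_config()].
#' @param budget Number of trials.
#' @param seed Integer seed.
#' @param base_tcfg [training_config()] supplying the non-searched
#'   protocol settings (episode budget, annealing, window length).
#' @param n_init Random trials before the surrogate takes over.
#' @return List with `best` (the winning [training_config()]) and
#'   `trials`, a data frame of sampled configurations and their greedy
#'   scores for downstream distribution analysis.
#' @export
hyperparameter_search <- function(params, cfg = objective_config(),
                                  budget = 20, seed = 1,
                                  base_tcfg = training_config(),
                                  n_init = max(5, budget %/% 4)) {
  if (budget < 1) stop("'budget' must be at least 1")
  hd_grid <- seq(64, 256, by = 32)
  bs_grid <- seq(32, 128, by = 32)
  set.seed(seed)
  draw <- function() data.frame(
    hd1 = sample(hd_grid, 1), hd2 = sample(hd_grid, 1),
    batch = sample(bs_grid, 1),
    lr = 10^runif(1, -4, -1), discount = runif(1))
  trials <- data.frame()
  for (i in seq_len(budget)) {
    cand <- if (i <= n_init || nrow(trials) < 3 ||
                !requireNamespace("randomForest", quietly = TRUE)) {
      draw()
    } else {
      pool <- do.call(rbind, replicate(64, draw(), simplify = FALSE))
      fit <- randomForest::randomForest(
        score ~ hd1 + hd2 + batch + lr + discount, data = trials,
        ntree = 100)
      pool[which.max(predict(fit, pool)), , drop = FALSE]
    }
    tcfg <- base_tcfg
    tcfg$hd1 <- cand$hd1
    tcfg$hd2 <- cand$hd2
    tcfg$batch <- cand$batch
    tcfg$lr <- cand$lr
    tcfg$discount <- cand$discount
    pol <- ddqn_train(params, cfg, tcfg, seed = seed + i)
    cand$score <- rollout_policy(pol, params, cfg)$value
    trials <- rbind(trials, cand)
  }
  best_row <- trials[which.max(trials$score), , drop = FALSE]
  best <- base_tcfg
  best$hd1 <- best_row$hd1
  best$hd2 <- best_row$hd2
  best$batch <- best_row$batch
  best$lr <- best_row$lr
  best$discount <- best_row$discount
  list(best = best, trials = trials)
}
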