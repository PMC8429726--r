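#' @useDynLib chemosched, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm median sd predict
#' @importFrom graphics hist
NULL

# Generator of the linear system d/dt (P, Q) under constant dose f.
# Columns act on (P, Q); off-diagonals are non-negative (Metzler), so the
# propagator is elementwise non-negative and the positive orthant is
# forward-invariant.
generator_matrix <- function(params, dose) {
  matrix(c(params$gamma - params$delta - params$alpha - params$s * dose,
           params$alpha,
           params$beta,
           -(params$beta + params$lambda)),
         nrow = 2, ncol = 2)
}

# Exact propagator over one interval of length dt at constant dose:
# A is the 2x2 state propagator, r the row vector such that the running
# integral of (P + Q) over the interval equals r . x(0). Both come from the
# matrix exponential of the system augmented with the integral coordinate
# z' = P + Q.
dose_propagator <- function(params, dose, dt) {
  B <- rbind(cbind(generator_matrix(params, dose), c(0, 0)), c(1, 1, 0))
  M <- as.matrix(Matrix::expm(Matrix::Matrix(dt * B)))
  list(A = M[1:2, 1:2, drop = FALSE], r = M[3, 1:2], dose = dose)
}

# Propagators for every admissible dose level, reused across a whole episode.
propagator_set <- function(params, actions, dt) {
  lapply(actions, dose_propagator, params = params, dt = dt)
}

#' Steady-state proliferative fraction
#'
#' In the absence of chemotherapy the proliferative share
#' `rho(t) = P / (P + Q)` settles to the unique root in (0, 1) of the
#' quadratic `(delta - gamma - lambda) rho^2 +
#' (gamma + lambda - beta - alpha - delta) rho + beta = 0`, which has the
#' closed form returned here.
#'
#' @param params A [compartment_params()] object.
#' @return The steady-state proliferative fraction, a number in (0, 1).
#'   Signals an error when the quadratic has no root in the open interval
#'   (for instance when `beta = 0`, where the root degenerates to 0).
#' @export
#' @examples
#' steady_state_fraction(cell_params("ovarian")) # 0.3600
steady_state_fraction <- function(params) {
  a2 <- params$delta - params$gamma - params$lambda
  a1 <- params$gamma + params$lambda - params$beta - params$alpha - params$delta
  a0 <- params$beta
  disc <- a1^2 - 4 * a2 * a0
  if (disc < 0) stop("steady-state quadratic has no real root")
  if (abs(a2) < 1e-14) {
    rho <- -a0 / a1
  } else {
    rho <- (-a1 - sqrt(disc)) / (2 * a2)
  }
  if (!is.finite(rho) || rho <= 0 || rho >= 1)
    stop(sprintf("no steady-state proliferative fraction in (0, 1): root = %g",
                 rho))
  rho
}

#' Pre-treatment initial state
#'
#' The model is started from the untreated steady state with the total mass
#' normalised to 1: `P(0)` equals the steady-state proliferative fraction and
#' `Q(0)` its complement.
#'
#' @inheritParams steady_state_fraction
#' @return Named numeric vector `c(P = ..., Q = ...)` with `P + Q = 1`.
#' @export
initial_state <- function(params) {
  rho <- steady_state_fraction(params)
  c(P = rho, Q = 1 - rho)
}

as_state <- function(state) {
  x <- as.numeric(state)
  if (length(x) != 2 || any(!is.finite(x)) || any(x < 0))
    stop("state must be two non-negative finite numbers (P, Q)")
  x
}

#' Evolve the populations over one constant-dose interval
#'
#' Exact propagation of the linear system over `dt` days with the dose held
#' constant, via the matrix exponential.
#'
#' @param state Numeric `(P, Q)` state at the start of the interval.
#' @param params A [compartment_params()] object.
#' @param dose Dose fraction in `[0, 1]`.
#' @param dt Interval length in days (`dt = 0` returns the state unchanged).
#' @return Named `(P, Q)` state at the end of the interval.
#' @export
propagate <- function(state, params, dose, dt) {
  x <- as_state(state)
  if (length(dose) != 1 || dose < 0 || dose > 1)
    stop("'dose' must be a single value in [0, 1]")
  if (dt < 0) stop("'dt' must be non-negative")
  if (dt == 0) return(c(P = x[1], Q = x[2]))
  pr <- dose_propagator(params, dose, dt)
  y <- as.vector(pr$A %*% x)
  c(P = y[1], Q = y[2])
}

#' Immediate reward of one unit dosing step
#'
#' The per-step reward is the running bone-marrow integral minus the dose
#' penalty: `integral_t^{t+dt} (P + Q) ds - (b/2) (1 - dose)^2 dt`. The
#' integral is carried exactly as an augmented coordinate of the linear
#' system, so summing step rewards over an episode reproduces the episode
#' objective to machine precision.
#'
#' @param state Bone-marrow `(P, Q)` state at the start of the step.
#' @param params Bone-marrow [compartment_params()].
#' @param dose Dose level for the step.
#' @param b Penalty weight.
#' @param dt Step length in days (default 1).
#' @return A scalar reward.
#' @export
step_reward <- function(state, params, dose, b, dt = 1) {
  x <- as_state(state)
  pr <- dose_propagator(params, dose, dt)
  sum(pr$r * x) - (b / 2) * (1 - dose)^2 * dt
}

check_schedule <- function(schedule, cfg) {
  if (length(schedule) != cfg$n_steps)
    stop(sprintf("schedule has %d entries; expected %d (horizon/dt)",
                 length(schedule), cfg$n_steps))
  if (any(schedule < 0 | schedule > 1))
    stop("doses must lie in [0, 1]")
  as.numeric(schedule)
}

#' Simulate a dosing schedule
#'
#' Runs the model from its steady-state initial condition under a
#' piecewise-constant dosing schedule and returns the daily trajectory.
#'
#' @param schedule Dose levels, one per decision step.
#' @param params A [compartment_params()] object.
#' @param cfg An [objective_config()].
#' @return A data frame with one row per day boundary (`day`, `dose`
#'   applied over the following step, `NA` on the final row, `P`, `Q`,
#'   `total`), with the objective value in attribute `"objective"`.
#' @export
simulate_schedule <- function(schedule, params, cfg = objective_config()) {
  schedule <- check_schedule(schedule, cfg)
  doses <- unique(schedule)
  props <- lapply(doses, dose_propagator, params = params, dt = cfg$dt)
  dose_idx <- match(schedule, doses)
  x <- as.vector(initial_state(params))
  n <- cfg$n_steps
  out <- matrix(NA_real_, n + 1, 3)
  out[1, ] <- c(x, sum(x))
  obj <- 0
  for (t in seq_len(n)) {
    pr <- props[[dose_idx[t]]]
    obj <- obj + sum(pr$r * x) - (cfg$b / 2) * (1 - schedule[t])^2 * cfg$dt
    x <- as.vector(pr$A %*% x)
    out[t + 1, ] <- c(x, sum(x))
  }
  traj <- data.frame(day = seq(0, cfg$horizon, by = cfg$dt),
                     dose = c(schedule, NA),
                     P = out[, 1], Q = out[, 2], total = out[, 3])
  attr(traj, "objective") <- obj
  traj
}

#' Episode objective of a dosing schedule
#'
#' The finite-horizon objective
#' `J_b(f) = integral_0^T (P_bm + Q_bm - (b/2)(1 - f)^2) dt` for the
#' piecewise-constant dose function induced by `schedule`, started from the
#' steady-state initial condition. Equals the sum of [step_reward()] values
#' along the trajectory.
#'
#' @inheritParams simulate_schedule
#' @return The scalar objective value.
#' @export
episode_objective <- function(schedule, params, cfg = objective_config()) {
  attr(simulate_schedule(schedule, params, cfg), "objective")
}

#' Alternative objective: cancer-kill with bone-marrow preservation
#'
#' Evolves two decoupled copies of the model (bone marrow and a cancer
#' tissue) under the same schedule and returns
#' `integral_0^T (P_bm + Q_bm - b (P_ca + Q_ca)) dt`.
#'
#' @inheritParams simulate_schedule
#' @param params_bm Bone-marrow parameters.
#' @param params_cancer Cancer-tissue parameters.
#' @return The scalar objective value.
#' @export
alt_objective <- function(schedule, params_bm, params_cancer,
                          cfg = objective_config()) {
  schedule <- check_schedule(schedule, cfg)
  int_mass <- function(params) {
    x <- as.vector(initial_state(params))
    tot <- 0
    for (t in seq_len(cfg$n_steps)) {
      pr <- dose_propagator(params, schedule[t], cfg$dt)
      tot <- tot + sum(pr$r * x)
      x <- as.vector(pr$A %*% x)
    }
    tot
  }
  int_mass(params_bm) - cfg$b * int_mass(params_cancer)
}

#' Observation vector for feedback controllers
#'
#' Builds the agent state: the current day index followed by a
#' most-recent-first window of `wl` relative bone-marrow totals. Days before
#' treatment start are represented by the pre-treatment total, exactly 1
#' under the normalised initial condition.
#'
#' @param history Numeric vector of bone-marrow totals for days `0..t`
#'   (relative to the pre-treatment mass).
#' @param t Current day index (non-negative integer).
#' @param wl Window length (default 10).
#' @return Numeric vector of length `wl + 1`:
#'   `c(t, total(t), total(t-1), ..., total(t-wl+1))`.
#' @export
#' @examples
#' observation(1, 0) # c(0, 1, 1, ..., 1)
observation <- function(history, t, wl = 10) {
  if (t < 0) stop("'t' must be non-negative")
  if (length(history) < t + 1)
    stop("'history' must contain totals for days 0..t")
  idx <- t - seq_len(wl) + 2        # days t, t-1, ..., t-wl+1 (1-based + 1)
  win <- ifelse(idx >= 1, history[pmax(idx, 1)], 1)
  c(t, win)
}

#' Local relative sensitivity of the untreated model
#'
#' Perturbs each non-zero rate constant one at a time by a fraction `dp`,
#' recomputes the steady-state initial condition for the perturbed set,
#' integrates the untreated system (`f = 0`) to the horizon, and reports the
#' relative sensitivity `R = ((x - x0)/x0) / dp` of `P(T)` and `Q(T)`.
#'
#' @param params A [compartment_params()] object.
#' @param horizon Simulation length T in days (default 21).
#' @param dp Perturbation fraction (default 0.01, i.e. +1%).
#' @return A matrix with rows `P`, `Q` and one column per non-zero parameter,
#'   with attributes `"dp"` and `"horizon"`.
#' @export
#' @examples
#' rowMeans(abs(sensitivity_table(cell_params("breast"))))
sensitivity_table <- function(params, horizon = 21, dp = 0.01) {
  if (dp <= 0) stop("'dp' must be positive")
  run <- function(p) {
    x0 <- as.vector(initial_state(p))
    M <- as.matrix(Matrix::expm(Matrix::Matrix(horizon *
                                               generator_matrix(p, 0))))
    as.vector(M %*% x0)
  }
  base <- run(params)
  nms <- c("gamma", "delta", "alpha", "beta", "lambda")
  nz <- nms[vapply(nms, function(n) params[[n]] > 0, logical(1))]
  R <- vapply(nz, function(n) {
    q <- params
    q[[n]] <- q[[n]] * (1 + dp)
    (run(q) - base) / base / dp
  }, numeric(2))
  rownames(R) <- c("P", "Q")
  structure(R, dp = dp, horizon = horizon)
}
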