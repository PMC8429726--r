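# Exact solution of the daily-dose, discrete-level, finite-horizon optimal
# control problem. Within a decision step the dynamics are linear and the
# running reward is affine in the (P, Q) state, so the optimal value-to-go
# at every stage is the upper envelope of finitely many affine functions of
# the state. The solver propagates these pieces backward, pruning exactly
# redundant ones over the box of reachable states, and extracts the optimal
# schedule by a forward pass.

# shared setup for the DP and brute-force paths
oc_setup <- function(params, cfg) {
  props <- propagator_set(params, cfg$actions, cfg$dt)
  list(props = props,
       kpen = -(cfg$b / 2) * (1 - cfg$actions)^2 * cfg$dt,
       x0 = as.vector(initial_state(params)))
}

# componentwise upper bound on every reachable state over the horizon: the
# propagators are elementwise non-negative and decrease with dose, so the
# untreated trajectory bounds all dosed ones
reachable_box <- function(setup, n_steps) {
  x <- setup$x0
  box <- x
  A0 <- setup$props[[1]]$A
  for (t in seq_len(n_steps)) {
    x <- as.vector(A0 %*% x)
    box <- pmax(box, x)
  }
  box * 1.05
}

#' Exact discrete optimal control by dynamic programming
#'
#' Maximises the episode objective over all piecewise-constant schedules
#' drawn from the discrete action set, by backward dynamic programming over
#' affine value pieces with exact dominated-piece pruning. The result is
#' exact up to floating-point rounding; near-ties in the forward pass are
#' broken toward the lower dose.
#'
#' @param params Bone-marrow [compartment_params()] of the patient (treated
#'   as known).
#' @param cfg An [objective_config()].
#' @param prune_tol Piece-pruning tolerance (default 1e-12).
#' @return An object of class `oc_solution`: a list with `schedule`,
#'   `value`, `method`, `gap` (0 for the exact solver) and `n_pieces`, the
#'   per-stage piece counts after pruning.
#' @export
#' @examples
#' sol <- oc_solve(cell_params("bone_marrow"), objective_config(horizon = 5))
#' sol$schedule
oc_solve <- function(params, cfg = objective_config(), prune_tol = 1e-12) {
  su <- oc_setup(params, cfg)
  n <- cfg$n_steps
  na <- length(cfg$actions)
  box <- reachable_box(su, n)

  W_stage <- vector("list", n + 1)
  C_stage <- vector("list", n + 1)
  W_stage[[n + 1]] <- matrix(0, 1, 2)
  C_stage[[n + 1]] <- 0
  for (t in n:1) {
    W <- W_stage[[t + 1]]
    C <- C_stage[[t + 1]]
    Wn <- do.call(rbind, lapply(seq_len(na), function(ai)
      sweep(W %*% su$props[[ai]]$A, 2, su$props[[ai]]$r, "+")))
    Cn <- rep(C, times = na) + rep(su$kpen, each = length(C))
    keep <- .prune_pieces(Wn, Cn, box, prune_tol)
    W_stage[[t]] <- Wn[keep, , drop = FALSE]
    C_stage[[t]] <- Cn[keep]
  }

  x <- su$x0
  schedule <- numeric(n)
  value <- 0
  for (t in seq_len(n)) {
    best <- -Inf
    bi <- 1L
    for (ai in seq_len(na)) {
      xn <- as.vector(su$props[[ai]]$A %*% x)
      v <- sum(su$props[[ai]]$r * x) + su$kpen[ai] +
        max(W_stage[[t + 1]] %*% xn + C_stage[[t + 1]])
      if (ai == 1L || v > best + 1e-9 * (1 + abs(best))) {
        best <- v
        bi <- ai
      }
    }
    schedule[t] <- cfg$actions[bi]
    value <- value + sum(su$props[[bi]]$r * x) + su$kpen[bi]
    x <- as.vector(su$props[[bi]]$A %*% x)
  }
  structure(list(schedule = schedule, value = value,
                 method = "affine-piece dynamic programming", gap = 0,
                 n_pieces = vapply(W_stage, nrow, integer(1))),
            class = "oc_solution")
}

#' @export
print.oc_solution <- function(x, ...) {
  cat(sprintf("Discrete optimal control (%s)\n", x$method))
  cat(sprintf("  value = %.6f (gap %g)\n", x$value, x$gap))
  cat("  schedule:", paste(format(x$schedule), collapse = " "), "\n")
  invisible(x)
}

#' Exhaustive-search oracle for the discrete control problem
#'
#' Enumerates every schedule in the action set (feasible only for short
#' horizons) and returns the exact maximiser, breaking exact ties toward
#' the lowest total dose and then the lexicographically earliest schedule.
#'
#' @inheritParams oc_solve
#' @param max_enum Upper limit on the number of enumerated schedules.
#' @return An `oc_solution` object.
#' @export
oc_brute_force <- function(params, cfg = objective_config(),
                           max_enum = 1e6) {
  na <- length(cfg$actions)
  n <- cfg$n_steps
  if (na^n > max_enum)
    stop(sprintf("horizon too large for enumeration: %d^%d schedules",
                 na, n))
  su <- oc_setup(params, cfg)

  # breadth-first expansion over prefixes; day t is the t-th base-na digit
  # (day 1 least significant)
  X <- matrix(su$x0, 2, 1)
  vals <- 0
  for (t in seq_len(n)) {
    m <- ncol(X)
    Xn <- matrix(0, 2, m * na)
    vn <- numeric(m * na)
    for (ai in seq_len(na)) {
      cols <- (ai - 1) * m + seq_len(m)
      Xn[, cols] <- su$props[[ai]]$A %*% X
      vn[cols] <- vals + as.vector(su$props[[ai]]$r %*% X) + su$kpen[ai]
    }
    X <- Xn
    vals <- vn
  }

  vmax <- max(vals)
  ties <- which(vals == vmax)
  decode <- function(i) {
    i <- i - 1
    digits <- integer(n)
    for (t in seq_len(n)) {
      digits[t] <- i %% na
      i <- i %/% na
    }
    cfg$actions[digits + 1]
  }
  scheds <- lapply(ties, decode)
  if (length(scheds) > 1) {
    tot <- vapply(scheds, sum, numeric(1))
    scheds <- scheds[tot == min(tot)]
    ord <- do.call(order, as.data.frame(t(matrix(unlist(scheds),
                                                 nrow = n))))
    scheds <- scheds[ord]
  }
  structure(list(schedule = scheds[[1]], value = vmax,
                 method = "exhaustive enumeration", gap = 0,
                 n_pieces = NULL),
            class = "oc_solution")
}

#' Per-patient theoretical maximum scores
#'
#' Solves the discrete optimal control problem for every patient in a
#' cohort with the patient's parameters treated as known, returning the
#' maximal objective value used to scale controller scores.
#'
#' @param cohort A cohort data frame from [sample_cohort()].
#' @param cfg An [objective_config()].
#' @return Named numeric vector of optimal values, one per patient id.
#' @export
oc_max_scores <- function(cohort, cfg = objective_config()) {
  vals <- vapply(cohort$id, function(id)
    oc_solve(patient_params(cohort, id), cfg)$value, numeric(1))
  names(vals) <- cohort$id
  vals
}
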