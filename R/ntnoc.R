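# Nearest-training-neighbour optimal controller (NTNOC): each training
# patient's known-parameter optimal schedule is simulated once and its
# daily observation windows logged; at treatment time a test patient
# receives, day by day, the dose of the training patient whose logged
# same-day window is Euclidean-closest to the observed one.

#' Build an NTNOC state library from a training cohort
#'
#' Solves the discrete optimal control problem for every training patient
#' (parameters treated as known), simulates each patient under its own
#' optimal schedule, and logs the observation window and applied dose at
#' every day.
#'
#' @param training A training cohort from [sample_cohort()].
#' @param cfg An [objective_config()].
#' @param wl Observation window length (default 10).
#' @return An object of class `ntnoc_library`: a data frame with columns
#'   `day` (0-based), `patient_id`, `w1..w<wl>` (window, most recent
#'   first) and `dose`; one row per patient per day.
#' @export
ntnoc_library <- function(training, cfg = objective_config(), wl = 10) {
  rows <- lapply(training$id, function(id) {
    p <- patient_params(training, id)
    sol <- oc_solve(p, cfg)
    traj <- simulate_schedule(sol$schedule, p, cfg)
    wins <- t(vapply(seq_len(cfg$n_steps), function(t)
      observation(traj$total, t - 1, wl)[-1], numeric(wl)))
    df <- data.frame(day = seq_len(cfg$n_steps) - 1L, patient_id = id,
                     wins, dose = sol$schedule)
    names(df)[2 + seq_len(wl)] <- paste0("w", seq_len(wl))
    df
  })
  lib <- do.call(rbind, rows)
  lib <- lib[order(lib$day, lib$patient_id), ]
  rownames(lib) <- NULL
  attr(lib, "wl") <- wl
  class(lib) <- c("ntnoc_library", "data.frame")
  lib
}

#' Nearest-neighbour dose lookup
#'
#' Returns the dose logged for the training patient whose same-day window
#' is Euclidean-closest to the observed one; ties are broken toward the
#' lowest patient id.
#'
#' @param library An [ntnoc_library()].
#' @param obs Observation vector from [observation()] (day index followed
#'   by the window).
#' @return A dose level.
#' @export
ntnoc_dose <- function(library, obs) {
  wl <- attr(library, "wl")
  day <- obs[1]
  bucket <- library[library$day == day, , drop = FALSE]
  if (nrow(bucket) == 0)
    stop(sprintf("no library entries for day %g", day))
  win <- matrix(as.numeric(obs[-1]), nrow(bucket), wl, byrow = TRUE)
  d2 <- rowSums((as.matrix(bucket[, paste0("w", seq_len(wl))]) - win)^2)
  bucket$dose[which.min(d2)]   # rows are ordered by patient id within a day
}

#' Run the NTNOC on a test patient
#'
#' Closed loop: simulate the test patient, observe the bone-marrow window,
#' query the library, apply the retrieved dose, repeat.
#'
#' @param library An [ntnoc_library()].
#' @param params The test patient's [compartment_params()].
#' @param cfg An [objective_config()].
#' @return List with `schedule`, `value` (episode objective) and `totals`.
#' @export
run_ntnoc <- function(library, params, cfg = objective_config()) {
  wl <- attr(library, "wl")
  props <- propagator_set(params, cfg$actions, cfg$dt)
  kpen <- -(cfg$b / 2) * (1 - cfg$actions)^2 * cfg$dt
  x <- as.vector(initial_state(params))
  hist <- sum(x)
  schedule <- numeric(cfg$n_steps)
  value <- 0
  for (t in seq_len(cfg$n_steps)) {
    dose <- ntnoc_dose(library, observation(hist, t - 1, wl))
    ai <- which.min(abs(cfg$actions - dose))
    schedule[t] <- cfg$actions[ai]
    value <- value + sum(props[[ai]]$r * x) + kpen[ai]
    x <- as.vector(props[[ai]]$A %*% x)
    hist <- c(hist, sum(x))
  }
  list(schedule = schedule, value = value, totals = hist)
}
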