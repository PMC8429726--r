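#' Rate constants for one cell type
#'
#' Bundles the five rate constants of the two-compartment
#' proliferative/quiescent model together with the dimensionless
#' chemotherapeutic strength `s`. All rates are per day.
#'
#' @param gamma Proliferation rate of P cells (days^-1).
#' @param delta Death rate of P cells (days^-1).
#' @param alpha Transfer rate P -> Q (days^-1).
#' @param beta Transfer rate Q -> P (days^-1).
#' @param lambda Death rate of Q cells (days^-1).
#' @param s Relative chemotherapeutic strength (dimensionless). The dose
#'   `f(t)` in `[0, 1]` removes P cells at rate `s * f(t)`. `s` is a
#'   calibration constant of the dosing problem, not a measured rate.
#'
#' @return An object of class `compartment_params`.
#' @seealso [cell_params()] for the packaged nominal parameter sets.
#' @export
#' @examples
#' p <- compartment_params(1.470, 0, 5.643, 0.480, 0.164)
#' steady_state_fraction(p)
compartment_params <- function(gamma, delta, alpha, beta, lambda, s = 1) {
  vals <- c(gamma = gamma, delta = delta, alpha = alpha, beta = beta,
            lambda = lambda)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all rate constants must be finite and non-negative")
  if (!is.finite(s) || s < 0)
    stop("'s' must be finite and non-negative")
  structure(list(gamma = gamma, delta = delta, alpha = alpha, beta = beta,
                 lambda = lambda, s = s),
            class = "compartment_params")
}

#' @export
print.compartment_params <- function(x, ...) {
  cat("Two-compartment model parameters (days^-1):\n")
  cat(sprintf("  gamma = %g, delta = %g, alpha = %g, beta = %g, lambda = %g\n",
              x$gamma, x$delta, x$alpha, x$beta, x$lambda))
  cat(sprintf("  chemotherapeutic strength s = %g\n", x$s))
  invisible(x)
}

param_config_path <- function() {
  system.file("extdata", "cell_params.yaml", package = "chemosched",
              mustWork = TRUE)
}

read_param_config <- function() {
  yaml::read_yaml(param_config_path())
}

#' Packaged nominal parameter sets
#'
#' Loads the packaged nominal rate constants for bone marrow, breast cancer
#' or ovarian cancer cells.
#'
#' @param tissue One of `"bone_marrow"`, `"breast"`, `"ovarian"`.
#' @param s Chemotherapeutic strength override; defaults to the packaged
#'   global value.
#'
#' @return A [compartment_params()] object.
#' @export
#' @examples
#' cell_params("breast")
cell_params <- function(tissue = c("bone_marrow", "breast", "ovarian"),
                        s = NULL) {
  tissue <- match.arg(tissue)
  cfg <- read_param_config()
  p <- cfg$tissues[[tissue]]
  if (is.null(s)) s <- cfg$global$s
  compartment_params(p$gamma, p$delta, p$alpha, p$beta, p$lambda, s = s)
}

#' Configuration of the dosing objective
#'
#' Describes the finite-horizon dosing problem: the toxicity/penalty weight
#' `b`, the horizon `T` in days, the decision interval `dt`, and the
#' admissible dose levels.
#'
#' @param b Non-negative penalty weight multiplying `(1 - f)^2 / 2` in the
#'   running objective. Larger `b` biases the optimiser toward delivering
#'   dose; `b = 0` rewards bone-marrow mass only. Calibration constant.
#' @param horizon Treatment duration T in days (positive multiple of `dt`).
#' @param dt Decision interval in days (dose held constant within a step).
#' @param actions Admissible dose levels, a strictly increasing vector within
#'   `[0, 1]` containing both 0 and 1 (unless a deliberately degenerate
#'   action set is supplied for testing).
#'
#' @return An object of class `objective_config`.
#' @export
objective_config <- function(b = NULL, horizon = NULL, dt = NULL,
                             actions = NULL) {
  g <- read_param_config()$global
  if (is.null(b)) b <- g$b
  if (is.null(horizon)) horizon <- g$T
  if (is.null(dt)) dt <- g$dt
  if (is.null(actions)) actions <- as.numeric(g$actions)
  if (!is.finite(b) || b < 0) stop("'b' must be non-negative")
  if (dt <= 0) stop("'dt' must be positive")
  n_steps <- horizon / dt
  if (abs(n_steps - round(n_steps)) > 1e-9 || n_steps < 1)
    stop("'horizon' must be a positive integer multiple of 'dt'")
  if (any(actions < 0 | actions > 1)) stop("dose levels must lie in [0, 1]")
  if (is.unsorted(actions, strictly = TRUE))
    stop("dose levels must be strictly increasing")
  structure(list(b = b, horizon = horizon, dt = dt, actions = actions,
                 n_steps = as.integer(round(n_steps))),
            class = "objective_config")
}

#' @export
print.objective_config <- function(x, ...) {
  cat(sprintf("Dosing objective: b = %g, T = %g days, dt = %g, %d dose levels\n",
              x$b, x$horizon, x$dt, length(x$actions)))
  invisible(x)
}
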