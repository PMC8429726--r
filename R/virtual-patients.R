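#' Nominal bone-marrow virtual patient
#'
#' The unperturbed mean-value bone-marrow parameterisation, the patient on
#' which the reinforcement-learning agent is trained.
#'
#' @param s Chemotherapeutic strength override (default: packaged global).
#' @return A one-row cohort data frame (see [sample_cohort()]) with `k = 0`
#'   and unit perturbation factors.
#' @export
nominal_patient <- function(s = NULL) {
  p <- cell_params("bone_marrow", s = s)
  data.frame(id = 1L, k = 0,
             factor_gamma = 1, factor_alpha = 1, factor_beta = 1,
             factor_lambda = 1,
             gamma = p$gamma, delta = 0, alpha = p$alpha, beta = p$beta,
             lambda = p$lambda, s = p$s)
}

#' Generate a virtual-patient cohort by Latin hypercube perturbation
#'
#' Perturbs the non-zero nominal bone-marrow rates (`gamma`, `alpha`,
#' `beta`, `lambda`; `delta` is zero and never perturbed) by multiplicative
#' factors drawn uniformly from `[1-k, 1+k]` with 4-dimensional Latin
#' hypercube sampling: per parameter, exactly one draw falls in each of the
#' `n` equal strata of the interval.
#'
#' @param n Number of patients (training cohorts use 1000, testing cohorts
#'   200).
#' @param k Perturbation strength in `[0, 1)`; 0 replicates the nominal
#'   patient.
#' @param seed Integer RNG seed; the cohort is deterministic given the seed.
#' @param role Cohort role label: `"testing"`, `"training"` or `"nominal"`.
#' @param s Chemotherapeutic strength override.
#' @return A data frame with columns `id`, `k`, the four perturbation
#'   factors, the derived rates (`gamma`, `delta`, `alpha`, `beta`,
#'   `lambda`), and `s`; attributes `"role"` and `"seed"`.
#' @export
#' @examples
#' coh <- sample_cohort(10, k = 0.25, seed = 1)
#' range(coh$factor_gamma) # within [0.75, 1.25]
sample_cohort <- function(n, k, seed, role = c("testing", "training",
                                               "nominal"), s = NULL) {
  role <- match.arg(role)
  if (n < 1) stop("'n' must be at least 1")
  if (k < 0 || k >= 1) stop("'k' must lie in [0, 1)")
  nominal <- cell_params("bone_marrow", s = s)
  if (k == 0) {
    fac <- matrix(1, n, 4)
  } else {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    fac <- 1 - k + 2 * k * lhs::randomLHS(n, 4)
  }
  colnames(fac) <- c("gamma", "alpha", "beta", "lambda")
  coh <- data.frame(id = seq_len(n), k = k,
                    factor_gamma = fac[, "gamma"],
                    factor_alpha = fac[, "alpha"],
                    factor_beta = fac[, "beta"],
                    factor_lambda = fac[, "lambda"],
                    gamma = nominal$gamma * fac[, "gamma"],
                    delta = 0,
                    alpha = nominal$alpha * fac[, "alpha"],
                    beta = nominal$beta * fac[, "beta"],
                    lambda = nominal$lambda * fac[, "lambda"],
                    s = nominal$s)
  # every perturbed patient must retain a steady-state fraction in (0, 1);
  # at k <= 0.25 this always holds and we assert rather than resample
  for (i in seq_len(n)) steady_state_fraction(patient_params(coh, i))
  attr(coh, "role") <- role
  attr(coh, "seed") <- seed
  coh
}

#' Parameters of one cohort patient
#'
#' @param cohort A cohort data frame from [sample_cohort()] or
#'   [nominal_patient()].
#' @param id Patient id (row with `cohort$id == id`).
#' @return A [compartment_params()] object.
#' @export
patient_params <- function(cohort, id) {
  row <- cohort[cohort$id == id, , drop = FALSE]
  if (nrow(row) != 1) stop(sprintf("patient id %s not found", id))
  compartment_params(row$gamma, row$delta, row$alpha, row$beta, row$lambda,
                     s = row$s)
}
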