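# Controller evaluation on testing cohorts: raw objective scores, scaling
# by per-patient theoretical maxima, a random-dosing baseline, and the
# comparison statistics used to contrast controller robustness.

#' Score a controller on a testing cohort
#'
#' Applies a controller to every patient of a cohort and records the raw
#' objective score and the scaled score (raw divided by the patient's
#' theoretical maximum). Open-loop controllers (a fixed schedule) apply the
#' identical dose sequence to every patient; feedback controllers (a
#' `dosing_policy` or an `ntnoc_library`) observe only the daily relative
#' bone-marrow totals, never the patient's parameters.
#'
#' @param controller A numeric schedule, a `dosing_policy`, or an
#'   `ntnoc_library`.
#' @param cohort A testing cohort from [sample_cohort()].
#' @param cfg An [objective_config()].
#' @param sigma_max Named vector of per-patient maxima from
#'   [oc_max_scores()]. Computed on the fly when `NULL`.
#' @param tag Controller label stored in the records.
#' @return A data frame of score records: `id`, `k`, `controller`, `sigma`
#'   (raw), `sigma_max`, `sigma_hat` (scaled, in (0, 1] up to solver
#'   rounding).
#' @export
evaluate_controller <- function(controller, cohort,
                                cfg = objective_config(),
                                sigma_max = NULL, tag = NULL) {
  if (is.null(sigma_max)) sigma_max <- oc_max_scores(cohort, cfg)
  if (is.null(tag)) {
    tag <- if (inherits(controller, "dosing_policy")) "RL"
    else if (inherits(controller, "ntnoc_library")) "NTNOC"
    else "OC-nominal"
  }
  sig <- vapply(cohort$id, function(id) {
    p <- patient_params(cohort, id)
    if (inherits(controller, "dosing_policy"))
      rollout_policy(controller, p, cfg)$value
    else if (inherits(controller, "ntnoc_library"))
      run_ntnoc(controller, p, cfg)$value
    else
      episode_objective(controller, p, cfg)
  }, numeric(1))
  mx <- sigma_max[as.character(cohort$id)]
  if (any(is.na(mx))) stop("missing sigma_max entries for some patients")
  rec <- data.frame(id = cohort$id, k = cohort$k, controller = tag,
                    sigma = sig, sigma_max = unname(mx),
                    sigma_hat = unname(sig / mx))
  if (any(rec$sigma_hat > 1 + 1e-6))
    stop("scaled score exceeds 1 beyond solver rounding; normalisers invalid")
  rec
}

#' Random-dosing baseline
#'
#' Monte-Carlo estimate of the episode score when a dose level is chosen
#' independently and uniformly at each step. Reports the raw-score mean and
#' both dispersion conventions (sample standard deviation and standard
#' error of the mean), plus the same quantities scaled by a supplied
#' normaliser.
#'
#' @param params Bone-marrow [compartment_params()].
#' @param cfg An [objective_config()].
#' @param n_sims Number of simulated episodes.
#' @param seed Integer seed.
#' @param sigma_max Optional normaliser (e.g. the nominal optimum) for the
#'   scaled-convention columns.
#' @return A one-row data frame: `mean`, `sd`, `se`, `n`, and when a
#'   normaliser is given `mean_scaled`, `sd_scaled`.
#' @export
random_baseline <- function(params, cfg = objective_config(),
                            n_sims = 1e6, seed = 1, sigma_max = NULL) {
  if (n_sims < 1) stop("'n_sims' must be at least 1")
  props <- propagator_set(params, cfg$actions, cfg$dt)
  kpen <- -(cfg$b / 2) * (1 - cfg$actions)^2 * cfg$dt
  na <- length(cfg$actions)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  X <- matrix(as.vector(initial_state(params)), 2, n_sims)
  vals <- numeric(n_sims)
  for (t in seq_len(cfg$n_steps)) {
    ai <- sample.int(na, n_sims, replace = TRUE)
    for (a in unique(ai)) {
      cols <- ai == a
      vals[cols] <- vals[cols] +
        as.vector(props[[a]]$r %*% X[, cols, drop = FALSE]) + kpen[a]
      X[, cols] <- props[[a]]$A %*% X[, cols, drop = FALSE]
    }
  }
  out <- data.frame(mean = mean(vals), sd = sd(vals),
                    se = sd(vals) / sqrt(n_sims), n = n_sims)
  if (!is.null(sigma_max)) {
    out$mean_scaled <- out$mean / sigma_max
    out$sd_scaled <- out$sd / sigma_max
  }
  out
}

#' One-sided Wilcoxon signed-rank test for paired scaled scores
#'
#' Classic signed-rank convention: zero differences are discarded, ties in
#' the absolute differences receive average ranks, and the statistic is the
#' sum of ranks of positive differences. Degenerate input (all differences
#' zero) is signalled as an error.
#'
#' @param x,y Paired score vectors of equal length, matched by patient.
#' @param alternative `"greater"` tests whether `x` tends to exceed `y`.
#' @return List with `statistic` (sum of positive ranks), `p.value` and
#'   `n` (non-zero pairs).
#' @export
wilcoxon_one_sided <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("'x' and 'y' must be paired")
  d <- x - y
  if (all(d == 0)) stop("all paired differences are zero; test degenerate")
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, alternative = alternative))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       n = sum(d != 0))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Sup-distance between the empirical CDFs of two samples with the
#' asymptotic p-value.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `statistic` (in `[0, 1]`) and `p.value`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  kt <- suppressWarnings(stats::ks.test(x, y))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Summarise controller score records
#'
#' Per-controller medians, means and standard deviations of the scaled
#' scores, per-patient differences between controller pairs, and
#' fixed-width histograms (bin width 0.025 on (0, 1]).
#'
#' @param records A score-record data frame (rows from
#'   [evaluate_controller()], possibly several controllers row-bound).
#' @param bin_width Histogram bin width (default 0.025).
#' @return List with `by_controller` (median/mean/sd table), `differences`
#'   (per-patient scaled-score differences for every controller pair,
#'   matched by patient id) and `histograms` (counts per bin per
#'   controller, bin edges at multiples of `bin_width`).
#' @export
summarize_scores <- function(records, bin_width = 0.025) {
  tags <- unique(records$controller)
  by_controller <- do.call(rbind, lapply(tags, function(tg) {
    s <- records$sigma_hat[records$controller == tg]
    data.frame(controller = tg, n = length(s), median = median(s),
               mean = mean(s), sd = sd(s))
  }))
  edges <- seq(0, 1, by = bin_width)
  if (max(records$sigma_hat) > 1) edges <- c(edges, 1 + bin_width)
  histograms <- do.call(rbind, lapply(tags, function(tg) {
    s <- records$sigma_hat[records$controller == tg]
    h <- hist(s, breaks = edges, plot = FALSE, right = TRUE)
    data.frame(controller = tg, bin_lo = h$breaks[-length(h$breaks)],
               bin_hi = h$breaks[-1], count = h$counts)
  }))
  differences <- NULL
  if (length(tags) > 1) {
    pairs <- utils::combn(tags, 2, simplify = FALSE)
    differences <- do.call(rbind, lapply(pairs, function(pr) {
      a <- records[records$controller == pr[1], ]
      b <- records[records$controller == pr[2], ]
      m <- merge(a[, c("id", "k", "sigma_hat")],
                 b[, c("id", "k", "sigma_hat")], by = c("id", "k"))
      if (nrow(m) != nrow(a) || nrow(m) != nrow(b))
        stop("cohort mismatch between controllers")
      data.frame(comparison = paste(pr[1], "-", pr[2]), id = m$id, k = m$k,
                 diff = m$sigma_hat.x - m$sigma_hat.y)
    }))
  }
  list(by_controller = by_controller, differences = differences,
       histograms = histograms)
}
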