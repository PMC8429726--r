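test_that("scaled scores are 1 for the optimum and never exceed 1", {
  cfg <- objective_config()
  coh0 <- sample_cohort(3, 0, seed = 1)
  mx <- oc_max_scores(coh0, cfg)
  nom <- nominal_solution()
  rec <- evaluate_controller(nom$schedule, coh0, cfg, mx)
  expect_equal(rec$sigma_hat, rep(1, 3), tolerance = 1e-9)
  expect_equal(unique(rec$controller), "OC-nominal")

  coh <- test_cohort(0.25)
  mx <- cohort_maxima(0.25)
  rec <- evaluate_controller(nom$schedule, coh, cfg, mx)
  expect_true(all(rec$sigma_hat <= 1 + 1e-9))
  expect_true(all(rec$sigma_hat > 0))
})

test_that("the random baseline is consistent across sample sizes", {
  p <- bm_params()
  cfg <- objective_config()
  a <- random_baseline(p, cfg, n_sims = 3000, seed = 4)
  b <- random_baseline(p, cfg, n_sims = 30000, seed = 5)
  expect_lt(abs(a$mean - b$mean), 3 * sqrt(a$se^2 + b$se^2))
  # degenerate action set: no randomness, mean equals the fixed schedule
  cfg0 <- objective_config(actions = 0)
  z <- random_baseline(p, cfg0, n_sims = 50, seed = 1)
  expect_equal(z$sd, 0)
  expect_equal(z$mean, episode_objective(rep(0, 21), p, cfg0))
  # scaled convention
  s <- random_baseline(p, cfg, n_sims = 1000, seed = 2,
                       sigma_max = nominal_solution()$value)
  expect_equal(s$mean_scaled, s$mean / nominal_solution()$value)
})

test_that("signed-rank statistic and p-value match full enumeration", {
  x <- c(1.3, 0.9, 1.8, 2.4, 1.1)
  y <- c(1.0, 1.0, 1.2, 1.9, 0.7)
  got <- wilcoxon_one_sided(x, y)
  d <- x - y
  r <- rank(abs(d))
  expect_equal(got$statistic, sum(r[d > 0]))
  # exact null distribution over all 2^5 sign assignments
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 5)))
  stats <- signs %*% r
  expect_equal(got$p.value, mean(stats >= got$statistic))
})

test_that("signed-rank test has power and guards its pairing", {
  set.seed(8)
  y <- runif(60)
  x <- y + 0.3 + rnorm(60, 0, 0.05)
  expect_lt(wilcoxon_one_sided(x, y)$p.value, 0.001)
  shuffled <- wilcoxon_one_sided(x, sample(y))
  expect_false(isTRUE(all.equal(shuffled$statistic,
                                wilcoxon_one_sided(x, y)$statistic)))
  expect_error(wilcoxon_one_sided(x, x), "degenerate")
})

test_that("KS statistic behaves on identical and shifted samples", {
  set.seed(3)
  x <- runif(200)
  expect_equal(ks_two_sample(x, x)$statistic, 0)
  y <- runif(200, 0.5, 1.5)
  out <- ks_two_sample(x, y)
  expect_lt(out$p.value, 1e-6)
  expect_gte(out$statistic, 0)
  expect_lte(out$statistic, 1)
  expect_error(ks_two_sample(numeric(0), x), "empty")
})

test_that("summaries report gaps, pairs and 0.025-wide bins", {
  rec1 <- data.frame(id = 1:10, k = 0.2, controller = "A",
                     sigma = 1:10, sigma_max = 10, sigma_hat = (1:10) / 10)
  rec2 <- rec1
  rec2$controller <- "B"
  out <- summarize_scores(rbind(rec1, rec2))
  expect_equal(out$differences$diff, rep(0, 10))
  expect_equal(out$by_controller$median, rep(0.55, 2))
  edges <- sort(unique(c(out$histograms$bin_lo, out$histograms$bin_hi)))
  expect_true(all(abs(edges / 0.025 - round(edges / 0.025)) < 1e-12))
  expect_equal(sum(out$histograms$count[out$histograms$controller == "A"]),
               10)
  # mismatched cohorts fail loudly
  rec3 <- rec2[1:5, ]
  rec3$controller <- "C"
  expect_error(summarize_scores(rbind(rec1, rec3)), "mismatch")
})
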