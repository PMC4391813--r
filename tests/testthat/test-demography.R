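test_that("mismatch distributions count pairs correctly", {
  hs <- tiny_haps(c("AA", "AT", "TT"))
  mm <- mismatch_distribution(hs)
  expect_equal(unname(mm), c(0L, 2L, 1L))   # diffs {1,2,1}
  hs0 <- tiny_haps(rep("ACGT", 5))
  mm0 <- mismatch_distribution(hs0)
  expect_equal(unname(mm0[1]), 10L)         # N(N-1)/2 identical pairs
  # mean of the distribution equals nucleotide diversity
  set.seed(501)
  h <- simulate_mtdna(sim_config(theta = 15, samples_per_deme = 30),
                      seq_length = 200)
  mm <- mismatch_distribution(h, "sequence_only")
  expect_equal(sum(as.numeric(names(mm)) * mm) / sum(mm),
               sequence_summaries(h)["pooled", "pi"])
})

test_that("the equilibrium mismatch distribution is geometric with mean theta", {
  expect_equal(equilibrium_mismatch(0, 0), 1)
  expect_equal(equilibrium_mismatch(1, 0:1), c(1 / 2, 1 / 4))
  j <- 0:200
  p5 <- equilibrium_mismatch(5, j)
  expect_equal(sum(p5), 1, tolerance = 1e-6)
  expect_equal(sum(j * p5), 5, tolerance = 1e-4)
})

test_that("closed-form expansion expectations agree with the coalescent oracle", {
  set.seed(502)
  sim_mm <- gagconnect:::sim_mismatch_model
  check <- function(model, par, reps = 150, jmax = 25) {
    fexp <- expected_mismatch(model, par, jmax)
    acc <- numeric(jmax + 1)
    for (r in seq_len(reps)) {
      s <- sim_mm(40, model, par)
      f <- s / sum(s)
      f <- f[seq_len(min(jmax + 1, length(f)))]
      acc[seq_along(f)] <- acc[seq_along(f)] + f
    }
    max(abs(acc / reps - fexp))
  }
  expect_lt(check("demographic", c(tau = 3, theta0 = 0.3, theta1 = 20)),
            0.02)
  expect_lt(check("spatial", c(tau = 4, thetaS = 1, M = 5)), 0.02)
  # limits: tau = 0 reduces to the ancestral equilibrium
  expect_equal(expected_mismatch("demographic",
                                 c(tau = 0, theta0 = 2, theta1 = 50), 30),
               equilibrium_mismatch(2, 0:30), tolerance = 1e-9)
})

test_that("raggedness matches hand sums and extreme cases", {
  expect_equal(raggedness(c(0.25, 0.5, 0.25)), 3 * 0.0625)
  expect_equal(raggedness(c(0, 1)), 2)     # all mass in one interior class
  expect_equal(raggedness(c(0, 5, 0)), 2 * 25 / 25)
})

test_that("expansion data are smoother than stationary data", {
  set.seed(503)
  sim_mm <- gagconnect:::sim_mismatch_model
  r_exp <- replicate(60, raggedness(
    sim_mm(50, "demographic", c(tau = 5, theta0 = 0.1, theta1 = 60))))
  r_stat <- replicate(60, raggedness(
    sim_mm(50, "demographic", c(tau = 0, theta0 = 5, theta1 = 5))))
  expect_lt(mean(r_exp), mean(r_stat))
})

test_that("fit_expansion recovers a sudden expansion and flags misfits", {
  set.seed(504)
  sim_mm <- gagconnect:::sim_mismatch_model
  s <- sim_mm(60, "demographic", c(tau = 3, theta0 = 0.1, theta1 = 50))
  f <- fit_expansion(s, "demographic", bootstrap_reps = 80)
  expect_s3_class(f, "mismatch_fit")
  expect_true(f$model_p > 0.01)     # its own model is not rejected
  expect_true(f$par[["tau"]] > 0.5 && f$par[["tau"]] < 10)
  expect_true(all(f$quantiles[1, ] <= f$quantiles[2, ]))
  # stationary data under the demographic model: poor fit or significant
  # raggedness far more often than for true expansions (checked by level)
  s0 <- sim_mm(60, "demographic", c(tau = 0, theta0 = 6, theta1 = 6))
  f0 <- fit_expansion(s0, "demographic", bootstrap_reps = 60)
  expect_true(is.finite(f0$ssd))
  # degenerate input
  expect_error(fit_expansion(c(3, 0), "demographic"), "pairs")
  z <- fit_expansion(c(`0` = 45), "demographic")
  expect_match(z$flagged, "zero-variance")
})

test_that("expansion dating reproduces the published conversions exactly", {
  cfg <- dating_config(mu = 1.23e-4, G = 7.94)
  expect_equal(round(expansion_time_years(3.4, cfg)), 109740)
  expect_equal(round(expansion_time_years(0.74, cfg)), 23885)
  expect_equal(round(expansion_time_years(4.8, cfg)), 154927)
  expect_equal(expansion_time_years(0, cfg), 0)
  # linear in tau and G; halving mu doubles the age
  expect_equal(expansion_time_years(2, cfg), 2 * expansion_time_years(1, cfg))
  cfg2 <- dating_config(mu = 1.23e-4 / 2, G = 7.94)
  expect_equal(expansion_time_years(1, cfg2), 2 * expansion_time_years(1, cfg))
})

test_that("the per-sequence mutation rate derivation inverts the reported control-region rate", {
  expect_equal(derive_sequence_mu(0.02888, 7.94, 536), 1.23e-4,
               tolerance = 0.005)
  expect_equal(derive_sequence_mu(0.02888, 7.94, 0), 0)
  expect_equal(derive_sequence_mu(0.02888, 7.94, 1072),
               2 * derive_sequence_mu(0.02888, 7.94, 536))
  expect_error(dating_config(mu = 0), "mu")
})

test_that("the bottleneck test detects He deficiency and skips fixed loci", {
  set.seed(505)
  # expansion-like spectra: one common allele plus many rare ones gives
  # He below the equilibrium expectation for the observed allele count
  rare_freqs <- replicate(6, c(0.82, rep(0.03, 6)), simplify = FALSE)
  g <- sample_null_frequencies(rare_freqs, 0, 60, deme_names = "GOM")
  # append a monomorphic locus: must be skipped without crashing
  g$calls <- array(c(g$calls[, , 1], rep(1L, 60), g$calls[, , 2],
                     rep(1L, 60)), dim = c(60, 7, 2))
  g$loci <- paste0("L", 1:7)
  bt <- bottleneck_test(g, sim_reps = 250)$GOM
  expect_false("L7" %in% bt$per_locus$locus)
  expect_lt(bt$he_deficiency, 0.2)
  expect_gt(bt$he_excess, 0.5)
})

test_that("too few usable loci refuse the Wilcoxon but keep the sign test", {
  set.seed(506)
  g <- sample_null_frequencies(random_base_freqs(2, 4), 0, 30,
                               deme_names = "GOM")
  bt <- bottleneck_test(g, sim_reps = 150)$GOM
  expect_true(bt$wilcoxon_refused)
  expect_true(is.numeric(bt$sign_test))
})
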