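test_that("the scenario catalog contains exactly the ten ranked models", {
  cat10 <- scenario_catalog()
  expect_length(cat10, 10)
  expect_named(cat10, c("scenario_1", "scenario_2", "full_3pop",
                        "symmetric_3pop", "cb_to_wfs", "wfs_to_cb",
                        "full_2pop", "symmetric_2pop", "panmixia",
                        "scenario_3"))
  # Scenario 1: one-way CB -> both WFS demes, free within WFS
  m1 <- cat10$scenario_1$mask
  expect_equal(m1["CB", "SWFS"], "free")
  expect_equal(m1["CB", "NWFS"], "free")
  expect_equal(m1["SWFS", "NWFS"], "free")
  expect_equal(m1["NWFS", "SWFS"], "free")
  expect_equal(m1["SWFS", "CB"], "zero")
  expect_equal(m1["NWFS", "CB"], "zero")
  # Scenario 2: everything free except SWFS -> CB
  m2 <- cat10$scenario_2$mask
  expect_equal(m2["SWFS", "CB"], "zero")
  expect_equal(sum(m2 == "free"), 5)
  # Scenario 3 is the reverse source-sink orientation of Scenario 1
  m3 <- cat10$scenario_3$mask
  expect_equal(m3["SWFS", "CB"], "free")
  expect_equal(m3["NWFS", "CB"], "free")
  expect_equal(m3["CB", "SWFS"], "zero")
  expect_equal(m3["CB", "NWFS"], "zero")
  # panmixia has one deme and no migration entries
  expect_equal(cat10$panmixia$k, 1)
  expect_length(gagconnect:::scenario_params(cat10$panmixia), 1)
  # symmetric models tie each pair to a single rate
  expect_length(gagconnect:::scenario_params(cat10$symmetric_3pop), 3 + 3)
  expect_length(gagconnect:::scenario_params(cat10$full_3pop), 3 + 6)
})

test_that("scenario masks drive the simulator's migration matrix", {
  sc1 <- scenario_catalog()$scenario_1
  cfg <- sim_config(3, theta = 10, M = 5, samples_per_deme = 5, n_loci = 2)
  M <- gagconnect:::masked_M(cfg, sc1)
  expect_equal(M["SWFS", "CB"], 0)
  expect_equal(M["NWFS", "CB"], 0)
  expect_equal(M["CB", "SWFS"], 5)
  # tied-symmetric entries are forced equal
  scs <- scenario_catalog()$symmetric_3pop
  cfg2 <- sim_config(3, theta = 10,
                     M = matrix(c(0, 1, 2, 3, 0, 4, 5, 6, 0), 3, 3),
                     samples_per_deme = 5, n_loci = 2)
  Ms <- gagconnect:::masked_M(cfg2, scs)
  expect_equal(Ms[1, 2], Ms[2, 1])
  expect_equal(Ms[1, 3], Ms[3, 1])
  bp <- gagconnect:::scenario_build(sc1, c(30, 10, 10, 8, 8, 8, 8))
  expect_equal(bp$theta, c(30, 10, 10))
  expect_equal(bp$M["SWFS", "CB"], 0)
})

test_that("Bayes factors follow the >150 decision rule", {
  expect_equal(bayes_factor(0.5, 0.5)$bf, 1)
  expect_equal(bayes_factor(0.5, 0.5)$support, "none")
  expect_equal(bayes_factor(151, 1)$support, "very strong")
  expect_equal(bayes_factor(150, 1)$support, "none")
  a <- bayes_factor(0.9, 0.003); b <- bayes_factor(0.003, 0.9)
  expect_equal(a$bf, 1 / b$bf)
  z <- bayes_factor(0.1, 0)
  expect_true(is.infinite(z$bf))
  expect_match(z$flagged, "zero evidence")
})

test_that("migrant numbers derive linearly from theta and M", {
  expect_equal(nm_from_theta_M(8, 10), 20)
  expect_equal(nm_from_theta_M(8, 0), 0)
  expect_equal(nm_from_theta_M(16, 10), 2 * nm_from_theta_M(8, 10))
  expect_equal(nm_from_theta_M(8, 20), 2 * nm_from_theta_M(8, 10))
  expect_error(nm_from_theta_M(-1, 1), "non-negative")
})

test_that("inference summaries are deterministic with a stable layout", {
  set.seed(601)
  g <- sample_null_frequencies(random_base_freqs(6, 6), 0, c(30, 30, 30))
  s1 <- summarize_for_inference(g)
  s2 <- summarize_for_inference(g)
  expect_identical(s1, s2)
  g2 <- sample_null_frequencies(random_base_freqs(6, 8), 0, c(25, 25, 25))
  expect_identical(names(s1), names(summarize_for_inference(g2)))
  # identical demes: pairwise differentiation entries near zero
  expect_true(all(abs(s1[grep("^fst_", names(s1))]) < 0.05))
  # heavily missing loci are dropped with a warning
  g$calls[, 1, ] <- NA_integer_
  expect_warning(s3 <- summarize_for_inference(g), "dropped")
  expect_identical(names(s3), names(s1))
})

test_that("summary-vector pairwise F_ST equals the reference estimator", {
  set.seed(605)
  g <- sample_null_frequencies(random_base_freqs(5, 6), 0.03, c(30, 30, 30))
  s <- summarize_for_inference(g)
  for (pair in list(c("CB", "SWFS"), c("CB", "NWFS"), c("NWFS", "SWFS"))) {
    ref <- weir_cockerham_fst(g, demes = pair)$value
    got <- s[intersect(grep(pair[1], names(s)), grep(pair[2], names(s)))]
    got <- got[grep("^fst_", names(got))]
    expect_equal(unname(got), ref, tolerance = 1e-12)
  }
})

test_that("asymmetric gene flow leaves the expected diversity footprint", {
  set.seed(602)
  # CB -> WFS one-way flow: the sink inherits source diversity
  sc <- scenario_catalog()$cb_to_wfs
  theta <- c(30, 3)
  M <- matrix(c(0, 20, 0, 0), 2, 2, byrow = TRUE)  # CB row -> WFS column
  he_sink <- he_src <- he_iso <- numeric(25)
  for (i in 1:25) {
    g <- simulate_microsats(sim_config(2, theta = theta, M = M,
                                       samples_per_deme = 25, n_loci = 6),
                            scenario = sc)
    s <- summarize_for_inference(g)
    he_src[i] <- s[["He_CB"]]; he_sink[i] <- s[["He_WFS"]]
    gi <- simulate_microsats(sim_config(1, theta = 3, samples_per_deme = 25,
                                        n_loci = 6))
    he_iso[i] <- summarize_for_inference(gi)[["He_GOM"]]
  }
  expect_gt(mean(he_sink), mean(he_iso))       # flow props the sink up
  expect_lt(abs(mean(he_sink) - mean(he_src)), 0.12)
})

test_that("rank_models orders by evidence and reports support", {
  sc <- scenario_catalog()
  fake_fit <- function(name, dists) {
    structure(list(scenario = sc[[name]], distances = dists,
                   n_sims = length(dists)), class = "migration_fit")
  }
  set.seed(603)
  f_good <- fake_fit("scenario_1", c(runif(900, 0.01, 1), runif(100, 5, 9)))
  f_bad <- fake_fit("scenario_3", runif(1000, 5, 9))
  rm <- rank_models(list(f_bad, f_good), tolerance_quantile = 0.01)
  expect_equal(rm$ranking$scenario[1], "scenario_1")
  expect_true(rm$all_adjacent_strong)  # 20/1000 vs 0/1000 at the tolerance
  expect_equal(sum(rm$posterior_prob), 1)
  # input order does not change the ranking
  rm2 <- rank_models(list(f_good, f_bad), tolerance_quantile = 0.01)
  expect_equal(rm2$ranking$scenario, rm$ranking$scenario)
  expect_error(rank_models(list(f_good)), "at least two")
})

test_that("single-deme ABC recovers theta inside its credible interval", {
  set.seed(604)
  pan <- scenario_catalog()$panmixia
  theta_true <- 25
  g <- simulate_microsats(sim_config(1, theta = theta_true,
                                     samples_per_deme = 40, n_loci = 8,
                                     deme_names = "GOM"))
  f <- fit_scenario(g, pan, n_loci = 8, samples_per_deme = 40,
                    n_sims = 400, accept_frac = 0.1)
  s <- f$summary[, "theta_GOM"]
  expect_true(s[["q2.5"]] <= theta_true && theta_true <= s[["q97.5"]])
  expect_true(s[["q2.5"]] <= s[["median"]] &&
                s[["median"]] <= s[["q97.5"]])
})
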