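test_that("single-deme SMM diversity matches the closed-form equilibrium", {
  set.seed(201)
  g <- simulate_microsats(sim_config(theta = 20, samples_per_deme = 85,
                                     n_loci = 200))
  he <- locus_summaries(g)$H_e
  expect_equal(mean(he), 1 - 1 / sqrt(1 + 2 * 20), tolerance = 0.02)
  # allele counts inside the observed band of real 10-locus data
  an <- locus_summaries(g)$A_n
  expect_gt(mean(an), 4); expect_lt(mean(an), 33)
})

test_that("isolated demes drift to complete sorting (F_ST -> 1)", {
  set.seed(202)
  # near-monomorphic demes forced apart: identity-based F_ST approaches 1
  cfg <- sim_config(2, theta = 0.05, M = 0, samples_per_deme = 30,
                    n_loci = 20, max_height = 5000)
  expect_warning(g <- simulate_microsats(cfg), "all-zero migration")
  expect_gt(weir_cockerham_fst(g)$value, 0.8)
})

test_that("symmetric island model reproduces coalescent F_ST expectations", {
  set.seed(203)
  k <- 3; theta <- 2
  for (Nm in c(1, 5, 20)) {
    M <- 4 * Nm / theta
    g <- simulate_microsats(sim_config(k, theta = theta, M = M,
                                       samples_per_deme = 40, n_loci = 150))
    expected <- 1 / (1 + k * theta * M)  # = 1/(1 + 4 k Nm) per deme pair
    got <- weir_cockerham_fst(g)$value
    expect_lt(abs(got - expected), max(0.3 * expected, 0.01))
  }
})

test_that("scenario-1 gene flow at Nm = 20 keeps differentiation below 0.03", {
  set.seed(204)
  sc1 <- scenario_catalog()$scenario_1
  theta <- c(30, 10, 10)
  M <- matrix(0, 3, 3)
  M[1, 2] <- M[1, 3] <- 8   # Nm = theta_sink * M / 4 = 20
  M[2, 3] <- M[3, 2] <- 8
  fsts <- replicate(10, {
    g <- simulate_microsats(sim_config(3, theta = theta, M = M,
                                       samples_per_deme = 40, n_loci = 10),
                            scenario = sc1)
    weir_cockerham_fst(g)$value
  })
  expect_lt(mean(fsts), 0.03)
})

test_that("forward drift matches 1 - exp(-t/2Ne) at shallow and deep splits", {
  set.seed(205)
  for (ratio in c(0.065, 0.7)) {
    Ne <- 400
    dv <- simulate_divergence(divergence_config(
      Ne = Ne, t_gens = round(2 * Ne * ratio), n_loci = 10,
      alleles_per_locus = 10, sample_size = 85, replicates = 40))
    se <- dv$sd / sqrt(40)
    expect_lt(abs(dv$mean - dv$expected), 3 * se + 0.01)
  }
})

test_that("an unsplit population shows no differentiation", {
  set.seed(206)
  dv <- simulate_divergence(divergence_config(Ne = 500, t_gens = 0,
                                              replicates = 10))
  expect_lt(abs(dv$mean), 0.01)
})

test_that("degenerate fixed loci are excluded from divergence F_ST", {
  set.seed(207)
  freqs <- c(replicate(3, rep(0.25, 4), simplify = FALSE), list(1))
  expect_warning(
    dv <- simulate_divergence(divergence_config(Ne = 300, t_gens = 50,
                                                initial_freqs = freqs,
                                                replicates = 3)),
    "fixed")
  expect_length(dv$fst, 3)
})

test_that("null sampling hits the requested differentiation level", {
  set.seed(208)
  bf <- random_base_freqs(8, 6)
  for (target in c(0.01, 0.05)) {
    fst <- replicate(120, weir_cockerham_fst(
      sample_null_frequencies(bf, target, c(40, 40)))$value)
    expect_lt(abs(mean(fst) - target), 3 * sd(fst) / sqrt(120) + 0.005)
  }
  fst0 <- replicate(60, weir_cockerham_fst(
    sample_null_frequencies(bf, 0, c(40, 40)))$value)
  expect_lt(abs(mean(fst0)), 0.01)
  expect_error(sample_null_frequencies(bf, 0.7, c(10, 10)), "target_fst")
})

test_that("strong differentiation yields near-certain detection", {
  set.seed(209)
  # a diallelic locus driven to expected F_ST 0.5: strong differentiation
  # on average (single realizations are drift-variable)
  # replicates where both demes fix the same allele are flagged NaN
  fst <- replicate(30, weir_cockerham_fst(
    sample_null_frequencies(list(c(0.5, 0.5)), 0.5, c(30, 30)))$value)
  expect_gt(mean(fst, na.rm = TRUE), 0.25)
})

test_that("fixed seeds reproduce simulations exactly", {
  cfg <- sim_config(2, theta = 5, M = 2, samples_per_deme = 10, n_loci = 4)
  set.seed(42); g1 <- simulate_microsats(cfg)
  set.seed(42); g2 <- simulate_microsats(cfg)
  expect_identical(g1$calls, g2$calls)
  set.seed(42); h1 <- simulate_mtdna(cfg, seq_length = 50)
  set.seed(42); h2 <- simulate_mtdna(cfg, seq_length = 50)
  expect_identical(h1$sequences, h2$sequences)
  expect_identical(h1$repeat_counts, h2$repeat_counts)
})

test_that("mtDNA simulation behaves at the degenerate and typical regimes", {
  set.seed(210)
  # all mutation rates zero: every sequence identical, S = 0
  h0 <- simulate_mtdna(sim_config(theta = 40, samples_per_deme = 20),
                       seq_length = 60, seq_rel_rate = 0,
                       indel_rel_rates = c(motif_9bp = 0, motif_40bp = 0))
  expect_equal(length(unique(h0$sequences)), 1)
  expect_equal(sequence_summaries(h0)["pooled", "S"], 0)
  # theta_mt = 10: haplotype diversity typically high
  Hs <- replicate(15, {
    h <- simulate_mtdna(sim_config(theta = 40, samples_per_deme = 50),
                        seq_length = 400)
    sequence_summaries(h, view = "sequence_plus_indels")["pooled", "H"]
  })
  expect_gt(mean(Hs), 0.75)
  expect_true(all(h0$repeat_counts >= 0) &&
                all(h0$repeat_counts[, 1] <= 7) &&
                all(h0$repeat_counts[, 2] <= 13))
})

test_that("one-deme coalescent samples are neutral (Tajima's D near zero)", {
  set.seed(211)
  Ds <- replicate(60, {
    h <- simulate_mtdna(sim_config(theta = 20, samples_per_deme = 30),
                        seq_length = 300)
    sequence_summaries(h)["pooled", "D"]
  })
  Ds <- Ds[!is.na(Ds)]
  expect_lt(abs(mean(Ds)), 3 * sd(Ds) / sqrt(length(Ds)) + 0.05)
})
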