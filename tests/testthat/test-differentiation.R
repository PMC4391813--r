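test_that("Weir-Cockerham F_ST equals an independent arithmetic oracle", {
  set.seed(401)
  for (i in 1:5) {
    g <- tiny_genotypes(lapply(1:8, function(j)
      sample.int(4, 4, replace = TRUE)), rep(c("A", "B"), each = 4))
    expect_equal(weir_cockerham_fst(g)$value, oracle_wc_fst(g),
                 tolerance = 1e-12)
  }
  # three demes, missing data
  g3 <- tiny_genotypes(c(lapply(1:9, function(j)
    sample.int(5, 6, replace = TRUE)), list(c(NA, NA, 1, 2, 2, 3))),
    rep(c("A", "B", "C"), times = c(4, 3, 3)))
  expect_equal(weir_cockerham_fst(g3)$value, oracle_wc_fst(g3),
               tolerance = 1e-12)
})

test_that("F_ST hits the boundary cases", {
  # demes fixed for different alleles
  g <- tiny_genotypes(list(c(1, 1), c(1, 1), c(2, 2), c(2, 2)),
                      rep(c("A", "B"), each = 2))
  expect_equal(weir_cockerham_fst(g)$value, 1)
  # identical demes: estimate near zero, may be negative
  set.seed(402)
  g0 <- sample_null_frequencies(random_base_freqs(5, 5), 0, c(60, 60))
  v <- weir_cockerham_fst(g0)$value
  expect_lt(abs(v), 0.05)
  # permutation p-value is non-significant under the null
  p <- weir_cockerham_fst(g0, permutations = 99)$p_value
  expect_gt(p, 0.01)
})

test_that("per-locus components average to the multilocus estimate", {
  set.seed(403)
  g <- sample_null_frequencies(random_base_freqs(6, 5), 0.05, c(40, 40))
  r <- weir_cockerham_fst(g)
  expect_length(r$per_locus, 6)
  expect_true(all(is.finite(r$per_locus)))
})

test_that("phi_ST matches a hand AMOVA on a tiny configuration", {
  # two demes, each fixed for its own haplotype at distance 1
  hs <- tiny_haps(c("A", "A", "T", "T"), c("X", "X", "Y", "Y"))
  r <- phi_st(hs, permutations = 0)
  expect_equal(r$value, 1)
  # hand-computed mixed case: demes {A,T} and {T,T}
  hs2 <- tiny_haps(c("A", "T", "T", "T"), c("X", "X", "Y", "Y"))
  d <- pairwise_steps(hs2, "sequence_plus_indels")$total
  ssd_t <- sum(d[upper.tri(d)]) / 4
  ssd_w <- (d[1, 2] / 2 + d[3, 4] / 2)
  ms_a <- (ssd_t - ssd_w) / 1; ms_w <- ssd_w / 2
  sig_a <- (ms_a - ms_w) / 2
  expect_equal(phi_st(hs2, permutations = 0)$value,
               sig_a / (sig_a + ms_w))
  # identical sequences everywhere: flagged undefined
  hs3 <- tiny_haps(c("A", "A", "A", "A"), c("X", "X", "Y", "Y"))
  expect_true(is.na(phi_st(hs3, permutations = 0)$value))
})

test_that("phi_ST is calibrated under label permutation", {
  set.seed(404)
  h <- simulate_mtdna(sim_config(theta = 20, samples_per_deme = 30),
                      seq_length = 200)
  ps <- replicate(40, {
    h$labels <- factor(sample(rep(c("X", "Y"), each = 15)))
    phi_st(h, permutations = 60)$p_value
  })
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps < 0.05), 0.2)
})

test_that("phi'_ST standardization inflates F_ST and hits 1 at fixation", {
  g <- tiny_genotypes(list(c(1, 1), c(1, 1), c(2, 2), c(2, 2)),
                      rep(c("A", "B"), each = 2))
  expect_equal(standardized_phi_prime(g)$value, 1)
  set.seed(405)
  gm <- sample_null_frequencies(random_base_freqs(8, 12), 0.03, c(50, 50))
  r <- standardized_phi_prime(gm)
  expect_gt(r$value, r$fst)     # standardization inflates
  expect_lt(r$fst_max, 1 + 1e-9)
  # null data: phi' may be negative, reported as computed
  g0 <- sample_null_frequencies(random_base_freqs(8, 12), 0, c(50, 50))
  r0 <- standardized_phi_prime(g0)
  expect_true(is.finite(r0$value))
  expect_lt(r0$value, 0.05)
})

test_that("combined chi-squared test matches direct computation", {
  # CB 10/90 vs WFS 30/70 allele copies at a diallelic locus
  tab <- matrix(c(10, 90, 30, 70), 2, byrow = FALSE)
  ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  # 100 copies per deme as 50 homozygous diploids each
  g <- tiny_genotypes(c(rep(list(c(1, 1)), 5), rep(list(c(2, 2)), 45),
                        rep(list(c(1, 1)), 15), rep(list(c(2, 2)), 35)),
                      rep(c("CB", "WFS"), each = 50))
  ct <- chifish_combined_test(g)
  expect_equal(ct$chisq, unname(ref$statistic))
  expect_equal(ct$df, 1)
  expect_equal(ct$p, ref$p.value)
})

test_that("identical allele counts give zero chi-squared and p = 1", {
  g <- tiny_genotypes(list(c(1, 2), c(1, 2)), c("A", "B"))
  ct <- chifish_combined_test(g)
  expect_equal(ct$chisq, 0)
  expect_equal(ct$p, 1)
})

test_that("rare-allele pooling keeps expected counts honest", {
  set.seed(406)
  rows <- c(rep(list(c(1, 1)), 30), rep(list(c(2, 2)), 29), list(c(3, 7)))
  g <- tiny_genotypes(rows[sample(60)], rep(c("A", "B"), each = 30))
  ct_pool <- chifish_combined_test(g, pool_rare = TRUE)
  ct_raw <- chifish_combined_test(g, pool_rare = FALSE)
  expect_lt(ct_pool$df, ct_raw$df)
  expect_true(is.finite(ct_pool$p))
})

test_that("exact differentiation test agrees with full enumeration", {
  # 2x2 diagonal table: exact two-sided p = 0.1
  t1 <- matrix(c(3L, 0L, 0L, 3L), 2)
  r1 <- exact_differentiation_test(t1, mc = list(dememorization = 5000,
                                                 batches = 100,
                                                 iterations = 500))
  expect_lt(abs(r1$p - 0.1), 0.02)
  expect_equal(oracle_exact_p(t1), 0.1, tolerance = 1e-9)
  # identical columns: the observed table is modal, p = 1
  t2 <- matrix(c(2L, 3L, 2L, 3L), 2)
  r2 <- exact_differentiation_test(t2, mc = list(dememorization = 2000,
                                                 batches = 50,
                                                 iterations = 200))
  expect_equal(r2$p, 1)
  # random 3x3 tables with n = 20: chain vs enumeration within 3 SE
  set.seed(407)
  for (i in 1:3) {
    tab <- matrix(rmultinom(1, 20, rep(1 / 9, 9)), 3)
    r <- exact_differentiation_test(tab, mc = list(dememorization = 5000,
                                                   batches = 100,
                                                   iterations = 500))
    expect_lt(abs(r$p - oracle_exact_p(tab)), 3 * max(r$se, 0.01))
  }
  # degenerate margins
  t3 <- matrix(c(4L, 0L, 3L, 0L), 2)
  expect_equal(exact_differentiation_test(t3)$p, 1)
})

test_that("multilocus exact p-values combine by Fisher's method", {
  set.seed(408)
  g <- sample_null_frequencies(random_base_freqs(4, 4), 0, c(30, 30))
  r <- exact_differentiation_test(g, mc = list(dememorization = 1000,
                                               batches = 20,
                                               iterations = 100))
  expect_equal(r$df, 8)
  expect_equal(r$p,
               pchisq(-2 * sum(log(pmax(r$per_locus$p, 1e-12))), 8,
                      lower.tail = FALSE))
})

test_that("power rises monotonically with target differentiation", {
  set.seed(409)
  bf <- random_base_freqs(6, 5)
  pw <- power_simulation(bf, c(0, 0.02, 0.1), c(40, 40), n_datasets = 40)
  chi <- pw[pw$test == "chisq", ]
  expect_lte(chi$rate[chi$level == 0], 0.05 + 2 * sqrt(0.05 * 0.95 / 40))
  expect_lte(chi$rate[chi$level == 0], chi$rate[chi$level == 0.1])
  expect_gt(chi$rate[chi$level == 0.1], 0.9)
})

test_that("the minimum spanning network matches brute force and flags ties", {
  # symmetric triangle: three haplotypes at mutual distance 1
  hs <- tiny_haps(c("A", "C", "T"))
  net <- minimum_spanning_network(hs, view = "sequence_only")
  expect_equal(sum(net$edges$in_tree), 2)
  expect_equal(sum(net$edges$alternative), 1)
  # brute-force MST weight on random recoded haplotype sets
  set.seed(410)
  for (i in 1:3) {
    seqs <- replicate(6, paste(sample(c("A", "C", "T"), 12, replace = TRUE),
                               collapse = ""))
    hs <- tiny_haps(seqs)
    if (length(unique(seqs)) < 3) next
    net <- minimum_spanning_network(hs, view = "sequence_only")
    d <- pairwise_steps(subset_haplotypes(hs, !duplicated(seqs)),
                        "sequence_only")$total
    expect_equal(sum(net$edges$steps[net$edges$in_tree]),
                 oracle_mst_weight(d))
  }
})

test_that("MST weight matches igraph on larger random instances", {
  skip_if_not_installed("igraph")
  set.seed(411)
  for (i in 1:3) {
    seqs <- replicate(20, paste(sample(c("A", "C", "G", "T"), 25,
                                       replace = TRUE), collapse = ""))
    hs <- tiny_haps(seqs)
    net <- minimum_spanning_network(hs, view = "sequence_only")
    d <- pairwise_steps(subset_haplotypes(hs, !duplicated(seqs)),
                        "sequence_only")$total
    gr <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                              weighted = TRUE)
    w <- sum(igraph::E(igraph::mst(gr))$weight)
    expect_equal(sum(net$edges$steps[net$edges$in_tree]), w)
  }
})

test_that("network edges decompose into base and repeat steps", {
  # identical sequence, 40-bp copy numbers 3 vs 5: one path of 2 indel steps
  hs <- tiny_haps(c("ACGT", "ACGT"), counts = cbind(motif_9bp = c(2L, 2L),
                                                    motif_40bp = c(3L, 5L)),
                  motif_max = c(7L, 13L))
  net <- minimum_spanning_network(hs, view = "sequence_plus_indels")
  expect_equal(nrow(net$nodes), 2)
  expect_equal(net$edges$steps, 2)
  expect_equal(net$edges$motif_40bp, 2)
  expect_equal(net$edges$motif_9bp, 0)
  expect_equal(net$edges$base, 0)
  # node frequencies sum to the sample size
  expect_equal(sum(net$nodes$frequency), 2)
  dot <- network_to_dot(net)
  expect_true(any(grepl("--", dot)))
})
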