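#' Simulation configuration for the structured coalescent generator
#'
#' Parameters follow the mutation-scaled convention of coalescent migration
#' inference: per-deme `theta = 4*Ne*mu` and migration matrix `M = m/mu`
#' oriented row -> column = direction of gene flow (so `M[s, d]` scales
#' immigration into deme `d` from deme `s`), with `Nm = theta * M / 4`
#' effective migrants per generation into the recipient deme.
#'
#' @param n_demes number of demes.
#' @param theta mutation-scaled deme size(s), recycled to `n_demes`.
#' @param M `n_demes x n_demes` migration matrix (diagonal ignored); a
#'   scalar fills every off-diagonal entry.
#' @param samples_per_deme diploid individuals sampled per deme, recycled.
#' @param n_loci number of microsatellite loci.
#' @param mutation_model `"SMM"` (strict stepwise) or `"TPM"` (two-phase:
#'   single steps with probability `p_single`, otherwise geometric
#'   multi-step jumps with mean `geom_mean`).
#' @param p_single,geom_mean TPM parameters.
#' @param deme_names deme labels; defaults to the Gulf-of-Mexico naming
#'   (GOM; CB/WFS; CB/SWFS/NWFS) for 1-3 demes.
#' @param max_height hard cap on genealogy height (mutational units),
#'   applied when migration cannot connect all demes.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_demes = 1, theta = 10, M = 0,
                       samples_per_deme = 85, n_loci = 10,
                       mutation_model = c("SMM", "TPM"),
                       p_single = 0.9, geom_mean = 2,
                       deme_names = NULL, max_height = 1e4) {
  mutation_model <- match.arg(mutation_model)
  k <- as.integer(n_demes)
  theta <- rep_len(theta, k)
  samples_per_deme <- rep_len(as.integer(samples_per_deme), k)
  if (length(M) == 1) {
    Mm <- matrix(as.numeric(M), k, k); diag(Mm) <- 0
  } else {
    Mm <- as.matrix(M)
    if (!all(dim(Mm) == k)) stop("config error: M must be ", k, "x", k)
  }
  if (any(theta < 0) || any(Mm < 0) || any(samples_per_deme < 1))
    stop("config error: theta and M must be non-negative, samples positive")
  if (is.null(deme_names))
    deme_names <- switch(as.character(k),
                         "1" = "GOM", "2" = c("CB", "WFS"),
                         "3" = c("CB", "SWFS", "NWFS"),
                         paste0("deme", seq_len(k)))
  dimnames(Mm) <- list(deme_names, deme_names)
  structure(list(n_demes = k, theta = theta, M = Mm,
                 samples_per_deme = samples_per_deme, n_loci = n_loci,
                 mutation_model = mutation_model, p_single = p_single,
                 geom_mean = geom_mean, deme_names = deme_names,
                 max_height = max_height),
            class = "sim_config")
}

# effective migration matrix after applying a scenario mask
masked_M <- function(cfg, scenario = NULL) {
  M <- cfg$M
  if (!is.null(scenario)) {
    if (scenario$k != cfg$n_demes)
      stop("config error: scenario has ", scenario$k, " demes, config ",
           cfg$n_demes)
    M[scenario$mask == "zero"] <- 0
    sym <- scenario$mask == "sym"
    if (any(sym)) {
      for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M)))
        if (i < j && sym[i, j]) M[j, i] <- M[i, j]
    }
  }
  diag(M) <- 0
  M
}

#' Simulate multilocus microsatellite genotypes
#'
#' Draws one structured-coalescent genealogy per locus under the
#' configuration's theta/M (optionally masked by a migration scenario) and
#' mutates repeat counts down the tree under the stepwise or two-phase
#' model. Allele codes are repeat counts anchored at 100.
#'
#' @param cfg a [sim_config()].
#' @param scenario optional [migration_scenario()] whose mask zeroes or
#'   symmetrizes entries of `cfg$M`.
#' @return a [genotype_matrix()] labelled by deme.
#' @examples
#' set.seed(1)
#' g <- simulate_microsats(sim_config(theta = 20, samples_per_deme = 30,
#'                                    n_loci = 5))
#' locus_summaries(g)
#' @export
simulate_microsats <- function(cfg, scenario = NULL) {
  M <- masked_M(cfg, scenario)
  if (cfg$n_demes > 1 && all(M == 0))
    warning("all-zero migration with >1 deme: genealogy height capped at ",
            cfg$max_height, " (demes cannot share ancestry)")
  copies <- 2L * cfg$samples_per_deme
  steps <- cpp_microsat_sim(copies, cfg$theta, M, cfg$n_loci,
                            if (cfg$mutation_model == "TPM") 1L else 0L,
                            cfg$p_single, cfg$geom_mean, cfg$max_height)
  codes <- pmax(steps + 100L, 1L)
  n_ind <- sum(cfg$samples_per_deme)
  calls <- array(NA_integer_, dim = c(n_ind, cfg$n_loci, 2))
  calls[, , 1] <- codes[seq(1, 2 * n_ind, by = 2), , drop = FALSE]
  calls[, , 2] <- codes[seq(2, 2 * n_ind, by = 2), , drop = FALSE]
  pop <- rep(cfg$deme_names, cfg$samples_per_deme)
  genotype_matrix(calls, paste0(rep(cfg$deme_names, cfg$samples_per_deme),
                                "_", unlist(lapply(cfg$samples_per_deme, seq_len))),
                  paste0("loc", seq_len(cfg$n_loci)), pop)
}

#' Simulate mtDNA control-region haplotypes with repeat-indel loci
#'
#' One genealogy (no recombination) is shared by the sequence and both
#' repeat loci. The sequence evolves under an equal-rates finite-sites
#' model at total rate 1 per lineage per mutational time unit (so the
#' per-deme mtDNA theta sets expected pairwise differences); each repeat
#' locus performs a +/-1 copy-number walk, bounded at `[0, max]`, at the
#' given rate relative to the sequence rate.
#'
#' @param cfg a [sim_config()]; `theta` is the nuclear value, scaled by
#'   `mt_scale` (haploid, maternal inheritance).
#' @param scenario optional [migration_scenario()].
#' @param seq_length aligned sites.
#' @param indel_rel_rates per-motif mutation rates relative to the whole
#'   sequence rate.
#' @param motif_max copy-number maxima (9-bp motif 7, 40-bp motif 13).
#' @param mt_scale multiplier taking nuclear theta to mtDNA theta
#'   (default 1/4: haploid and maternally inherited).
#' @param seq_rel_rate whole-sequence substitution rate relative to the
#'   unit rate implied by theta (0 switches substitutions off).
#' @return a [haplotype_set()] with `repeat_counts`; one sequence per
#'   sampled individual, labelled by deme.
#' @export
simulate_mtdna <- function(cfg, scenario = NULL, seq_length = 536,
                           indel_rel_rates = c(motif_9bp = 0.015,
                                               motif_40bp = 0.015),
                           motif_max = c(motif_9bp = 7L, motif_40bp = 13L),
                           mt_scale = 0.25, seq_rel_rate = 1) {
  if (seq_length <= 0) stop("config error: seq_length must be positive")
  M <- masked_M(cfg, scenario)
  gen <- cpp_genealogy(cfg$samples_per_deme, cfg$theta * mt_scale, M,
                       cfg$max_height)
  n <- length(gen$tip_deme)
  nn <- 2 * n - 1
  parent <- gen$parent + 1L  # 1-based; root parent = 0
  seqmat <- matrix(0L, nn, seq_length)
  seqmat[nn, ] <- sample.int(4, seq_length, replace = TRUE)
  nrep <- length(motif_max)
  repmat <- matrix(0L, nn, nrep)
  repmat[nn, ] <- as.integer(round(motif_max / 2))
  for (v in seq(nn - 1, 1)) {
    p <- parent[v]
    seqmat[v, ] <- seqmat[p, ]
    nmut <- rpois(1, gen$blen[v] * seq_rel_rate)
    if (nmut > 0) {
      sites <- sample.int(seq_length, nmut, replace = TRUE)
      for (s in sites)
        seqmat[v, s] <- sample(setdiff(1:4, seqmat[v, s]), 1)
    }
    for (m in seq_len(nrep)) {
      x <- repmat[p, m]
      nr <- rpois(1, gen$blen[v] * indel_rel_rates[m])
      if (nr > 0)
        for (i in seq_len(nr)) {
          x <- x + sample(c(-1L, 1L), 1)
          x <- min(max(x, 0L), as.integer(motif_max[m]))
        }
      repmat[v, m] <- x
    }
  }
  bases <- c("A", "C", "G", "T")
  seqs <- apply(seqmat[seq_len(n), , drop = FALSE], 1,
                function(r) paste(bases[r], collapse = ""))
  demes <- cfg$deme_names[gen$tip_deme + 1L]
  names(seqs) <- paste0(demes, "_", stats::ave(seq_len(n), demes,
                                               FUN = seq_along))
  counts <- repmat[seq_len(n), , drop = FALSE]
  colnames(counts) <- names(motif_max)
  haplotype_set(seqs, demes, counts, motif_max = as.integer(motif_max))
}

#' Embed literal repeat arrays into simulated haplotypes
#'
#' Reconstructs raw-style sequences in which the repeat-count loci appear as
#' literal tandem motif arrays inserted at fixed positions — the form
#' [recode_indels()] consumes — so generator output can exercise the
#' recoding path end to end.
#'
#' @param hs a [haplotype_set()] with `repeat_counts`.
#' @param motifs motif descriptors as in [control_region_motifs()].
#' @param at 1-based insertion positions within the sequence, one per motif,
#'   in increasing order.
#' @return named character vector of raw sequences (unequal lengths when
#'   copy numbers differ).
#' @export
embed_repeats <- function(hs, motifs = control_region_motifs(), at = NULL) {
  if (is.null(hs$repeat_counts)) stop("haplotype set has no repeat counts")
  L <- nchar(hs$sequences[1])
  if (is.null(at))
    at <- round(L * seq_along(motifs) / (length(motifs) + 1))
  at <- sort(at)
  out <- hs$sequences
  for (i in seq_along(out)) {
    s <- out[i]; shift <- 0L
    for (m in seq_along(motifs)) {
      arr <- strrep(motifs[[m]]$motif, hs$repeat_counts[i, m])
      pos <- at[m] + shift
      s <- paste0(substr(s, 1, pos - 1), arr, substr(s, pos, nchar(s)))
      shift <- shift + nchar(arr)
    }
    out[i] <- s
  }
  out
}

#' Forward-drift divergence experiment configuration
#'
#' Two daughter populations drift independently from shared ancestral
#' allele frequencies with no migration; after `t_gens` generations of
#' multinomial Wright-Fisher resampling, diploid samples are drawn and
#' multilocus Weir-Cockerham F_ST is computed. Under pure drift the
#' expectation is `1 - exp(-t / (2 Ne))`.
#'
#' @param Ne diploid effective size of each daughter population.
#' @param t_gens generations since the split.
#' @param n_loci,alleles_per_locus locus count and alleles per locus.
#' @param initial_freqs optional list of per-locus frequency vectors
#'   (default: equifrequent `alleles_per_locus` alleles).
#' @param mutation_rate per-locus per-generation rate toward a uniform
#'   allele (default 0: pure drift).
#' @param sample_size diploids sampled per population.
#' @param replicates independent replicates.
#' @return object of class `divergence_config`.
#' @export
divergence_config <- function(Ne = 10000, t_gens = 1300, n_loci = 10,
                              alleles_per_locus = 10, initial_freqs = NULL,
                              mutation_rate = 0, sample_size = 85,
                              replicates = 100) {
  if (Ne <= 0 || t_gens < 0) stop("config error: Ne and t_gens must be positive")
  if (is.null(initial_freqs))
    initial_freqs <- replicate(n_loci,
                               rep(1 / alleles_per_locus, alleles_per_locus),
                               simplify = FALSE)
  sums <- vapply(initial_freqs, sum, 0)
  if (any(abs(sums - 1) > 1e-8))
    stop("config error: initial frequencies must sum to 1 at every locus")
  structure(list(Ne = Ne, t_gens = as.integer(t_gens),
                 n_loci = length(initial_freqs),
                 initial_freqs = initial_freqs,
                 mutation_rate = mutation_rate,
                 sample_size = as.integer(sample_size),
                 replicates = as.integer(replicates)),
            class = "divergence_config")
}

# HWE diploid sample of `n` individuals at one locus from frequencies p
sample_genotypes_hwe <- function(p, n) {
  copies <- sample(rep.int(seq_along(p), rmultinom(1, 2 * n, p)[, 1]))
  cbind(copies[seq_len(n)], copies[n + seq_len(n)])
}

#' Forward-drift divergence simulation
#'
#' @param cfg a [divergence_config()].
#' @return list with `fst` (per-replicate multilocus Weir-Cockerham F_ST),
#'   `mean`, `sd`, and the drift expectation `expected = 1 - exp(-t/2Ne)`.
#' @examples
#' set.seed(42)
#' simulate_divergence(divergence_config(Ne = 500, t_gens = 100,
#'                                       replicates = 5))$mean
#' @export
simulate_divergence <- function(cfg) {
  fixed <- vapply(cfg$initial_freqs, function(p) sum(p > 0) < 2, TRUE)
  if (any(fixed)) {
    warning(sum(fixed), " fixed locus/loci excluded from F_ST")
    cfg$initial_freqs <- cfg$initial_freqs[!fixed]
    cfg$n_loci <- length(cfg$initial_freqs)
  }
  K <- max(vapply(cfg$initial_freqs, length, 0L))
  init <- vapply(cfg$initial_freqs, function(p) c(p, rep(0, K - length(p))),
                 numeric(K))
  fst <- vapply(seq_len(cfg$replicates), function(r) {
    fr <- lapply(1:2, function(pop) {
      f <- cpp_drift_freqs(init, 2L * cfg$Ne, cfg$t_gens)
      if (cfg$mutation_rate > 0)
        f <- f * (1 - cfg$mutation_rate) + cfg$mutation_rate / K
      f
    })
    n <- cfg$sample_size
    calls <- array(NA_integer_, dim = c(2 * n, cfg$n_loci, 2))
    for (pop in 1:2) for (l in seq_len(cfg$n_loci)) {
      gt <- sample_genotypes_hwe(fr[[pop]][, l], n)
      calls[(pop - 1) * n + seq_len(n), l, ] <- gt
    }
    g <- genotype_matrix(calls, paste0("i", seq_len(2 * n)),
                         paste0("loc", seq_len(cfg$n_loci)),
                         rep(c("A", "B"), each = n))
    weir_cockerham_fst(g, permutations = 0)$value
  }, 0)
  list(fst = fst, mean = mean(fst), sd = sd(fst),
       expected = 1 - exp(-cfg$t_gens / (2 * cfg$Ne)))
}

#' Random polymorphic base frequencies
#'
#' Dirichlet draws, one frequency vector per locus, used as the ancestral
#' allele pool for null and power simulations.
#'
#' @param n_loci loci.
#' @param n_alleles alleles per locus.
#' @param alpha Dirichlet concentration (1 = flat).
#' @return list of frequency vectors.
#' @export
random_base_freqs <- function(n_loci = 10, n_alleles = 8, alpha = 1) {
  replicate(n_loci, {
    x <- stats::rgamma(n_alleles, alpha)
    x / sum(x)
  }, simplify = FALSE)
}

#' Sample genotype datasets at a controlled differentiation level
#'
#' Generates deme samples whose expected Weir-Cockerham F_ST equals
#' `target_fst`: each deme drifts independently from the shared base
#' frequencies for `t` generations in a population of `2N` gene copies,
#' with `t` chosen so that `1 - (1 - 1/2N)^t = target_fst`;
#' `target_fst = 0` samples all demes directly from the base frequencies.
#' Genotypes are in Hardy-Weinberg proportions within demes.
#'
#' @param base_freqs list of per-locus allele frequency vectors.
#' @param target_fst expected differentiation, in `[0, 0.5]`.
#' @param samples_per_deme diploid sample sizes (length = number of demes).
#' @param Ne drift population size used to reach the target.
#' @param deme_names optional labels.
#' @return a [genotype_matrix()].
#' @export
sample_null_frequencies <- function(base_freqs, target_fst = 0,
                                    samples_per_deme = c(85, 85, 85),
                                    Ne = 2000, deme_names = NULL) {
  if (target_fst < 0 || target_fst > 0.5)
    stop("config error: target_fst must be in [0, 0.5]")
  k <- length(samples_per_deme)
  if (is.null(deme_names))
    deme_names <- switch(as.character(k), "1" = "GOM", "2" = c("CB", "WFS"),
                         "3" = c("CB", "SWFS", "NWFS"),
                         paste0("deme", seq_len(k)))
  K <- max(vapply(base_freqs, length, 0L))
  init <- vapply(base_freqs, function(p) c(p, rep(0, K - length(p))),
                 numeric(K))
  t_gens <- if (target_fst == 0) 0L else
    as.integer(round(log(1 - target_fst) / log(1 - 1 / (2 * Ne))))
  L <- length(base_freqs)
  n_tot <- sum(samples_per_deme)
  calls <- array(NA_integer_, dim = c(n_tot, L, 2))
  row0 <- 0L
  for (d in seq_len(k)) {
    f <- if (t_gens > 0) cpp_drift_freqs(init, 2L * Ne, t_gens) else init
    n <- samples_per_deme[d]
    for (l in seq_len(L)) {
      p <- f[, l]
      if (sum(p) <= 0) p <- init[, l]
      calls[row0 + seq_len(n), l, ] <- sample_genotypes_hwe(p / sum(p), n)
    }
    row0 <- row0 + n
  }
  genotype_matrix(calls, paste0("i", seq_len(n_tot)),
                  paste0("loc", seq_len(L)),
                  rep(deme_names, samples_per_deme))
}
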