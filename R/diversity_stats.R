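#' Per-locus, per-deme diversity summaries
#'
#' Allele richness, observed and unbiased expected heterozygosity, and the
#' inbreeding coefficient for every locus in every deme of the active
#' grouping scheme. `H_e` uses the sample-size-corrected (unbiased)
#' estimator `n/(n-1) * (1 - sum p^2)` on allele copies; `F_IS = 1 -
#' H_o/H_e`, undefined (NA, flagged) at monomorphic loci.
#'
#' @param g a [genotype_matrix()].
#' @param scheme optional [grouping_scheme()].
#' @return data frame with columns deme, locus, n (allele copies), A_n,
#'   H_o, H_e, F_IS, monomorphic.
#' @export
locus_summaries <- function(g, scheme = NULL) {
  demes <- deme_of(g, scheme)
  out <- list()
  for (d in levels(demes)) {
    rows <- which(demes == d)
    for (l in seq_along(g$loci)) {
      a1 <- g$calls[rows, l, 1]; a2 <- g$calls[rows, l, 2]
      ok <- !is.na(a1)
      n <- 2 * sum(ok)
      if (n == 0) next
      alleles <- c(a1[ok], a2[ok])
      p <- tabulate(factor(alleles)) / n
      p <- p[p > 0]
      He <- if (n > 1) n / (n - 1) * (1 - sum(p^2)) else 0
      Ho <- mean(a1[ok] != a2[ok])
      out[[length(out) + 1]] <- data.frame(
        deme = d, locus = g$loci[l], n = n, A_n = length(p),
        H_o = Ho, H_e = He,
        F_IS = if (He > 0) 1 - Ho / He else NA_real_,
        monomorphic = length(p) < 2, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# log-probability of a genotype table given its allele counts
# (Levene / Haldane conditional distribution): varies across tables with
# the same allele counts only through n_het and the genotype-count factorials
hwe_table_logprob <- function(gt_pairs) {
  key <- paste(pmin(gt_pairs[, 1], gt_pairs[, 2]),
               pmax(gt_pairs[, 1], gt_pairs[, 2]))
  cnt <- table(key)
  h <- sum(gt_pairs[, 1] != gt_pairs[, 2])
  h * log(2) - sum(lgamma(cnt + 1))
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Monte-Carlo estimate of the exact conditional test: genotype tables with
#' the observed allele counts are sampled by random re-pairing of the gene
#' copies, and the p-value is the probability of a table no more probable
#' than the observed one.
#'
#' @param g a [genotype_matrix()].
#' @param locus locus name or index.
#' @param scheme optional [grouping_scheme()].
#' @param reps Monte-Carlo re-pairings.
#' @return data frame per deme: p, se, n, n_alleles.
#' @export
hwe_exact_test <- function(g, locus, scheme = NULL, reps = 2000) {
  l <- if (is.character(locus)) match(locus, g$loci) else locus
  demes <- deme_of(g, scheme)
  out <- list()
  for (d in levels(demes)) {
    rows <- which(demes == d)
    a1 <- g$calls[rows, l, 1]; a2 <- g$calls[rows, l, 2]
    ok <- !is.na(a1)
    pairs <- cbind(a1[ok], a2[ok])
    k <- length(unique(c(pairs)))
    if (k < 2) {
      out[[d]] <- data.frame(deme = d, p = NA_real_, se = NA_real_,
                             n = 2 * nrow(pairs), n_alleles = k)
      next
    }
    obs <- hwe_table_logprob(pairs)
    copies <- c(pairs)
    n_ind <- nrow(pairs)
    hits <- 0L
    for (r in seq_len(reps)) {
      perm <- sample(copies)
      lp <- hwe_table_logprob(cbind(perm[seq_len(n_ind)],
                                    perm[n_ind + seq_len(n_ind)]))
      if (lp <= obs + 1e-9) hits <- hits + 1L
    }
    p <- (hits + 1) / (reps + 1)
    out[[d]] <- data.frame(deme = d, p = p, se = sqrt(p * (1 - p) / reps),
                           n = 2 * n_ind, n_alleles = k)
  }
  do.call(rbind, out)
}

#' Exact test of genotypic linkage disequilibrium
#'
#' Markov-chain exact test on the genotype-by-genotype contingency table of
#' a locus pair, per deme.
#'
#' @param g a [genotype_matrix()].
#' @param loci length-2 vector of locus names or indices.
#' @param scheme optional [grouping_scheme()].
#' @param mc chain parameters: `dememorization`, `batches`, `iterations`
#'   per batch.
#' @return data frame per deme: p, se, n.
#' @export
ld_exact_test <- function(g, loci, scheme = NULL,
                          mc = list(dememorization = 1000, batches = 50,
                                    iterations = 200)) {
  li <- vapply(loci, function(l)
    if (is.character(l)) match(l, g$loci) else as.integer(l), 0L)
  demes <- deme_of(g, scheme)
  gt_key <- function(a1, a2) paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  out <- list()
  for (d in levels(demes)) {
    rows <- which(demes == d)
    gA <- gt_key(g$calls[rows, li[1], 1], g$calls[rows, li[1], 2])
    gB <- gt_key(g$calls[rows, li[2], 1], g$calls[rows, li[2], 2])
    ok <- !grepl("NA", gA) & !grepl("NA", gB)
    tab <- table(gA[ok], gB[ok])
    res <- cpp_mc_exact(matrix(as.integer(tab), nrow(tab)),
                        mc$dememorization, mc$batches, mc$iterations)
    out[[d]] <- data.frame(deme = d, p = res$p, se = res$se, n = sum(ok))
  }
  do.call(rbind, out)
}

#' Bonferroni-corrected significance thresholds
#'
#' Plain (non-sequential) Bonferroni at the two granularities used for
#' locus-pair screening: per-locus (alpha divided by the pairwise
#' comparisons each locus enters, e.g. 0.05/9 = 0.0056 for 10 loci) and
#' global (alpha divided by all tests).
#'
#' @param alpha nominal level.
#' @param n_loci number of loci.
#' @return list with `per_locus` and `global` thresholds.
#' @export
bonferroni_alpha <- function(alpha = 0.05, n_loci = 10) {
  n_pairs <- n_loci * (n_loci - 1) / 2
  list(per_locus = alpha / (n_loci - 1), global = alpha / n_pairs)
}

# Watterson's a1 and Tajima's D variance constants
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# log unsigned Stirling numbers of the first kind, row n (k = 1..n)
log_stirling_row <- function(n) {
  lg <- c(0, rep(-Inf, n - 1))  # row 1
  if (n == 1) return(lg)
  for (m in seq_len(n - 1)) {
    new <- rep(-Inf, m + 1)
    for (k in seq_len(m + 1)) {
      a <- if (k <= m) log(m) + lg[k] else -Inf
      b <- if (k > 1) lg[k - 1] else -Inf
      hi <- pmax(a, b)
      new[k] <- ifelse(is.infinite(hi), -Inf,
                       hi + log(exp(a - hi) + exp(b - hi)))
    }
    lg <- new
  }
  lg
}

#' Fu's Fs neutrality statistic
#'
#' `Fs = ln(S'/(1-S'))` with `S' = P(K >= k_obs | theta = pi)` under the
#' Ewens sampling distribution of the number of distinct haplotypes K.
#' Negative values flag an excess of haplotypes relative to the pairwise
#' diversity, the signature of recent expansion.
#'
#' @param n sequences sampled.
#' @param k_obs observed haplotype count.
#' @param pi_hat nucleotide diversity (mean pairwise differences).
#' @return Fs, or NA (flagged) when k_obs = 1 or pi_hat = 0.
#' @export
fu_fs <- function(n, k_obs, pi_hat) {
  if (k_obs <= 1 || pi_hat <= 0 || n < 2) return(NA_real_)
  lst <- log_stirling_row(n)
  lth <- log(pi_hat)
  lp <- lst + seq_len(n) * lth
  lp <- lp - max(lp)
  p <- exp(lp) / sum(exp(lp))
  sprime <- sum(p[k_obs:n])
  if (sprime <= 0 || sprime >= 1) return(NA_real_)
  log(sprime / (1 - sprime))
}

#' Sequence diversity and neutrality summaries
#'
#' Sample size, haplotype count and diversity, segregating sites,
#' Watterson's theta, nucleotide diversity (mean pairwise differences),
#' Tajima's D and Fu's Fs, per deme and pooled, under one of the three
#' mtDNA data views (see [view_matrix()]). In the `sequence_only` view,
#' columns containing gaps are excluded; in the combined view each recoded
#' indel site counts as a standard site; in the RFLP view the repeat-count
#' loci alone define haplotypes and distances.
#'
#' @param hs a [haplotype_set()].
#' @param scheme optional [grouping_scheme()].
#' @param view data view.
#' @return data frame with columns deme, N, L, h, H, S, theta_W, pi, D, Fs.
#' @export
sequence_summaries <- function(hs, scheme = NULL,
                               view = c("sequence_only",
                                        "sequence_plus_indels",
                                        "indels_as_rflp")) {
  view <- match.arg(view)
  demes <- deme_of(hs, scheme)
  groups <- c(as.list(setNames(levels(demes), levels(demes))),
              list(pooled = levels(demes)))
  steps <- pairwise_steps(hs, view)
  key <- if (view == "indels_as_rflp")
    apply(hs$repeat_counts, 1, paste, collapse = "/")
  else apply(view_matrix(hs, view), 1, paste, collapse = "")
  L <- if (view == "indels_as_rflp") ncol(hs$repeat_counts)
       else ncol(view_matrix(hs, view))
  out <- list()
  for (gname in names(groups)) {
    idx <- which(demes %in% groups[[gname]])
    N <- length(idx)
    if (N < 2) next
    d <- steps$total[idx, idx]
    pi_hat <- mean(d[upper.tri(d)])
    kf <- table(key[idx])
    h <- length(kf)
    H <- N / (N - 1) * (1 - sum((kf / N)^2))
    S <- if (view == "indels_as_rflp")
      sum(apply(hs$repeat_counts[idx, , drop = FALSE], 2,
                function(x) length(unique(x)) > 1))
    else sum(apply(view_matrix(hs, view)[idx, , drop = FALSE], 2,
                   function(x) length(unique(x)) > 1))
    cst <- tajima_constants(N)
    theta_w <- S / cst$a1
    D <- if (S > 0)
      (pi_hat - theta_w) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
    else NA_real_
    out[[gname]] <- data.frame(
      deme = gname, N = N, L = L, h = h, H = H, S = S,
      theta_W = theta_w, pi = pi_hat, D = D,
      Fs = fu_fs(N, h, pi_hat), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
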