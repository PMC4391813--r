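#' Weir-Cockerham F_ST with permutation test
#'
#' The variance-components estimator: per-allele, per-locus components a
#' (among demes), b (among individuals within demes) and c (within
#' individuals), with the multilocus estimate `sum(a) / sum(a+b+c)`.
#' Negative estimates are reported as computed (effectively zero under the
#' null), never truncated. The permutation test shuffles individuals across
#' demes, preserving within-individual dependence.
#'
#' @param g a [genotype_matrix()].
#' @param scheme optional [grouping_scheme()].
#' @param permutations label permutations for the p-value (0 = none).
#' @param demes optional subset of demes (pairwise comparisons).
#' @return object of class `diff_result`: statistic, value, per-locus
#'   values, p_value, comparison, n_permutations.
#' @export
weir_cockerham_fst <- function(g, scheme = NULL, permutations = 0,
                               demes = NULL) {
  labs <- deme_of(g, scheme)
  if (!is.null(demes)) {
    keep <- labs %in% demes
    g <- subset_individuals(g, keep)
    labs <- factor(as.character(labs[keep]))
  }
  obs <- wc_components(g$calls, labs)
  value <- sum(obs$a) / sum(obs$a + obs$b + obs$c)
  per_locus <- obs$per_locus
  p <- NA_real_
  if (permutations > 0) {
    hits <- 0L
    for (i in seq_len(permutations)) {
      perm <- wc_components(g$calls, sample(labs))
      v <- sum(perm$a) / sum(perm$a + perm$b + perm$c)
      if (!is.na(v) && v >= value) hits <- hits + 1L
    }
    p <- (hits + 1) / (permutations + 1)
  }
  structure(list(statistic = "F_ST(WC)", value = value,
                 per_locus = per_locus, p_value = p,
                 comparison = paste(levels(labs), collapse = "/"),
                 n_permutations = permutations),
            class = "diff_result")
}

#' @export
print.diff_result <- function(x, ...) {
  cat(x$statistic, "=", format(x$value, digits = 4),
      "(", x$comparison, ")")
  if (!is.na(x$p_value)) cat(", p =", format(x$p_value, digits = 3),
                             "from", x$n_permutations, "permutations")
  cat("\n")
  invisible(x)
}

# Weir & Cockerham (1984) variance components summed over alleles and loci
wc_components <- function(calls, labs) {
  r <- nlevels(labs)
  if (r < 2) stop("need at least two demes")
  L <- dim(calls)[2]
  A <- B <- C <- numeric(L)
  for (l in seq_len(L)) {
    a1 <- calls[, l, 1]; a2 <- calls[, l, 2]
    ok <- !is.na(a1)
    if (!any(ok)) next
    dl <- droplevels(labs[ok]); x1 <- a1[ok]; x2 <- a2[ok]
    ni <- as.numeric(table(dl))
    if (length(ni) < 2) next
    nbar <- mean(ni); rl <- length(ni)
    n_tot <- sum(ni)
    nc <- (n_tot - sum(ni^2) / n_tot) / (rl - 1)
    alleles <- sort(unique(c(x1, x2)))
    if (length(alleles) < 2) next
    f1 <- factor(x1, levels = alleles); f2 <- factor(x2, levels = alleles)
    # allele-copy counts and heterozygote-carrier counts per allele x deme
    cnt <- table(f1, dl) + table(f2, dl)
    hh <- x1 != x2
    het <- table(f1[hh], dl[hh]) + table(f2[hh], dl[hh])
    p_m <- sweep(unclass(cnt), 2, 2 * ni, "/")
    h_m <- sweep(unclass(het), 2, ni, "/")
    pbar <- as.numeric(p_m %*% ni) / n_tot
    s2 <- as.numeric((p_m - pbar)^2 %*% ni) / ((rl - 1) * nbar)
    hbar <- as.numeric(h_m %*% ni) / n_tot
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (rl - 1) / rl * s2 -
                              hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (rl - 1) / rl * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    A[l] <- sum(a); B[l] <- sum(b); C[l] <- sum(cc)
  }
  denom <- A + B + C
  per_locus <- ifelse(denom > 0, A / denom, NA_real_)
  list(a = A, b = B, c = C, per_locus = per_locus)
}

#' AMOVA phi_ST on a haplotype distance matrix
#'
#' Partitions the pairwise step distances (each step a base change or an
#' indel copy-number change, per the active view) into among- and
#' within-deme variance components; `phi_ST` is the among-deme fraction.
#' The permutation test shuffles sequences across demes.
#'
#' @param hs a [haplotype_set()].
#' @param scheme optional [grouping_scheme()].
#' @param view distance mode, as in [pairwise_steps()].
#' @param permutations permutations for the p-value.
#' @param demes optional subset of demes.
#' @return a `diff_result` (per_locus is NA: single non-recombining locus).
#' @export
phi_st <- function(hs, scheme = NULL, view = "sequence_plus_indels",
                   permutations = 999, demes = NULL) {
  labs <- deme_of(hs, scheme)
  d <- pairwise_steps(hs, view)$total
  if (!is.null(demes)) {
    keep <- which(labs %in% demes)
    d <- d[keep, keep]
    labs <- factor(as.character(labs[keep]))
  }
  if (all(d == 0)) {
    return(structure(list(statistic = "phi_ST", value = NA_real_,
                          per_locus = NA_real_, p_value = NA_real_,
                          comparison = paste(levels(labs), collapse = "/"),
                          n_permutations = 0, flagged = "no variation"),
                     class = "diff_result"))
  }
  value <- amova_phi(d, labs)
  p <- NA_real_
  if (permutations > 0) {
    hits <- 0L
    for (i in seq_len(permutations)) {
      v <- amova_phi(d, sample(labs))
      if (!is.na(v) && v >= value) hits <- hits + 1L
    }
    p <- (hits + 1) / (permutations + 1)
  }
  structure(list(statistic = "phi_ST", value = value, per_locus = NA_real_,
                 p_value = p, comparison = paste(levels(labs), collapse = "/"),
                 n_permutations = permutations),
            class = "diff_result")
}

# phi_ST from AMOVA sums of squares; d holds squared inter-haplotype
# distances (pairwise step counts, the molecular-variance convention)
amova_phi <- function(d, labs) {
  N <- length(labs)
  k <- nlevels(labs)
  ssd_t <- sum(d[upper.tri(d)]) / N
  ssd_w <- 0
  for (g in levels(labs)) {
    i <- which(labs == g)
    if (length(i) > 1)
      ssd_w <- ssd_w + sum(d[i, i][upper.tri(d[i, i])]) / length(i)
  }
  ssd_a <- ssd_t - ssd_w
  df_a <- k - 1; df_w <- N - k
  if (df_w <= 0) return(NA_real_)
  ms_a <- ssd_a / df_a; ms_w <- ssd_w / df_w
  ni <- as.numeric(table(labs))
  n0 <- (N - sum(ni^2) / N) / df_a
  sig_a <- (ms_a - ms_w) / n0
  sig_a / (sig_a + ms_w)
}

#' Standardized phi'_ST for high-heterozygosity markers
#'
#' `phi'_ST = F_ST / F_ST(max)`, where the maximum is the Weir-Cockerham
#' estimate on a recoded dataset in which every deme's alleles are made
#' deme-private (the maximal differentiation attainable given within-deme
#' diversity). Compensates for the downward bias of F_ST at
#' high-heterozygosity microsatellites. Negative values (null datasets) are
#' reported as computed and read as zero.
#'
#' @inheritParams weir_cockerham_fst
#' @return a `diff_result` with `fst` and `fst_max` attached.
#' @export
standardized_phi_prime <- function(g, scheme = NULL, permutations = 0,
                                   demes = NULL) {
  labs <- deme_of(g, scheme)
  if (!is.null(demes)) {
    keep <- labs %in% demes
    g <- subset_individuals(g, keep)
    labs <- factor(as.character(labs[keep]))
  }
  phi_of <- function(calls, labs) {
    obs <- wc_components(calls, labs)
    fst <- sum(obs$a) / sum(obs$a + obs$b + obs$c)
    mx <- wc_components(privatize_alleles(calls, labs), labs)
    fst_max <- sum(mx$a) / sum(mx$a + mx$b + mx$c)
    c(fst, fst_max)
  }
  v <- phi_of(g$calls, labs)
  if (is.na(v[2]) || v[2] == 0)
    return(structure(list(statistic = "phi'_ST", value = NA_real_,
                          per_locus = NA_real_, p_value = NA_real_,
                          comparison = paste(levels(labs), collapse = "/"),
                          n_permutations = 0, flagged = "F_ST(max) = 0"),
                     class = "diff_result"))
  value <- v[1] / v[2]
  p <- NA_real_
  if (permutations > 0) {
    hits <- 0L
    for (i in seq_len(permutations)) {
      pv <- phi_of(g$calls, sample(labs))
      if (!is.na(pv[2]) && pv[2] > 0 && pv[1] / pv[2] >= value)
        hits <- hits + 1L
    }
    p <- (hits + 1) / (permutations + 1)
  }
  structure(list(statistic = "phi'_ST", value = value, per_locus = NA_real_,
                 p_value = p, comparison = paste(levels(labs), collapse = "/"),
                 n_permutations = permutations,
                 fst = v[1], fst_max = v[2]),
            class = "diff_result")
}

# recode allele a in deme d to a deme-private code
privatize_alleles <- function(calls, labs) {
  k <- nlevels(labs)
  di <- as.integer(labs)
  out <- calls
  out[, , 1] <- calls[, , 1] * k + rep(di, dim(calls)[2])
  out[, , 2] <- calls[, , 2] * k + rep(di, dim(calls)[2])
  out
}

# allele-count contingency table (alleles x demes) for one locus
allele_count_table <- function(g, labs, l) {
  a <- c(g$calls[, l, 1], g$calls[, l, 2])
  d <- rep(labs, 2)
  ok <- !is.na(a)
  table(factor(a[ok]), factor(d[ok], levels = levels(labs)))
}

#' Combined chi-squared test of allele-frequency differentiation
#'
#' Per-locus Pearson chi-squared on the allele-count table (alleles x
#' demes), summed over loci into a multilocus statistic with summed degrees
#' of freedom. Alleles whose expected count in some deme falls below 1 are
#' pooled into an "other" class (toggle with `pool_rare`) to keep the
#' chi-squared approximation honest. Monomorphic loci are skipped with a
#' note.
#'
#' @param g a [genotype_matrix()].
#' @param scheme optional [grouping_scheme()].
#' @param pool_rare pool rare alleles before testing.
#' @return list: per-locus table (chisq, df, p), combined chisq, df, p,
#'   skipped loci.
#' @export
chifish_combined_test <- function(g, scheme = NULL, pool_rare = TRUE) {
  labs <- deme_of(g, scheme)
  per <- list(); skipped <- character()
  for (l in seq_along(g$loci)) {
    tab <- allele_count_table(g, labs, l)
    if (nrow(tab) < 2) { skipped <- c(skipped, g$loci[l]); next }
    if (pool_rare && nrow(tab) > 2) {
      exp_cnt <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      rare <- apply(exp_cnt, 1, min) < 1
      if (sum(rare) > 1) {
        tab <- rbind(tab[!rare, , drop = FALSE],
                     other = colSums(tab[rare, , drop = FALSE]))
      }
      if (nrow(tab) < 2) { skipped <- c(skipped, g$loci[l]); next }
    }
    exp_cnt <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    chi2 <- sum((tab - exp_cnt)^2 / exp_cnt)
    df <- (nrow(tab) - 1) * (ncol(tab) - 1)
    per[[g$loci[l]]] <- data.frame(locus = g$loci[l], chisq = chi2, df = df,
                                   p = pchisq(chi2, df, lower.tail = FALSE),
                                   stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, per)
  chisq <- sum(per$chisq); df <- sum(per$df)
  list(per_locus = per, chisq = chisq, df = df,
       p = pchisq(chisq, df, lower.tail = FALSE), skipped = skipped)
}

#' Markov-chain exact test of population differentiation
#'
#' Estimates the exact probability, margins fixed, of allele-count (or
#' haplotype-count) tables no more probable than the observed one, using a
#' Metropolis chain over tables; defaults are the standard chain of 10,000
#' dememorization steps, 100 batches and 5,000 iterations per batch, with
#' the standard error from batch means. Ties count as extreme. Per-locus
#' p-values are combined by Fisher's method.
#'
#' @param x a [genotype_matrix()], or a single contingency table (matrix)
#'   of haplotype counts.
#' @param scheme optional [grouping_scheme()] (genotype input only).
#' @param mc chain parameters (`dememorization`, `batches`, `iterations`).
#' @return for a table: list(p, se). For genotypes: list with per-locus
#'   p/se and Fisher-combined chisq, df, p.
#' @export
exact_differentiation_test <- function(x, scheme = NULL,
                                       mc = list(dememorization = 10000,
                                                 batches = 100,
                                                 iterations = 5000)) {
  run1 <- function(tab) {
    tab <- as.matrix(tab)
    nz_r <- rowSums(tab) > 0; nz_c <- colSums(tab) > 0
    tab <- tab[nz_r, nz_c, drop = FALSE]
    if (nrow(tab) < 2 || ncol(tab) < 2)
      return(list(p = 1, se = 0, flagged = "degenerate margins"))
    res <- cpp_mc_exact(matrix(as.integer(tab), nrow(tab)),
                        mc$dememorization, mc$batches, mc$iterations)
    # add-one Monte-Carlo correction: a sampled p-value of exactly zero
    # only means "below chain resolution", and the observed table itself
    # always counts among the extreme ones
    N <- mc$batches * mc$iterations
    res$p <- (res$p * N + 1) / (N + 1)
    res
  }
  if (is.matrix(x) || is.table(x)) return(run1(x))
  labs <- deme_of(x, scheme)
  per <- lapply(seq_along(x$loci), function(l)
    run1(allele_count_table(x, labs, l)))
  ps <- vapply(per, function(z) z$p, 0)
  ps_adj <- pmax(ps, 1e-12)  # Fisher's method guard for p estimated as 0
  X <- -2 * sum(log(ps_adj))
  df <- 2 * length(ps)
  list(per_locus = data.frame(locus = x$loci, p = ps,
                              se = vapply(per, function(z) z$se, 0)),
       chisq = X, df = df, p = pchisq(X, df, lower.tail = FALSE))
}

#' Type-I error and power of the differentiation tests
#'
#' For each target differentiation level, simulates datasets with
#' [sample_null_frequencies()] and reports the rejection proportion of the
#' combined chi-squared test and the Markov-chain exact test at level
#' `alpha`, with binomial standard errors.
#'
#' @param base_freqs list of per-locus allele frequency vectors.
#' @param target_fst_levels differentiation levels (0 = null).
#' @param samples_per_deme diploid samples per deme.
#' @param n_datasets simulated datasets per level.
#' @param alpha nominal level.
#' @param mc exact-test chain parameters (shortened default for batch use).
#' @return data frame: level, test, rejections, n, rate, se.
#' @export
power_simulation <- function(base_freqs, target_fst_levels = c(0, 0.01),
                             samples_per_deme = c(85, 85, 85),
                             n_datasets = 200, alpha = 0.05,
                             mc = list(dememorization = 2000, batches = 50,
                                       iterations = 200)) {
  out <- list()
  for (level in target_fst_levels) {
    rej_chi <- rej_ex <- 0L
    for (i in seq_len(n_datasets)) {
      g <- sample_null_frequencies(base_freqs, level, samples_per_deme)
      if (chifish_combined_test(g)$p < alpha) rej_chi <- rej_chi + 1L
      if (exact_differentiation_test(g, mc = mc)$p < alpha)
        rej_ex <- rej_ex + 1L
    }
    for (z in list(c("chisq", rej_chi), c("exact", rej_ex))) {
      r <- as.integer(z[2]); rate <- r / n_datasets
      out[[length(out) + 1]] <- data.frame(
        level = level, test = z[1], rejections = r, n = n_datasets,
        rate = rate, se = sqrt(rate * (1 - rate) / n_datasets),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Minimum spanning network of haplotypes
#'
#' Collapses identical haplotypes (under the chosen view) into nodes with
#' frequencies and per-deme composition, builds a minimum spanning tree on
#' the step-distance matrix with deterministic tie-breaking (distance, then
#' lexicographic node ids), and additionally flags every co-minimal
#' alternative edge — a non-tree edge whose weight equals the largest
#' weight on the tree path between its endpoints — so the output is
#' seed-free and a true network. Edges are annotated by step decomposition:
#' base changes vs 9-bp vs 40-bp repeat-count changes.
#'
#' @param hs a [haplotype_set()].
#' @param view distance mode, as in [pairwise_steps()].
#' @return object of class `haplotype_network`: `nodes` (id, frequency,
#'   per-deme counts) and `edges` (from, to, steps, per-component steps,
#'   in_tree, alternative).
#' @export
minimum_spanning_network <- function(hs, view = "sequence_plus_indels") {
  steps <- pairwise_steps(hs, view)
  key <- if (view == "indels_as_rflp")
    apply(hs$repeat_counts, 1, paste, collapse = "/")
  else apply(view_matrix(hs, view), 1, paste, collapse = "")
  if (view == "sequence_plus_indels" && !is.null(hs$repeat_counts))
    key <- paste(key, apply(hs$repeat_counts, 1, paste, collapse = "/"))
  # stable haplotype ids in order of first appearance
  first <- which(!duplicated(key))
  hap_of <- match(key, key[first])
  n_h <- length(first)
  if (n_h < 2) stop("need at least two distinct haplotypes")
  ids <- paste0("H", seq_len(n_h))
  demes <- deme_of(hs)
  comp <- matrix(unlist(lapply(seq_len(n_h), function(h)
    as.integer(table(demes[hap_of == h])))), nrow = n_h,
    ncol = nlevels(demes), byrow = TRUE)
  colnames(comp) <- levels(demes)
  nodes <- data.frame(id = ids, frequency = as.integer(table(hap_of)),
                      stringsAsFactors = FALSE)
  nodes <- cbind(nodes, comp)
  dmat <- steps$total[first, first, drop = FALSE]
  comp_mats <- lapply(steps[-1], function(m) m[first, first, drop = FALSE])
  # candidate edges sorted by (distance, id pair)
  pairs <- which(upper.tri(dmat), arr.ind = TRUE)
  ord <- order(dmat[pairs], pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  parent <- seq_len(n_h)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  in_tree <- logical(nrow(pairs))
  for (e in seq_len(nrow(pairs))) {
    ri <- find(pairs[e, 1]); rj <- find(pairs[e, 2])
    if (ri != rj) { parent[ri] <- rj; in_tree[e] <- TRUE }
  }
  tree_e <- pairs[in_tree, , drop = FALSE]
  # adjacency of the tree for path-maximum queries
  adj <- vector("list", n_h)
  for (e in seq_len(nrow(tree_e))) {
    i <- tree_e[e, 1]; j <- tree_e[e, 2]
    adj[[i]] <- rbind(adj[[i]], c(j, dmat[i, j]))
    adj[[j]] <- rbind(adj[[j]], c(i, dmat[i, j]))
  }
  path_max <- function(i, j) {
    # DFS from i to j over the tree, tracking the max edge weight
    stack <- list(list(node = i, from = 0, mx = 0))
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (cur$node == j) return(cur$mx)
      nb <- adj[[cur$node]]
      if (!is.null(nb)) for (q in seq_len(nrow(nb)))
        if (nb[q, 1] != cur$from)
          stack[[length(stack) + 1]] <- list(node = nb[q, 1],
                                             from = cur$node,
                                             mx = max(cur$mx, nb[q, 2]))
    }
    NA_real_
  }
  alt <- logical(nrow(pairs))
  nt <- which(!in_tree)
  for (e in nt)
    if (dmat[pairs[e, 1], pairs[e, 2]] <=
        path_max(pairs[e, 1], pairs[e, 2]))
      alt[e] <- TRUE
  keep <- in_tree | alt
  ed <- pairs[keep, , drop = FALSE]
  edges <- data.frame(from = ids[ed[, 1]], to = ids[ed[, 2]],
                      steps = dmat[ed], stringsAsFactors = FALSE)
  for (nm in names(comp_mats)) edges[[nm]] <- comp_mats[[nm]][ed]
  edges$in_tree <- in_tree[keep]
  edges$alternative <- alt[keep]
  structure(list(nodes = nodes, edges = edges, view = view),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("haplotype_network:", nrow(x$nodes), "haplotypes,",
      sum(x$edges$in_tree), "tree edges,", sum(x$edges$alternative),
      "co-minimal alternatives (view:", x$view, ")\n")
  invisible(x)
}

#' Export a haplotype network as a DOT edge list
#' @param net a `haplotype_network`.
#' @param file output path; `NULL` returns the lines.
#' @return DOT lines, invisibly.
#' @export
network_to_dot <- function(net, file = NULL) {
  lines <- c("graph msn {",
             sprintf('  %s [label="%s (%d)"];', net$nodes$id, net$nodes$id,
                     net$nodes$frequency),
             sprintf('  %s -- %s [label="%d"%s];', net$edges$from,
                     net$edges$to, net$edges$steps,
                     ifelse(net$edges$in_tree, "", ", style=dashed")),
             "}")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
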