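# programmatic fixtures shared across test files

# random GENEPOP text with pops x loci structure; returns list(lines, truth)
random_genepop <- function(n_per_pop, n_loci, width = 3, miss_rate = 0.02) {
  loci <- paste0("Loc", seq_len(n_loci))
  lines <- c("random fixture", loci)
  fmt <- function(a) sprintf(paste0("%0", width, "d"), a)
  for (p in seq_along(n_per_pop)) {
    lines <- c(lines, "Pop")
    for (i in seq_len(n_per_pop[p])) {
      a1 <- sample.int(10^width - 1, n_loci, replace = TRUE)
      a2 <- sample.int(10^width - 1, n_loci, replace = TRUE)
      drop <- runif(n_loci) < miss_rate
      a1[drop] <- 0L; a2[drop] <- 0L
      lines <- c(lines, paste0("p", p, "i", i, " , ",
                               paste0(fmt(a1), fmt(a2), collapse = " ")))
    }
  }
  lines
}

# tiny genotype matrix from a list of per-individual allele pair rows
tiny_genotypes <- function(rows, pops, loci = NULL) {
  n <- length(rows)
  L <- length(rows[[1]]) / 2
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  calls <- array(NA_integer_, c(n, L, 2))
  for (i in seq_len(n)) {
    m <- matrix(rows[[i]], ncol = 2, byrow = TRUE)
    calls[i, , 1] <- m[, 1]; calls[i, , 2] <- m[, 2]
  }
  genotype_matrix(calls, paste0("i", seq_len(n)), loci, pops)
}

# haplotype set from plain sequences
tiny_haps <- function(seqs, labels = rep("GOM", length(seqs)), counts = NULL,
                      motif_max = NULL) {
  names(seqs) <- paste0("h", seq_along(seqs))
  haplotype_set(seqs, labels, counts, motif_max = motif_max)
}

# independent textbook implementation of the Weir-Cockerham estimator,
# written as straight-line arithmetic over alleles (test oracle)
oracle_wc_fst <- function(g) {
  labs <- deme_of(g)
  num <- den <- 0
  for (l in seq_along(g$loci)) {
    a1 <- g$calls[, l, 1]; a2 <- g$calls[, l, 2]
    ok <- !is.na(a1)
    d <- droplevels(labs[ok]); a1 <- a1[ok]; a2 <- a2[ok]
    ni <- as.numeric(table(d)); r <- length(ni)
    if (r < 2) next
    nbar <- mean(ni)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    for (al in unique(c(a1, a2))) {
      p_i <- vapply(levels(d), function(dd) {
        idx <- d == dd
        sum(a1[idx] == al, a2[idx] == al) / (2 * sum(idx))
      }, 0)
      h_i <- vapply(levels(d), function(dd) {
        idx <- d == dd
        mean((a1[idx] == al) != (a2[idx] == al))
      }, 0)
      pbar <- sum(ni * p_i) / sum(ni)
      s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * h_i) / sum(ni)
      a <- nbar / nc *
        (s2 - 1 / (nbar - 1) *
           (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
      b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 -
           (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a; den <- den + a + b + cc
    }
  }
  num / den
}

# exact conditional p-value of an R x C table by full enumeration
# (recursive over cells, margins fixed) -- test oracle
oracle_exact_p <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  logp <- function(x) -sum(lgamma(x + 1))
  obs <- logp(tab)
  R <- nrow(tab); C <- ncol(tab)
  tot_num <- 0; tot_hit <- 0
  rec <- function(mat, r, c, rrem, crem) {
    if (r > R) {
      lp <- logp(mat)
      w <- exp(lp)  # probability up to the fixed-margin constant
      tot_num <<- tot_num + w
      if (lp <= obs + 1e-9) tot_hit <<- tot_hit + w
      return(invisible(NULL))
    }
    vals <- if (c == C) {
      if (rrem[r] <= crem[c]) rrem[r] else integer(0)
    } else 0:min(rrem[r], crem[c])
    for (v in vals) {
      m2 <- mat; m2[r, c] <- v
      rr <- rrem; rr[r] <- rr[r] - v
      cc <- crem; cc[c] <- cc[c] - v
      if (c == C) rec(m2, r + 1, 1, rr, cc) else rec(m2, r, c + 1, rr, cc)
    }
  }
  rec(matrix(0L, R, C), 1, 1, rs, cs)
  tot_hit / tot_num
}

# brute-force minimum spanning tree weight over all spanning trees (n <= 7)
oracle_mst_weight <- function(d) {
  n <- nrow(d)
  edges <- which(upper.tri(d), arr.ind = TRUE)
  best <- Inf
  for (sel in utils::combn(nrow(edges), n - 1, simplify = FALSE)) {
    e <- edges[sel, , drop = FALSE]
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    acyclic <- TRUE
    for (q in seq_len(nrow(e))) {
      a <- find(e[q, 1]); b <- find(e[q, 2])
      if (a == b) { acyclic <- FALSE; break }
      parent[a] <- b
    }
    if (acyclic) best <- min(best, sum(d[e]))
  }
  best
}
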