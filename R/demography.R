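#' Mismatch distribution of pairwise differences
#'
#' Counts of pairwise step differences among all `N(N-1)/2` sequence pairs
#' under the chosen data view. The mean of the distribution equals the
#' nucleotide diversity reported by [sequence_summaries()].
#'
#' @param hs a [haplotype_set()].
#' @param view distance mode, as in [pairwise_steps()].
#' @return named integer vector of counts for 0, 1, 2, ... differences.
#' @export
mismatch_distribution <- function(hs, view = "sequence_only") {
  d <- pairwise_steps(hs, view)$total
  v <- d[upper.tri(d)]
  counts <- tabulate(v + 1, nbins = max(v) + 1)
  names(counts) <- seq_along(counts) - 1
  counts
}

#' Equilibrium mismatch distribution
#'
#' Stationary expectation for a constant-size population: the geometric
#' form `F_j(theta) = theta^j / (1 + theta)^(j+1)`, whose mean equals
#' theta.
#'
#' @param theta mutation-scaled population size.
#' @param j number of differences (vectorized).
#' @return probabilities.
#' @export
equilibrium_mismatch <- function(theta, j) {
  if (theta < 0) stop("theta must be non-negative")
  if (theta == 0) return(as.numeric(j == 0))
  exp(j * log(theta) - (j + 1) * log1p(theta))
}

#' Expected mismatch distribution under an expansion model
#'
#' Exact expectations from the phase-type distribution of the pairwise
#' coalescence time, with time in mutational (pairwise-difference) units so
#' that `tau = 2*mu*t` generations:
#'
#' * demographic (sudden) expansion `(tau, theta0, theta1)`: a population
#'   of present size theta1 that was theta0 before time tau;
#' * spatial expansion `(tau, thetaS, M)`: an infinite-island range of
#'   demes of size thetaS exchanging `M = 2Nm` migrants, colonized at time
#'   tau from a single ancestral deme of size thetaS. A pair separated by
#'   migration cannot coalesce until the expansion time.
#'
#' @param model `"demographic"` or `"spatial"`.
#' @param par named vector: `tau, theta0, theta1` or `tau, thetaS, M`.
#' @param jmax largest difference class.
#' @return vector of probabilities for j = 0..jmax.
#' @export
expected_mismatch <- function(model = c("demographic", "spatial"), par,
                              jmax) {
  model <- match.arg(model)
  j <- 0:jmax
  tau <- max(par[["tau"]], 0)
  if (model == "demographic") {
    th_rec <- max(par[["theta1"]], 1e-8)  # recent epoch
    th_anc <- max(par[["theta0"]], 0)
    mig <- 0
  } else {
    th_rec <- max(par[["thetaS"]], 1e-8)
    th_anc <- th_rec
    mig <- max(par[["M"]], 0)
  }
  b <- 1 + (1 + mig) / th_rec
  # coalescence during the recent epoch
  recent <- pgamma(b * tau, shape = j + 1) / (th_rec * b^(j + 1))
  # probability of entering the ancestral epoch uncoalesced
  p_nc <- if (model == "demographic") exp(-tau / th_rec)
  else 1 - (1 - exp(-(1 + mig) * tau / th_rec)) / (1 + mig)
  anc_geom <- equilibrium_mismatch(th_anc, j)
  wave <- dpois(j, tau)
  conv <- pmax(as.numeric(stats::convolve(wave, rev(anc_geom),
                                          type = "open"))[seq_along(j)], 0)
  recent + p_nc * conv
}

#' Harpending's raggedness index
#'
#' `r = sum over i of (f_i - f_(i-1))^2` over the normalized mismatch
#' frequencies, with one trailing zero class; large values indicate the
#' multimodality typical of stationary populations.
#'
#' @param counts mismatch counts (or frequencies) for 0..d differences.
#' @return raggedness index r.
#' @export
raggedness <- function(counts) {
  f <- counts / sum(counts)
  f <- c(f, 0)
  sum(diff(f)^2)
}

# coalescent simulation of pairwise differences for n sequences under the
# fitted expansion demography; infinite sites, time in pairwise-difference
# units (mutations per lineage at rate 1/2)
sim_mismatch_model <- function(n, model, par) {
  tau <- max(par[["tau"]], 0)
  if (model == "demographic") {
    th_rec <- max(par[["theta1"]], 1e-8); th_anc <- max(par[["theta0"]], 1e-8)
    mig_rate <- 0
    return(sim_mismatch_twoepoch(n, tau, th_rec, th_anc))
  } else {
    th_rec <- th_anc <- max(par[["thetaS"]], 1e-8)
    mig_rate <- max(par[["M"]], 0) / (2 * th_rec)  # per-lineage emigration
  }
  deme <- rep(1L, n)          # infinite islands: migrants get fresh ids
  born <- rep(0, n)           # lineage start time
  tips <- lapply(seq_len(n), identity)
  acc <- rep(0, n)            # mutations from tip to current lineage start
  diffs <- matrix(0L, n, n)
  t <- 0; next_deme <- 2L; epoch2 <- FALSE
  alive <- seq_len(n)
  repeat {
    k <- length(alive)
    if (k == 1) break
    if (!epoch2 && t >= tau) epoch2 <- TRUE
    th <- if (epoch2) th_anc else th_rec
    # coalescible pairs: same deme (all, once in the ancestral epoch)
    if (epoch2) {
      npairs <- k * (k - 1) / 2
      rate_c <- npairs / th
      rate_m <- 0
    } else {
      tb <- table(deme[alive])
      npairs_by <- tb * (tb - 1) / 2
      rate_c <- sum(npairs_by) / th
      rate_m <- k * mig_rate
    }
    total <- rate_c + rate_m
    if (total <= 0) { t <- tau; epoch2 <- TRUE; next }
    dt <- rexp(1, total)
    if (!epoch2 && t + dt > tau) { t <- tau; epoch2 <- TRUE; next }
    t <- t + dt
    if (runif(1) < rate_m / total) {
      i <- sample(alive, 1)
      deme[i] <- next_deme; next_deme <- next_deme + 1L
      next
    }
    # coalescence: pick a deme weighted by pair count, then a pair
    if (epoch2) {
      pick <- sample(alive, 2)
    } else {
      tb <- table(deme[alive])
      w <- tb * (tb - 1) / 2
      dm <- as.integer(names(tb))[sample.int(length(tb), 1, prob = w)]
      pick <- sample(alive[deme[alive] == dm], 2)
    }
    i <- pick[1]; jj <- pick[2]
    # flush mutations on both dying branches
    for (x in c(i, jj)) {
      m <- rpois(1, (t - born[x]) / 2)
      if (m > 0) acc[tips[[x]]] <- acc[tips[[x]]] + m
    }
    da <- acc[tips[[i]]]; db <- acc[tips[[jj]]]
    diffs[tips[[i]], tips[[jj]]] <- outer(da, db, "+")
    diffs[tips[[jj]], tips[[i]]] <- outer(db, da, "+")
    tips[[i]] <- c(tips[[i]], tips[[jj]])
    born[i] <- t
    alive <- setdiff(alive, jj)
  }
  v <- diffs[upper.tri(diffs)]
  counts <- tabulate(v + 1, nbins = max(v) + 1)
  names(counts) <- seq_along(counts) - 1
  counts
}

# fast path for the panmictic two-epoch demography: no migration, so
# coalescence times can be drawn directly epoch by epoch
sim_mismatch_twoepoch <- function(n, tau, th_rec, th_anc) {
  tips <- lapply(seq_len(n), identity)
  born <- rep(0, n)
  acc <- rep(0, n)
  diffs <- matrix(0L, n, n)
  alive <- seq_len(n)
  t <- 0; epoch2 <- tau <= 0
  while (length(alive) > 1) {
    k <- length(alive)
    rate <- k * (k - 1) / 2 / (if (epoch2) th_anc else th_rec)
    dt <- rexp(1, rate)
    if (!epoch2 && t + dt > tau) { t <- tau; epoch2 <- TRUE; next }
    t <- t + dt
    pick <- alive[sample.int(k, 2)]
    i <- pick[1]; jj <- pick[2]
    for (x in c(i, jj)) {
      m <- rpois(1, (t - born[x]) / 2)
      if (m > 0) acc[tips[[x]]] <- acc[tips[[x]]] + m
    }
    da <- acc[tips[[i]]]
    db <- acc[tips[[jj]]]
    diffs[tips[[i]], tips[[jj]]] <- outer(da, db, "+")
    diffs[tips[[jj]], tips[[i]]] <- outer(db, da, "+")
    tips[[i]] <- c(tips[[i]], tips[[jj]])
    born[i] <- t
    alive <- setdiff(alive, jj)
  }
  v <- diffs[upper.tri(diffs)]
  counts <- tabulate(v + 1, nbins = max(v) + 1)
  names(counts) <- seq_along(counts) - 1
  counts
}

# SSD between observed mismatch frequencies and the model expectation
mismatch_ssd <- function(par, model, fobs) {
  Fj <- expected_mismatch(model, par, length(fobs) - 1)
  sum((fobs - Fj)^2)
}

fit_one_mismatch <- function(counts, model, cap = 99999, init = NULL) {
  fobs <- counts / sum(counts)
  mbar <- sum((seq_along(fobs) - 1) * fobs)
  to_par <- if (model == "demographic")
    function(x) c(tau = x[1], theta0 = exp(x[2]), theta1 = exp(x[3]))
  else
    function(x) c(tau = x[1], thetaS = exp(x[2]), M = exp(x[3]))
  obj <- function(x) mismatch_ssd(to_par(x), model, fobs)
  # the SSD surface carries a tau / size-parameter ridge; the same
  # deterministic multi-start grid is used for data and bootstrap fits so
  # the goodness-of-fit comparison is like for like
  starts <- list(c(max(mbar, 0.5), log(0.1), log(max(mbar, 1))),
                 c(max(mbar / 2, 0.25), log(max(mbar / 4, 0.05)),
                   log(max(2 * mbar, 2))),
                 c(1, log(1), log(10)),
                 c(max(2 * mbar, 1), log(0.01), log(max(mbar, 1))))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      nlminb(s, obj, lower = c(0, log(1e-6), log(1e-6)),
             upper = c(4 * (length(fobs) + 5), log(cap), log(cap))),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective))
      best <- fit
  }
  if (is.null(best)) return(NULL)
  par <- to_par(best$par)
  list(par = par, ssd = best$objective, converged = best$convergence == 0)
}

#' Fit a demographic or spatial expansion model to a mismatch distribution
#'
#' Least-squares fit of the model-expected mismatch to the observed
#' frequencies (bounded multi-start optimization on tau and log-scale size
#' parameters, cap 99,999 reported as a sentinel), with a parametric
#' bootstrap: data are re-simulated by coalescent under the fitted model,
#' refitted, and used both for the goodness-of-fit p-value (probability of
#' a simulated SSD at least as large as observed) and for 5%/95% parameter
#' quantiles. The raggedness index and its bootstrap p-value come from the
#' same replicates.
#'
#' @param counts observed mismatch counts (from [mismatch_distribution()]).
#' @param model `"demographic"` or `"spatial"`.
#' @param n_seqs number of sequences behind the distribution (inferred from
#'   the pair count when NULL).
#' @param bootstrap_reps parametric-bootstrap replicates.
#' @param cap optimizer upper bound, reported as the sentinel value when
#'   hit.
#' @return object of class `mismatch_fit`: model, estimates, 5%/95%
#'   bootstrap quantiles, ssd, model_p, raggedness r and r_p, flags.
#' @export
fit_expansion <- function(counts, model = c("demographic", "spatial"),
                          n_seqs = NULL, bootstrap_reps = 1000,
                          cap = 99999) {
  model <- match.arg(model)
  npairs <- sum(counts)
  if (npairs < 10) stop("need at least 10 sequence pairs")
  if (is.null(n_seqs))
    n_seqs <- round((1 + sqrt(1 + 8 * npairs)) / 2)
  if (sum(counts > 0) < 2) {
    return(structure(list(model = model, par = NULL, flagged =
                            "zero-variance mismatch distribution"),
                     class = "mismatch_fit"))
  }
  fit <- fit_one_mismatch(counts, model, cap)
  if (is.null(fit))
    return(structure(list(model = model, par = NULL,
                          flagged = "optimizer failed"),
                     class = "mismatch_fit"))
  r_obs <- raggedness(counts)
  boot_par <- matrix(NA_real_, bootstrap_reps, 3,
                     dimnames = list(NULL, names(fit$par)))
  boot_ssd <- boot_r <- rep(NA_real_, bootstrap_reps)
  for (b in seq_len(bootstrap_reps)) {
    sim <- sim_mismatch_model(n_seqs, model, fit$par)
    bf <- fit_one_mismatch(sim, model, cap)
    if (is.null(bf)) next
    boot_par[b, ] <- bf$par
    boot_ssd[b] <- bf$ssd
    boot_r[b] <- raggedness(sim)
  }
  ok <- !is.na(boot_ssd)
  qs <- apply(boot_par[ok, , drop = FALSE], 2, quantile,
              probs = c(0.05, 0.95), names = FALSE)
  est <- pmin(fit$par, cap)
  structure(list(model = model,
                 par = est,
                 capped = fit$par >= cap * 0.999,
                 quantiles = qs,
                 ssd = fit$ssd,
                 model_p = mean(boot_ssd[ok] >= fit$ssd),
                 raggedness_r = r_obs,
                 r_p = mean(boot_r[ok] >= r_obs),
                 converged = fit$converged,
                 bootstrap_reps = sum(ok), n_seqs = n_seqs),
            class = "mismatch_fit")
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat("mismatch_fit (", x$model, " expansion)\n", sep = "")
  if (!is.null(x$flagged)) { cat("flagged:", x$flagged, "\n"); return(invisible(x)) }
  for (i in seq_along(x$par))
    cat(sprintf("  %-7s %.4g  [%.4g, %.4g]%s\n", names(x$par)[i], x$par[i],
                x$quantiles[1, i], x$quantiles[2, i],
                if (x$capped[i]) " (capped)" else ""))
  cat(sprintf("  SSD %.4g (model p = %.3g), raggedness r %.4g (p = %.3g)\n",
              x$ssd, x$model_p, x$raggedness_r, x$r_p))
  invisible(x)
}

#' Mutation-rate and generation-time configuration for expansion dating
#'
#' @param mu per-sequence per-generation mutation rate (1.23e-4 for the
#'   536-site control-region sequence data, 3.67e-6 for the indel repeats,
#'   1.26e-4 combined).
#' @param G generation time in years (7.94 for an unfished population).
#' @return object of class `dating_config`.
#' @export
dating_config <- function(mu = 1.23e-4, G = 7.94) {
  if (mu <= 0) stop("config error: mu must be positive")
  if (G <= 0) stop("config error: G must be positive")
  structure(list(mu = mu, G = G), class = "dating_config")
}

#' Convert a mismatch expansion time tau to years
#'
#' With tau in mutational units (tau = 2*mu*t for t generations), the
#' expansion age is `t = tau / (2*mu)` generations, i.e.
#' `years = G * tau / (2*mu)`. Linear in tau and G; halving mu doubles the
#' age.
#'
#' @param tau expansion time estimate(s) in mutational units (vectorized,
#'   e.g. a point estimate with bootstrap quantiles).
#' @param cfg a [dating_config()].
#' @return years before present, same length as `tau`.
#' @examples
#' expansion_time_years(c(0.74, 3.4, 4.8), dating_config(mu = 1.23e-4))
#' @export
expansion_time_years <- function(tau, cfg = dating_config()) {
  if (any(tau < 0)) stop("tau must be non-negative")
  cfg$G * tau / (2 * cfg$mu)
}

#' Derive the per-sequence per-generation mutation rate
#'
#' From a per-site per-million-year substitution rate (0.02888
#' changes/site/Myr, the average over eight fish control regions), a
#' generation time and a sequence length:
#' `mu = rate * 1e-6 * G * L`.
#'
#' @param per_site_per_myr substitution rate per site per Myr.
#' @param G generation time in years.
#' @param L sequence length in sites.
#' @return mutation rate per sequence per generation.
#' @export
derive_sequence_mu <- function(per_site_per_myr = 0.02888, G = 7.94,
                               L = 536) {
  if (per_site_per_myr < 0 || G <= 0 || L < 0)
    stop("rates, G and L must be non-negative (G positive)")
  per_site_per_myr * 1e-6 * G * L
}

# equilibrium He samples conditional on observed allele count k:
# single-deme TPM coalescent, rejection on the simulated allele count.
# theta is first calibrated by simulation under the same mutation model so
# that E[K | theta] matches k_obs (an infinite-alleles theta would sit too
# low — repeat-number homoplasy yields fewer distinct alleles per theta —
# and bias the conditional He distribution downward); only then are
# conditional samples collected.
bottleneck_he_null <- function(n_copies, k_obs, sim_reps, p_single,
                               geom_mean, max_batches = 60) {
  ek <- function(th) sum(th / (th + 0:(n_copies - 1)))
  th <- tryCatch(stats::uniroot(function(x) ek(x) - k_obs, c(1e-3, 1e4))$root,
                 error = function(e) 1)
  sim_k <- function(th, b) {
    sims <- cpp_microsat_sim(n_copies, th, matrix(0, 1, 1), b, 1L,
                             p_single, geom_mean, 1e4)
    list(sims = sims, ks = apply(sims, 2, function(x) length(unique(x))))
  }
  # calibration: multiplicative updates on theta until E[K] matches k_obs
  for (it in seq_len(25)) {
    z <- sim_k(th, 80)
    mk <- mean(z$ks)
    if (abs(mk - k_obs) < 0.25) break
    th <- th * exp(1.2 * (k_obs - mk) / max(mk, 2))
    th <- min(max(th, 1e-3), 1e4)
  }
  he <- numeric(0)
  batch <- max(200, sim_reps)
  tol <- 0L
  for (it in seq_len(max_batches)) {
    z <- sim_k(th, batch)
    hit <- abs(z$ks - k_obs) <= tol
    if (any(hit)) {
      hes <- apply(z$sims[, hit, drop = FALSE], 2, function(x) {
        p <- tabulate(factor(x)) / length(x)
        length(x) / (length(x) - 1) * (1 - sum(p^2))
      })
      he <- c(he, hes)
    }
    if (length(he) >= sim_reps) break
    if (it > 5 && length(he) < sim_reps / 10) tol <- 1L
  }
  he[seq_len(min(length(he), sim_reps))]
}

#' Heterozygosity-based bottleneck/expansion test (two-phase model)
#'
#' For every polymorphic locus in every deme, the equilibrium distribution
#' of expected heterozygosity conditional on the observed allele count and
#' sample size is simulated under the two-phase mutation model, and the
#' observed (unbiased) heterozygosity is standardized against it. Loci are
#' then combined by Wilcoxon signed-rank tests (two-tailed, and one-tailed
#' for He excess and deficiency) and a sign test. Heterozygosity excess is
#' the classic bottleneck signature; deficiency indicates population
#' expansion or undetected substructure with gene flow.
#'
#' @param g a [genotype_matrix()].
#' @param scheme optional [grouping_scheme()] (use the pooled scheme for a
#'   whole-basin test).
#' @param p_single probability of a single-step mutation under the TPM.
#' @param geom_mean mean magnitude of multi-step jumps.
#' @param sim_reps equilibrium samples per locus.
#' @return list per deme: per-locus table (n, k, He_obs, He_null mean/sd,
#'   DH standardized deviation, excess flag) and p-values `two_tailed`,
#'   `he_excess`, `he_deficiency`, `sign_test`; `wilcoxon_refused` when
#'   fewer than 4 usable loci.
#' @export
bottleneck_test <- function(g, scheme = NULL, p_single = 0.9,
                            geom_mean = 2, sim_reps = 1000) {
  demes <- deme_of(g, scheme)
  out <- list()
  for (d in levels(demes)) {
    rows <- which(demes == d)
    loc <- list()
    for (l in seq_along(g$loci)) {
      a <- c(g$calls[rows, l, 1], g$calls[rows, l, 2])
      a <- a[!is.na(a)]
      k <- length(unique(a))
      if (k < 2) next  # monomorphic loci are skipped
      n <- length(a)
      p <- tabulate(factor(a)) / n
      he_obs <- n / (n - 1) * (1 - sum(p^2))
      null_he <- bottleneck_he_null(n, k, sim_reps, p_single, geom_mean)
      if (length(null_he) < 20) next
      mu0 <- mean(null_he); sd0 <- sd(null_he)
      loc[[length(loc) + 1]] <- data.frame(
        locus = g$loci[l], n = n, k = k, He_obs = he_obs,
        He_null = mu0, He_sd = sd0,
        DH = (he_obs - mu0) / sd0, excess = he_obs > mu0,
        stringsAsFactors = FALSE)
    }
    loc <- do.call(rbind, loc)
    res <- list(deme = d, per_locus = loc)
    if (is.null(loc) || nrow(loc) < 4) {
      res$wilcoxon_refused <- TRUE
      if (!is.null(loc) && nrow(loc) > 0)
        res$sign_test <- binom.test(sum(loc$excess), nrow(loc), 0.5)$p.value
    } else {
      res$wilcoxon_refused <- FALSE
      res$two_tailed <- wilcox.test(loc$DH, mu = 0, exact = FALSE)$p.value
      res$he_excess <- wilcox.test(loc$DH, mu = 0, alternative = "greater",
                                   exact = FALSE)$p.value
      res$he_deficiency <- wilcox.test(loc$DH, mu = 0, alternative = "less",
                                       exact = FALSE)$p.value
      res$sign_test <- binom.test(sum(loc$excess), nrow(loc), 0.5)$p.value
    }
    out[[d]] <- res
  }
  out
}
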