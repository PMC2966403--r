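# Within-population diversity statistics and neutrality tests.
#
# Conventions. theta_pi is the mean number of pairwise differences over all
# n(n-1)/2 sequence pairs; pi = theta_pi / L. Watterson's theta_s = S / a1.
# Neutrality p-values are obtained from neutral constant-size coalescent
# simulations conditioned on theta estimated from the data (theta = theta_pi),
# the convention of the standard population-genetics packages.

harmonic <- function(m) if (m < 1L) 0 else sum(1 / seq_len(m))
harmonic2 <- function(m) if (m < 1L) 0 else sum(1 / seq_len(m)^2)

#' Gene (haplotype) diversity
#'
#' `h = n/(n-1) * (1 - sum(p_i^2))` with its sampling variance (Nei 1987).
#'
#' @param counts integer vector of haplotype counts
#' @return list with `h` and `sd`
#' @export
gene_diversity <- function(counts) {
  counts <- as.numeric(counts)
  n <- sum(counts)
  if (n < 2) stop("insufficient-data: need >= 2 sequences", call. = FALSE)
  p <- counts / n
  sum2 <- sum(p^2)
  h <- n / (n - 1) * (1 - sum2)
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - sum2^2) + sum2 - sum2^2)
  list(h = h, sd = sqrt(max(v, 0)))
}

# Pairwise difference count between rows i and j of the character matrix,
# comparing only A/C/G/T columns shared by the pair (pairwise deletion) or
# using the columns as given (the caller applies complete deletion upstream).
pairwise_differences <- function(aln, missing_policy = c("complete-deletion", "strict")) {
  used <- unclass(apply_missing_policy(aln, missing_policy))
  n <- nrow(used)
  d <- matrix(0, n, n, dimnames = list(rownames(used), rownames(used)))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- used[i, ] %in% c("A", "C", "G", "T") & used[j, ] %in% c("A", "C", "G", "T")
      dij <- sum(used[i, ok] != used[j, ok])
      d[i, j] <- dij
      d[j, i] <- dij
    }
  }
  d
}

#' Mean number of pairwise differences (theta-pi)
#'
#' @param aln a `seq_alignment` with n >= 2
#' @param missing_policy column handling before comparison
#' @return list with `theta_pi` and `sd` (total variance of Tajima 1983,
#'   the convention of the standard packages' diversity tables)
#' @export
theta_pi <- function(aln, missing_policy = c("complete-deletion", "strict")) {
  n <- nrow(aln)
  if (n < 2L) stop("insufficient-data: need >= 2 sequences", call. = FALSE)
  d <- pairwise_differences(aln, missing_policy)
  tp <- mean(d[upper.tri(d)])
  v <- (n + 1) / (3 * (n - 1)) * tp +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * tp^2
  list(theta_pi = tp, sd = sqrt(max(v, 0)))
}

#' Watterson's theta from segregating sites
#'
#' `theta_s = S / a1` with `a1 = sum_{i=1}^{n-1} 1/i`. The variance uses the
#' unbiased estimator of `theta^2`, `S(S-1)/(a1^2 + a2)`.
#'
#' @param S number of segregating sites
#' @param n number of sequences
#' @return list with `theta_s` and `sd`
#' @export
watterson_theta <- function(S, n) {
  if (n < 2) stop("insufficient-data: need n >= 2", call. = FALSE)
  if (S < 0) stop("S must be >= 0", call. = FALSE)
  a1 <- harmonic(n - 1L)
  a2 <- harmonic2(n - 1L)
  th <- S / a1
  th2 <- if (S > 1) S * (S - 1) / (a1^2 + a2) else 0
  v <- th / a1 + (a2 / a1^2) * th2
  list(theta_s = th, sd = sqrt(max(v, 0)))
}

#' Full diversity summary for an alignment
#'
#' @param aln a `seq_alignment`
#' @param missing_policy column handling
#' @return list with n, L (sites used), K haplotypes, gene diversity,
#'   nucleotide diversity pi (= theta_pi / L), theta_pi and theta_s,
#'   each with its standard deviation.
#' @export
diversity_summary <- function(aln, missing_policy = c("complete-deletion", "strict")) {
  ht <- collapse_haplotypes(aln, missing_policy)
  ss <- site_summary(aln, missing_policy)
  gd <- gene_diversity(ht$counts)
  tp <- theta_pi(aln, missing_policy)
  ws <- watterson_theta(ss$S, nrow(aln))
  L <- ht$length
  list(
    n = nrow(aln), L = L, K = length(ht$haplotypes),
    S = ss$S, transitions = ss$transitions, transversions = ss$transversions,
    h = gd$h, h_sd = gd$sd,
    pi = tp$theta_pi / L, pi_sd = tp$sd / L,
    theta_pi = tp$theta_pi, theta_pi_sd = tp$sd,
    theta_s = ws$theta_s, theta_s_sd = ws$sd
  )
}

# ---------------------------------------------------------------------------
# Neutral coalescent machinery (infinite sites), used for null distributions.

# Simulate one constant-size coalescent genealogy for n lineages and place
# Poisson(theta/2 * length) mutations on each branch (infinite sites).
# Returns summary statistics only: S, theta_pi, K (haplotype count).
sim_neutral_summaries <- function(n, theta) {
  n_nodes <- 2L * n - 1L
  desc <- integer(n_nodes); desc[seq_len(n)] <- 1L
  blen <- numeric(n_nodes)
  hap <- integer(n_nodes)
  active <- seq_len(n)
  parent <- integer(n_nodes)
  nxt <- n + 1L
  k <- n
  while (k > 1L) {
    t <- stats::rexp(1L, rate = k * (k - 1) / 2)
    blen[active] <- blen[active] + t
    pick <- sample.int(k, 2L)
    a <- active[pick[1L]]; b <- active[pick[2L]]
    desc[nxt] <- desc[a] + desc[b]
    parent[a] <- nxt; parent[b] <- nxt
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
    k <- k - 1L
  }
  root <- n_nodes
  mut <- stats::rpois(n_nodes, theta / 2 * blen)
  mut[root] <- 0L
  S <- sum(mut)
  tp <- sum(mut * desc * (n - desc)) / (n * (n - 1) / 2)
  # haplotype ids: inherit parent's id through mutation-free branches
  hap[root] <- root
  ord <- order(seq_len(n_nodes), decreasing = TRUE) # root first (nodes created upward)
  for (v in rev(seq_len(n_nodes - 1L))) {
    hap[v] <- if (mut[v] == 0L) hap[parent[v]] else v
  }
  # nodes numbered so parent index > child index, rev order visits parents first
  K <- length(unique(hap[seq_len(n)]))
  list(S = S, theta_pi = tp, K = K)
}

#' Tajima's D with a simulated p-value
#'
#' `D = (theta_pi - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the usual constants.
#' The p-value comes from neutral constant-size coalescent simulations with
#' theta set to the observed `theta_pi`. The default convention (that of the
#' standard packages, visible in their printed p-values for positive D) is
#' the lower-tail probability `P(D_sim <= D_obs)`, so small p flags the
#' haplotype excess expected under expansion; `"two-sided"` is available.
#'
#' @param aln a `seq_alignment`
#' @param n_sims number of null simulations (0 skips the p-value)
#' @param seed RNG seed for the simulations
#' @param alternative "lower" (default) or "two-sided"
#' @param missing_policy column handling
#' @return list with `D`, `p`, `n_sims`, `seed`
#' @export
tajimas_d <- function(aln, n_sims = 1000L, seed = 1L,
                      alternative = c("lower", "two-sided"),
                      missing_policy = c("complete-deletion", "strict")) {
  alternative <- match.arg(alternative)
  n <- nrow(aln)
  ss <- site_summary(aln, missing_policy)
  if (ss$S == 0L) stop("undefined-statistic: no segregating sites", call. = FALSE)
  tp <- theta_pi(aln, missing_policy)$theta_pi
  D <- tajima_d_stat(tp, ss$S, n)
  p <- NA_real_
  if (n_sims >= 1L) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    dsim <- replicate(n_sims, {
      s <- sim_neutral_summaries(n, tp)
      if (s$S == 0L) 0 else tajima_d_stat(s$theta_pi, s$S, n)
    })
    # Monte-Carlo p with the observation counted (so the null rejection rate
    # at level alpha is floor(alpha*(m+1))/(m+1), never above alpha)
    p <- if (alternative == "lower") {
      (1 + sum(dsim <= D)) / (n_sims + 1)
    } else {
      (1 + sum(abs(dsim) >= abs(D))) / (n_sims + 1)
    }
  }
  list(D = D, p = p, n_sims = n_sims, seed = seed)
}

# The normalized-difference statistic itself (Tajima 1989 constants).
tajima_d_stat <- function(theta_pi, S, n) {
  a1 <- harmonic(n - 1L); a2 <- harmonic2(n - 1L)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  if (v <= 0) return(0)
  (theta_pi - S / a1) / sqrt(v)
}

# log |s(n, k)| for k = 1..n, unsigned Stirling numbers of the first kind,
# computed by the recurrence |s(n+1,k)| = |s(n,k-1)| + n*|s(n,k)| in log space.
log_stirling_first <- function(n) {
  ls <- -Inf
  cur <- 0 # row m = 1: |s(1,1)| = 1
  row <- c(0)
  if (n == 1L) return(row)
  for (m in 1L:(n - 1L)) {
    new <- numeric(m + 1L)
    for (k in 1L:(m + 1L)) {
      lower <- if (k >= 2L) row[k - 1L] else -Inf
      upper <- if (k <= m) log(m) + row[k] else -Inf
      new[k] <- logsumexp2(lower, upper)
    }
    row <- new
  }
  row
}

logsumexp2 <- function(a, b) {
  if (a == -Inf) return(b)
  if (b == -Inf) return(a)
  m <- max(a, b)
  m + log(exp(a - m) + exp(b - m))
}

#' Ewens sampling distribution of the haplotype count
#'
#' Log-probabilities `log P(K = k | theta, n)` for k = 1..n under the Ewens
#' sampling formula, via log-space unsigned Stirling numbers of the first
#' kind.
#'
#' @param n sample size
#' @param theta scaled mutation parameter (> 0)
#' @return numeric vector of length n of log-probabilities
#' @export
ewens_log_probs <- function(n, theta) {
  if (theta <= 0) stop("theta must be > 0", call. = FALSE)
  ls <- log_stirling_first(n)
  lnorm <- sum(log(theta + 0:(n - 1)))
  ls + (1:n) * log(theta) - lnorm
}

#' Fu's Fs with a simulated p-value
#'
#' `S' = P(K >= k_obs | theta = theta_pi, n)` under the Ewens sampling
#' formula; `Fs = ln(S' / (1 - S'))`. The p-value is the fraction of neutral
#' coalescent simulations with `Fs_sim <= Fs_obs` (the standard convention:
#' small Fs indicates haplotype excess).
#'
#' @param aln a `seq_alignment`
#' @param n_sims number of null simulations (0 skips the p-value)
#' @param seed RNG seed
#' @param missing_policy column handling
#' @return list with `Fs`, `p`, `S_prime`, `n_sims`, `seed`. `Fs` is
#'   `+/-Inf` (flagged via `boundary = TRUE`) when `S'` underflows to 0 or 1.
#' @export
fus_fs <- function(aln, n_sims = 1000L, seed = 1L,
                   missing_policy = c("complete-deletion", "strict")) {
  n <- nrow(aln)
  if (n < 2L) stop("insufficient-data: need >= 2 sequences", call. = FALSE)
  tp <- theta_pi(aln, missing_policy)$theta_pi
  ht <- collapse_haplotypes(aln, missing_policy)
  k_obs <- length(ht$haplotypes)
  Fs <- fs_stat(n, tp, k_obs)
  p <- NA_real_
  if (n_sims >= 1L && is.finite(Fs)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    fsim <- replicate(n_sims, {
      s <- sim_neutral_summaries(n, tp)
      if (s$theta_pi <= 0) 0 else fs_stat(n, s$theta_pi, s$K)
    })
    p <- (1 + sum(fsim <= Fs)) / (n_sims + 1)
  }
  sp <- attr(Fs, "S_prime")
  list(Fs = as.numeric(Fs), p = p, S_prime = sp,
       boundary = !is.finite(Fs), n_sims = n_sims, seed = seed)
}

# Fs statistic from (n, theta, observed haplotype count).
fs_stat <- function(n, theta, k_obs) {
  if (theta <= 0) return(structure(Inf, S_prime = 1))
  lp <- ewens_log_probs(n, theta)
  # log S' = log sum_{k >= k_obs} P(K = k)
  tail <- lp[k_obs:n]
  m <- max(tail)
  lsp <- m + log(sum(exp(tail - m)))
  sp <- exp(lsp)
  if (sp >= 1) return(structure(-Inf, S_prime = 1)) # impossible: guard
  # log(1 - S') computed stably from the head of the distribution
  head_ <- if (k_obs > 1L) lp[1:(k_obs - 1L)] else -Inf
  mh <- max(head_)
  l1msp <- if (is.infinite(mh)) -Inf else mh + log(sum(exp(head_ - mh)))
  if (l1msp == -Inf) return(structure(Inf, S_prime = sp))
  if (sp == 0) return(structure(-Inf, S_prime = 0))
  structure(lsp - l1msp, S_prime = sp)
}

# Save/restore the global RNG state so seeded internals do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
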