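# Mismatch distributions, sudden-expansion model fitting, and
# mutation-rate-calibrated expansion dating.
#
# Model. A population at equilibrium theta0 expands instantaneously to
# theta1 at tau units of mutational time before the present. The expected
# distribution of the number of pairwise differences d is the equilibrium
# geometric distribution propagated through the expansion:
#
#   F(d) = F_e(d, theta1) +
#          exp(-tau (theta1 + 1) / theta1) *
#          sum_{m=0}^{d} tau^m / m! * [F_e(d - m, theta0) - F_e(d - m, theta1)]
#
# with F_e(d, theta) = theta^d / (1 + theta)^(d + 1).

#' Mismatch histogram of pairwise differences
#'
#' @param aln a `seq_alignment` with n >= 2
#' @param missing_policy column handling
#' @return object of class `mismatch_histogram`: integer vector `counts`
#'   indexed by difference d = 0..d_max, plus `n_pairs` and `n`.
#' @export
mismatch_histogram <- function(aln, missing_policy = c("complete-deletion", "strict")) {
  n <- nrow(aln)
  if (n < 2L) stop("insufficient-data: need >= 2 sequences", call. = FALSE)
  d <- pairwise_differences(aln, missing_policy)
  dv <- d[upper.tri(d)]
  counts <- tabulate(dv + 1L, nbins = max(dv) + 1L)
  structure(
    list(counts = counts, d = 0:(length(counts) - 1L),
         n_pairs = length(dv), n = n),
    class = "mismatch_histogram"
  )
}

#' @export
print.mismatch_histogram <- function(x, ...) {
  cat(sprintf("mismatch_histogram: %d pairs, mean %.3f differences\n",
              x$n_pairs, mismatch_mean(x)))
  invisible(x)
}

#' Mean of a mismatch histogram (equals theta-pi of the same alignment)
#' @param hist a `mismatch_histogram`
#' @return numeric
#' @export
mismatch_mean <- function(hist) sum(hist$d * hist$counts) / hist$n_pairs

geometric_eq <- function(d, theta) {
  # F_e(d) = theta^d / (1+theta)^(d+1), stable for large theta in logs
  exp(d * log(theta) - (d + 1) * log1p(theta))
}

#' Expected mismatch distribution under the sudden-expansion model
#'
#' @param tau mutational time since expansion (>= 0)
#' @param theta0,theta1 pre- and post-expansion scaled population sizes,
#'   `0 <= theta0 <= theta1`
#' @param d_max largest difference class to return
#' @return numeric vector `F(0..d_max)`; attribute `truncation` holds the
#'   probability mass beyond `d_max`.
#' @export
expected_mismatch <- function(tau, theta0, theta1, d_max) {
  if (!all(is.finite(c(tau, theta0, theta1))) || tau < 0 ||
      theta0 < 0 || theta1 < theta0) {
    stop("domain-error: invalid sudden-expansion parameters", call. = FALSE)
  }
  d <- 0:d_max
  f1 <- if (theta1 == 0) as.numeric(d == 0) else geometric_eq(d, theta1)
  f0 <- if (theta0 == 0) as.numeric(d == 0) else geometric_eq(d, theta0)
  if (theta1 == 0) {
    # recent size zero: pairs coalesce immediately, no differences accrue
    out <- as.numeric(d == 0)
    return(structure(out, truncation = 0))
  }
  if (tau == 0) {
    # no-expansion limit: equilibrium at theta1 only when theta0 == theta1;
    # an instantaneous expansion at time zero leaves the ancient equilibrium
    out <- f0
  } else {
    lpois <- d * log(tau) - lgamma(d + 1) # tau^m / m! in logs (unnormalized)
    pois <- exp(lpois)
    conv <- numeric(d_max + 1L)
    for (j in d) {
      m <- 0:j
      conv[j + 1L] <- sum(pois[m + 1L] * (f0[j - m + 1L] - f1[j - m + 1L]))
    }
    out <- f1 + exp(-tau * (theta1 + 1) / theta1) * conv
  }
  out <- pmax(out, 0)
  structure(out, truncation = max(0, 1 - sum(out)))
}

#' Harpending's raggedness index
#'
#' `r = sum_{i=1}^{d+1} (x_i - x_{i-1})^2` over relative frequencies `x`,
#' with `x_{d+1} = 0` and `d` the maximum observed difference.
#'
#' @param hist a `mismatch_histogram` (or a bare relative-frequency vector)
#' @return numeric raggedness index
#' @export
raggedness <- function(hist) {
  x <- if (inherits(hist, "mismatch_histogram")) hist$counts / hist$n_pairs else hist
  sum(diff(c(0, x, 0))^2)
}

#' Fit the sudden-expansion model to a mismatch histogram
#'
#' Least squares between observed relative frequencies and
#' [expected_mismatch()], by a deterministic coarse grid over
#' `(tau, theta0, theta1)` followed by Nelder-Mead refinement within bounds.
#' Parametric-bootstrap replicates (coalescent data simulated under the
#' fitted model, then re-fit) give the SSD and raggedness p-values and
#' percentile confidence intervals.
#'
#' @param hist a `mismatch_histogram` built from >= 3 sequences
#' @param n_boot parametric bootstrap replicates (0 disables)
#' @param seed RNG seed for the bootstrap
#' @param L sequence length used when simulating bootstrap replicates
#'   (defaults to a length comfortably above `d_max`)
#' @param tau_max,theta0_max,theta1_max search bounds; `theta1_max` defaults
#'   to 99999, the conventional upper bound at which boundary estimates are
#'   reported
#' @return object of class `sudden_expansion_fit`
#' @export
fit_sudden_expansion <- function(hist, n_boot = 1000L, seed = 1L, L = NULL,
                                 tau_max = 50, theta0_max = 50,
                                 theta1_max = 99999) {
  if (hist$n < 3L) stop("insufficient-data: need >= 3 sequences", call. = FALSE)
  obs <- hist$counts / hist$n_pairs
  d_max <- length(obs) - 1L
  est <- fit_expansion_point(obs, tau_max, theta0_max, theta1_max)
  rag <- raggedness(hist)
  boot <- NULL
  p_ssd <- NA_real_; p_rag <- NA_real_
  ci <- NULL
  if (n_boot >= 1L) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    if (is.null(L)) L <- max(4L * (d_max + 1L), 100L)
    boot <- matrix(NA_real_, n_boot, 5L,
                   dimnames = list(NULL, c("tau", "theta0", "theta1", "SSD", "raggedness")))
    for (b in seq_len(n_boot)) {
      sim <- simulate_alignment(
        demography_model("sudden_expansion", theta0 = est$theta0,
                         theta1 = min(est$theta1, theta1_max),
                         tau = est$tau, n = hist$n),
        L = L, seed = NULL, infinite_sites = TRUE
      )
      hs <- mismatch_histogram(sim)
      ob <- hs$counts / hs$n_pairs
      eb <- fit_expansion_point(ob, tau_max, theta0_max, theta1_max)
      boot[b, ] <- c(eb$tau, eb$theta0, eb$theta1, eb$SSD, raggedness(hs))
    }
    p_ssd <- mean(boot[, "SSD"] >= est$SSD)
    p_rag <- mean(boot[, "raggedness"] >= rag)
    ci <- apply(boot[, 1:3, drop = FALSE], 2L, stats::quantile,
                probs = c(0.025, 0.975), names = FALSE)
    rownames(ci) <- c("low", "high")
  }
  structure(
    list(tau = est$tau, theta0 = est$theta0, theta1 = est$theta1,
         SSD = est$SSD, p_SSD = p_ssd,
         raggedness = rag, p_raggedness = p_rag,
         ci95 = ci, n_boot = n_boot, seed = seed,
         boundary_theta1 = est$theta1 >= theta1_max,
         observed = obs, n = hist$n, n_pairs = hist$n_pairs),
    class = "sudden_expansion_fit"
  )
}

# Deterministic point estimation: coarse grid then Nelder-Mead on a clamped
# parameterization. SSD over classes 0..d_max of the observed histogram.
fit_expansion_point <- function(obs, tau_max, theta0_max, theta1_max) {
  d_max <- length(obs) - 1L
  ssd <- function(par) {
    tau <- min(max(par[1], 0), tau_max)
    th0 <- min(max(par[2], 0), theta0_max)
    th1 <- min(max(par[3], th0), theta1_max)
    e <- expected_mismatch(tau, th0, th1, d_max)
    sum((obs - e)^2)
  }
  mu_obs <- sum((0:d_max) * obs)
  taus <- unique(c(0, mu_obs, seq(0, min(tau_max, 2 * (d_max + 1)), length.out = 13)))
  th0s <- unique(c(0, 0.5, exp(seq(log(0.1), log(theta0_max), length.out = 7))))
  th1s <- unique(c(1, 5, 10, 50, 100, 1000, theta1_max))
  grid <- expand.grid(tau = taus, theta0 = th0s, theta1 = th1s)
  grid <- grid[grid$theta1 >= grid$theta0, , drop = FALSE]
  vals <- apply(grid, 1L, ssd)
  best <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(best, ssd, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  # polish from the grid optimum too, keep the better of the two
  if (opt$value > min(vals)) opt <- list(par = best, value = min(vals))
  tau <- min(max(opt$par[1], 0), tau_max)
  th0 <- min(max(opt$par[2], 0), theta0_max)
  th1 <- min(max(opt$par[3], th0), theta1_max)
  list(tau = tau, theta0 = th0, theta1 = th1, SSD = opt$value)
}

#' @export
print.sudden_expansion_fit <- function(x, ...) {
  cat("Sudden-expansion model fit\n")
  cat(sprintf("  tau    = %.3f\n  theta0 = %.3f\n  theta1 = %s\n",
              x$tau, x$theta0,
              if (x$boundary_theta1) sprintf("%.1f (upper bound)", x$theta1)
              else sprintf("%.3f", x$theta1)))
  cat(sprintf("  SSD = %.4f (P = %s)   raggedness = %.3f (P = %s)\n",
              x$SSD, format_p(x$p_SSD), x$raggedness, format_p(x$p_raggedness)))
  if (!is.null(x$ci95)) {
    cat(sprintf("  95%% CI: tau (%.3f-%.3f), theta0 (%.3f-%.3f), theta1 (%.3f-%.3f)\n",
                x$ci95["low", "tau"], x$ci95["high", "tau"],
                x$ci95["low", "theta0"], x$ci95["high", "theta0"],
                x$ci95["low", "theta1"], x$ci95["high", "theta1"]))
  }
  invisible(x)
}

format_p <- function(p) if (is.na(p)) "NA" else sprintf("%.3f", p)

#' @export
coef.sudden_expansion_fit <- function(object, ...) {
  c(tau = object$tau, theta0 = object$theta0, theta1 = object$theta1)
}

#' @export
summary.sudden_expansion_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Predicted mismatch probabilities from a fitted expansion model
#' @param object a `sudden_expansion_fit`
#' @param d_max largest difference class (defaults to the observed range)
#' @param ... unused
#' @return numeric vector of expected relative frequencies
#' @export
predict.sudden_expansion_fit <- function(object, d_max = NULL, ...) {
  if (is.null(d_max)) d_max <- length(object$observed) - 1L
  as.numeric(expected_mismatch(object$tau, object$theta0, object$theta1, d_max))
}

#' @export
plot.sudden_expansion_fit <- function(x, ...) {
  d <- seq_along(x$observed) - 1L
  graphics::barplot(x$observed, names.arg = d, border = NA, col = "grey80",
                    xlab = "pairwise differences", ylab = "relative frequency", ...)
  graphics::lines(seq_along(d) - 0.5, predict(x), lwd = 2)
  invisible(x)
}

#' Time since expansion from tau and a mutation-rate calibration
#'
#' `t = tau / (2 mu)` generations, with `mu = L * rate_per_bp_per_year *
#' generation_time` the per-sequence per-generation mutation rate. With a
#' one-year generation time, generations equal years.
#'
#' @param tau mutational time since expansion (>= 0)
#' @param L sequence length in bp
#' @param rate_per_bp_per_year substitution rate per bp per year
#'   (e.g. `1.3e-8` for 1.3 percent per bp per million years)
#' @param generation_time generation time in years
#' @return list with exact time `t`, `t_truncated` (whole generations,
#'   matching conventional printed values), `mu`, and the inputs
#' @export
expansion_time <- function(tau, L, rate_per_bp_per_year, generation_time = 1) {
  if (rate_per_bp_per_year <= 0) stop("domain-error: rate must be > 0", call. = FALSE)
  if (L <= 0 || generation_time <= 0) stop("domain-error: L and generation_time must be > 0", call. = FALSE)
  if (tau < 0) stop("domain-error: tau must be >= 0", call. = FALSE)
  mu <- L * rate_per_bp_per_year * generation_time
  t <- tau / (2 * mu)
  list(t = t, t_truncated = trunc(t), mu = mu, L = L,
       rate_per_bp_per_year = rate_per_bp_per_year,
       generation_time = generation_time)
}
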