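# Population structure: haplotypic AMOVA (Phi-ST from pairwise molecular
# distances -- commonly reported as F_ST), permutation tests, great-circle
# distances, and the Mantel test of isolation by distance.
#
# Phi-ST here is the one-level AMOVA estimator of Excoffier, Smouse &
# Quattro (1992) on a matrix of pairwise sequence differences used as
# squared distances: SS_total = sum_{i<j} d_ij / N, SS_within summed per
# population, variance components from expected mean squares with unequal
# sample sizes, Phi_ST = sigma2_among / (sigma2_among + sigma2_within).

#' Matrix of pairwise sequence differences
#'
#' @param aln a `seq_alignment` with n >= 2
#' @param missing_policy column handling before comparison
#' @return symmetric numeric matrix with zero diagonal, labelled by sample id
#' @export
pairwise_difference_matrix <- function(aln, missing_policy = c("complete-deletion", "strict")) {
  if (nrow(aln) < 2L) stop("insufficient-data: need >= 2 sequences", call. = FALSE)
  pairwise_differences(aln, missing_policy)
}

# Sums of squares for one grouping of a squared-distance matrix.
amova_ss <- function(d2, pop) {
  N <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- 0
  for (p in unique(pop)) {
    idx <- which(pop == p)
    if (length(idx) > 1L) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  list(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

phi_from_ss <- function(ss, pop) {
  N <- length(pop)
  sizes <- table(pop)
  P <- length(sizes)
  df_among <- P - 1L
  df_within <- N - P
  n_prime <- (N - sum(sizes^2) / N) / df_among
  ms_among <- ss$among / df_among
  ms_within <- if (df_within > 0) ss$within / df_within else 0
  sigma2_within <- ms_within
  sigma2_among <- (ms_among - ms_within) / n_prime
  tot <- sigma2_among + sigma2_within
  phi <- if (tot == 0) 0 else sigma2_among / tot
  list(phi_st = phi, sigma2_among = sigma2_among, sigma2_within = sigma2_within,
       pct_among = if (tot == 0) 0 else 100 * sigma2_among / tot,
       df_among = df_among, df_within = df_within)
}

#' One-level AMOVA with a permutation test
#'
#' Individuals are permuted among populations (population sizes held fixed);
#' the p-value is the fraction of permutations, the observed configuration
#' included, with `Phi_perm >= Phi_obs`.
#'
#' Negative variance components (and hence Phi_ST below 0) are retained, not
#' truncated, and flagged via `negative_component`.
#'
#' @param dist square matrix of pairwise differences (labels = sample ids)
#' @param grouping named character vector: population label per sample id
#' @param n_perm number of permutations (0 disables the test)
#' @param seed RNG seed
#' @return object of class `amova_result`
#' @export
amova <- function(dist, grouping, n_perm = 10000L, seed = 1L) {
  ids <- rownames(dist)
  pop <- as.character(grouping[ids])
  if (anyNA(pop)) {
    stop("grouping-error: samples without a population label", call. = FALSE)
  }
  sizes <- table(pop)
  if (length(sizes) < 2L) {
    stop("grouping-error: need >= 2 populations", call. = FALSE)
  }
  if (sum(sizes >= 2L) < 1L) {
    stop("grouping-error: no population with >= 2 samples", call. = FALSE)
  }
  ss <- amova_ss(dist, pop)
  est <- phi_from_ss(ss, pop)
  p <- NA_real_
  if (n_perm >= 1L) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    hits <- 1L # observed configuration counts
    for (b in seq_len(n_perm)) {
      pp <- sample(pop)
      phi_b <- phi_from_ss(amova_ss(dist, pp), pp)$phi_st
      if (phi_b >= est$phi_st) hits <- hits + 1L
    }
    p <- hits / (n_perm + 1L)
  }
  structure(
    c(est, list(p = p, n_perm = n_perm, seed = seed,
                sizes = sizes, ss = ss,
                negative_component = est$sigma2_among < 0)),
    class = "amova_result"
  )
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (one level)\n")
  cat(sprintf("  Phi_ST = %.4f%s   P = %s  (%d permutations)\n",
              x$phi_st,
              if (x$negative_component) " [negative variance component]" else "",
              format_p(x$p), x$n_perm))
  cat(sprintf("  sigma2 among = %.4f (%.1f%%), within = %.4f\n",
              x$sigma2_among, x$pct_among, x$sigma2_within))
  invisible(x)
}

#' Pairwise population Phi-ST matrix
#'
#' Runs [amova()] on every population pair; no multiple-testing correction
#' is applied unless `p_adjust` names a method.
#'
#' @param dist square matrix of pairwise differences
#' @param grouping named character vector: population per sample id
#' @param n_perm permutations per pair
#' @param seed RNG seed (each pair uses an offset of it, deterministically)
#' @param p_adjust method for [stats::p.adjust()], or `"none"`
#' @return list with symmetric matrices `phi_st` and `p` (diagonal `NA`)
#' @export
pairwise_phist <- function(dist, grouping, n_perm = 10000L, seed = 1L,
                           p_adjust = "none") {
  ids <- rownames(dist)
  pop <- as.character(grouping[ids])
  pops <- sort(unique(pop))
  k <- length(pops)
  phi <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  pv <- phi
  pair_idx <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      pair_idx <- pair_idx + 1L
      keep <- ids[pop %in% c(pops[i], pops[j])]
      a <- amova(dist[keep, keep, drop = FALSE], grouping[keep],
                 n_perm = n_perm, seed = seed + pair_idx)
      phi[i, j] <- phi[j, i] <- a$phi_st
      pv[i, j] <- pv[j, i] <- a$p
    }
  }
  if (p_adjust != "none") {
    lower <- lower.tri(pv)
    pv[lower] <- stats::p.adjust(pv[lower], method = p_adjust)
    pv[upper.tri(pv)] <- t(pv)[upper.tri(pv)]
  }
  list(phi_st = phi, p = pv)
}

#' Great-circle (haversine) distance matrix in km
#'
#' Haversine distances on a sphere of radius 6371 km. With a `populations`
#' vector, returns the population-level matrix whose entries are the mean
#' distance over all cross-population sample pairs.
#'
#' @param coords data.frame with `latitude`, `longitude`, rownames = sample
#'   ids (or a `sample_id` column)
#' @param populations optional named character vector, population per sample
#' @return symmetric distance matrix (km)
#' @export
great_circle_matrix <- function(coords, populations = NULL) {
  if ("sample_id" %in% names(coords)) rownames(coords) <- coords$sample_id
  miss <- !stats::complete.cases(coords[, c("latitude", "longitude")])
  if (any(miss)) {
    warning(sprintf("%d samples without coordinates excluded", sum(miss)))
    coords <- coords[!miss, , drop = FALSE]
  }
  ids <- rownames(coords)
  lat <- coords$latitude * pi / 180
  lon <- coords$longitude * pi / 180
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(max(n - 1L, 0L))) {
    j <- (i + 1L):n
    dlat <- lat[j] - lat[i]
    dlon <- lon[j] - lon[i]
    a <- sin(dlat / 2)^2 + cos(lat[i]) * cos(lat[j]) * sin(dlon / 2)^2
    dij <- 2 * 6371 * asin(pmin(1, sqrt(a)))
    d[i, j] <- dij
    d[j, i] <- dij
  }
  if (is.null(populations)) return(d)
  pop <- as.character(populations[ids])
  if (anyNA(pop)) stop("grouping-error: samples without a population", call. = FALSE)
  pops <- sort(unique(pop))
  if (any(!pops %in% pop)) stop("grouping-error: empty population", call. = FALSE)
  k <- length(pops)
  pd <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(max(k - 1L, 0L))) {
    for (j in (i + 1L):k) {
      pd[i, j] <- pd[j, i] <- mean(d[pop == pops[i], pop == pops[j]])
    }
  }
  pd
}

#' Mantel test of matrix correlation
#'
#' Pearson correlation over the lower triangles; the p-value is the
#' proportion of simultaneous row/column permutations of one matrix (the
#' observed ordering included) with `r_perm >= r_obs` (one-tailed, positive
#' association). With `exact = TRUE`, or whenever the label count is at
#' most `exact_limit`, all permutations are enumerated.
#'
#' @param geo,gen square symmetric matrices with identical labels
#' @param n_perm number of random permutations
#' @param seed RNG seed
#' @param exact force exhaustive enumeration
#' @param exact_limit matrix size up to which enumeration is automatic
#' @return object of class `mantel_result` with `r`, `p`, `n_perm`, `seed`
#' @export
mantel_test <- function(geo, gen, n_perm = 10000L, seed = 1L,
                        exact = FALSE, exact_limit = 5L) {
  if (!identical(dim(geo), dim(gen))) stop("matrix shapes differ", call. = FALSE)
  if (!is.null(rownames(geo)) && !is.null(rownames(gen))) {
    if (!identical(rownames(geo), rownames(gen))) {
      stop("matrix labels differ", call. = FALSE)
    }
  }
  n <- nrow(geo)
  if (n < 3L) stop("need >= 3 labels", call. = FALSE)
  lt <- lower.tri(geo)
  x <- geo[lt]; y <- gen[lt]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined-correlation: constant matrix", call. = FALSE)
  }
  r_obs <- stats::cor(x, y)
  perm_r <- function(ord) stats::cor(geo[ord, ord][lt], y)
  if (exact || n <= exact_limit) {
    perms <- all_permutations(n)
    rs <- vapply(perms, perm_r, numeric(1))
    p <- mean(rs >= r_obs - 1e-12)
    n_used <- length(perms)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    hits <- 1L
    for (b in seq_len(n_perm)) {
      if (perm_r(sample.int(n)) >= r_obs - 1e-12) hits <- hits + 1L
    }
    p <- hits / (n_perm + 1L)
    n_used <- n_perm
  }
  structure(list(r = r_obs, p = p, n_perm = n_used, seed = seed,
                 exact = exact || n <= exact_limit),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, P = %.4f (%s, %d permutations)\n",
              x$r, x$p, if (x$exact) "exact" else "randomized", x$n_perm))
  invisible(x)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Latitudinal band classification
#'
#' Bands broadly covering southern, central and northern India:
#' `10N-19.9N`, `20N-28.9N`, `29N-35N`. The printed bands leave gaps
#' (19.9 to 20, 28.9 to 29); the closure rule assigns a gap value to the
#' lower band, i.e. the half-open intervals `[10,20)`, `[20,29)`, `[29,35]`.
#'
#' @param lat latitude in decimal degrees (vectorized)
#' @return character vector of band labels; values outside `[10, 35]` get
#'   `"unclassified"` with a warning
#' @export
assign_latitudinal_class <- function(lat) {
  out <- rep("unclassified", length(lat))
  out[lat >= 10 & lat < 20] <- "10N-19.9N"
  out[lat >= 20 & lat < 29] <- "20N-28.9N"
  out[lat >= 29 & lat <= 35] <- "29N-35N"
  if (any(out == "unclassified")) {
    warning(sprintf("%d latitudes outside [10, 35] left unclassified",
                    sum(out == "unclassified")))
  }
  out
}
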