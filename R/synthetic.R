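# Synthetic-data generators: coalescent sequence alignments under the
# demographies the analyses assume, and climate rasters with
# threshold-governed presence points.
#
# Time scale. Genealogies are simulated in units of N_e generations for the
# reference (most recent) population, where for maternally inherited mtDNA
# theta = 2 * N_e * mu_seq. A pair of lineages in one deme then coalesces at
# rate 1 per unit time and each lineage mutates at rate theta/2 per unit, so
# E[pairwise differences] = theta at equilibrium and the expansion time
# parameter tau (mutational units) maps to tau/theta1 time units.

#' Describe a demographic model for the coalescent simulator
#'
#' @param kind `"constant"`, `"sudden_expansion"`, or `"two_island"`
#' @param theta scaled mutation parameter (constant and two-island models)
#' @param theta0,theta1,tau sudden-expansion parameters: ancient and recent
#'   theta and the expansion time in mutational units
#' @param M scaled migration rate between the two islands (events per
#'   lineage per coalescent time unit)
#' @param T_split time (coalescent units) at which, looking backward, the two
#'   islands merge into one ancestral population (`Inf` = never)
#' @param n sample size (single population) or vector of two deme sizes
#' @return object of class `demography_model`
#' @export
demography_model <- function(kind = c("constant", "sudden_expansion", "two_island"),
                             theta = 5, theta0 = NULL, theta1 = NULL, tau = NULL,
                             M = 1, T_split = Inf, n = 20L) {
  kind <- match.arg(kind)
  if (kind == "sudden_expansion") {
    if (is.null(theta0) || is.null(theta1) || is.null(tau)) {
      stop("sudden_expansion needs theta0, theta1, tau", call. = FALSE)
    }
    if (theta0 < 0 || theta1 < theta0 || tau < 0) {
      stop("domain-error: need 0 <= theta0 <= theta1 and tau >= 0", call. = FALSE)
    }
  }
  if (kind == "two_island") {
    if (length(n) != 2L) stop("two_island needs two deme sample sizes", call. = FALSE)
    if (M <= 0 && !is.finite(T_split)) {
      stop("domain-error: two_island with M = 0 needs a finite T_split", call. = FALSE)
    }
  }
  if (any(n < 1L) || sum(n) < 2L) stop("domain-error: need >= 2 samples", call. = FALSE)
  structure(list(kind = kind, theta = theta, theta0 = theta0, theta1 = theta1,
                 tau = tau, M = M, T_split = T_split, n = as.integer(n)),
            class = "demography_model")
}

# Structured coalescent genealogy. Returns parent pointers, branch lengths,
# and descendant-leaf counts; nodes 1..n are leaves, internals are numbered
# in coalescence order so every parent index exceeds its children's.
simulate_genealogy <- function(model) {
  n <- sum(model$n)
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  blen <- numeric(n_nodes)
  birth <- numeric(n_nodes)
  desc <- integer(n_nodes); desc[seq_len(n)] <- 1L
  deme <- if (model$kind == "two_island") rep(1:2, model$n) else rep(1L, n)
  active <- seq_len(n)
  act_deme <- deme
  nxt <- n + 1L
  t <- 0
  # epoch machinery
  mult <- 1 # coalescence-rate multiplier (recent epoch)
  t_exp <- Inf; mult_ancient <- 1
  if (model$kind == "sudden_expansion") {
    t_exp <- if (model$theta1 > 0) model$tau / model$theta1 else 0
    mult_ancient <- if (model$theta0 > 0) model$theta1 / model$theta0 else Inf
  }
  t_merge <- if (model$kind == "two_island") model$T_split else Inf
  repeat {
    k <- length(active)
    if (k == 1L) break
    k1 <- sum(act_deme == 1L); k2 <- k - k1
    rc1 <- k1 * (k1 - 1) / 2 * mult
    rc2 <- k2 * (k2 - 1) / 2 * mult
    rm <- if (t < t_merge && model$kind == "two_island") model$M * k else 0
    R <- rc1 + rc2 + rm
    b <- min(if (t < t_exp) t_exp else Inf, if (t < t_merge) t_merge else Inf)
    dt <- if (R > 0) stats::rexp(1L, R) else Inf
    if (t + dt >= b) {
      t <- b
      if (b == t_exp) {
        if (is.infinite(mult_ancient)) {
          # ancient size zero: everything coalesces at the boundary
          while (length(active) > 1L) {
            blen[active[1:2]] <- t - birth[active[1:2]]
            desc[nxt] <- desc[active[1L]] + desc[active[2L]]
            parent[active[1:2]] <- nxt
            birth[nxt] <- t
            active <- c(active[-(1:2)], nxt)
            act_deme <- c(act_deme[-(1:2)], 1L)
            nxt <- nxt + 1L
          }
          break
        }
        mult <- mult_ancient
        t_exp <- Inf
      } else {
        act_deme[] <- 1L
        t_merge <- Inf
      }
      next
    }
    t <- t + dt
    u <- stats::runif(1L) * R
    if (u < rc1 + rc2) {
      d <- if (u < rc1) 1L else 2L
      idx <- which(act_deme == d)
      pick <- idx[sample.int(length(idx), 2L)]
      a <- active[pick[1L]]; c2 <- active[pick[2L]]
      blen[c(a, c2)] <- t - birth[c(a, c2)]
      desc[nxt] <- desc[a] + desc[c2]
      parent[c(a, c2)] <- nxt
      birth[nxt] <- t
      active <- c(active[-pick], nxt)
      act_deme <- c(act_deme[-pick], d)
      nxt <- nxt + 1L
    } else {
      i <- sample.int(k, 1L)
      act_deme[i] <- 3L - act_deme[i]
    }
  }
  list(parent = parent, blen = blen, desc = desc, n = n,
       root = active[1L], deme = deme)
}

#' Simulate a sequence alignment under a coalescent demography
#'
#' Mutations are placed on branches as a Poisson process at rate `theta/2`
#' per lineage per coalescent time unit (theta = `theta1` for the
#' sudden-expansion model). Under finite sites (default) each mutation hits a
#' uniformly chosen position and substitutes with transition:transversion
#' bias `ti_tv`; under `infinite_sites = TRUE` every mutation creates a new
#' segregating column.
#'
#' @param model a [demography_model()]
#' @param L alignment length in bp
#' @param ti_tv transition/transversion ratio of the mutation process
#' @param seed RNG seed (`NULL` = use the current RNG stream)
#' @param infinite_sites logical
#' @return a `seq_alignment` with attributes `genealogy` (the simulated
#'   tree summary) and `provenance` (seed and parameters); sample ids are
#'   `s1..sn`, prefixed by deme for the two-island model.
#' @export
simulate_alignment <- function(model, L = 601L, ti_tv = 4.7, seed = NULL,
                               infinite_sites = FALSE) {
  if (L < 1L) stop("domain-error: L must be >= 1", call. = FALSE)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  g <- simulate_genealogy(model)
  theta <- if (model$kind == "sudden_expansion") model$theta1 else model$theta
  n_nodes <- 2L * g$n - 1L
  mut <- stats::rpois(n_nodes, theta / 2 * g$blen)
  mut[g$root] <- 0L
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  transversions <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  if (infinite_sites) {
    total <- sum(mut)
    ncols <- max(total, 1L)
    seqs <- matrix("A", n_nodes, ncols)
    site_counter <- 0L
  } else {
    anc <- sample(bases, L, replace = TRUE)
    seqs <- matrix(rep(anc, each = n_nodes), n_nodes, L)
  }
  p_ti <- ti_tv / (ti_tv + 1)
  # propagate sequences root-down (parents have larger indices than children)
  for (v in rev(seq_len(n_nodes))) {
    if (v != g$root) seqs[v, ] <- seqs[g$parent[v], ]
    m <- mut[v]
    if (m == 0L) next
    if (infinite_sites) {
      sites <- site_counter + seq_len(m)
      site_counter <- site_counter + m
      # flip the new columns in this subtree (A -> G marker)
      seqs[v, sites] <- "G"
    } else {
      sites <- sample.int(L, m, replace = TRUE)
      for (s in sites) {
        cur <- seqs[v, s]
        seqs[v, s] <- if (stats::runif(1L) < p_ti) transition[[cur]] else
          sample(transversions[[cur]], 1L)
      }
    }
  }
  if (infinite_sites) {
    # descendants inherit flipped columns: redo propagation top-down with
    # cumulative mutations (handled above since children copy parents before
    # applying their own mutations)
    NULL
  }
  ids <- if (model$kind == "two_island") {
    paste0("d", g$deme, "_s", seq_len(g$n))
  } else paste0("s", seq_len(g$n))
  aln <- structure(seqs[seq_len(g$n), , drop = FALSE], class = "seq_alignment")
  rownames(aln) <- ids
  attr(aln, "genealogy") <- g
  attr(aln, "provenance") <- list(seed = seed, model = model, L = L,
                                  ti_tv = ti_tv, infinite_sites = infinite_sites)
  aln
}

#' Simulate a stack of climate rasters
#'
#' Each layer is a deterministic linear gradient in row/column plus seeded
#' Gaussian noise, optionally with a nodata border.
#'
#' @param nrows,ncols grid shape
#' @param variables list of specs `list(name=, intercept=, per_row=,
#'   per_col=, noise_sd=)`
#' @param seed RNG seed (`NULL` = current stream)
#' @param nodata_border width in cells of a NA border around the grid
#' @param xll,yll,cellsize georeferencing (lower-left corner, degrees)
#' @return a [climate_stack()]
#' @export
simulate_climate_stack <- function(nrows, ncols, variables, seed = NULL,
                                   nodata_border = 0L,
                                   xll = 0, yll = 0, cellsize = 0.1) {
  if (nrows < 1L || ncols < 1L) stop("domain-error: shape must be positive", call. = FALSE)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  layers <- list()
  for (v in variables) {
    r <- matrix(rep(seq_len(nrows) - 1L, ncols), nrows, ncols)
    cc <- matrix(rep(seq_len(ncols) - 1L, each = nrows), nrows, ncols)
    m <- v$intercept + v$per_row * r + v$per_col * cc
    if (!is.null(v$noise_sd) && v$noise_sd > 0) {
      m <- m + matrix(stats::rnorm(nrows * ncols, sd = v$noise_sd), nrows, ncols)
    }
    if (nodata_border > 0L) {
      b <- seq_len(nodata_border)
      m[b, ] <- NA; m[nrows + 1L - b, ] <- NA
      m[, b] <- NA; m[, ncols + 1L - b] <- NA
    }
    layers[[v$name]] <- m
  }
  climate_stack(layers, xll = xll, yll = yll, cellsize = cellsize)
}

#' Sample presence points governed by a climate rule
#'
#' Uniform sampling without replacement from the grid cells whose values
#' satisfy `rule`, jittered within the cell.
#'
#' @param stack a [climate_stack()]
#' @param rule function taking a data.frame of per-cell variable values and
#'   returning a logical vector (TRUE = occupiable)
#' @param n number of points
#' @param seed RNG seed (`NULL` = current stream)
#' @param jitter logical; uniform within-cell jitter of the returned
#'   coordinates
#' @return data.frame with `latitude`, `longitude`, `source = "synthetic"`
#' @export
sample_presences <- function(stack, rule, n, seed = NULL, jitter = TRUE) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  vals <- stack_cell_table(stack)
  ok <- stats::complete.cases(vals[stack$variables]) & rule(vals)
  ok[is.na(ok)] <- FALSE
  idx <- which(ok)
  if (length(idx) < n) {
    stop(sprintf("sampling-error: rule satisfied on %d < n = %d cells",
                 length(idx), n), call. = FALSE)
  }
  pick <- idx[sample.int(length(idx), n)]
  lat <- vals$latitude[pick]
  lon <- vals$longitude[pick]
  if (jitter) {
    half <- stack$cellsize * 0.49
    lat <- lat + stats::runif(n, -half, half)
    lon <- lon + stats::runif(n, -half, half)
  }
  data.frame(latitude = lat, longitude = lon, source = "synthetic",
             stringsAsFactors = FALSE)
}
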