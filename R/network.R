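# Median-joining haplotype networks (Bandelt, Forster & Roehl 1999).
#
# The algorithm alternates two steps until convergence: (1) build the
# epsilon-relaxed minimum-spanning network (MSN) over the current sequence
# set under Hamming distance; (2) for every triple of mutually linked
# sequences, add the quasi-median (per-site majority consensus; sites where
# all three states differ branch over the three choices) when novel.
# Median vectors of degree <= 2 are pruned after convergence.
# All tie-breaking is by lexicographic node index, so the result is
# deterministic for a fixed input order.

hamming <- function(a, b) sum(a != b)

# Pairwise Hamming distance matrix over rows of a character matrix.
hamming_matrix <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0L, n, n)
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- hamming(mat[i, ], mat[j, ])
    }
  }
  d
}

# Epsilon-relaxed minimum spanning network. Returns a logical adjacency
# matrix: edge (u,v) present iff d(u,v) <= (weight at which u's and v's
# components first connect under ascending Kruskal processing) + epsilon.
msn_edges <- function(d, epsilon = 0L) {
  n <- nrow(d)
  comp <- seq_len(n)
  conn_w <- matrix(Inf, n, n)
  for (w in sort(unique(d[upper.tri(d)]))) {
    # union all edges of weight exactly w that link distinct components
    link <- which(d == w & outer(comp, comp, "!="), arr.ind = TRUE)
    if (nrow(link)) {
      for (k in seq_len(nrow(link))) {
        a <- comp[link[k, 1]]; b <- comp[link[k, 2]]
        if (a != b) comp[comp == b] <- a
      }
    }
    joined <- which(outer(comp, comp, "==") & !is.finite(conn_w), arr.ind = TRUE)
    if (nrow(joined)) {
      conn_w[joined] <- w
    }
    if (length(unique(comp)) == 1L && all(is.finite(conn_w[upper.tri(conn_w)]))) break
  }
  diag(conn_w) <- 0
  adj <- d > 0 & d <= conn_w + epsilon
  adj | t(adj)
}

# Quasi-median set of three aligned sequences: per-site majority; sites with
# three distinct states branch over the three choices. Returns a character
# matrix (possibly several rows); NULL when the expansion would exceed `cap`.
quasi_medians <- function(u, v, w, cap = 9L) {
  L <- length(u)
  med <- character(L)
  free <- integer(0)
  for (s in seq_len(L)) {
    st <- c(u[s], v[s], w[s])
    tab <- table(st)
    if (max(tab) >= 2L) {
      med[s] <- names(tab)[which.max(tab)]
    } else {
      free <- c(free, s)
    }
  }
  if (!length(free)) return(matrix(med, 1L))
  if (3L^length(free) > cap) return(NULL)
  choices <- expand.grid(rep(list(1:3), length(free)))
  out <- matrix(rep(med, nrow(choices)), nrow(choices), L, byrow = TRUE)
  for (r in seq_len(nrow(choices))) {
    for (k in seq_along(free)) {
      s <- free[k]
      out[r, s] <- c(u[s], v[s], w[s])[choices[r, k]]
    }
  }
  out
}

#' Median-joining haplotype network
#'
#' @param haps a `haplotype_table` from [collapse_haplotypes()], or a
#'   character vector of equal-length haplotype sequences
#' @param epsilon relaxation parameter of the minimum-spanning network
#'   (0 = strict, the distributed program's default)
#' @param counts haplotype counts when `haps` is a bare character vector
#' @param max_iter safety cap on median-addition sweeps
#' @return object of class `haplo_network`: an [igraph] graph with node
#'   attributes `name`, `sequence`, `count`, `is_median` and edge attribute
#'   `mutations`, plus the final sequence matrix
#' @export
median_joining <- function(haps, epsilon = 0L, counts = NULL, max_iter = 20L) {
  if (inherits(haps, "haplotype_table")) {
    seqs <- haps$haplotypes
    counts <- haps$counts
  } else {
    seqs <- haps
    if (is.null(counts)) counts <- rep(1L, length(seqs))
  }
  if (!length(seqs)) stop("need >= 1 haplotype", call. = FALSE)
  if (length(unique(nchar(seqs))) > 1L) {
    stop("alignment-error: haplotypes of unequal length", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  n_obs <- nrow(mat)
  is_median <- rep(FALSE, n_obs)
  if (n_obs == 1L) {
    g <- igraph::make_empty_graph(directed = FALSE)
    g <- igraph::add_vertices(g, 1L, name = "H1", sequence = seqs[1],
                              count = counts[1], is_median = FALSE)
    return(structure(list(graph = g, sequences = mat, counts = counts,
                          is_median = is_median), class = "haplo_network"))
  }
  # -- median-addition sweeps ----------------------------------------------
  for (iter in seq_len(max_iter)) {
    d <- hamming_matrix(mat)
    adj <- msn_edges(d, epsilon)
    keys <- apply(mat, 1L, paste, collapse = "")
    new_rows <- list()
    n <- nrow(mat)
    for (u in seq_len(n - 1L)) {
      for (v in (u + 1L):n) {
        if (!adj[u, v] && !any(adj[u, ] & adj[v, ])) next
        for (w in seq_len(n)) {
          if (w == u || w == v) next
          # connected triple: at least two of the three pairs are MSN links
          if (sum(adj[u, v], adj[u, w], adj[v, w]) < 2L) next
          qm <- quasi_medians(mat[u, ], mat[v, ], mat[w, ])
          if (is.null(qm)) next
          for (r in seq_len(nrow(qm))) {
            key <- paste(qm[r, ], collapse = "")
            if (!(key %in% keys) &&
                !(key %in% vapply(new_rows, function(x) x$key, character(1)))) {
              new_rows[[length(new_rows) + 1L]] <- list(key = key, row = qm[r, ])
            }
          }
        }
      }
    }
    if (!length(new_rows)) break
    add <- do.call(rbind, lapply(new_rows, `[[`, "row"))
    mat <- rbind(mat, add)
    counts <- c(counts, rep(0L, nrow(add)))
    is_median <- c(is_median, rep(TRUE, nrow(add)))
  }
  # -- prune obsolete median vectors ---------------------------------------
  repeat {
    d <- hamming_matrix(mat)
    adj <- msn_edges(d, epsilon)
    deg <- rowSums(adj)
    obsolete <- which(is_median & deg <= 2)
    if (!length(obsolete)) break
    keep <- setdiff(seq_len(nrow(mat)), obsolete)
    mat <- mat[keep, , drop = FALSE]
    counts <- counts[keep]
    is_median <- is_median[keep]
  }
  d <- hamming_matrix(mat)
  adj <- msn_edges(d, epsilon)
  # -- assemble the graph ---------------------------------------------------
  n <- nrow(mat)
  obs_idx <- which(!is_median)
  names_ <- character(n)
  names_[obs_idx] <- paste0("H", seq_along(obs_idx))
  med_idx <- which(is_median)
  names_[med_idx] <- paste0("mv", seq_along(med_idx))
  el <- which(adj & upper.tri(adj), arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = names_[el[, 1]], to = names_[el[, 2]],
               mutations = d[el]),
    directed = FALSE,
    vertices = data.frame(name = names_,
                          sequence = apply(mat, 1L, paste, collapse = ""),
                          count = counts, is_median = is_median)
  )
  structure(list(graph = g, sequences = mat, counts = counts,
                 is_median = is_median), class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf(
    "haplo_network: %d observed haplotypes, %d median vectors, %d edges\n",
    sum(!x$is_median), sum(x$is_median), igraph::ecount(x$graph)))
  invisible(x)
}

#' Total edge weight (mutation count) of a network
#' @param net a `haplo_network`
#' @return integer sum of edge mutation counts
#' @export
network_total_weight <- function(net) {
  if (igraph::ecount(net$graph) == 0L) return(0L)
  sum(igraph::E(net$graph)$mutations)
}

#' Export a haplotype network
#'
#' @param net a `haplo_network`
#' @param path output path
#' @param format `"graphml"` or `"dot"`
#' @return `path`, invisibly
#' @export
write_network <- function(net, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  if (format == "dot") {
    # DOT has no boolean attribute type; igraph's numeric coercion is fine
    suppressWarnings(igraph::write_graph(net$graph, path, format = format))
  } else {
    igraph::write_graph(net$graph, path, format = format)
  }
  invisible(path)
}
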