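# Distance-based trees: Jukes-Cantor distances, neighbour-joining with
# site-resampling bootstrap, and reciprocal-monophyly checks.

#' Jukes-Cantor distance matrix
#'
#' `d = -(3/4) * log(1 - 4p/3)` from the proportion `p` of differing sites,
#' computed per pair over the columns retained by the missing-data policy.
#'
#' @param aln a `seq_alignment`
#' @param missing_policy column handling before comparison
#' @return symmetric matrix of JC69 distances (substitutions per site)
#' @export
jukes_cantor_matrix <- function(aln, missing_policy = c("complete-deletion", "strict")) {
  used <- unclass(apply_missing_policy(aln, missing_policy))
  n <- nrow(used)
  d <- matrix(0, n, n, dimnames = list(rownames(used), rownames(used)))
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      ok <- used[i, ] %in% c("A", "C", "G", "T") & used[j, ] %in% c("A", "C", "G", "T")
      p <- sum(used[i, ok] != used[j, ok]) / sum(ok)
      if (p >= 0.75) {
        stop(sprintf("saturation-error: p = %.3f >= 0.75 for pair (%s, %s)",
                     p, rownames(used)[i], rownames(used)[j]), call. = FALSE)
      }
      d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
    }
  }
  d
}

#' Neighbour-joining tree
#'
#' Saitou-Nei agglomeration (via [ape::nj()]). Negative branch lengths are
#' clamped to zero with the deficit moved to the sister branch so that
#' leaf-to-leaf path lengths through the parent are preserved; clamped trees
#' carry attribute `clamped = TRUE`.
#'
#' @param dist symmetric distance matrix with >= 3 labels
#' @return an [ape::phylo] tree (unrooted)
#' @export
nj_tree <- function(dist) {
  if (nrow(dist) < 3L) stop("insufficient-taxa: need >= 3 labels", call. = FALSE)
  tr <- ape::nj(stats::as.dist(dist))
  neg <- which(tr$edge.length < 0)
  if (length(neg)) {
    for (e in neg) {
      child <- tr$edge[e, 2]
      parent <- tr$edge[e, 1]
      sisters <- which(tr$edge[, 1] == parent & tr$edge[, 2] != child)
      deficit <- tr$edge.length[e]
      tr$edge.length[e] <- 0
      if (length(sisters)) {
        s <- sisters[1]
        tr$edge.length[s] <- tr$edge.length[s] + deficit
      }
    }
    tr$edge.length[tr$edge.length < 0] <- 0
    attr(tr, "clamped") <- TRUE
  } else {
    attr(tr, "clamped") <- FALSE
  }
  tr
}

#' Neighbour-joining tree with site-resampling bootstrap support
#'
#' Columns are resampled with replacement; each replicate alignment yields a
#' JC69 NJ tree, and support for each internal bipartition of the
#' point-estimate tree is the percentage of replicate trees containing it.
#' Replicates whose JC distance saturates (p >= 0.75) are skipped and
#' counted.
#'
#' @param aln a `seq_alignment`
#' @param n_reps bootstrap replicates
#' @param seed RNG seed
#' @param missing_policy column handling
#' @return the point-estimate tree with `node.label` holding support
#'   percentages (root label empty); attributes `n_effective` (replicates
#'   used) and `n_saturated` (skipped)
#' @export
bootstrap_support <- function(aln, n_reps = 1000L, seed = 1L,
                              missing_policy = c("complete-deletion", "strict")) {
  used <- apply_missing_policy(aln, missing_policy)
  point <- nj_tree(jukes_cantor_matrix(used, "strict"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  L <- ncol(used)
  reps <- vector("list", n_reps)
  n_sat <- 0L
  for (b in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- structure(unclass(used)[, cols, drop = FALSE], class = "seq_alignment")
    tr <- tryCatch(nj_tree(jukes_cantor_matrix(rep_aln, "strict")),
                   error = function(e) NULL)
    if (is.null(tr)) n_sat <- n_sat + 1L else reps[[b]] <- tr
  }
  reps <- Filter(Negate(is.null), reps)
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  point$node.label <- round(100 * counts / length(reps), 1)
  attr(point, "n_effective") <- length(reps)
  attr(point, "n_saturated") <- n_sat
  point
}

#' Test reciprocal monophyly of a partition on an outgroup-rooted tree
#'
#' @param tree an [ape::phylo] tree containing `outgroup` among its tips
#' @param partition list of character vectors partitioning the ingroup tips
#' @param outgroup tip label used to root the tree
#' @return TRUE iff every set in `partition` forms a clade on the rooted tree
#' @export
is_reciprocally_monophyletic <- function(tree, partition, outgroup) {
  if (!outgroup %in% tree$tip.label) {
    stop(sprintf("key-error: outgroup '%s' not in tree", outgroup), call. = FALSE)
  }
  ingroup <- setdiff(tree$tip.label, outgroup)
  claimed <- unlist(partition)
  if (!setequal(claimed, ingroup) || anyDuplicated(claimed)) {
    stop("partition must cover the ingroup tips exactly once", call. = FALSE)
  }
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  all(vapply(partition, function(set) {
    length(set) == 1L || ape::is.monophyletic(rooted, tips = set)
  }, logical(1)))
}

#' Write a tree in Newick format (supports as internal node labels)
#' @param tree an [ape::phylo]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
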