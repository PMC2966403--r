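# Sequence I/O, haplotype collapsing and polymorphism summaries.
#
# An alignment is stored as a character matrix (rows = samples, columns =
# sites, single upper-case characters from A,C,G,T,N,-) with rownames as
# sample ids, wrapped in the lightweight S3 class "seq_alignment".

VALID_SYMBOLS <- c("A", "C", "G", "T", "N", "-")
PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Construct a sequence alignment
#'
#' @param seqs named character vector of equal-length sequences, or a
#'   character matrix (one row per sample, one column per site).
#' @param ids sample identifiers; defaults to `names(seqs)` / rownames.
#' @return An object of class `seq_alignment`: a character matrix with
#'   unique rownames, symbols restricted to `A,C,G,T,N,-`.
#' @details Input is case-insensitive; `U` is mapped to `T` with a warning.
#' @export
seq_alignment <- function(seqs, ids = NULL) {
  if (is.matrix(seqs)) {
    mat <- seqs
    if (!is.null(ids)) rownames(mat) <- ids
  } else {
    if (is.null(ids)) ids <- names(seqs)
    if (is.null(ids)) stop("sample ids are required", call. = FALSE)
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      stop(sprintf(
        "alignment-error: unequal sequence lengths (%s)",
        paste(unique(lens), collapse = ", ")
      ), call. = FALSE)
    }
    if (length(seqs) == 0L || lens[1] < 1L) {
      stop("format-error: empty alignment", call. = FALSE)
    }
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(mat) <- ids
  }
  mat[] <- toupper(mat)
  if (any(mat == "U")) {
    warning("U symbols mapped to T on input")
    mat[mat == "U"] <- "T"
  }
  bad <- which(!(mat %in% VALID_SYMBOLS))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(mat))
    stop(sprintf(
      "format-error: illegal symbol '%s' in record '%s' at position %d",
      mat[bad[1]], rownames(mat)[i[1]], i[2]
    ), call. = FALSE)
  }
  if (anyDuplicated(rownames(mat))) {
    stop("alignment-error: duplicate sample ids", call. = FALSE)
  }
  structure(mat, class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("seq_alignment: %d sequences x %d bp\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Number of sequences and alignment length
#' @param aln a `seq_alignment`
#' @return integer
#' @export
n_sequences <- function(aln) nrow(aln)

#' @rdname n_sequences
#' @export
alignment_length <- function(aln) ncol(aln)

#' Read an aligned FASTA file
#'
#' Record order is preserved; lower-case input is upper-cased. All records
#' must have equal length.
#'
#' @param path path to a FASTA file
#' @return a [seq_alignment()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("format-error: empty file", call. = FALSE)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("format-error: not FASTA (no leading '>')", call. = FALSE)
  idx <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  seqs <- vapply(
    split(lines[!hdr], idx[!hdr]),
    function(x) paste(x, collapse = ""), character(1)
  )
  if (length(seqs) != length(ids)) stop("format-error: record with no sequence", call. = FALSE)
  names(seqs) <- ids
  seq_alignment(seqs)
}

#' Write an alignment to FASTA
#' @param aln a `seq_alignment`
#' @param path output path
#' @param width line-wrap width in bp
#' @return `path`, invisibly
#' @export
write_fasta <- function(aln, path, width = 70L) {
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Concatenate two gene alignments sample-by-sample
#'
#' Fragments are joined in argument order (e.g. NADH5 then cytochrome b);
#' the sample sets must match exactly.
#'
#' @param alnA,alnB `seq_alignment` objects over the same sample ids
#' @return a `seq_alignment` of length `L_A + L_B`, rows ordered as `alnA`
#' @export
concatenate <- function(alnA, alnB) {
  a <- rownames(alnA); b <- rownames(alnB)
  if (!setequal(a, b)) {
    diff <- union(setdiff(a, b), setdiff(b, a))
    stop(sprintf(
      "key-error: sample ids differ between alignments: {%s}",
      paste(sort(diff), collapse = ", ")
    ), call. = FALSE)
  }
  if (ncol(alnB) == 0L) return(alnA)
  if (ncol(alnA) == 0L) return(alnB)
  out <- cbind(unclass(alnA), unclass(alnB)[a, , drop = FALSE])
  structure(out, class = "seq_alignment")
}

# Drop alignment columns containing N or - anywhere (complete deletion).
complete_deletion <- function(aln) {
  keep <- colSums(unclass(aln) == "N" | unclass(aln) == "-") == 0L
  if (!any(keep)) {
    stop("degenerate-data: complete deletion removed every column", call. = FALSE)
  }
  structure(unclass(aln)[, keep, drop = FALSE], class = "seq_alignment")
}

apply_missing_policy <- function(aln, missing_policy = c("complete-deletion", "strict")) {
  missing_policy <- match.arg(missing_policy)
  if (missing_policy == "complete-deletion") complete_deletion(aln) else aln
}

#' Collapse identical sequences into haplotypes
#'
#' Under `complete-deletion` (default), columns containing `N` or `-` in any
#' sequence are removed before comparison; under `strict`, sequences must be
#' character-identical to share a haplotype. Haplotypes are ordered by
#' decreasing count, ties broken by first occurrence.
#'
#' @param aln a `seq_alignment`
#' @param missing_policy `"complete-deletion"` or `"strict"`
#' @return an object of class `haplotype_table` with elements `haplotypes`
#'   (character vector of distinct sequences), `counts`, `members` (list of
#'   sample-id vectors), and `assignment` (haplotype index per sample).
#' @export
collapse_haplotypes <- function(aln, missing_policy = c("complete-deletion", "strict")) {
  if (nrow(aln) < 1L) stop("empty alignment", call. = FALSE)
  used <- apply_missing_policy(aln, missing_policy)
  keys <- apply(unclass(used), 1L, paste, collapse = "")
  first <- !duplicated(keys)
  uniq <- keys[first]
  assignment <- match(keys, uniq)
  counts <- tabulate(assignment, nbins = length(uniq))
  ord <- order(-counts, seq_along(uniq))
  uniq <- uniq[ord]
  counts <- counts[ord]
  assignment <- match(keys, uniq)
  members <- split(rownames(aln), factor(assignment, levels = seq_along(uniq)))
  names(members) <- NULL
  structure(
    list(
      haplotypes = uniq, counts = counts, members = members,
      assignment = stats::setNames(assignment, rownames(aln)),
      length = ncol(used)
    ),
    class = "haplotype_table"
  )
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf(
    "haplotype_table: %d haplotypes from %d samples (%d comparable sites)\n",
    length(x$haplotypes), sum(x$counts), x$length
  ))
  invisible(x)
}

#' Haplotype-by-population count matrix
#' @param ht a `haplotype_table`
#' @param populations named character vector mapping sample id to population
#' @return integer matrix, haplotypes in rows, populations in columns
#' @export
haplotype_population_counts <- function(ht, populations) {
  pops <- populations[names(ht$assignment)]
  if (anyNA(pops)) stop("key-error: samples missing a population label", call. = FALSE)
  table(haplotype = ht$assignment, population = pops)
}

#' Write a haplotype table as TSV
#' @param ht a `haplotype_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_haplotype_table <- function(ht, path) {
  df <- data.frame(
    haplotype = seq_along(ht$haplotypes),
    sequence = ht$haplotypes,
    count = ht$counts,
    members = vapply(ht$members, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarize segregating sites
#'
#' A site is segregating when at least two distinct symbols among
#' `A,C,G,T` occur there (after applying the missing-data policy). Each
#' segregating site is classified as a transition (purine-purine or
#' pyrimidine-pyrimidine pair) and/or a transversion over its observed state
#' pairs; a site with more than two states can contribute to both tallies.
#'
#' @param aln a `seq_alignment` with at least 2 records
#' @param missing_policy passed to [collapse_haplotypes()]'s column rule
#' @return list with `S`, `transitions`, `transversions`, and 0-based
#'   `positions` (relative to the columns retained by the policy).
#' @export
site_summary <- function(aln, missing_policy = c("complete-deletion", "strict")) {
  if (nrow(aln) < 2L) stop("need >= 2 records", call. = FALSE)
  used <- unclass(apply_missing_policy(aln, missing_policy))
  ti <- 0L; tv <- 0L; pos <- integer(0)
  for (j in seq_len(ncol(used))) {
    states <- setdiff(unique(used[, j]), c("N", "-"))
    if (length(states) < 2L) next
    pos <- c(pos, j - 1L)
    prs <- utils::combn(states, 2L)
    is_ti <- apply(prs, 2L, function(p) {
      all(p %in% PURINES) || all(p %in% PYRIMIDINES)
    })
    if (any(is_ti)) ti <- ti + 1L
    if (any(!is_ti)) tv <- tv + 1L
  }
  list(S = length(pos), transitions = ti, transversions = tv, positions = pos)
}

#' Read a sample metadata CSV
#'
#' Expected header:
#' `sample_id,population,biogeographic,taxonomic,latitudinal,latitude,longitude`.
#' Extra columns are kept; missing coordinates may be empty.
#'
#' @param path CSV path
#' @return data.frame with validated coordinate ranges
#' @export
read_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(md)) stop("format-error: no sample_id column", call. = FALSE)
  if (anyDuplicated(md$sample_id)) stop("format-error: duplicate sample ids", call. = FALSE)
  if ("latitude" %in% names(md)) {
    bad <- !is.na(md$latitude) & abs(md$latitude) > 90
    if (any(bad)) stop("format-error: latitude outside [-90, 90]", call. = FALSE)
  }
  if ("longitude" %in% names(md)) {
    bad <- !is.na(md$longitude) & abs(md$longitude) > 180
    if (any(bad)) stop("format-error: longitude outside [-180, 180]", call. = FALSE)
  }
  md
}

#' Extract an alignment for a subset of samples
#' @param aln a `seq_alignment`
#' @param ids sample ids to keep (order preserved)
#' @return a `seq_alignment`
#' @export
subset_alignment <- function(aln, ids) {
  miss <- setdiff(ids, rownames(aln))
  if (length(miss)) {
    stop(sprintf("key-error: samples not in alignment: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  structure(unclass(aln)[ids, , drop = FALSE], class = "seq_alignment")
}
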