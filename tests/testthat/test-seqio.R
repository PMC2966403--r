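test_that("FASTA read preserves records and rejects malformed input", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "acgt", ">b", "ACGT"), path)
  aln <- read_fasta(path)
  expect_s3_class(aln, "seq_alignment")
  expect_equal(n_sequences(aln), 2L)
  expect_equal(alignment_length(aln), 4L)
  expect_equal(unname(apply(unclass(aln), 1, paste, collapse = "")),
               c("ACGT", "ACGT"))

  writeLines(c(">a", "ACGT", ">b", "ACGTA"), path)
  expect_error(read_fasta(path), "alignment-error")
  writeLines(character(0), path)
  expect_error(read_fasta(path), "format-error")
  writeLines(c(">a", "ACXT"), path)
  expect_error(read_fasta(path), "illegal symbol 'X' in record 'a' at position 3")
})

test_that("write/read round-trip reproduces a synthetic alignment exactly", {
  aln <- random_alignment(10, 601, seed = 5, p_missing = 0.01)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(aln, path)
  back <- read_fasta(path)
  expect_identical(unclass(back), unclass(aln))
})

test_that("concatenate joins fragments per sample and validates ids", {
  a <- random_alignment(6, 460, seed = 1)
  b <- random_alignment(6, 141, seed = 2)
  ab <- concatenate(a, b)
  expect_equal(alignment_length(ab), 601L)
  expect_identical(unclass(ab)[, 1:460], unclass(a))
  expect_identical(unclass(ab)[, 461:601], unclass(b)[rownames(a), ])

  empty <- structure(matrix(character(0), nrow = 6, ncol = 0,
                            dimnames = list(rownames(a), NULL)),
                     class = "seq_alignment")
  expect_identical(concatenate(a, empty), a)

  b2 <- b
  rownames(b2)[1] <- "zz"
  expect_error(concatenate(a, b2), "key-error.*s1.*zz|key-error.*zz.*s1")
})

test_that("haplotype collapsing matches a brute-force identity partition", {
  aln <- random_alignment(5, 12, seed = 9)
  # force some duplicates
  m <- unclass(aln)
  m[2, ] <- m[1, ]; m[5, ] <- m[1, ]
  aln <- seq_alignment(m)
  ht <- collapse_haplotypes(aln, "strict")
  # oracle: quadratic pairwise identity partition
  seqs <- apply(m, 1, paste, collapse = "")
  oracle <- split(rownames(m), match(seqs, unique(seqs)))
  got <- lapply(ht$members, sort)
  expect_setequal(lapply(oracle, sort), got)
  expect_equal(sum(ht$counts), nrow(aln))
  # ordering: decreasing count, ties by first occurrence
  expect_true(all(diff(ht$counts) <= 0))
})

test_that("collapsing is idempotent and respects the missing-data policy", {
  aln <- random_alignment(8, 30, seed = 3, p_missing = 0.05)
  ht <- collapse_haplotypes(aln)
  again <- collapse_haplotypes(seq_alignment(
    do.call(rbind, strsplit(ht$haplotypes, "")),
    ids = paste0("h", seq_along(ht$haplotypes))
  ), "strict")
  expect_equal(length(again$haplotypes), length(ht$haplotypes))

  # complete deletion merges sequences differing only at a masked column
  m <- matrix("A", 3, 4, dimnames = list(c("x", "y", "z"), NULL))
  m[1, 2] <- "N"; m[2, 2] <- "T"
  aln2 <- seq_alignment(m)
  expect_equal(length(collapse_haplotypes(aln2, "complete-deletion")$haplotypes), 1L)
  expect_equal(length(collapse_haplotypes(aln2, "strict")$haplotypes), 3L)
  # all-identical alignment collapses to one haplotype of count n
  all_same <- seq_alignment(matrix("C", 7, 5, dimnames = list(paste0("s", 1:7), NULL)))
  hts <- collapse_haplotypes(all_same)
  expect_equal(hts$counts, 7L)

  m3 <- matrix(c("A", "N"), 2, 1, dimnames = list(c("a", "b"), NULL))
  expect_error(collapse_haplotypes(seq_alignment(m3)), "degenerate-data")
})

test_that("site summary counts transitions and transversions per site", {
  m <- matrix("C", 4, 6, dimnames = list(paste0("s", 1:4), NULL))
  m[, 2] <- c("A", "A", "G", "G") # transition site
  m[, 5] <- c("A", "T", "A", "T") # transversion site
  ss <- site_summary(seq_alignment(m))
  expect_equal(ss$S, 2L)
  expect_equal(ss$transitions, 1L)
  expect_equal(ss$transversions, 1L)
  expect_equal(ss$positions, c(1L, 4L))

  mono <- seq_alignment(matrix("G", 3, 10, dimnames = list(paste0("s", 1:3), NULL)))
  expect_equal(site_summary(mono)$S, 0L)

  # a three-state site contributes to both tallies
  m2 <- matrix("A", 3, 3, dimnames = list(paste0("s", 1:3), NULL))
  m2[, 1] <- c("A", "G", "T")
  ss2 <- site_summary(seq_alignment(m2))
  expect_equal(ss2$S, 1L)
  expect_equal(ss2$transitions, 1L)
  expect_equal(ss2$transversions, 1L)
})

test_that("site summary is invariant under record reordering", {
  aln <- random_alignment(6, 40, seed = 12)
  perm <- subset_alignment(aln, rev(rownames(aln)))
  expect_equal(site_summary(aln)[c("S", "transitions", "transversions")],
               site_summary(perm)[c("S", "transitions", "transversions")])
})

test_that("metadata reader validates coordinates and ids", {
  path <- withr::local_tempfile(fileext = ".csv")
  md <- data.frame(sample_id = c("a", "b"), population = c("p", "q"),
                   latitude = c(12.5, NA), longitude = c(77, 80))
  utils::write.csv(md, path, row.names = FALSE)
  got <- read_metadata(path)
  expect_equal(got$sample_id, c("a", "b"))
  md$latitude[1] <- 120
  utils::write.csv(md, path, row.names = FALSE)
  expect_error(read_metadata(path), "latitude")
})
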