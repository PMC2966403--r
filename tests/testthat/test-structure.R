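test_that("pairwise difference matrix equals site-by-site comparison", {
  aln <- random_alignment(6, 40, seed = 2, p_missing = 0.03)
  d <- pairwise_difference_matrix(aln, "complete-deletion")
  used <- unclass(phylogeocat:::complete_deletion(aln))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(d[i, j], sum(used[i, ] != used[j, ]))
  }
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
})

test_that("AMOVA hits the fixed-difference and no-structure limits", {
  a <- seq_alignment(c(x1 = "AAAA", x2 = "AAAA", y1 = "TTTT", y2 = "TTTT"))
  g <- stats::setNames(c("X", "X", "Y", "Y"), rownames(a))
  res <- amova(pairwise_difference_matrix(a), g, n_perm = 99, seed = 1)
  expect_equal(res$phi_st, 1)
  expect_equal(res$sigma2_within, 0)

  # identical haplotype compositions across populations: Phi about 0
  b <- seq_alignment(c(p1 = "AAAA", p2 = "TTTT", q1 = "AAAA", q2 = "TTTT"))
  g2 <- stats::setNames(c("P", "P", "Q", "Q"), rownames(b))
  res2 <- amova(pairwise_difference_matrix(b), g2, n_perm = 0)
  expect_lte(res2$phi_st, 0.01)
  expect_true(res2$negative_component || res2$phi_st <= 0)
})

test_that("AMOVA is invariant to relabelling and sample order", {
  aln <- random_alignment(12, 60, seed = 6)
  d <- pairwise_difference_matrix(aln)
  g <- stats::setNames(rep(c("a", "b", "c"), each = 4), rownames(aln))
  r1 <- amova(d, g, n_perm = 0)
  perm <- sample(rownames(d))
  r2 <- amova(d[perm, perm], g, n_perm = 0)
  g3 <- stats::setNames(c(a = "pop3", b = "pop1", c = "pop2")[g], names(g))
  r3 <- amova(d, g3, n_perm = 0)
  expect_equal(r1$phi_st, r2$phi_st)
  expect_equal(r1$phi_st, r3$phi_st)
})

test_that("AMOVA guards degenerate groupings", {
  aln <- random_alignment(4, 20, seed = 7)
  d <- pairwise_difference_matrix(aln)
  one <- stats::setNames(rep("only", 4), rownames(aln))
  expect_error(amova(d, one), "grouping-error")
  partial <- stats::setNames(c("a", "b", NA, "b"), rownames(aln))
  expect_error(amova(d, partial), "grouping-error")
})

test_that("pairwise Phi-ST agrees with single-pair AMOVA calls", {
  aln <- simulate_alignment(demography_model("constant", theta = 6, n = 18L),
                            L = 300, seed = 40)
  d <- pairwise_difference_matrix(aln)
  g <- stats::setNames(rep(c("A", "B", "C"), each = 6), rownames(aln))
  pw <- pairwise_phist(d, g, n_perm = 0)
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    keep <- names(g)[g %in% pair]
    single <- amova(d[keep, keep], g[keep], n_perm = 0)
    expect_equal(pw$phi_st[pair[1], pair[2]], single$phi_st)
  }
  expect_true(all(is.na(diag(pw$phi_st))))
})

test_that("great-circle distances follow the haversine closed form", {
  co <- data.frame(sample_id = c("o", "e", "anti"),
                   latitude = c(0, 0, 0), longitude = c(0, 1, 180))
  d <- great_circle_matrix(co)
  expect_equal(d["o", "o"], 0)
  expect_equal(d["o", "e"], 6371 * pi / 180, tolerance = 1e-9)
  expect_equal(d["o", "anti"], 6371 * pi, tolerance = 1e-9)
})

test_that("great-circle distances agree with an independent implementation", {
  skip_if_not_installed("geosphere")
  set.seed(31)
  co <- data.frame(sample_id = paste0("s", 1:5),
                   latitude = runif(5, -60, 60), longitude = runif(5, -170, 170))
  d <- great_circle_matrix(co)
  for (i in 1:4) for (j in (i + 1):5) {
    ref <- geosphere::distHaversine(
      c(co$longitude[i], co$latitude[i]),
      c(co$longitude[j], co$latitude[j]), r = 6371000) / 1000
    expect_equal(d[i, j], ref, tolerance = 1e-6)
  }
})

test_that("population-level distances average cross-population pairs", {
  co <- data.frame(sample_id = c("a1", "a2", "b1"),
                   latitude = c(0, 0, 0), longitude = c(0, 2, 10))
  pops <- stats::setNames(c("A", "A", "B"), co$sample_id)
  pd <- great_circle_matrix(co, populations = pops)
  d <- great_circle_matrix(co)
  expect_equal(pd["A", "B"], mean(c(d["a1", "b1"], d["a2", "b1"])))
})

test_that("Mantel r is 1 for identical matrices and p matches enumeration", {
  m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  res <- mantel_test(m, m)
  expect_equal(res$r, 1)
  expect_true(res$exact)

  # oracle: enumerate all 24 permutations for a 4x4 case by hand
  set.seed(5)
  g1 <- as.matrix(stats::dist(runif(4))); dimnames(g1) <- list(letters[1:4], letters[1:4])
  g2 <- as.matrix(stats::dist(runif(4))); dimnames(g2) <- list(letters[1:4], letters[1:4])
  res2 <- mantel_test(g1, g2)
  lt <- lower.tri(g1)
  r_obs <- cor(g1[lt], g2[lt])
  perms <- phylogeocat:::all_permutations(4)
  rs <- vapply(perms, function(p) cor(g1[p, p][lt], g2[lt]), numeric(1))
  expect_equal(res2$p, mean(rs >= r_obs - 1e-12))

  const <- matrix(1, 3, 3); diag(const) <- 0
  dimnames(const) <- dimnames(m)
  expect_error(mantel_test(const, m), "undefined-correlation")
})

test_that("randomized Mantel p approaches the exact value", {
  set.seed(9)
  x <- cbind(runif(6), runif(6))
  g1 <- as.matrix(stats::dist(x))
  g2 <- as.matrix(stats::dist(x + matrix(rnorm(12, 0, 0.3), 6)))
  labs <- paste0("p", 1:6)
  dimnames(g1) <- dimnames(g2) <- list(labs, labs)
  exact <- mantel_test(g1, g2, exact = TRUE)
  rand <- mantel_test(g1, g2, n_perm = 4000, seed = 2, exact_limit = 0)
  expect_equal(rand$p, exact$p, tolerance = 0.05)
  skip_if_not_installed("vegan")
  ref <- vegan::mantel(g1, g2, permutations = 999)
  expect_equal(exact$r, unname(ref$statistic), tolerance = 1e-10)
})

test_that("latitudinal bands use half-open closure over the printed gaps", {
  expect_equal(assign_latitudinal_class(15), "10N-19.9N")
  expect_equal(assign_latitudinal_class(19.95), "10N-19.9N")
  expect_equal(assign_latitudinal_class(20), "20N-28.9N")
  expect_equal(assign_latitudinal_class(28.95), "20N-28.9N")
  expect_equal(assign_latitudinal_class(29), "29N-35N")
  expect_equal(assign_latitudinal_class(35), "29N-35N")
  expect_warning(out <- assign_latitudinal_class(c(9, 36)), "unclassified")
  expect_equal(out, c("unclassified", "unclassified"))
})

test_that("deep-split islands give high Phi-ST, migration erodes it", {
  med_phi <- vapply(c(0.1, 10), function(M) {
    m <- demography_model("two_island", theta = 5, M = M, n = c(8L, 8L))
    set.seed(round(M * 100))
    median(replicate(12, {
      a <- simulate_alignment(m, L = 400)
      g <- stats::setNames(sub("_.*", "", rownames(a)), rownames(a))
      amova(pairwise_difference_matrix(a), g, n_perm = 0)$phi_st
    }))
  }, numeric(1))
  expect_gt(med_phi[1], med_phi[2])
})
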