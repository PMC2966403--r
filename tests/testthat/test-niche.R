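# Helper: deterministic gradient stack value(x, y) = row + col effects.
gradient_stack <- function(nr = 20, nc = 20) {
  simulate_climate_stack(nr, nc, list(
    list(name = "bio5", intercept = 20, per_row = 1, per_col = 0, noise_sd = 0),
    list(name = "bio13", intercept = 50, per_row = 0, per_col = 2, noise_sd = 0)
  ))
}

test_that("ASC grids round-trip through write and read", {
  st <- simulate_climate_stack(8, 11, list(
    list(name = "bio5", intercept = 5, per_row = 0.25, per_col = -0.5,
         noise_sd = 0.7)), seed = 3, nodata_border = 1L,
    xll = 70, yll = 8, cellsize = 0.5)
  path <- withr::local_tempfile(fileext = ".asc")
  write_asc(st, "bio5", path, digits = 12)
  back <- read_asc(path, "bio5")
  expect_equal(back$layers$bio5, st$layers$bio5, tolerance = 1e-9)
  expect_equal(back$xll, 70)
  expect_equal(back$cellsize, 0.5)
})

test_that("extraction returns exact cell values and flags bad points", {
  st <- gradient_stack()
  # cell centers: row r from top -> value 20 + (r-1)
  pt <- phylogeocat:::cell_center(st, 5, 7)
  v <- extract_values(st, data.frame(latitude = pt$latitude,
                                     longitude = pt$longitude))
  expect_equal(v$bio5, 20 + 4)
  expect_equal(v$bio13, 50 + 12)

  expect_error(extract_values(st, data.frame(latitude = 999, longitude = 0)),
               "point-error")
  stna <- st; stna$layers$bio5[1, 1] <- NA
  top_left <- phylogeocat:::cell_center(stna, 1, 1)
  expect_error(extract_values(stna, data.frame(latitude = top_left$latitude,
                                               longitude = top_left$longitude)),
               "nodata")
})

test_that("extraction matches the analytic gradient everywhere", {
  st <- gradient_stack()
  set.seed(10)
  pts <- data.frame(latitude = runif(30, st$yll + 0.01, st$yll + st$nrows * st$cellsize - 0.01),
                    longitude = runif(30, st$xll + 0.01, st$xll + st$ncols * st$cellsize - 0.01))
  v <- extract_values(st, pts)
  rc <- phylogeocat:::point_to_cell(st, pts$latitude, pts$longitude)
  expect_equal(v$bio5, 20 + (rc$row - 1))
  expect_equal(v$bio13, 50 + 2 * (rc$col - 1))
})

test_that("correlation filter removes exactly the conflicting variables", {
  set.seed(4)
  n <- 400
  x <- rnorm(n)
  tab <- data.frame(
    a = x,
    b = 0.9 * x + sqrt(1 - 0.81) * rnorm(n), # r ~ 0.9 with a
    c = rnorm(n),
    d = rnorm(n)
  )
  kept <- correlation_filter(tab, r_max = 0.7)
  expect_true("a" %in% kept)
  expect_false("b" %in% kept)
  expect_true(all(c("c", "d") %in% kept))

  two <- data.frame(u = x, v = x)
  kept2 <- correlation_filter(two, r_max = 0.7)
  expect_equal(as.character(kept2), "u")
  expect_equal(attr(kept2, "dropped"), "v")

  indep <- as.data.frame(matrix(rnorm(n * 5), n))
  expect_length(correlation_filter(indep, 0.7), 5L)

  expect_warning(correlation_filter(data.frame(k = rep(1, 10), m = rnorm(10),
                                               o = rnorm(10)), 0.7),
                 "constant")
})

test_that("the priority order decides which of a correlated pair survives", {
  set.seed(5)
  x <- rnorm(300)
  tab <- data.frame(first = x + rnorm(300, 0, 0.1), second = x)
  kept <- correlation_filter(tab, r_max = 0.7, priority = c("second", "first"))
  expect_equal(as.character(kept), "second")
})

test_that("envelopes use the linear-interpolation quantile rule", {
  vals <- data.frame(v = as.numeric(1:100))
  m0 <- fit_bioclim(vals, tail = 0)
  expect_equal(m0$envelopes$v$lower, 1)
  expect_equal(m0$envelopes$v$upper, 100)

  m <- fit_bioclim(vals, tail = 0.025)
  expect_equal(m$envelopes$v$lower, 3.475)
  expect_equal(m$envelopes$v$upper, 97.525)

  const <- data.frame(v = rep(7, 10))
  mc <- fit_bioclim(const, tail = 0.025)
  expect_equal(mc$envelopes$v$lower, 7)
  expect_equal(mc$envelopes$v$upper, 7)

  expect_error(fit_bioclim(vals[1:3, , drop = FALSE]), "insufficient-data")
})

test_that("suitability is the tent-percentile-min rule", {
  vals <- data.frame(v = as.numeric(1:99))
  m <- fit_bioclim(vals, tail = 0)
  # the training median scores 1
  expect_equal(score_suitability(m, data.frame(v = 50))$suitability, 1)
  # closed form: uniform training values give a linear tent in the value
  sc <- score_suitability(m, data.frame(v = c(25, 75)))$suitability
  expect_equal(sc[1], 1 - 2 * abs(25 / 99 - 0.5), tolerance = 0.02)
  expect_equal(sc[2], 1 - 2 * abs((75 - 0.5) / 99 - 0.5), tolerance = 0.02)
  # outside any envelope: 0 under the min rule
  m2 <- fit_bioclim(data.frame(v = as.numeric(1:99), w = as.numeric(1:99)), tail = 0)
  out <- score_suitability(m2, data.frame(v = 50, w = 1000))
  expect_equal(out$suitability, 0)
  expect_false(out$in_envelope)
  expect_error(score_suitability(m2, data.frame(v = 1)), "key-error")
})

test_that("every training presence scores positive at tail zero", {
  st <- gradient_stack()
  pres <- sample_presences(st, function(v) v$bio5 < 35, n = 40, seed = 6)
  vals <- extract_values(st, pres)
  m <- fit_bioclim(vals, tail = 0)
  expect_true(all(score_suitability(m, vals)$suitability > 0))
  # at tail 0.025, at most ~5% of training points fall outside
  m2 <- fit_bioclim(vals, tail = 0.025)
  frac_zero <- mean(score_suitability(m2, vals)$suitability == 0)
  expect_lte(frac_zero, 0.15)
})

test_that("pseudo-absences are uniform, seeded, and bounded by valid cells", {
  st <- gradient_stack(10, 10)
  a1 <- pseudo_absences(st, 20, seed = 3)
  a2 <- pseudo_absences(st, 20, seed = 3)
  expect_identical(a1, a2)
  all_cells <- pseudo_absences(st, 100, seed = 1)
  expect_equal(nrow(unique(all_cells[c("latitude", "longitude")])), 100L)
  expect_error(pseudo_absences(st, 101), "sampling-error")

  # uniformity: chi-square over quadrants of many draws
  draws <- do.call(rbind, lapply(1:40, function(s) pseudo_absences(st, 50, seed = s)))
  qx <- draws$longitude > st$xll + 5 * st$cellsize
  qy <- draws$latitude > st$yll + 5 * st$cellsize
  tab <- table(qx, qy)
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.001)
})

test_that("AUC equals the exhaustive pair-count oracle", {
  expect_equal(rank_auc(c(0.9, 0.8), c(0.1, 0.2))$auc, 1)
  expect_true(rank_auc(c(1, 1), c(1, 1))$degenerate)
  expect_equal(rank_auc(c(1, 1), c(1, 1))$auc, 0.5)

  set.seed(12)
  for (rep in 1:3) {
    p <- sample(seq(0, 1, 0.1), 7, replace = TRUE)
    a <- sample(seq(0, 1, 0.1), 9, replace = TRUE)
    wins <- 0
    for (x in p) for (y in a) wins <- wins + (x > y) + 0.5 * (x == y)
    expect_equal(rank_auc(p, a)$auc, wins / (7 * 9))
  }
})

test_that("AUC is invariant to monotone transforms of the scores", {
  set.seed(2)
  p <- runif(10); a <- runif(12)
  base <- rank_auc(p, a)$auc
  expect_equal(rank_auc(p^3, a^3)$auc, base)
  expect_equal(rank_auc(log(p + 1), log(a + 1))$auc, base)
})

test_that("the replicate protocol separates niche-limited presences", {
  st <- simulate_climate_stack(25, 25, list(
    list(name = "bio5", intercept = 20, per_row = 0.8, per_col = 0, noise_sd = 0.3)
  ), seed = 20)
  pres <- sample_presences(st, function(v) v$bio5 < 26, n = 60, seed = 21)
  reps <- replicate_protocol(pres, st, n_reps = 5, seed = 22)
  expect_gt(reps$mean_auc, 0.6)
  again <- replicate_protocol(pres, st, n_reps = 5, seed = 22)
  expect_identical(reps$replicates, again$replicates)

  # background-drawn presences carry no signal
  bg <- pseudo_absences(st, 60, seed = 23)
  bg$source <- "synthetic"
  reps0 <- replicate_protocol(bg, st, n_reps = 5, seed = 24)
  expect_lt(abs(reps0$mean_auc - 0.5), 0.2)
})

test_that("threshold recovery: the fitted envelope finds the occupancy limit", {
  st <- simulate_climate_stack(40, 40, list(
    list(name = "bio5", intercept = 15, per_row = 0.6, per_col = 0, noise_sd = 0)
  ), seed = 30)
  cutoff <- 30
  pres <- sample_presences(st, function(v) v$bio5 < cutoff, n = 120, seed = 31,
                           jitter = FALSE)
  vals <- extract_values(st, pres)
  expect_equal(threshold_map(st, "bio5", pres, threshold = cutoff)$n_exceeding, 0L)
  m <- fit_bioclim(vals, tail = 0)
  # upper envelope within one cell-value step (0.6) of the cutoff
  expect_lte(m$envelopes$bio5$upper, cutoff)
  expect_gte(m$envelopes$bio5$upper, cutoff - 2 * 0.6)
})

test_that("threshold report matches the t-interval closed form", {
  st <- gradient_stack()
  pres <- sample_presences(st, function(v) TRUE, n = 25, seed = 40)
  x <- extract_values(st, pres)$bio5
  rep <- threshold_map(st, "bio5", pres, threshold = 30)
  half <- stats::qt(0.975, 24) * stats::sd(x) / 5
  expect_equal(rep$mean, mean(x))
  expect_equal(rep$ci95, c(mean(x) - half, mean(x) + half))
  expect_equal(rep$n_exceeding, sum(x > 30))

  const <- simulate_climate_stack(6, 6, list(
    list(name = "bio5", intercept = 3, per_row = 0, per_col = 0, noise_sd = 0)))
  presc <- sample_presences(const, function(v) TRUE, n = 10, seed = 41)
  repc <- threshold_map(const, "bio5", presc, threshold = 10)
  expect_equal(repc$ci95, c(3, 3))
})
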