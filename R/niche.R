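# BIOCLIM percentile-envelope niche modelling on gridded climate data.
#
# Rasters are north-up matrices (row 1 = northernmost) with cell-center
# registration derived from an ESRI ASCII-grid header (xllcorner, yllcorner,
# cellsize). A climate_stack holds named layers sharing one grid.

#' Construct a climate stack
#'
#' @param layers named list of numeric matrices of identical shape; `NA`
#'   marks nodata
#' @param xll,yll coordinates of the lower-left corner (degrees)
#' @param cellsize cell size in degrees
#' @return object of class `climate_stack`
#' @export
climate_stack <- function(layers, xll = 0, yll = 0, cellsize = 0.1) {
  if (!length(layers) || is.null(names(layers)) || any(!nzchar(names(layers)))) {
    stop("layers must be a named list", call. = FALSE)
  }
  if (anyDuplicated(names(layers))) stop("layer names must be unique", call. = FALSE)
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all layers must share one shape", call. = FALSE)
  }
  structure(
    list(layers = layers, variables = names(layers),
         nrows = dims[1, 1], ncols = dims[2, 1],
         xll = xll, yll = yll, cellsize = cellsize),
    class = "climate_stack"
  )
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("climate_stack: %d layers (%s), %d x %d cells, cellsize %g\n",
              length(x$layers), paste(x$variables, collapse = ", "),
              x$nrows, x$ncols, x$cellsize))
  invisible(x)
}

# Cell-center coordinates for row r (from the top) and column c.
cell_center <- function(stack, r, c) {
  list(
    longitude = stack$xll + (c - 0.5) * stack$cellsize,
    latitude = stack$yll + (stack$nrows - r + 0.5) * stack$cellsize
  )
}

# Row/column of the cell containing a point; NA when outside the extent.
point_to_cell <- function(stack, latitude, longitude) {
  c0 <- floor((longitude - stack$xll) / stack$cellsize) + 1L
  r0 <- stack$nrows - floor((latitude - stack$yll) / stack$cellsize)
  bad <- c0 < 1L | c0 > stack$ncols | r0 < 1L | r0 > stack$nrows
  r0[bad] <- NA_integer_; c0[bad] <- NA_integer_
  list(row = as.integer(r0), col = as.integer(c0))
}

# Long table of every cell: row, col, latitude, longitude, one column per
# variable.
stack_cell_table <- function(stack) {
  nr <- stack$nrows; nc <- stack$ncols
  r <- rep(seq_len(nr), nc)
  cc <- rep(seq_len(nc), each = nr)
  ctr <- cell_center(stack, r, cc)
  out <- data.frame(row = r, col = cc,
                    latitude = ctr$latitude, longitude = ctr$longitude)
  for (v in stack$variables) out[[v]] <- as.vector(stack$layers[[v]])
  out
}

#' Read an ESRI ASCII grid (.asc)
#'
#' @param path file path
#' @param name layer name (defaults to the file name without extension)
#' @return a single-layer [climate_stack()]
#' @export
read_asc <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("format-error: incomplete ASCII-grid header", call. = FALSE)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("format-error: cell count does not match header", call. = FALSE)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  layers <- stats::setNames(list(m), name)
  climate_stack(layers, xll = hdr$xllcorner, yll = hdr$yllcorner,
                cellsize = hdr$cellsize)
}

#' Write one layer of a climate stack as an ESRI ASCII grid
#'
#' @param stack a [climate_stack()]
#' @param variable layer name
#' @param path output path
#' @param nodata_value value written for `NA` cells
#' @param digits significant digits for cell values
#' @return `path`, invisibly
#' @export
write_asc <- function(stack, variable, path, nodata_value = -9999, digits = 8) {
  if (!variable %in% stack$variables) {
    stop(sprintf("key-error: no layer '%s'", variable), call. = FALSE)
  }
  m <- stack$layers[[variable]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", stack$ncols),
    sprintf("nrows %d", stack$nrows),
    sprintf("xllcorner %.10g", stack$xll),
    sprintf("yllcorner %.10g", stack$yll),
    sprintf("cellsize %.10g", stack$cellsize),
    sprintf("NODATA_value %.10g", nodata_value)
  ), con)
  m[is.na(m)] <- nodata_value
  apply(m, 1L, function(row) {
    writeLines(paste(formatC(row, digits = digits, format = "g"),
                     collapse = " "), con)
  })
  invisible(path)
}

#' Read a directory of .asc rasters into one stack
#' @param dir directory containing `.asc` files
#' @return a [climate_stack()]
#' @export
read_asc_stack <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  if (!length(files)) stop(sprintf("no .asc files in %s", dir), call. = FALSE)
  stacks <- lapply(files, read_asc)
  layers <- stats::setNames(
    lapply(stacks, function(s) s$layers[[1]]),
    vapply(stacks, function(s) s$variables[1], character(1))
  )
  s1 <- stacks[[1]]
  climate_stack(layers, xll = s1$xll, yll = s1$yll, cellsize = s1$cellsize)
}

#' Extract climate values at points (nearest cell)
#'
#' @param stack a [climate_stack()]
#' @param points data.frame with `latitude` and `longitude`
#' @param na_error error on points falling outside the extent or on nodata
#'   cells (default) instead of returning NA rows
#' @return data.frame of per-point variable values, row order preserved
#' @export
extract_values <- function(stack, points, na_error = TRUE) {
  rc <- point_to_cell(stack, points$latitude, points$longitude)
  if (na_error && anyNA(rc$row)) {
    stop(sprintf("point-error: points outside extent: %s",
                 paste(which(is.na(rc$row)), collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(row = rc$row, col = rc$col)
  for (v in stack$variables) {
    m <- stack$layers[[v]]
    out[[v]] <- ifelse(is.na(rc$row), NA_real_, m[cbind(rc$row, rc$col)])
  }
  if (na_error) {
    bad <- which(!stats::complete.cases(out[stack$variables]))
    if (length(bad)) {
      stop(sprintf("point-error: points on nodata cells: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  out[stack$variables]
}

#' Greedy Pearson-correlation variable filter
#'
#' Computes all pairwise Pearson correlations and repeatedly removes a
#' variable until no pair exceeds `|r| > r_max`. At each step the offending
#' pair with the largest |r| is examined and the member later in `priority`
#' is dropped, so the caller's preferred variables survive.
#'
#' @param values data.frame of candidate variable columns (numeric)
#' @param r_max correlation cut-off (pairs with `|r| > r_max` conflict)
#' @param priority character vector; earlier = keep preferentially
#'   (defaults to column order)
#' @return character vector of retained variable names; attribute `dropped`
#'   lists removals
#' @export
correlation_filter <- function(values, r_max = 0.7, priority = NULL) {
  vars <- names(values)
  if (length(vars) < 2L || nrow(values) < 3L) {
    stop("need >= 2 variables and >= 3 rows", call. = FALSE)
  }
  constant <- vapply(values, function(x) stats::sd(x, na.rm = TRUE) == 0, logical(1))
  if (any(constant)) {
    warning(sprintf("constant columns excluded: %s",
                    paste(vars[constant], collapse = ", ")))
    vars <- vars[!constant]
  }
  if (is.null(priority)) priority <- vars
  rank_of <- function(v) match(v, priority, nomatch = length(priority) + 1L)
  dropped <- character(0)
  repeat {
    if (length(vars) < 2L) break
    cm <- abs(stats::cor(values[vars], use = "pairwise.complete.obs"))
    diag(cm) <- 0
    if (max(cm) <= r_max) break
    ij <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    pair <- vars[ij]
    drop <- pair[which.max(rank_of(pair))]
    dropped <- c(dropped, drop)
    vars <- setdiff(vars, drop)
  }
  structure(vars, dropped = dropped)
}

#' Fit a BIOCLIM percentile-envelope model
#'
#' Per variable, the envelope is `[quantile(tail), quantile(1 - tail)]` of
#' the presence (training) values, with the linear-interpolation quantile
#' (R type 7). Training values are retained for percentile scoring.
#'
#' @param values data.frame of presence-point climate values (one column per
#'   variable)
#' @param tail two-sided tail fraction in `[0, 0.5)`; 0.025 excludes the
#'   most extreme 2.5 percent at each end
#' @return object of class `bioclim_model`
#' @export
fit_bioclim <- function(values, tail = 0.025) {
  if (tail < 0 || tail >= 0.5) stop("tail must be in [0, 0.5)", call. = FALSE)
  values <- values[stats::complete.cases(values), , drop = FALSE]
  if (nrow(values) < 5L) stop("insufficient-data: need >= 5 presences", call. = FALSE)
  envelopes <- lapply(values, function(x) {
    q <- stats::quantile(x, c(tail, 1 - tail), names = FALSE, type = 7)
    list(lower = q[1], upper = q[2], training = sort(x))
  })
  structure(list(envelopes = envelopes, variables = names(values),
                 tail = tail, n_train = nrow(values)),
            class = "bioclim_model")
}

#' @export
print.bioclim_model <- function(x, ...) {
  cat(sprintf("bioclim_model: %d variables, tail %.3f, %d training points\n",
              length(x$variables), x$tail, x$n_train))
  for (v in x$variables) {
    e <- x$envelopes[[v]]
    cat(sprintf("  %-8s [%.4g, %.4g]\n", v, e$lower, e$upper))
  }
  invisible(x)
}

#' @export
coef.bioclim_model <- function(object, ...) {
  t(vapply(object$envelopes,
           function(e) c(lower = e$lower, upper = e$upper), numeric(2)))
}

#' @export
summary.bioclim_model <- function(object, ...) {
  print(object)
  invisible(object)
}

# Tent score of a value against one envelope: 1 at the training median,
# declining linearly in the training percentile, 0 outside the envelope.
tent_score <- function(x, envelope) {
  tr <- envelope$training
  n <- length(tr)
  # percentile of x among training values (mean of <= and < ranks)
  p <- (findInterval(x, tr) + findInterval(x, tr, left.open = TRUE)) / (2 * n)
  s <- 1 - 2 * abs(p - 0.5)
  s[x < envelope$lower | x > envelope$upper] <- 0
  s[is.na(x)] <- NA
  s
}

#' Suitability scores for a table of climate values
#'
#' Per variable, score `s_v = 1 - 2 * |P_v - 0.5|` where `P_v` is the
#' training percentile of the value (0 outside the envelope); the combined
#' score is the minimum over variables. The raw in-all-envelopes Boolean is
#' returned alongside.
#'
#' @param model a [fit_bioclim()] model
#' @param values data.frame containing at least the model's variables
#' @return data.frame with `suitability` and `in_envelope`
#' @export
score_suitability <- function(model, values) {
  miss <- setdiff(model$variables, names(values))
  if (length(miss)) {
    stop(sprintf("key-error: missing variables: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  scores <- vapply(model$variables,
                   function(v) tent_score(values[[v]], model$envelopes[[v]]),
                   numeric(nrow(values)))
  scores <- matrix(scores, nrow = nrow(values))
  suit <- apply(scores, 1L, function(r) if (anyNA(r)) NA_real_ else min(r))
  data.frame(suitability = suit, in_envelope = !is.na(suit) & suit > 0)
}

#' Predict a suitability grid from a BIOCLIM model
#'
#' @param object a `bioclim_model`
#' @param stack a [climate_stack()] holding at least the model's variables
#' @param ... unused
#' @return a single-layer `climate_stack` named `suitability` (nodata
#'   propagated)
#' @export
predict.bioclim_model <- function(object, stack, ...) {
  tab <- stack_cell_table(stack)
  sc <- score_suitability(object, tab)
  m <- matrix(sc$suitability, stack$nrows, stack$ncols)
  climate_stack(list(suitability = m), xll = stack$xll, yll = stack$yll,
                cellsize = stack$cellsize)
}

#' @export
plot.bioclim_model <- function(x, stack = NULL, ...) {
  if (is.null(stack)) stop("supply a climate_stack to map suitability", call. = FALSE)
  s <- predict(x, stack)
  m <- s$layers$suitability
  graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  main = "BIOCLIM suitability", ...)
  invisible(x)
}

#' Draw pseudo-absence points from the valid cells of a stack
#'
#' Uniform over non-nodata cells, without replacement within one draw.
#'
#' @param stack a [climate_stack()]
#' @param n number of points
#' @param seed RNG seed (`NULL` = current stream)
#' @return data.frame with `latitude`, `longitude`, `source = "pseudo_absence"`
#' @export
pseudo_absences <- function(stack, n, seed = NULL) {
  if (n < 1L) stop("sampling-error: n must be >= 1", call. = FALSE)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  tab <- stack_cell_table(stack)
  ok <- stats::complete.cases(tab[stack$variables])
  idx <- which(ok)
  if (n > length(idx)) {
    stop(sprintf("sampling-error: n = %d exceeds %d valid cells",
                 n, length(idx)), call. = FALSE)
  }
  pick <- if (n == length(idx)) idx else idx[sample.int(length(idx), n)]
  data.frame(latitude = tab$latitude[pick], longitude = tab$longitude[pick],
             source = "pseudo_absence", stringsAsFactors = FALSE)
}

#' Rank-based AUC of presence vs absence suitability scores
#'
#' The Mann-Whitney statistic: the probability that a random presence
#' outranks a random absence, ties counted half.
#'
#' @param presence_scores,absence_scores numeric score vectors
#' @return list with `auc`, `n_presence`, `n_absence`, and `degenerate`
#'   (TRUE when all scores are identical, in which case auc = 0.5)
#' @export
rank_auc <- function(presence_scores, absence_scores) {
  if (!length(presence_scores) || !length(absence_scores)) {
    stop("both score sets must be non-empty", call. = FALSE)
  }
  np <- length(presence_scores); na <- length(absence_scores)
  r <- rank(c(presence_scores, absence_scores))
  u <- sum(r[seq_len(np)]) - np * (np + 1) / 2
  degenerate <- length(unique(c(presence_scores, absence_scores))) == 1L
  list(auc = u / (np * na), n_presence = np, n_absence = na,
       degenerate = degenerate)
}

#' AUC of a fitted envelope model on held-out points
#'
#' @param model a `bioclim_model`
#' @param presence_test data.frame of test presence points (lat/lon)
#' @param absences data.frame of pseudo-absence points (lat/lon)
#' @param stack the [climate_stack()] to extract values from
#' @return list as [rank_auc()]
#' @export
evaluate_auc <- function(model, presence_test, absences, stack) {
  vp <- extract_values(stack, presence_test, na_error = FALSE)
  va <- extract_values(stack, absences, na_error = FALSE)
  sp <- score_suitability(model, vp)$suitability
  sa <- score_suitability(model, va)$suitability
  rank_auc(sp[!is.na(sp)], sa[!is.na(sa)])
}

#' Replicated train/test evaluation of the BIOCLIM model
#'
#' Per replicate: a random 75/25 presence split, envelope fit on the training
#' portion, AUC of the test presences against freshly drawn pseudo-absences
#' of size equal to the full presence count.
#'
#' @param presences data.frame of presence points (lat/lon)
#' @param stack a [climate_stack()]
#' @param n_reps number of replicates
#' @param train_frac training fraction of the presence points
#' @param tail envelope tail fraction
#' @param seed RNG seed
#' @return object of class `bioclim_replicates`: data.frame `replicates`
#'   (auc, n_presence_test, n_absence, replicate, seed) plus `mean_auc`
#'   and `range_auc`
#' @export
replicate_protocol <- function(presences, stack, n_reps = 10L,
                               train_frac = 0.75, tail = 0.025, seed = 1L) {
  n <- nrow(presences)
  if (n < 8L) stop("insufficient-data: need >= 8 presences", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    tr <- sample.int(n, round(train_frac * n))
    train <- presences[tr, , drop = FALSE]
    test <- presences[-tr, , drop = FALSE]
    model <- fit_bioclim(extract_values(stack, train, na_error = FALSE), tail = tail)
    abs_pts <- pseudo_absences(stack, n)
    a <- evaluate_auc(model, test, abs_pts, stack)
    rows[[r]] <- data.frame(replicate = r, auc = a$auc,
                            n_presence_test = a$n_presence,
                            n_absence = a$n_absence, seed = seed)
  }
  reps <- do.call(rbind, rows)
  structure(list(replicates = reps, mean_auc = mean(reps$auc),
                 range_auc = range(reps$auc), n_reps = n_reps,
                 train_frac = train_frac, tail = tail, seed = seed),
            class = "bioclim_replicates")
}

#' @export
print.bioclim_replicates <- function(x, ...) {
  cat(sprintf(
    "BIOCLIM evaluation: %d replicates, mean AUC %.3f (range %.3f-%.3f)\n",
    x$n_reps, x$mean_auc, x$range_auc[1], x$range_auc[2]))
  invisible(x)
}

#' Per-variable threshold report at presence points
#'
#' Extracts one variable at all presence points and reports its mean, the
#' 95 percent t-interval of the mean, the maximum, and how many presences
#' exceed a supplied threshold.
#'
#' @param stack a [climate_stack()]
#' @param variable layer name
#' @param presences data.frame of presence points (lat/lon)
#' @param threshold exceedance threshold (same units as the variable)
#' @return list with `mean`, `ci95`, `max`, `n`, `threshold`, `n_exceeding`
#' @export
threshold_map <- function(stack, variable, presences, threshold) {
  if (!variable %in% stack$variables) {
    stop(sprintf("key-error: no layer '%s'", variable), call. = FALSE)
  }
  x <- extract_values(stack, presences)[, variable]
  n <- length(x)
  se <- stats::sd(x) / sqrt(n)
  half <- if (se == 0 || n < 2) 0 else stats::qt(0.975, n - 1) * se
  list(mean = mean(x), ci95 = c(mean(x) - half, mean(x) + half),
       max = max(x), n = n, threshold = threshold,
       n_exceeding = sum(x > threshold))
}

#' Write an envelope model as JSON
#' @param model a `bioclim_model`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bioclim_json <- function(model, path) {
  obj <- list(
    variables = model$variables, tail = model$tail, n_train = model$n_train,
    envelopes = lapply(model$envelopes, function(e)
      list(lower = e$lower, upper = e$upper))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
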