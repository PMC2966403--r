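# Configuration-driven pipeline: runs the full comparative analysis per
# species and writes machine-readable reports.
#
# All randomized stages draw their seeds deterministically from the single
# top-level seed, so a rerun with the same configuration is byte-identical.
# The run log records versions, seeds and parameters (no timestamps); stage
# timings go to a separate timings file excluded from the determinism
# guarantee.

#' Read a pipeline configuration (YAML or JSON)
#' @param path configuration file
#' @return named list
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

default_settings <- function() {
  list(n_sims = 1000L, n_perm = 1000L, n_boot = 100L, n_tree_boot = 100L,
       rate_per_bp_per_year = 1.3e-8, generation_time = 1,
       missing_policy = "complete-deletion")
}

merge_settings <- function(config) {
  s <- default_settings()
  for (k in names(config$settings)) s[[k]] <- config$settings[[k]]
  s
}

num <- function(x) sprintf("%.10g", x)

write_report <- function(df, path) {
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the comparative phylogeography pipeline
#'
#' Per species: diversity and neutrality tables, mismatch histogram with
#' sudden-expansion fit and expansion dating, AMOVA (global and pairwise)
#' under each configured grouping scheme, a Mantel isolation-by-distance
#' test where coordinates and at least three populations are available, a
#' median-joining network (GraphML) and an NJ tree with bootstrap supports
#' (Newick).
#'
#' @param config configuration list (see the package vignette) or a path to
#'   a YAML/JSON file
#' @param out_dir output directory (created if needed)
#' @return invisible list of per-species result objects
#' @export
run_phylogeography <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  st <- merge_settings(config)
  log_lines <- c(
    sprintf("phylogeocat %s | R %s.%s", as.character(utils::packageVersion("phylogeocat")),
            R.version$major, R.version$minor),
    sprintf("seed: %d", seed),
    sprintf("settings: %s", paste(sprintf("%s=%s", names(st),
                                          vapply(st, function(x)
                                            if (is.numeric(x)) num(x[1]) else as.character(x[1]),
                                            character(1))),
                                  collapse = " "))
  )
  timings <- character(0)
  results <- list()
  for (sp in config$species) {
    t0 <- proc.time()[3]
    name <- sp$name
    dir_sp <- file.path(out_dir, name)
    dir.create(dir_sp, showWarnings = FALSE)
    alns <- lapply(sp$fasta, read_fasta)
    aln <- Reduce(concatenate, alns)
    md <- read_metadata(sp$metadata)
    rownames(md) <- md$sample_id
    md <- md[rownames(aln), , drop = FALSE]
    mp <- st$missing_policy

    div <- diversity_summary(aln, mp)
    write_report(data.frame(
      statistic = c("n", "bp_used", "haplotypes", "segregating_sites",
                    "transitions", "transversions",
                    "gene_diversity", "gene_diversity_sd",
                    "nucleotide_diversity", "nucleotide_diversity_sd",
                    "theta_pi", "theta_pi_sd", "theta_s", "theta_s_sd"),
      value = num(c(div$n, div$L, div$K, div$S, div$transitions,
                    div$transversions, div$h, div$h_sd, div$pi, div$pi_sd,
                    div$theta_pi, div$theta_pi_sd, div$theta_s, div$theta_s_sd))
    ), file.path(dir_sp, "diversity.csv"))

    td <- tajimas_d(aln, n_sims = st$n_sims, seed = seed + 11L, missing_policy = mp)
    ff <- fus_fs(aln, n_sims = st$n_sims, seed = seed + 13L, missing_policy = mp)
    write_report(data.frame(
      statistic = c("tajimas_D", "tajimas_D_p", "fus_Fs", "fus_Fs_p"),
      value = num(c(td$D, td$p, ff$Fs, ff$p)),
      n_sims = c(td$n_sims, td$n_sims, ff$n_sims, ff$n_sims)
    ), file.path(dir_sp, "neutrality.csv"))

    hist <- mismatch_histogram(aln, mp)
    write_report(data.frame(differences = hist$d, count = hist$counts),
                 file.path(dir_sp, "mismatch.csv"))
    fit <- fit_sudden_expansion(hist, n_boot = st$n_boot, seed = seed + 17L)
    et_lo <- expansion_time(if (!is.null(fit$ci95)) fit$ci95["low", "tau"] else fit$tau,
                            div$L, st$rate_per_bp_per_year, st$generation_time)
    et <- expansion_time(fit$tau, div$L, st$rate_per_bp_per_year, st$generation_time)
    et_hi <- expansion_time(if (!is.null(fit$ci95)) fit$ci95["high", "tau"] else fit$tau,
                            div$L, st$rate_per_bp_per_year, st$generation_time)
    write_report(data.frame(
      statistic = c("tau", "theta0", "theta1", "SSD", "p_SSD",
                    "raggedness", "p_raggedness",
                    "t_years", "t_years_low", "t_years_high"),
      value = num(c(fit$tau, fit$theta0, fit$theta1, fit$SSD, fit$p_SSD,
                    fit$raggedness, fit$p_raggedness,
                    et$t_truncated, et_lo$t_truncated, et_hi$t_truncated))
    ), file.path(dir_sp, "expansion.csv"))

    dmat <- pairwise_difference_matrix(aln, mp)
    for (scheme in sp$groupings) {
      grouping <- stats::setNames(as.character(md[[scheme]]), md$sample_id)
      am <- amova(dmat, grouping, n_perm = st$n_perm, seed = seed + 19L)
      write_report(data.frame(
        statistic = c("phi_st", "p", "sigma2_among", "sigma2_within", "pct_among"),
        value = num(c(am$phi_st, am$p, am$sigma2_among, am$sigma2_within,
                      am$pct_among))
      ), file.path(dir_sp, sprintf("amova_%s.csv", scheme)))
      pw <- pairwise_phist(dmat, grouping, n_perm = st$n_perm, seed = seed + 23L)
      utils::write.csv(round(pw$phi_st, 6),
                       file.path(dir_sp, sprintf("pairwise_phist_%s.csv", scheme)))
      utils::write.csv(round(pw$p, 6),
                       file.path(dir_sp, sprintf("pairwise_p_%s.csv", scheme)))
      if (all(c("latitude", "longitude") %in% names(md)) &&
          length(unique(grouping)) >= 3L) {
        geo <- great_circle_matrix(md, populations = grouping)
        pops <- rownames(geo)
        mt <- mantel_test(geo, pw$phi_st[pops, pops],
                          n_perm = st$n_perm, seed = seed + 29L)
        write_report(data.frame(statistic = c("r", "p"),
                                value = num(c(mt$r, mt$p)),
                                n_perm = mt$n_perm),
                     file.path(dir_sp, sprintf("mantel_%s.csv", scheme)))
      }
    }

    ht <- collapse_haplotypes(aln, mp)
    net <- median_joining(ht)
    write_network(net, file.path(dir_sp, "network.graphml"), "graphml")
    if (nrow(aln) >= 3L) {
      tr <- bootstrap_support(aln, n_reps = st$n_tree_boot, seed = seed + 31L,
                              missing_policy = mp)
      write_newick(tr, file.path(dir_sp, "tree.nwk"))
    }
    results[[name]] <- list(diversity = div, tajima = td, fu = ff, fit = fit,
                            expansion_years = et$t_truncated)
    timings <- c(timings, sprintf("%s: %.1f s", name, proc.time()[3] - t0))
    log_lines <- c(log_lines, sprintf("species %s: n=%d L=%d K=%d S=%d",
                                      name, div$n, div$L, div$K, div$S))
  }
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  writeLines(timings, file.path(out_dir, "timings.txt"))
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the BIOCLIM niche-modelling pipeline
#'
#' Correlation-filters the candidate variables on background points, fits
#' the percentile-envelope model on all presences, writes the suitability
#' grid, evaluates replicate train/test AUC against pseudo-absences, and
#' reports the per-variable threshold summary.
#'
#' @param config configuration list or YAML/JSON path; the `niche` block
#'   holds `presences` (CSV with latitude,longitude), `rasters` (directory
#'   of `.asc` layers), and optional `r_max`, `tail`, `n_reps`,
#'   `train_frac`, `n_background`, `threshold_variable`, `threshold`,
#'   `priority`
#' @param out_dir output directory
#' @param stack optionally a pre-built [climate_stack()] (overrides
#'   `rasters`)
#' @param presences optionally a pre-built presence data.frame
#' @return invisible list with the model, replicate AUCs and threshold report
#' @export
run_niche <- function(config, out_dir, stack = NULL, presences = NULL) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  nc <- config$niche
  if (is.null(stack)) stack <- read_asc_stack(nc$rasters)
  if (is.null(presences)) presences <- utils::read.csv(nc$presences)
  r_max <- nc$r_max %||% 0.7
  tail <- nc$tail %||% 0.025
  n_reps <- nc$n_reps %||% 10L
  train_frac <- nc$train_frac %||% 0.75
  n_background <- nc$n_background %||% 400L

  bg <- pseudo_absences(stack, n_background, seed = seed + 41L)
  bg_vals <- extract_values(stack, bg, na_error = FALSE)
  kept <- correlation_filter(bg_vals, r_max = r_max,
                             priority = nc$priority %||% names(bg_vals))
  write_report(data.frame(variable = names(bg_vals),
                          kept = names(bg_vals) %in% kept),
               file.path(out_dir, "correlation_filter.csv"))
  sub <- stack
  sub$layers <- sub$layers[kept]
  sub$variables <- kept

  vals <- extract_values(sub, presences, na_error = FALSE)
  model <- fit_bioclim(vals, tail = tail)
  write_bioclim_json(model, file.path(out_dir, "model.json"))
  suit <- predict(model, sub)
  write_asc(suit, "suitability", file.path(out_dir, "suitability.asc"))

  reps <- replicate_protocol(presences, sub, n_reps = n_reps,
                             train_frac = train_frac, tail = tail,
                             seed = seed + 43L)
  rep_df <- reps$replicates
  rep_df$auc <- num(rep_df$auc)
  write_report(rep_df, file.path(out_dir, "auc.csv"))

  thr <- NULL
  if (!is.null(nc$threshold_variable) && nc$threshold_variable %in% stack$variables) {
    thr <- threshold_map(stack, nc$threshold_variable, presences,
                         threshold = nc$threshold %||% Inf)
    write_report(data.frame(
      statistic = c("mean", "ci95_low", "ci95_high", "max", "n",
                    "threshold", "n_exceeding"),
      value = num(c(thr$mean, thr$ci95[1], thr$ci95[2], thr$max, thr$n,
                    thr$threshold, thr$n_exceeding))
    ), file.path(out_dir, "threshold.csv"))
  }
  writeLines(c(
    sprintf("phylogeocat %s niche run", as.character(utils::packageVersion("phylogeocat"))),
    sprintf("seed: %d", seed),
    sprintf("variables kept: %s", paste(kept, collapse = ", ")),
    sprintf("mean AUC: %s (range %s-%s)", num(reps$mean_auc),
            num(reps$range_auc[1]), num(reps$range_auc[2]))
  ), file.path(out_dir, "log.txt"))
  invisible(list(model = model, replicates = reps, threshold = thr,
                 kept = kept))
}
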