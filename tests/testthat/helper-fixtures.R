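# Shared fixture builders. Everything is generated in code at test time.

# Small deterministic alignment with two segregating sites.
toy_alignment <- function() {
  seq_alignment(c(
    s1 = "AAGACCTT",
    s2 = "AAGACCTT",
    s3 = "AAAACCTT",
    s4 = "AAAACCTA"
  ))
}

# Random alignment over A/C/G/T with optional missing symbols.
random_alignment <- function(n, L, seed, p_missing = 0) {
  set.seed(seed)
  mat <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  if (p_missing > 0) {
    idx <- which(stats::runif(n * L) < p_missing)
    mat[idx] <- sample(c("N", "-"), length(idx), replace = TRUE)
  }
  rownames(mat) <- paste0("s", seq_len(n))
  seq_alignment(mat)
}

# Two-species pipeline fixture written under `dir`: two gene FASTAs plus a
# metadata CSV per species, and a niche fixture (rasters + presences).
write_pipeline_fixture <- function(dir, seed = 101L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  species <- list()
  specs <- list(
    expander = demography_model("sudden_expansion", theta0 = 0.5, theta1 = 50,
                                tau = 4, n = 24L),
    split = demography_model("two_island", theta = 4, M = 0.05, T_split = 6,
                             n = c(12L, 12L))
  )
  for (nm in names(specs)) {
    aln <- simulate_alignment(specs[[nm]], L = 480L, seed = seed + match(nm, names(specs)))
    g1 <- structure(unclass(aln)[, 1:360, drop = FALSE], class = "seq_alignment")
    g2 <- structure(unclass(aln)[, 361:480, drop = FALSE], class = "seq_alignment")
    f1 <- file.path(dir, paste0(nm, "_gene1.fasta"))
    f2 <- file.path(dir, paste0(nm, "_gene2.fasta"))
    write_fasta(g1, f1)
    write_fasta(g2, f2)
    n <- nrow(aln)
    set.seed(seed + 7L)
    pop <- rep(c("north", "central", "south"), length.out = n)
    lat <- c(north = 31, central = 24, south = 14)[pop] + stats::runif(n, -1, 1)
    lon <- 77 + stats::runif(n, -3, 3)
    md <- data.frame(
      sample_id = rownames(aln), population = pop,
      biogeographic = pop,
      taxonomic = ifelse(pop == "south", "southern_ssp", "northern_ssp"),
      latitudinal = assign_latitudinal_class(lat),
      latitude = round(lat, 4), longitude = round(lon, 4)
    )
    mpath <- file.path(dir, paste0(nm, "_metadata.csv"))
    utils::write.csv(md, mpath, row.names = FALSE)
    species[[length(species) + 1L]] <- list(
      name = nm, fasta = c(f1, f2), metadata = mpath,
      groupings = list("biogeographic")
    )
  }
  rdir <- file.path(dir, "rasters")
  dir.create(rdir, showWarnings = FALSE)
  st <- simulate_climate_stack(25, 30, list(
    list(name = "bio5", intercept = 22, per_row = 0.6, per_col = 0, noise_sd = 0.4),
    list(name = "bio13", intercept = 80, per_row = 0, per_col = 3, noise_sd = 2)
  ), seed = seed + 11L)
  write_asc(st, "bio5", file.path(rdir, "bio5.asc"))
  write_asc(st, "bio13", file.path(rdir, "bio13.asc"))
  pres <- sample_presences(st, function(v) v$bio5 < 30, n = 50, seed = seed + 13L)
  ppath <- file.path(dir, "presences.csv")
  utils::write.csv(pres, ppath, row.names = FALSE)
  list(
    config = list(
      seed = seed,
      settings = list(n_sims = 50L, n_perm = 99L, n_boot = 15L,
                      n_tree_boot = 25L),
      species = species,
      niche = list(presences = ppath, rasters = rdir, n_reps = 4L,
                   n_background = 120L, threshold_variable = "bio5",
                   threshold = 30)
    ),
    stack = st
  )
}
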