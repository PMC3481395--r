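# Shared fixtures, built once per test run and memoised. The benchmark
# corpus is the generator's default configuration: 20 planted families x 10
# members at 70% identity over 4 genomes (half universal, half restricted
# to one genome), 10% fragments, 20 ORFans, seed 42.

.fixture_env <- new.env(parent = emptyenv())

benchmark_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_families(sim_config(seed = 42L))
  }
  .fixture_env$sim
}

benchmark_db <- function() {
  if (is.null(.fixture_env$db)) {
    sim <- benchmark_sim()
    .fixture_env$db <- initialize_database(sim$records,
                                           rep_genomes = paste0("G", 1:4),
                                           seed = 42L)
  }
  .fixture_env$db
}

# recovered family label per planted member (unclustered members get a
# unique label of their own)
recovered_labels <- function(db, member_ids) {
  lab <- setNames(rep(NA_character_, length(member_ids)), member_ids)
  for (f in db$families) {
    hit <- intersect(f$members, member_ids)
    lab[hit] <- paste0("R", f$family_id)
  }
  miss <- is.na(lab)
  lab[miss] <- paste0("U", seq_len(sum(miss)))
  lab
}

# superfamily fixture: 2 planted superfamily pairs + 2 separated families;
# the database is built from the planted memberships so the evaluation
# operations are tested independently of clustering granularity
superfamily_db <- function() {
  if (is.null(.fixture_env$sfdb)) {
    cfg <- sim_config(n_families = 6, members_per_family = 8,
                      n_genomes = 2, n_orfans = 0, fragment_rate = 0,
                      n_superfamily_pairs = 2, indel_rate = 0.005,
                      seed = 11L)
    sim <- simulate_families(cfg)
    fams <- split(sim$truth$seq_id, sim$truth$label)
    db <- sfams:::new_sfam_db(sim$records)
    th <- sfam_thresholds()
    id <- 0L
    for (nm in sort(names(fams))) {
      id <- id + 1L
      f <- sfam_family(id, fams[[nm]], 2L)
      f <- sfams:::build_family_artifacts(f, sim$records, th, seed = 11L)
      db$families[[as.character(id)]] <- f
    }
    db$unclustered <- character(0)
    .fixture_env$sfdb <- list(db = db, sim = sim,
                              superfamily_ids = 1:4, separated_ids = 5:6)
  }
  .fixture_env$sfdb
}

# small well-separated fixture for cheap unit tests: 3 families x 5 members
small_db <- function() {
  if (is.null(.fixture_env$smalldb)) {
    cfg <- sim_config(n_families = 3, members_per_family = 5,
                      n_genomes = 2, n_orfans = 2, fragment_rate = 0,
                      seed = 5L)
    sim <- simulate_families(cfg)
    db <- initialize_database(sim$records, rep_genomes = c("G1", "G2"),
                              seed = 5L)
    .fixture_env$smalldb <- list(db = db, sim = sim)
  }
  .fixture_env$smalldb
}

random_protein <- function(len) {
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], len,
               replace = TRUE), collapse = "")
}

blosum62_sub <- function() sfams:::scoring_matrix()
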