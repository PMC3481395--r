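test_that("initialization recovers planted structure with correct batches", {
  sim <- benchmark_sim()
  db <- benchmark_db()
  truth <- sim$truth
  members <- truth$seq_id[grepl("^FAM", truth$label)]

  # construction batches: universal families seed the database (id 1),
  # genome-restricted families arrive in the de novo round (id 2)
  cids <- vapply(db$families, `[[`, 0L, "construction_id")
  expect_equal(sum(cids == 1L), 10L)
  expect_equal(sum(cids == 2L), 10L)

  # each planted family maps onto exactly one recovered family
  for (fam in unique(truth$label[grepl("^FAM", truth$label)])) {
    ids <- truth$seq_id[truth$label == fam]
    holders <- Filter(function(f) any(ids %in% f$members), db$families)
    expect_length(holders, 1L)
    expect_setequal(intersect(holders[[1]]$members, members), ids)
  }

  # conservation: |members| + |unclustered| == |records|
  n_mem <- sum(vapply(db$families, function(f) length(f$members), 0L))
  expect_equal(n_mem + length(db$unclustered), NROW(sim$records))

  expect_error(initialize_database(sim$records, character(0)), "empty")
  expect_error(initialize_database(sim$records, "G99"), "absent")
})

test_that("a corpus of unrelated sequences yields no families", {
  set.seed(2)
  recs <- protein_records(sprintf("r%02d", 1:12), "G1",
                          vapply(rep(150, 12), random_protein, ""))
  db <- initialize_database(recs, "G1")
  expect_length(db$families, 0L)
  expect_setequal(db$unclustered, recs$seq_id)
})

test_that("sifting assigns to the best family with deterministic ties", {
  fix <- small_db()
  db <- fix$db
  # a record identical to a family consensus goes to that family
  f1 <- db$families[[1]]
  probe <- protein_records("probe", "G1", f1$profile$consensus)
  out <- classify_into_families(db, probe)
  expect_equal(out$assignments$family_id, f1$family_id)
  expect_length(out$residual, 0L)

  # an unrelated random record is residual
  set.seed(99)
  noise <- protein_records("noise", "G1", random_protein(180))
  out2 <- classify_into_families(db, noise)
  expect_equal(out2$residual, "noise")
  expect_equal(NROW(out2$assignments), 0L)

  # sifting never assigns a record to two families and never grows the pool
  both <- rbind(probe, noise)
  out3 <- classify_into_families(db, both)
  expect_equal(NROW(out3$assignments) + length(out3$residual), 2L)
  expect_lte(length(out3$residual), NROW(both))
})

test_that("updates sift relatives and cluster genuinely new families", {
  sim <- benchmark_sim()
  db <- benchmark_db()
  cids0 <- vapply(db$families, `[[`, 0L, "construction_id")
  max_cid0 <- max(cids0)
  n_fam0 <- length(db$families)

  # relabeled near-copies of existing members are all sifted; no new family
  set.seed(71)
  f <- db$families[[which(cids0 == 2L)[1]]]
  copies <- protein_records(
    paste0("COPY", seq_along(f$members)), "G1",
    vapply(f$members, function(id) {
      sfams:::mutate_sequence_impl(
        db$records$sequence[db$records$seq_id == id], 0.9, 0.005)
    }, ""))
  db2 <- update_database(db, copies, seed = 71L)
  expect_length(db2$families, n_fam0)
  expect_true(all(copies$seq_id %in% db2$families[[as.character(
    f$family_id)]]$members))

  # empty input leaves the database unchanged
  db3 <- update_database(db, db$records[0, ])
  expect_identical(db3, db)

  # id collisions are refused
  expect_error(update_database(db, db$records[1, ]), "collision")
})

test_that("unclustered sequences split into truncated / extended / novel", {
  sim <- benchmark_sim()
  db <- benchmark_db()
  rep_ <- classify_unclustered(db)
  expect_setequal(rep_$seq_id, db$unclustered)
  expect_true(all(rep_$class %in%
                    c("truncated", "extended", "novel_or_diverged")))

  truth <- sim$truth
  frag_ids <- truth$seq_id[grepl("^FRAGMENT", truth$label)]
  orfan_ids <- truth$seq_id[truth$label == "ORFAN"]
  # planted fragments overwhelmingly classify as truncated
  frag_cls <- rep_$class[rep_$seq_id %in% frag_ids]
  expect_gte(mean(frag_cls == "truncated"), 0.8)
  # ORFans have no significant hits
  orf_cls <- rep_$class[rep_$seq_id %in% orfan_ids]
  expect_true(all(orf_cls == "novel_or_diverged"))
})

test_that("fragment classification applies the stated length rules", {
  # construct a database with two known profiles: L = 130 and L = 60
  set.seed(55)
  long_anc <- random_protein(130)
  short_anc <- random_protein(60)
  mk <- function(anc, tag, n = 4) {
    setNames(vapply(seq_len(n), function(i) {
      sfams:::mutate_sequence_impl(anc, 0.9, 0)
    }, ""), paste0(tag, seq_len(n)))
  }
  th <- sfam_thresholds()
  fam_seqs <- c(mk(long_anc, "L"), mk(short_anc, "S"))
  # fragment of the long family: length 100, fully covered, 130 >= 1.2*100
  frag <- substr(long_anc, 11, 110)
  # an "extended" probe: longer than every profile it hits
  ext <- paste0(short_anc, random_protein(30))
  recs <- protein_records(c(names(fam_seqs), "frag", "ext", "orphan"),
                          "G1",
                          c(unname(fam_seqs), frag, ext,
                            random_protein(150)))
  db <- sfams:::new_sfam_db(recs)
  i <- 0
  for (tag in c("L", "S")) {
    i <- i + 1
    f <- sfam_family(i, names(fam_seqs)[startsWith(names(fam_seqs), tag)],
                     2L)
    f <- sfams:::build_family_artifacts(f, recs, th, seed = 55L)
    db$families[[as.character(i)]] <- f
  }
  db$unclustered <- c("frag", "ext", "orphan")
  rep_ <- classify_unclustered(db, th)
  cls <- setNames(rep_$class, rep_$seq_id)
  expect_equal(unname(cls["frag"]), "truncated")
  expect_equal(unname(cls["ext"]), "extended")
  expect_equal(unname(cls["orphan"]), "novel_or_diverged")
})

test_that("every pipeline stage conserves the sequence inventory", {
  sim <- benchmark_sim()
  db <- benchmark_db()
  count <- function(d) {
    sum(vapply(d$families, function(f) length(f$members), 0L)) +
      length(d$unclustered)
  }
  expect_equal(count(db), NROW(sim$records))
  set.seed(81)
  extra <- protein_records(paste0("X", 1:6), "G1",
                           vapply(rep(170, 6), random_protein, ""))
  db2 <- update_database(db, extra, seed = 81L)
  expect_equal(count(db2), NROW(sim$records) + 6L)
})
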