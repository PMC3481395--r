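test_that("profiles built from clean alignments have the forced shape", {
  row <- "MKVLAWTTE"
  aln <- setNames(rep(row, 4), paste0("s", 1:4))
  p <- build_profile(aln, 1L)
  expect_equal(p$L, nchar(row))
  chars <- strsplit(row, "")[[1]]
  for (k in seq_len(p$L)) {
    expect_equal(names(which.max(p$match[k, 1:20])), chars[k])
  }
  expect_equal(p$consensus, row)

  # a column at 60% gaps is an insert region, not a match state
  aln2 <- c(a = "MAK", b = "M-K", c = "M-K", d = "MAK", e = "MAK")
  p2 <- build_profile(aln2, 1L)
  expect_equal(p2$L, 3L)          # 40% gaps <= 0.5: still a match column
  aln3 <- c(a = "MAK", b = "M-K", c = "M-K", d = "M-K", e = "M-K")
  p3 <- build_profile(aln3, 1L)
  expect_equal(p3$L, 2L)          # 80% gaps: insert region

  expect_error(build_profile(aln["s1"]), "at least 2")
})

test_that("emission rows are probability distributions", {
  set.seed(4)
  for (i in 1:30) {
    n <- sample(2:8, 1)
    anc <- random_protein(sample(20:50, 1))
    seqs <- setNames(vapply(seq_len(n), function(k) {
      sfams:::mutate_sequence_impl(anc, runif(1, 0.5, 1), 0.03)
    }, ""), paste0("s", seq_len(n)))
    p <- build_profile(trim_alignment(build_msa(seqs)), 1L)
    expect_equal(unname(rowSums(p$match)), rep(1, p$L), tolerance = 1e-9)
    if (p$L > 1) {
      expect_equal(unname(2^p$tMM + 2^p$tMI + 2^p$tMD),
                   rep(1, p$L - 1), tolerance = 1e-9)
      expect_equal(unname(2^p$tIM + 2^p$tII), rep(1, p$L - 1),
                   tolerance = 1e-9)
      expect_equal(unname(2^p$tDM + 2^p$tDD), rep(1, p$L - 1),
                   tolerance = 1e-9)
    }
  }
})

test_that("scoring a profile's own source covers everything", {
  s <- random_protein(30)
  p <- build_profile(setNames(c(s, s), c("a", "b")), 1L)
  h <- score_sequence(p, list(seq_id = "a", sequence = s))
  expect_equal(h$seq_cov, 1.0)
  expect_equal(h$profile_cov, 1.0)
  expect_error(score_sequence(p, list(seq_id = "e", sequence = "")),
               "empty")
})

test_that("Viterbi equals exhaustive path enumeration on tiny profiles", {
  set.seed(6)
  for (i in 1:15) {
    L <- sample(2:4, 1)
    n_rows <- sample(2:4, 1)
    aln <- setNames(vapply(seq_len(n_rows), function(k) random_protein(L),
                           ""), paste0("s", seq_len(n_rows)))
    p <- build_profile(aln, 1L)
    seq <- random_protein(sample(2:5, 1))
    h <- score_sequence(p, list(seq_id = "x", sequence = seq))
    o <- oracle_profile_best(p, seq)
    expect_equal(h$score, o, tolerance = 1e-9)
  }
})

test_that("profile serialization round-trips scores exactly", {
  set.seed(9)
  anc <- random_protein(60)
  seqs <- setNames(vapply(1:4, function(k) {
    sfams:::mutate_sequence_impl(anc, 0.8, 0.02)
  }, ""), paste0("s", 1:4))
  p <- calibrate_profile(build_profile(trim_alignment(build_msa(seqs)), 7L),
                         100, seed = 2)
  path <- withr::local_tempfile(fileext = ".txt")
  sfams:::write_profile(p, path)
  q <- sfams:::read_profile(path)
  expect_equal(q$L, p$L)
  expect_equal(q$consensus, p$consensus)
  expect_equal(q$calibration, p$calibration)
  probe <- list(seq_id = "probe", sequence = random_protein(60))
  expect_equal(score_sequence(q, probe)$score,
               score_sequence(p, probe)$score, tolerance = 1e-12)
})

test_that("calibration is seeded and the moment estimator recovers Gumbel", {
  s <- random_protein(40)
  p <- build_profile(setNames(c(s, s, s), c("a", "b", "c")), 1L)
  c1 <- calibrate_profile(p, 60, seed = 11)$calibration
  c2 <- calibrate_profile(p, 60, seed = 11)$calibration
  expect_identical(c1, c2)
  expect_error(calibrate_profile(p, 10), ">= 50")

  # method-of-moments on draws from a known Gumbel(mu = 2, beta = 1)
  set.seed(123)
  u <- runif(5000)
  draws <- 2 - 1 * log(-log(u))
  fit <- fit_gumbel(draws)
  expect_lt(abs(fit[["mu"]] - 2), 0.2)
  expect_lt(abs(1 / fit[["lambda"]] - 1), 0.15)
  expect_error(fit_gumbel(rep(3, 100)), "zero variance")
})

test_that("calibrated e-values are honest on random sequences", {
  set.seed(3)
  anc <- sfams:::random_sequence(150)
  rows <- setNames(vapply(1:6, function(i) {
    sfams:::mutate_sequence_impl(anc, 0.75, 0.01)
  }, ""), paste0("s", 1:6))
  p <- build_profile(trim_alignment(build_msa(rows)), 1L)
  p <- calibrate_profile(p, 1000, seed = 5)
  scores <- vapply(1:1000, function(i) {
    score_sequence(p, list(seq_id = "r",
                           sequence = sfams:::random_sequence(150)))$score
  }, 0)
  cal <- p$calibration
  u <- exp(-cal[["lambda"]] * (scores - cal[["mu"]]))  # E at n_comparisons 1
  # false-positive rate at the 0.05 level is close to nominal
  expect_lt(abs(mean(u <= 0.05) - 0.05), 0.03)
  # the Gumbel p-value transform of the scores is uniform
  pvals <- 1 - exp(-u)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("recruitment applies the named coverage rule", {
  set.seed(15)
  anc <- random_protein(100)
  seqs <- setNames(vapply(1:5, function(k) {
    sfams:::mutate_sequence_impl(anc, 0.8, 0.01)
  }, ""), paste0("s", 1:5))
  recs <- protein_records(names(seqs), "g", unname(seqs))
  p <- calibrate_profile(build_profile(trim_alignment(build_msa(seqs)), 1L),
                         100, seed = 1)
  # a fragment: good seq coverage, poor profile coverage
  frag <- protein_records("frag", "g", substr(anc, 1, 45))
  expect_equal(NROW(recruit(p, frag, 1e-5, "both")), 0L)
  expect_equal(NROW(recruit(p, frag, 1e-5, "either")), 1L)
  expect_equal(NROW(recruit(p, frag, 1e-5, "seq_only")), 1L)
  expect_error(recruit(p, frag, 1e-5, "sideways"), "arg")
  expect_error(recruit(build_profile(setNames(c(anc, anc), c("x", "y"))),
                       recs, 1e-5, "both"), "not calibrated")

  # planted members are recruited by their own family's profile
  hits <- recruit(p, recs, 1e-5, "both")
  expect_setequal(hits$seq_id, names(seqs))
  # empty record list gives an empty hit list
  expect_equal(NROW(recruit(p, recs[0, ], 1e-5, "both")), 0L)
  # monotone in the e-value gate
  h_tight <- recruit(p, recs, 1e-80, "both")
  expect_true(all(h_tight$seq_id %in% hits$seq_id))
})

test_that("consensus emission takes the modal residue with alphabetic ties", {
  aln <- c(a = "AK", b = "AK", c = "VK", d = "VK")
  p <- build_profile(aln, 1L)
  expect_equal(substr(p$consensus, 1, 1), "A")  # tie A vs V -> A
  s <- "MKWLE"
  p2 <- build_profile(setNames(c(s, s), c("x", "y")), 2L)
  expect_equal(emit_consensus(p2)$sequence, s)
  expect_equal(emit_consensus(p2)$seq_id, "consensus_2")
})

test_that("the consensus maximizes its own profile score on tiny models", {
  set.seed(21)
  ab <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  aln <- setNames(c("AKW", "AKW", "VKW", "AQW"), paste0("s", 1:4))
  p <- build_profile(aln, 1L)
  cons_score <- score_sequence(p, list(seq_id = "c",
                                       sequence = p$consensus))$score
  # exhaustive search over all 20^3 sequences of length L
  grid <- expand.grid(ab, ab, ab, stringsAsFactors = FALSE)
  best <- max(vapply(seq_len(NROW(grid)), function(i) {
    s <- paste(grid[i, ], collapse = "")
    score_sequence(p, list(seq_id = "x", sequence = s))$score
  }, 0))
  expect_equal(cons_score, best, tolerance = 1e-9)
})

test_that("resubstitution recall is perfect for coherent planted families", {
  set.seed(33)
  for (rep in 1:3) {
    anc <- random_protein(120)
    k <- sample(3:6, 1)
    seqs <- setNames(vapply(seq_len(k), function(i) {
      sfams:::mutate_sequence_impl(anc, 0.75, 0.01)
    }, ""), paste0("m", seq_len(k)))
    recs <- protein_records(names(seqs), "g", unname(seqs))
    p <- calibrate_profile(
      build_profile(trim_alignment(build_msa(seqs)), 1L), 100, seed = rep)
    hits <- recruit(p, recs, 1e-5, "both")
    expect_setequal(hits$seq_id, names(seqs))
  }
})
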