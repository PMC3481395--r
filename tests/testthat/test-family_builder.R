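test_that("universality counts occupied genomes", {
  genomes <- list(g1 = c("a", "b"), g2 = c("c"), g3 = c("d"), g4 = c("e"))
  f <- sfam_family(1, c("a", "c", "d", "e"), 1)
  expect_equal(universality_score(f, genomes), 1.0)
  f2 <- sfam_family(2, c("a", "b", "c"), 1)  # 3 members in 2 of 4 genomes
  expect_equal(universality_score(f2, genomes), 0.5)
  # invariant under adding a member in an already-counted genome
  f3 <- sfam_family(3, c("a", "c"), 1)
  f3_dup <- sfam_family(4, c("a", "b", "c"), 1)  # b shares g1 with a
  expect_equal(universality_score(f3, genomes),
               universality_score(f3_dup, genomes))
  expect_error(universality_score(sfam_family(5, c("a", "zz"), 1), genomes),
               "unknown genome")
})

test_that("the widely distributed call is inclusive at the threshold", {
  genomes <- list(g1 = "a", g2 = "b", g3 = "c", g4 = "d")
  fams <- list(sfam_family(1, c("a", "b"), 1),   # universality 0.50
               sfam_family(3, c("c", "d"), 1))
  out <- widely_distributed(fams, genomes, 0.5)
  expect_length(out, 2L)
  # 0.49 threshold boundary: a family in 49% of genomes is excluded at 0.5
  g100 <- setNames(as.list(paste0("s", 1:100)), paste0("g", 1:100))
  f49 <- sfam_family(9, paste0("s", 1:49), 1)
  f50 <- sfam_family(10, paste0("s", 1:50), 1)
  out2 <- widely_distributed(list(f49, f50), g100, 0.5)
  expect_equal(vapply(out2, `[[`, 0L, "family_id"), 10L)
  expect_length(widely_distributed(list(), g100), 0L)
})

test_that("progressive alignment preserves sequences and handles gaps", {
  a <- build_msa(setNames(c("MKVLAWTT", "MKVLAWTT"), c("x", "y")))
  expect_equal(unname(a), c("MKVLAWTT", "MKVLAWTT"))  # gap-free

  a2 <- build_msa(setNames(c("MKVLA", "MKLA"), c("x", "y")))
  expect_equal(nchar(a2[[1]]), 5L)
  expect_equal(sum(strsplit(a2[["y"]], "")[[1]] == "-"), 1L)
  m <- do.call(rbind, strsplit(a2, ""))
  ident_cols <- sum(m[1, ] == m[2, ] & m[1, ] != "-")
  expect_equal(ident_cols, 4L)

  # ungapping any row returns its input, over random inputs
  set.seed(3)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    anc <- random_protein(sample(30:60, 1))
    seqs <- setNames(vapply(seq_len(n), function(k) {
      sfams:::mutate_sequence_impl(anc, runif(1, 0.6, 0.95), 0.02)
    }, ""), paste0("s", seq_len(n)))
    aln <- build_msa(seqs)
    expect_equal(gsub("-", "", aln, fixed = TRUE), seqs)
    expect_length(unique(nchar(aln)), 1L)
  }
  expect_error(build_msa(setNames("MKV", "x")), "at least 2")
})

test_that("gap-rich columns are excised with a strict boundary", {
  # column 1: 4 of 5 gaps (0.8) kept; with 5 of 6 gaps (0.833) removed
  aln5 <- c(a = "MA", b = "-A", c = "-A", d = "-A", e = "-A")
  out5 <- trim_alignment(aln5, 0.8)
  expect_equal(nchar(out5[[1]]), 2L)
  aln6 <- c(aln5, f = "-A")
  out6 <- trim_alignment(aln6, 0.8)
  expect_equal(nchar(out6[[1]]), 1L)
  expect_equal(names(out6), names(aln6))  # row order preserved

  gapfree <- c(a = "MKV", b = "MLV")
  expect_equal(trim_alignment(gapfree, 0.8), gapfree)
  # idempotent
  expect_equal(trim_alignment(out6, 0.8), out6)
  expect_error(trim_alignment(c(a = "-", b = "-", c = "-", d = "-",
                                e = "-", f = "A"), 0.8),
               "every alignment column")
})

test_that("neighbor-joining trees match the 3-taxon closed form", {
  # rows with pairwise p-distances d(ab)=0.2, d(ac)=0.4, d(bc)=0.4
  aln <- c(a = paste(rep("A", 10), collapse = ""),
           b = paste(c(rep("A", 8), "C", "C"), collapse = ""),
           c = paste(c(rep("G", 4), rep("A", 6)), collapse = ""))
  m <- do.call(rbind, strsplit(aln, ""))
  dab <- mean(m[1, ] != m[2, ]); dac <- mean(m[1, ] != m[3, ])
  dbc <- mean(m[2, ] != m[3, ])
  nwk <- build_nj_tree(aln)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("a", "b", "c"))
  # 3-taxon branch lengths: la = (dab + dac - dbc) / 2 etc.
  bl <- setNames(phy$edge.length[match(1:3, phy$edge[, 2])],
                 phy$tip.label)
  expect_equal(unname(bl["a"]), (dab + dac - dbc) / 2, tolerance = 1e-9)
  expect_equal(unname(bl["b"]), (dab + dbc - dac) / 2, tolerance = 1e-9)
  expect_equal(unname(bl["c"]), (dac + dbc - dab) / 2, tolerance = 1e-9)

  # identical rows form a zero-length cherry
  aln2 <- c(x = "MKVA", y = "MKVA", z = "WWWW")
  phy2 <- ape::read.tree(text = build_nj_tree(aln2))
  d <- ape::cophenetic.phylo(phy2)
  expect_equal(d["x", "y"], 0)
  expect_error(build_nj_tree(aln2[1:2]), "at least 3")
})

test_that("representative selection is seeded and respects the ceiling", {
  # family whose members are all highly similar: the <=80% edge filter
  # leaves the graph edgeless, the ceiling bottoms out with a warning
  members <- paste0("m", 1:12)
  edges <- t(combn(members, 2))
  g <- sfams:::similarity_graph(
    members, data.frame(from = edges[, 1], to = edges[, 2], weight = 95))
  fam <- sfam_family(1, members, 2)
  th <- sfam_thresholds(rep_cap = 10L)
  expect_warning(reps <- select_representatives(fam, g, th, seed = 3),
                 "floor")
  expect_length(reps, 12L)  # one per (singleton) sub-cluster

  # moderate similarity: sub-clusters form below the cap, no warning
  g2 <- sfams:::similarity_graph(
    members,
    rbind(data.frame(from = edges[, 1], to = edges[, 2], weight = 30),
          data.frame(from = "m1", to = "m2", weight = 95)))
  fam2 <- sfam_family(2, members, 2)
  th2 <- sfam_thresholds(rep_cap = 200L)
  r1 <- select_representatives(fam2, g2, th2, seed = 9)
  r2 <- select_representatives(fam2, g2, th2, seed = 9)
  expect_identical(r1, r2)  # deterministic for a fixed seed
  expect_lt(length(r1), th2$rep_cap)
})

test_that("greedy PD genome ranking matches exhaustive search", {
  # star tree with one long branch: that leaf is picked first
  star <- "(a:1,b:1,c:1,d:9);"
  expect_equal(select_representative_genomes(star, 1), "d")

  # caterpillar tree: greedy order equals brute-force max-PD subsets
  cat_tree <- "(((a:3,b:1):2,c:4):1,(d:2,e:6):3);"
  phy <- ape::read.tree(text = cat_tree)
  pd_of <- function(tips) {
    if (length(tips) < 2) return(0)
    sum(ape::drop.tip(phy, setdiff(phy$tip.label, tips),
                      collapse.singles = TRUE)$edge.length)
  }
  sel <- select_representative_genomes(cat_tree, 3)
  for (k in 2:3) {
    combos <- combn(phy$tip.label, k, simplify = FALSE)
    best_pd <- max(vapply(combos, pd_of, 0))
    expect_equal(pd_of(sel[1:k]), best_pd)
  }

  # k = number of leaves: all leaves, PD equals the total tree length
  all_sel <- select_representative_genomes(cat_tree, 5)
  expect_setequal(all_sel, phy$tip.label)
  expect_equal(pd_of(all_sel), sum(phy$edge.length))

  no_bl <- "((a,b),c);"
  expect_error(select_representative_genomes(no_bl, 2), "branch lengths")
})
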