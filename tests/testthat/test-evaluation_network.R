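test_that("precision and recall follow their definitions", {
  fix <- small_db()
  db <- fix$db
  for (f in db$families) {
    pr <- family_precision_recall(db, f$family_id)
    expect_gte(pr$precision, 0); expect_lte(pr$precision, 1)
    expect_gte(pr$recall, 0); expect_lte(pr$recall, 1)
    # well-separated planted families: perfect resubstitution metrics
    expect_equal(pr$precision, 1.0)
    expect_equal(pr$recall, 1.0)
  }
  expect_error(family_precision_recall(db, 999), "no such family")
})

test_that("superfamily subfamilies recruit across and lose precision", {
  fix <- superfamily_db()
  db <- fix$db
  for (i in fix$superfamily_ids) {
    pr <- family_precision_recall(db, i)
    expect_lt(pr$precision, 1.0)
    expect_equal(pr$recall, 1.0)
  }
  for (i in fix$separated_ids) {
    pr <- family_precision_recall(db, i)
    expect_equal(pr$precision, 1.0)
  }
})

test_that("leave-one-out recall is seeded and bounded by resubstitution", {
  fix <- small_db()
  db <- fix$db
  fid <- db$families[[1]]$family_id
  l1 <- leave_one_out_recall(db, fid, seed = 4, max_n = 3)
  l2 <- leave_one_out_recall(db, fid, seed = 4, max_n = 3)
  expect_identical(l1, l2)
  expect_gte(l1, 0); expect_lte(l1, 1)

  # a family of identical sequences is immune to removal
  s <- random_protein(90)
  recs <- protein_records(paste0("i", 1:5), "G1", rep(s, 5))
  th <- sfam_thresholds()
  dbi <- sfams:::new_sfam_db(recs)
  f <- sfam_family(1, recs$seq_id, 2L)
  f <- sfams:::build_family_artifacts(f, recs, th, seed = 2L)
  dbi$families[["1"]] <- f
  dbi$unclustered <- character(0)
  expect_equal(leave_one_out_recall(dbi, 1, seed = 1), 1.0)

  expect_error(leave_one_out_recall(dbi, 1, max_n = 2), NA)
  two <- sfams:::new_sfam_db(recs)
  two$families[["1"]] <- local({
    g <- sfam_family(1, recs$seq_id[1:2], 2L); g
  })
  expect_error(leave_one_out_recall(two, 1), "at least 3")
})

test_that("the consensus network links superfamily partners only", {
  fix <- superfamily_db()
  net <- build_family_network(fix$db)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- key(net$edges$from, net$edges$to)
  expect_true(key("1", "2") %in% edges)
  expect_true(key("3", "4") %in% edges)
  # separated families touch nobody
  expect_false(any(grepl("^5 | 5$|^6 | 6$", edges)))
})

test_that("network statistics match closed forms and the BFS oracle", {
  cyc <- sfams:::similarity_graph(
    letters[1:4],
    data.frame(from = c("a", "b", "c", "d"), to = c("b", "c", "d", "a"),
               weight = 1))
  st <- network_statistics(cyc)
  expect_equal(st$nodes$degree, rep(2, 4))
  expect_equal(st$nodes$transitivity, rep(0, 4))

  tri <- sfams:::similarity_graph(
    letters[1:3],
    data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"), weight = 1))
  st2 <- network_statistics(tri)
  expect_equal(st2$nodes$transitivity, rep(1, 3))
  expect_equal(st2$nodes$betweenness, rep(0, 3))

  set.seed(14)
  for (i in 1:10) {
    n <- sample(6:12, 1)
    nodes <- sprintf("v%02d", 1:n)
    p <- t(combn(n, 2))
    keep <- runif(NROW(p)) < 0.3
    if (!any(keep)) keep[1] <- TRUE
    edges <- data.frame(from = nodes[p[keep, 1]], to = nodes[p[keep, 2]],
                        weight = 1)
    st <- network_statistics(sfams:::similarity_graph(nodes, edges))
    o <- oracle_network_stats(nodes, edges)
    expect_equal(st$nodes$degree, o$degree)
    expect_equal(st$nodes$betweenness, o$betweenness, tolerance = 1e-9)
    expect_equal(st$nodes$transitivity, o$transitivity, tolerance = 1e-9)
    expect_equal(st$nodes$closeness, o$closeness, tolerance = 1e-9)
    expect_equal(length(st$component_sizes), max(o$component))
  }
})

test_that("reciprocal linking demands both directions at the threshold", {
  members <- list(A = paste0("a", 1:10), B = paste0("b", 1:10))
  # A recruits 9/10 of B; B recruits 8/10 of A: linked (>= is inclusive)
  rec <- list(A = c(members$A, members$B[1:9]),
              B = c(members$B, members$A[1:8]))
  l <- sfams:::reciprocal_links(rec, members, 0.8)
  expect_equal(l$from, 1L); expect_equal(l$to, 2L)
  # reciprocity required: 10/10 one way, 5/10 the other
  rec2 <- list(A = c(members$A, members$B),
               B = c(members$B, members$A[1:5]))
  expect_length(sfams:::reciprocal_links(rec2, members, 0.8)$from, 0L)
  # single linkage is transitive across pairs
  members3 <- list(A = paste0("a", 1:4), B = paste0("b", 1:4),
                   C = paste0("c", 1:4))
  rec3 <- list(A = c(members3$A, members3$B),
               B = c(members3$B, members3$A, members3$C),
               C = c(members3$C, members3$B))
  l3 <- sfams:::reciprocal_links(rec3, members3, 0.8)
  cl <- sfams:::clan_components(c("A", "B", "C"),
                                c("A", "B", "C")[l3$from],
                                c("A", "B", "C")[l3$to], "reciprocal")
  expect_equal(sort(cl$family_id[cl$clan_id == 1]), c("A", "B", "C"))
})

test_that("both clan constructions agree on the superfamily fixture", {
  fix <- superfamily_db()
  cc <- consensus_clans(build_family_network(fix$db))
  rc <- reciprocal_clans(fix$db)
  pairs <- function(cl) {
    out <- lapply(split(cl$family_id, cl$clan_id), function(x) {
      sort(as.character(x))
    })
    unname(out[order(vapply(out, `[`, "", 1))])
  }
  expect_equal(pairs(cc), list(c("1", "2"), c("3", "4")))
  expect_equal(pairs(rc), list(c("1", "2"), c("3", "4")))
  # partition validity: no family in two clans of the same method
  expect_false(anyDuplicated(cc$family_id) > 0)
  expect_false(anyDuplicated(rc$family_id) > 0)
})

test_that("clan components equal brute-force union-find", {
  set.seed(31)
  nodes <- sprintf("f%02d", 1:15)
  p <- t(combn(15, 2))
  keep <- runif(NROW(p)) < 0.12
  from <- nodes[p[keep, 1]]; to <- nodes[p[keep, 2]]
  cl <- sfams:::clan_components(nodes, from, to, "consensus_component")
  o <- oracle_components(nodes, from, to)
  o_multi <- Filter(function(x) length(x) >= 2, o)
  got <- lapply(split(cl$family_id, cl$clan_id), sort)
  expect_setequal(vapply(got, paste, "", collapse = ","),
                  vapply(o_multi, paste, "", collapse = ","))
})

test_that("an edgeless network yields no multi-family clans", {
  g <- sfams:::similarity_graph(c("1", "2", "3"),
                                data.frame(from = character(0),
                                           to = character(0),
                                           weight = numeric(0)))
  expect_equal(NROW(consensus_clans(g)), 0L)
})
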