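#' Precision and recall of a family profile
#'
#' The family's profile recruits from the full record set (e-value gate,
#' coverage rule "both"); precision is the fraction of recruited sequences
#' that are family members and recall the fraction of members that are
#' recruited. A profile that recruits nothing gets precision 1 with a
#' `vacuous` flag (the ratio is otherwise undefined).
#'
#' @param db An `sfam_db`.
#' @param family_id Integer id of the family to evaluate.
#' @param records Record set to recruit from (defaults to the database's).
#' @param thresholds An [sfam_thresholds()].
#' @return Named list `precision`, `recall`, `vacuous`, `recruited`
#'   (character vector of recruited seq_ids).
#' @export
family_precision_recall <- function(db, family_id, records = db$records,
                                    thresholds = sfam_thresholds()) {
  f <- db$families[[as.character(family_id)]]
  if (is.null(f)) stop("no such family: ", family_id, call. = FALSE)
  if (length(f$members) == 0L) stop("empty family", call. = FALSE)
  hits <- recruit(f$profile, records,
                  evalue_max = thresholds$evalue_general,
                  coverage_rule = "both",
                  coverage_min = thresholds$coverage,
                  n_comparisons = db_n_comparisons(db))
  rec_ids <- hits$seq_id
  vacuous <- length(rec_ids) == 0L
  precision <- if (vacuous) 1 else {
    length(intersect(rec_ids, f$members)) / length(rec_ids)
  }
  recall <- length(intersect(rec_ids, f$members)) / length(f$members)
  list(precision = precision, recall = recall, vacuous = vacuous,
       recruited = rec_ids)
}

#' Leave-one-out recall of a family profile
#'
#' For each tested member the family alignment is rebuilt without it, the
#' profile retrained and recalibrated (with a per-member seed offset for
#' reproducibility), and the left-out sequence tested for recruitment
#' under the usual gate. Returns the fraction recruited.
#'
#' @param db An `sfam_db`.
#' @param family_id Family with at least 3 members.
#' @param seed Integer seed (drives member sampling and recalibration).
#' @param max_n Test at most this many members (sampled with `seed`).
#' @param thresholds An [sfam_thresholds()].
#' @return Fraction of tested members recruited by their leave-one-out
#'   profile.
#' @export
leave_one_out_recall <- function(db, family_id, seed = 1L, max_n = Inf,
                                 thresholds = sfam_thresholds()) {
  f <- db$families[[as.character(family_id)]]
  if (is.null(f)) stop("no such family: ", family_id, call. = FALSE)
  if (length(f$members) < 3L) {
    stop("leave-one-out needs at least 3 members", call. = FALSE)
  }
  tested <- f$members
  if (length(tested) > max_n) {
    tested <- with_seed(seed, sample(tested, max_n))
  }
  ncmp <- db_n_comparisons(db)
  ok <- vapply(tested, function(m) {
    others <- setdiff(f$members, m)
    rec <- db$records[match(others, db$records$seq_id), , drop = FALSE]
    aln <- build_msa(rec, thresholds)
    prof <- build_profile(trim_alignment(aln, thresholds$gap_col_max),
                          f$family_id)
    prof <- calibrate_profile(prof, thresholds$n_shuffles,
                              seed = seed + match(m, f$members))
    h <- score_sequence(prof,
                        db$records[db$records$seq_id == m, , drop = FALSE],
                        n_comparisons = ncmp)
    !is.na(h$evalue) && h$evalue <= thresholds$evalue_general &&
      h$seq_cov >= thresholds$coverage &&
      h$profile_cov >= thresholds$coverage
  }, TRUE)
  mean(ok)
}

#' Consensus-sequence family network
#'
#' Every family's profile consensus is aligned against every other; an
#' unweighted edge joins two families iff the alignment passes the e-value
#' gate and covers at least `coverage` of the shorter consensus.
#'
#' @param db An `sfam_db` where every family has a consensus.
#' @param thresholds An [sfam_thresholds()].
#' @return An `sfam_graph` whose nodes are family ids (as characters) and
#'   whose edges are unweighted (`weight` fixed at 1).
#' @export
build_family_network <- function(db, thresholds = sfam_thresholds()) {
  fams <- db$families
  if (any(vapply(fams, function(f) is.null(f$consensus), TRUE))) {
    stop("family without consensus", call. = FALSE)
  }
  ids <- vapply(fams, `[[`, 0L, "family_id")
  cons <- vapply(fams, `[[`, "", "consensus")
  n_total <- sum(nchar(cons))
  from <- character(0); to <- character(0)
  if (length(fams) >= 2L) {
    for (i in 1:(length(fams) - 1L)) {
      for (j in (i + 1L):length(fams)) {
        hit <- align_pair(list(seq_id = "a", sequence = cons[i]),
                          list(seq_id = "b", sequence = cons[j]),
                          thresholds, n = n_total)
        if (hit$aln_len == 0L) next
        shorter_cov <- if (nchar(cons[i]) <= nchar(cons[j])) {
          hit$q_cov
        } else hit$s_cov
        if (hit$evalue <= thresholds$evalue_general &&
            shorter_cov >= thresholds$coverage) {
          from <- c(from, as.character(ids[i]))
          to <- c(to, as.character(ids[j]))
        }
      }
    }
  }
  similarity_graph(as.character(ids),
                   data.frame(from = from, to = to,
                              weight = rep(1, length(from)),
                              stringsAsFactors = FALSE))
}

#' Topology statistics of a family network
#'
#' Degree, unnormalised shortest-path betweenness, local transitivity
#' (clustering coefficient; 0 where undefined), within-component closeness
#' `(n_component - 1) / sum(distances)`, component membership and sizes,
#' plus the medians of the four node statistics.
#'
#' @param graph An `sfam_graph` (unweighted edges).
#' @return List with `nodes` (per-node `data.frame`), `component_sizes`
#'   and `medians`.
#' @export
network_statistics <- function(graph) {
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("from", "to"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = graph$nodes))
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  trans <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(trans) <- igraph::V(g)$name
  comp <- igraph::components(g)
  D <- igraph::distances(g, weights = NA)
  clo <- vapply(seq_along(deg), function(v) {
    same <- which(comp$membership == comp$membership[v])
    if (length(same) < 2L) return(0)
    (length(same) - 1) / sum(D[v, setdiff(same, v)])
  }, 0)
  nodes <- data.frame(node = igraph::V(g)$name, degree = unname(deg),
                      betweenness = unname(btw),
                      transitivity = unname(trans),
                      closeness = clo,
                      component = unname(comp$membership),
                      stringsAsFactors = FALSE)
  list(nodes = nodes,
       component_sizes = as.integer(comp$csize),
       medians = c(degree = median(nodes$degree),
                   betweenness = median(nodes$betweenness),
                   transitivity = median(nodes$transitivity),
                   closeness = median(nodes$closeness)))
}

#' Clans by reciprocal profile recruitment
#'
#' Two families are linked iff each one's profile recruits at least
#' `clan_recruit_frac` of the other's members (both directions, inclusive
#' bound); clans are the connected components of the link graph
#' (single-linkage). Families with no link stand alone and are not part of
#' any clan.
#'
#' @param db An `sfam_db`.
#' @param records Record set recruited from (defaults to the database's).
#' @param thresholds An [sfam_thresholds()].
#' @return A clan set: `data.frame` with `method`, `clan_id`, `family_id`.
#' @export
reciprocal_clans <- function(db, records = db$records,
                             thresholds = sfam_thresholds()) {
  fams <- db$families
  ids <- vapply(fams, `[[`, 0L, "family_id")
  rec_sets <- lapply(fams, function(f) {
    family_precision_recall(db, f$family_id, records,
                            thresholds)$recruited
  })
  member_sets <- lapply(fams, `[[`, "members")
  links <- reciprocal_links(rec_sets, member_sets,
                            thresholds$clan_recruit_frac)
  clan_components(ids, ids[links$from], ids[links$to],
                  "reciprocal_recruitment")
}

# pairs (i, j) where each profile recruits >= frac of the other's members
# (inclusive bound; reciprocity required)
reciprocal_links <- function(rec_sets, member_sets, frac) {
  n <- length(rec_sets)
  from <- integer(0); to <- integer(0)
  if (n >= 2L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        a_gets_b <- length(intersect(rec_sets[[i]], member_sets[[j]])) >=
          frac * length(member_sets[[j]])
        b_gets_a <- length(intersect(rec_sets[[j]], member_sets[[i]])) >=
          frac * length(member_sets[[i]])
        if (a_gets_b && b_gets_a) {
          from <- c(from, i); to <- c(to, j)
        }
      }
    }
  }
  list(from = from, to = to)
}

#' Clans from the consensus network
#'
#' Clans are the multi-family connected components of the
#' consensus-sequence network ([build_family_network()]).
#'
#' @param graph An `sfam_graph` over families.
#' @return A clan set `data.frame` tagged `consensus_component`.
#' @export
consensus_clans <- function(graph) {
  clan_components(graph$nodes, graph$edges$from, graph$edges$to,
                  "consensus_component")
}

# connected components with >= 2 members, tagged with the method
clan_components <- function(ids, from, to, method) {
  ids <- as.character(ids)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(from), to = as.character(to)),
    directed = FALSE, vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  keep <- which(comp$csize >= 2L)
  out <- data.frame(method = character(0), clan_id = integer(0),
                    family_id = character(0), stringsAsFactors = FALSE)
  cl <- 0L
  for (k in keep) {
    cl <- cl + 1L
    members <- igraph::V(g)$name[comp$membership == k]
    out <- rbind(out, data.frame(method = method, clan_id = cl,
                                 family_id = members,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
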