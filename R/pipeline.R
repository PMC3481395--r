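new_sfam_db <- function(records, families = list(),
                        unclustered = character(0),
                        next_construction_id = 1L,
                        thresholds = sfam_thresholds()) {
  structure(list(records = records, families = families,
                 unclustered = unclustered,
                 next_construction_id = as.integer(next_construction_id),
                 thresholds = thresholds, clans = NULL),
            class = "sfam_db")
}

#' @export
print.sfam_db <- function(x, ...) {
  nmem <- sum(vapply(x$families, function(f) length(f$members), 0L))
  cat(sprintf(paste0("<sfam_db> %d sequences: %d families (%d members), ",
                     "%d unclustered; next construction id %d\n"),
              NROW(x$records), length(x$families), nmem,
              length(x$unclustered), x$next_construction_id))
  invisible(x)
}

#' @export
summary.sfam_db <- function(object, ...) {
  cid <- vapply(object$families, `[[`, 0L, "construction_id")
  sizes <- vapply(object$families, function(f) length(f$members), 0L)
  out <- list(n_sequences = NROW(object$records),
              n_families = length(object$families),
              families_per_construction = table(cid),
              family_size_summary = if (length(sizes)) summary(sizes),
              n_unclustered = length(object$unclustered))
  class(out) <- "summary.sfam_db"
  out
}

#' @export
print.summary.sfam_db <- function(x, ...) {
  cat("Family database\n")
  cat("  sequences:  ", x$n_sequences, "\n")
  cat("  families:   ", x$n_families, "\n")
  if (x$n_families > 0) {
    cat("  by construction id:\n")
    print(x$families_per_construction)
  }
  cat("  unclustered:", x$n_unclustered, "\n")
  invisible(x)
}

# every sequence is a member of at most one family XOR unclustered, and
# members + unclustered account for every input record exactly once
validate_db <- function(db) {
  members <- unlist(lapply(db$families, `[[`, "members"), use.names = FALSE)
  if (anyDuplicated(members)) {
    stop("sequence in more than one family: ",
         paste(unique(members[duplicated(members)]), collapse = ", "),
         call. = FALSE)
  }
  both <- intersect(members, db$unclustered)
  if (length(both)) {
    stop("sequence both clustered and unclustered: ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  accounted <- c(members, db$unclustered)
  if (length(accounted) != NROW(db$records) ||
      !setequal(accounted, db$records$seq_id)) {
    stop("conservation violated: |members| + |unclustered| != |records|",
         call. = FALSE)
  }
  invisible(db)
}

# number of profile comparisons feeding the e-value scale
db_n_comparisons <- function(db) {
  max(1L, sum(vapply(db$families, function(f) !is.null(f$profile), TRUE)))
}

# alignment + profile + consensus + tree for one family; members over
# rep_trigger are aligned as representatives first, then the remaining
# members are folded into the training alignment
build_family_artifacts <- function(family, records, thresholds, seed,
                                   graph = NULL) {
  rec <- records[match(family$members, records$seq_id), , drop = FALSE]
  if (length(family$members) > thresholds$rep_trigger && !is.null(graph)) {
    reps <- select_representatives(family, graph, thresholds, seed)
    family$representatives <- unname(reps)
    train <- build_msa(rec[rec$seq_id %in% reps, , drop = FALSE],
                       thresholds)
    rest <- setdiff(family$members, reps)
    aln <- train
    for (id in rest) {
      s <- rec$sequence[rec$seq_id == id]
      aln <- merge_alignments(aln, setNames(s, id), thresholds)
    }
    family$alignment <- aln
  } else {
    family$alignment <- build_msa(rec, thresholds)
  }
  trimmed <- trim_alignment(family$alignment, thresholds$gap_col_max)
  prof <- build_profile(trimmed, family$family_id)
  prof <- calibrate_profile(prof, thresholds$n_shuffles,
                            seed = seed + family$family_id)
  family$profile <- prof
  family$consensus <- prof$consensus
  if (length(family$members) >= 3L) {
    family$tree <- build_nj_tree(trimmed)
  }
  family
}

# de novo clustering of a record subset: similarity graph -> MCL ->
# families of size >= 2 (list) plus the singleton ids
denovo_cluster <- function(records, thresholds, evalue_max) {
  if (NROW(records) < 2L) {
    return(list(clusters = list(), singletons = records$seq_id))
  }
  graph <- build_similarity_graph(records, thresholds,
                                  evalue_max = evalue_max)
  part <- run_mcl(graph, thresholds$inflation, thresholds)
  keep <- lengths(part$clusters) >= 2L
  list(clusters = unname(part$clusters[keep]),
       singletons = unlist(part$clusters[!keep], use.names = FALSE) %||%
         character(0),
       graph = graph)
}

#' Initialise a family database from representative genomes
#'
#' The seeding stage of the iterative workflow: (1) all-vs-all comparison
#' of the representative-genome proteins under the stringent gate
#' (`evalue_init`, bidirectional coverage) followed by MCL; (2) clusters
#' spanning at least `universality_min` of the representative genomes
#' become the widely distributed families (construction id 1) and get
#' profiles; (3) those profiles recruit members from the complete record
#' set (`evalue_general`, coverage rule "both") and recruited sequences
#' leave the de novo pool; (4) the remaining pool is clustered de novo
#' under the general gate, multi-member clusters becoming construction id
#' 2 families; leftover singletons are recorded as unclustered.
#'
#' @param records Full record table.
#' @param rep_genomes Character vector of representative genome ids.
#' @param thresholds An [sfam_thresholds()].
#' @param seed Integer seed driving representative draws and profile
#'   calibration.
#' @return An `sfam_db`.
#' @export
initialize_database <- function(records, rep_genomes,
                                thresholds = sfam_thresholds(),
                                seed = 1L) {
  if (length(rep_genomes) == 0L) {
    stop("empty representative genome set", call. = FALSE)
  }
  if (!all(rep_genomes %in% records$genome_id)) {
    stop("representative genome(s) absent from the records: ",
         paste(setdiff(rep_genomes, records$genome_id), collapse = ", "),
         call. = FALSE)
  }
  rep_records <- records[records$genome_id %in% rep_genomes, , drop = FALSE]
  dn <- denovo_cluster(rep_records, thresholds, thresholds$evalue_init)
  seed_families <- lapply(seq_along(dn$clusters), function(i) {
    sfam_family(i, dn$clusters[[i]], construction_id = 1L)
  })
  rep_genome_set <- genome_set(rep_records)
  wide <- widely_distributed(seed_families, rep_genome_set,
                             thresholds$universality_min)
  # renumber the retained families densely and build their artifacts
  families <- list()
  for (i in seq_along(wide)) {
    f <- wide[[i]]
    f$family_id <- i
    f <- build_family_artifacts(f, records, thresholds, seed,
                                graph = dn$graph)
    families[[as.character(i)]] <- f
  }

  db <- new_sfam_db(records, families, character(0),
                    next_construction_id = 2L, thresholds = thresholds)

  # profile screen of the complete record set; recruited sequences join
  # the widely distributed families and leave the de novo pool
  pool <- records
  if (length(families)) {
    already <- unlist(lapply(families, `[[`, "members"), use.names = FALSE)
    cand <- records[!records$seq_id %in% already, , drop = FALSE]
    sift <- classify_into_families(db, cand, thresholds)
    if (NROW(sift$assignments)) {
      for (i in seq_len(NROW(sift$assignments))) {
        fid <- as.character(sift$assignments$family_id[i])
        db$families[[fid]]$members <-
          c(db$families[[fid]]$members, sift$assignments$seq_id[i])
      }
    }
    member_now <- unlist(lapply(db$families, `[[`, "members"),
                         use.names = FALSE)
    pool <- records[!records$seq_id %in% member_now, , drop = FALSE]
  }

  # independent de novo round on the residue at the general gate
  dn2 <- denovo_cluster(pool, thresholds, thresholds$evalue_general)
  next_id <- length(db$families)
  for (cl in dn2$clusters) {
    next_id <- next_id + 1L
    f <- sfam_family(next_id, cl, construction_id = 2L)
    f <- build_family_artifacts(f, records, thresholds, seed,
                                graph = dn2$graph)
    db$families[[as.character(next_id)]] <- f
  }
  db$unclustered <- dn2$singletons
  db$next_construction_id <- 3L
  validate_db(db)
  db
}

#' Sift sequences against the existing family profiles
#'
#' Each record is scored against every profiled family; among the families
#' whose recruitment test it passes (e-value gate, coverage rule "both"),
#' it is assigned to the one with the lowest e-value (ties to the lowest
#' family id). Records passing no gate form the residual.
#'
#' @param db An `sfam_db` with at least one profiled family.
#' @param new_records Record table to classify.
#' @param thresholds An [sfam_thresholds()].
#' @return List with `assignments` (`seq_id`, `family_id`, `evalue`,
#'   `score`) and `residual` (character vector of seq_ids).
#' @export
classify_into_families <- function(db, new_records,
                                   thresholds = sfam_thresholds()) {
  profiled <- Filter(function(f) !is.null(f$profile), db$families)
  if (length(profiled) == 0L) {
    stop("database has no profiled family", call. = FALSE)
  }
  if (length(profiled) != length(db$families)) {
    stop("family without profile: ",
         paste(setdiff(names(db$families), names(profiled)),
               collapse = ", "), call. = FALSE)
  }
  ncmp <- db_n_comparisons(db)
  assignments <- data.frame(seq_id = character(0), family_id = integer(0),
                            evalue = numeric(0), score = numeric(0),
                            stringsAsFactors = FALSE)
  residual <- character(0)
  for (i in seq_len(NROW(new_records))) {
    rec <- new_records[i, , drop = FALSE]
    best <- NULL
    for (f in profiled) {
      h <- score_sequence(f$profile, rec, n_comparisons = ncmp)
      ok <- !is.na(h$evalue) && h$evalue <= thresholds$evalue_general &&
        h$seq_cov >= thresholds$coverage &&
        h$profile_cov >= thresholds$coverage
      if (ok && (is.null(best) || h$evalue < best$evalue ||
                 (h$evalue == best$evalue &&
                  h$family_id < best$family_id))) {
        best <- h
      }
    }
    if (is.null(best)) {
      residual <- c(residual, rec$seq_id)
    } else {
      assignments <- rbind(assignments,
                           data.frame(seq_id = rec$seq_id,
                                      family_id = best$family_id,
                                      evalue = best$evalue,
                                      score = best$score,
                                      stringsAsFactors = FALSE))
    }
  }
  list(assignments = assignments, residual = residual)
}

#' Update the family database with new sequences
#'
#' One iteration of the sift-then-cluster loop: new records are sifted
#' against the existing profiles ([classify_into_families()]); the
#' residual is pooled with the database's unclustered sequences and
#' clustered de novo; multi-member clusters become families under the next
#' construction id; remaining singletons become the new unclustered set.
#'
#' @param db An `sfam_db`.
#' @param new_records Record table; ids must not collide with the database.
#' @param thresholds An [sfam_thresholds()].
#' @param seed Integer seed.
#' @return The updated `sfam_db`.
#' @export
update_database <- function(db, new_records,
                            thresholds = sfam_thresholds(), seed = 1L) {
  stopifnot(inherits(db, "sfam_db"))
  if (NROW(new_records) == 0L) return(db)
  clash <- intersect(new_records$seq_id, db$records$seq_id)
  if (length(clash)) {
    stop("seq_id collision with the database: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  sift <- classify_into_families(db, new_records, thresholds)
  if (NROW(sift$assignments)) {
    for (i in seq_len(NROW(sift$assignments))) {
      fid <- as.character(sift$assignments$family_id[i])
      db$families[[fid]]$members <-
        c(db$families[[fid]]$members, sift$assignments$seq_id[i])
    }
  }
  db$records <- rbind(db$records, new_records)
  pool_ids <- c(db$unclustered, sift$residual)
  pool <- db$records[db$records$seq_id %in% pool_ids, , drop = FALSE]
  dn <- denovo_cluster(pool, thresholds, thresholds$evalue_general)
  if (length(dn$clusters)) {
    cid <- db$next_construction_id
    next_id <- max(c(0L, vapply(db$families, `[[`, 0L, "family_id")))
    for (cl in dn$clusters) {
      next_id <- next_id + 1L
      f <- sfam_family(next_id, cl, construction_id = cid)
      f <- build_family_artifacts(f, db$records, thresholds, seed,
                                  graph = dn$graph)
      db$families[[as.character(next_id)]] <- f
    }
    db$next_construction_id <- cid + 1L
  }
  db$unclustered <- dn$singletons
  validate_db(db)
  db
}

#' Classify never-clustered sequences as truncated, extended or novel
#'
#' Each unclustered sequence is compared to every family profile at the
#' general e-value gate with coverage rule "either". It is called
#' `truncated` if some hit's profile has at least `fragment_len_ratio`
#' times its length and the alignment covers at least 80% of the sequence;
#' otherwise `extended` if it is longer than the profile of every family it
#' hits; otherwise `novel_or_diverged` (which includes the no-hit case).
#' Truncated takes precedence, making the categories disjoint.
#'
#' @param db An `sfam_db` with calibrated profiles.
#' @param thresholds An [sfam_thresholds()].
#' @return `data.frame` per unclustered sequence: `seq_id`, `class`,
#'   `n_hits`, `best_family`, `best_evalue`.
#' @export
classify_unclustered <- function(db, thresholds = sfam_thresholds()) {
  profiled <- Filter(function(f) !is.null(f$profile), db$families)
  ncmp <- db_n_comparisons(db)
  out <- lapply(db$unclustered, function(id) {
    rec <- db$records[db$records$seq_id == id, , drop = FALSE]
    len <- rec$length
    hits <- do.call(rbind, lapply(profiled, function(f) {
      score_sequence(f$profile, rec, n_comparisons = ncmp)
    }))
    if (!is.null(hits)) {
      L_of <- vapply(profiled, function(f) f$profile$L, 0)
      pass <- !is.na(hits$evalue) &
        hits$evalue <= thresholds$evalue_general &
        (hits$seq_cov >= thresholds$coverage |
           hits$profile_cov >= thresholds$coverage)
      hits <- hits[pass, , drop = FALSE]
      L_of <- L_of[pass]
    }
    if (is.null(hits) || NROW(hits) == 0L) {
      return(data.frame(seq_id = id, class = "novel_or_diverged",
                        n_hits = 0L, best_family = NA_integer_,
                        best_evalue = NA_real_, stringsAsFactors = FALSE))
    }
    truncated <- any(L_of >= thresholds$fragment_len_ratio * len &
                       hits$seq_cov >= thresholds$coverage)
    cls <- if (truncated) "truncated"
    else if (all(len > L_of)) "extended"
    else "novel_or_diverged"
    b <- which.min(hits$evalue)
    data.frame(seq_id = id, class = cls, n_hits = NROW(hits),
               best_family = hits$family_id[b],
               best_evalue = hits$evalue[b], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out) %||%
    data.frame(seq_id = character(0), class = character(0),
               n_hits = integer(0), best_family = integer(0),
               best_evalue = numeric(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
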