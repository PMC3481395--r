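#' Universality score of a family
#'
#' The fraction of the representative genomes that contain at least one
#' member of the family.
#'
#' @param family An `sfam_family`.
#' @param genomes A genome set: named list mapping `genome_id` to the
#'   seq_ids it encodes.
#' @return Fraction in `[0, 1]`.
#' @export
universality_score <- function(family, genomes) {
  if (length(genomes) == 0L) stop("empty genome set", call. = FALSE)
  genome_of <- setNames(rep(names(genomes), lengths(genomes)),
                        unlist(genomes, use.names = FALSE))
  g <- genome_of[family$members]
  if (anyNA(g)) {
    stop("member(s) with unknown genome: ",
         paste(family$members[is.na(g)], collapse = ", "), call. = FALSE)
  }
  length(unique(g)) / length(genomes)
}

#' Select the widely distributed families
#'
#' Families whose universality score is at least `universality_min`
#' (inclusive; the pipeline default is 0.5, i.e. present in half of the
#' representative genomes).
#'
#' @param families List of `sfam_family` objects.
#' @param genomes Genome set (named list).
#' @param universality_min Inclusive threshold.
#' @return The qualifying subset, with `universality` filled in.
#' @export
widely_distributed <- function(families, genomes, universality_min = 0.5) {
  if (length(families) == 0L) return(families[0])
  scored <- lapply(families, function(f) {
    f$universality <- universality_score(f, genomes)
    f
  })
  keep <- vapply(scored, `[[`, 0, "universality") >= universality_min
  scored[keep]
}

#' Pick diverse representative sequences for a large family
#'
#' Sub-clusters the family with MCL on the member-restricted similarity
#' graph keeping only edges whose weight does not exceed a similarity
#' ceiling (start 80%). If that yields at least `rep_cap` sub-clusters the
#' ceiling is lowered by 5 percentage points and the process repeated, down
#' to a floor of 5%; if the floor is reached with the count still at or
#' above the cap, one member per sub-cluster is returned anyway with a
#' warning. One member is drawn at random (seeded) from each sub-cluster.
#'
#' @param family An `sfam_family`.
#' @param graph `sfam_graph` over (at least) the family members.
#' @param thresholds Provides `rep_cap`, `rep_sim_ceiling`, `inflation`.
#' @param seed Integer seed for the random member draw.
#' @return Character vector of representative seq_ids.
#' @export
select_representatives <- function(family, graph,
                                   thresholds = sfam_thresholds(),
                                   seed = 1L) {
  members <- family$members
  edges <- graph$edges
  keep <- edges$from %in% members & edges$to %in% members
  edges <- edges[keep, , drop = FALSE]
  ceiling_pct <- thresholds$rep_sim_ceiling * 100
  repeat {
    sub <- edges[edges$weight <= ceiling_pct, , drop = FALSE]
    part <- run_mcl(similarity_graph(members, sub),
                    inflation = thresholds$inflation, thresholds)
    n_sub <- length(part$clusters)
    if (n_sub < thresholds$rep_cap) break
    if (ceiling_pct - 5 < 5) {
      warning("similarity ceiling floor reached with ", n_sub,
              " sub-clusters (cap ", thresholds$rep_cap,
              "); returning one representative per sub-cluster",
              call. = FALSE)
      break
    }
    ceiling_pct <- ceiling_pct - 5
  }
  with_seed(seed, {
    vapply(part$clusters, function(cl) {
      cl[sample.int(length(cl), 1L)]
    }, "")
  })
}

# ---- progressive multiple alignment -------------------------------------

# alignment rows -> residue-frequency profile (A x L, gap mass excluded)
alignment_profile <- function(aln) {
  ab <- aa_alphabet()
  L <- nchar(aln[1])
  m <- matrix(0, length(ab), L, dimnames = list(ab, NULL))
  for (r in strsplit(aln, "", fixed = TRUE)) {
    hit <- match(r, ab)
    ok <- !is.na(hit)
    m[cbind(hit[ok], which(ok))] <- m[cbind(hit[ok], which(ok))] + 1
  }
  m / length(aln)
}

# merge two alignments by profile-profile global alignment
merge_alignments <- function(alnA, alnB, thresholds = sfam_thresholds()) {
  res <- nw_profile_cpp(alignment_profile(alnA), alignment_profile(alnB),
                        scoring_matrix(), thresholds$gap_open,
                        thresholds$gap_ext)
  expand <- function(rows, use) {
    out_chars <- matrix("-", length(rows), length(use))
    src <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
    out_chars[, use] <- src
    rows_out <- apply(out_chars, 1L, paste, collapse = "")
    names(rows_out) <- names(rows)
    rows_out
  }
  c(expand(alnA, res$use_a), expand(alnB, res$use_b))
}

# 1 - shared 3-mer fraction between two sequences
kmer_distance <- function(a, b, k = 3L) {
  ka <- unique(substring(a, 1:(nchar(a) - k + 1L), k:nchar(a)))
  kb <- unique(substring(b, 1:(nchar(b) - k + 1L), k:nchar(b)))
  1 - length(intersect(ka, kb)) / min(length(ka), length(kb))
}

#' Progressive multiple sequence alignment
#'
#' Stand-in progressive aligner: a guide tree is built by average-linkage
#' clustering of pairwise shared-3-mer distances, and alignments are merged
#' up the tree by profile-profile global alignment (BLOSUM62, affine gaps).
#' Removing the gaps from any output row returns the corresponding input
#' sequence unchanged.
#'
#' @param records Record table (or named character vector of sequences)
#'   with at least 2 sequences.
#' @param thresholds Scoring parameters.
#' @return Named character vector of equal-length aligned rows.
#' @export
build_msa <- function(records, thresholds = sfam_thresholds()) {
  seqs <- if (is.data.frame(records)) {
    setNames(records$sequence, records$seq_id)
  } else records
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences to align", call. = FALSE)
  if (n == 2L) {
    return(merge_alignments(seqs[1], seqs[2], thresholds))
  }
  D <- matrix(0, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- kmer_distance(seqs[[i]], seqs[[j]])
    }
  }
  hc <- hclust(as.dist(D), method = "average")
  partial <- vector("list", n - 1L)
  leaf <- function(i) setNames(seqs[i], names(seqs)[i])
  for (s in seq_len(n - 1L)) {
    a <- hc$merge[s, 1L]
    b <- hc$merge[s, 2L]
    alnA <- if (a < 0) leaf(-a) else partial[[a]]
    alnB <- if (b < 0) leaf(-b) else partial[[b]]
    partial[[s]] <- merge_alignments(alnA, alnB, thresholds)
  }
  out <- partial[[n - 1L]]
  out[names(seqs)]
}

#' Excise gap-rich alignment columns
#'
#' Columns whose gap fraction is strictly greater than `gap_col_max`
#' (default 0.8) are removed; a column at exactly the threshold is kept.
#' Row order is preserved and the operation is idempotent.
#'
#' @param aln Named character vector of aligned rows.
#' @param gap_col_max Maximum tolerated gap fraction.
#' @return The trimmed alignment.
#' @export
trim_alignment <- function(aln, gap_col_max = 0.8) {
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  gap_frac <- colMeans(m == "-")
  keep <- gap_frac <= gap_col_max
  if (!any(keep)) {
    stop("trimming removed every alignment column", call. = FALSE)
  }
  out <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  setNames(out, names(aln))
}

#' Neighbor-joining tree from an alignment
#'
#' Distances are p-distances computed with pairwise deletion (positions
#' where either row has a gap are ignored for that pair); the tree is built
#' with neighbor joining.
#'
#' @param aln Named character vector of at least 3 aligned rows.
#' @return Newick string.
#' @export
build_nj_tree <- function(aln) {
  if (length(aln) < 3L) stop("need at least 3 rows for a tree",
                             call. = FALSE)
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      D[i, j] <- D[j, i] <- if (any(ok)) {
        mean(m[i, ok] != m[j, ok])
      } else 1
    }
  }
  phy <- ape::nj(as.dist(D))
  ape::write.tree(phy)
}

# ---- phylogenetic-diversity genome ranking ------------------------------

# logical matrix: edge x tip, TRUE if the tip lies below the edge's child.
# Requires a postorder-reordered phylo so children are visited first.
edge_tip_sets <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  below <- matrix(FALSE, nnode, ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (e in seq_len(nrow(phy$edge))) {
    parent <- phy$edge[e, 1L]
    child <- phy$edge[e, 2L]
    below[parent, ] <- below[parent, ] | below[child, ]
  }
  below[phy$edge[, 2L], , drop = FALSE]
}

# total branch length of the minimal subtree spanning the tip index set
pd_of_set <- function(phy, below, tips) {
  if (length(tips) < 2L) return(0)
  inside <- rowSums(below[, tips, drop = FALSE])
  sum(phy$edge.length[inside > 0 & inside < length(tips)])
}

#' Rank genomes by phylogenetic-diversity contribution
#'
#' Greedy maximisation of retained branch length on a genome phylogeny:
#' the first pick is the leaf spanning the longest path (one end of the
#' tree diameter), and each subsequent pick maximises the gain in total
#' phylogenetic diversity (PD) of the selected set. Greedy selection is
#' optimal for PD maximisation, so the first `k` picks span the maximum
#' attainable branch length.
#'
#' @param tree Newick string or `phylo` object with branch lengths.
#' @param k Number of genomes to select.
#' @return Character vector of the selected leaf labels, in pick order.
#' @export
select_representative_genomes <- function(tree, k) {
  phy <- if (inherits(tree, "phylo")) tree else ape::read.tree(text = tree)
  if (is.null(phy$edge.length) || anyNA(phy$edge.length)) {
    stop("tree has missing branch lengths", call. = FALSE)
  }
  ntip <- length(phy$tip.label)
  if (k > ntip) stop("k exceeds the number of leaves", call. = FALSE)
  phy <- stats::reorder(phy, "postorder")
  below <- edge_tip_sets(phy)
  D <- ape::cophenetic.phylo(phy)
  # first pick: an endpoint of a maximum-distance leaf pair, preferring the
  # endpoint with the larger total distance (ties broken by label)
  far <- apply(D, 1L, max)
  ends <- names(far)[far == max(far)]
  tot <- rowSums(D)[ends]
  first <- ends[order(-tot, ends)][1L]
  sel <- match(first, phy$tip.label)
  while (length(sel) < k) {
    cand <- setdiff(seq_len(ntip), sel)
    base <- pd_of_set(phy, below, sel)
    gain <- vapply(cand, function(x) {
      pd_of_set(phy, below, c(sel, x)) - base
    }, 0)
    best <- cand[order(-gain, phy$tip.label[cand])][1L]
    sel <- c(sel, best)
  }
  phy$tip.label[sel]
}
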