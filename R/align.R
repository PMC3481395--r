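#' Locally align two protein sequences
#'
#' Smith-Waterman with BLOSUM62 and affine gaps (open 11, extend 1; a gap of
#' length k costs `open + k * ext`). Only the single best-scoring local
#' alignment is reported. Percent identity follows the BLAST `pident`
#' convention: identical aligned positions divided by alignment columns,
#' gaps included.
#'
#' @param a,b Single records (one-row record tables, or lists with `seq_id`
#'   and `sequence`).
#' @param thresholds An [sfam_thresholds()] (gap penalties and
#'   Karlin-Altschul constants are taken from it).
#' @param n Search-space residue count for the e-value (defaults to
#'   `nchar(b)`); [build_similarity_graph()] passes the total residue count
#'   of the record set.
#' @return A one-row `data.frame` ("hit") with the raw and bit score,
#'   e-value, `percent_identity` (fraction), alignment coordinates
#'   (1-based, inclusive) and both coverages.
#' @export
align_pair <- function(a, b, thresholds = sfam_thresholds(), n = NULL) {
  a <- as_record(a); b <- as_record(b)
  if (grepl("-", a$sequence, fixed = TRUE) ||
      grepl("-", b$sequence, fixed = TRUE)) {
    stop("sequences must not contain gap characters", call. = FALSE)
  }
  la <- nchar(a$sequence); lb <- nchar(b$sequence)
  if (la < 1L || lb < 1L) stop("empty sequence", call. = FALSE)
  res <- sw_align_cpp(encode_seq(a$sequence), encode_seq(b$sequence),
                      scoring_matrix(), thresholds$gap_open,
                      thresholds$gap_ext)
  if (is.null(n)) n <- lb
  ev <- if (res$score > 0) {
    estimate_evalue(res$score, la, n, thresholds)
  } else Inf
  data.frame(
    query_id = a$seq_id, subject_id = b$seq_id,
    raw_score = res$score,
    score = (thresholds$lambda * res$score - log(thresholds$K)) / log(2),
    evalue = ev,
    percent_identity = if (res$aln_len > 0) res$n_ident / res$aln_len else 0,
    aln_len = res$aln_len,
    q_start = res$q_start, q_end = res$q_end,
    s_start = res$s_start, s_end = res$s_end,
    q_cov = if (res$aln_len > 0) (res$q_end - res$q_start + 1) / la else 0,
    s_cov = if (res$aln_len > 0) (res$s_end - res$s_start + 1) / lb else 0,
    stringsAsFactors = FALSE)
}

as_record <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(NROW(x) == 1L)
    list(seq_id = x$seq_id, sequence = x$sequence)
  } else {
    stopifnot(!is.null(x$seq_id), !is.null(x$sequence))
    x
  }
}

#' Karlin-Altschul e-value for a raw local-alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with the fixed gapped-BLOSUM62
#' constants lambda = 0.267, K = 0.041.
#'
#' @param score Raw alignment score.
#' @param m Query length.
#' @param n Search-space residue count.
#' @param thresholds Source of `lambda` and `K`.
#' @return The expected number of chance hits at or above `score`.
#' @export
estimate_evalue <- function(score, m, n, thresholds = sfam_thresholds()) {
  if (m < 1 || n < 1) stop("m and n must be >= 1", call. = FALSE)
  thresholds$K * m * n * exp(-thresholds$lambda * score)
}

#' Dual e-value / coverage homology gate
#'
#' A hit passes iff its e-value is at most `evalue_max` and the alignment
#' covers at least `coverage_min` of the lengths of *both* sequences
#' (both bounds inclusive).
#'
#' @param hit A hit row from [align_pair()].
#' @param evalue_max,coverage_min The gate.
#' @return Logical.
#' @export
passes_homology_filter <- function(hit, evalue_max, coverage_min) {
  hit$evalue <= evalue_max & hit$q_cov >= coverage_min &
    hit$s_cov >= coverage_min
}

# internal constructor for the similarity graph container
similarity_graph <- function(nodes, edges) {
  structure(list(nodes = as.character(nodes), edges = edges),
            class = "sfam_graph")
}

#' @export
print.sfam_graph <- function(x, ...) {
  cat(sprintf("<sfam_graph> %d nodes, %d edges\n", length(x$nodes),
              NROW(x$edges)))
  invisible(x)
}

#' Build the coverage-filtered percent-identity similarity graph
#'
#' Every candidate pair is aligned once (the alignment is symmetric; the
#' e-value is evaluated with the shorter sequence as query, which is the
#' lower of the two directional e-values). An edge is kept iff the hit
#' passes the e-value gate and covers at least `coverage` of both
#' sequences; its weight is the percent identity on a 0-100 scale.
#' Candidate pairs are found through a shared 5-mer prefilter (pairs similar
#' enough to pass the gate share exact 5-mers with overwhelming probability;
#' disable with `seed_filter = FALSE` to align every pair, which is also the
#' behaviour whenever any sequence is shorter than 50 residues).
#'
#' @param records Record table (at least 2 rows).
#' @param thresholds An [sfam_thresholds()].
#' @param evalue_max E-value gate (defaults to `thresholds$evalue_general`).
#' @param seed_filter Use the k-mer prefilter.
#' @return An `sfam_graph`: `nodes` (all seq_ids) and an edge table
#'   `from`/`to`/`weight`.
#' @export
build_similarity_graph <- function(records, thresholds = sfam_thresholds(),
                                   evalue_max = thresholds$evalue_general,
                                   seed_filter = TRUE) {
  if (NROW(records) < 2L) stop("need at least 2 records", call. = FALSE)
  n_total <- sum(records$length)
  pairs <- if (seed_filter && min(records$length) >= 50L) {
    candidate_pairs(records$sequence, k = 5L)
  } else {
    t(combn(NROW(records), 2L))
  }
  enc <- lapply(records$sequence, encode_seq)
  S <- scoring_matrix()
  from <- character(0); to <- character(0); w <- numeric(0)
  if (NROW(pairs)) {
    for (r in seq_len(NROW(pairs))) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      res <- sw_align_cpp(enc[[i]], enc[[j]], S, thresholds$gap_open,
                          thresholds$gap_ext)
      if (res$aln_len == 0L) next
      li <- records$length[i]; lj <- records$length[j]
      ev <- estimate_evalue(res$score, min(li, lj), n_total, thresholds)
      qc <- (res$q_end - res$q_start + 1) / li
      sc <- (res$s_end - res$s_start + 1) / lj
      if (ev <= evalue_max && qc >= thresholds$coverage &&
          sc >= thresholds$coverage) {
        from <- c(from, records$seq_id[i])
        to <- c(to, records$seq_id[j])
        w <- c(w, 100 * res$n_ident / res$aln_len)
      }
    }
  }
  similarity_graph(records$seq_id,
                   data.frame(from = from, to = to, weight = w,
                              stringsAsFactors = FALSE))
}

# index pairs (i < j) of sequences sharing at least one exact k-mer
candidate_pairs <- function(seqs, k = 5L) {
  km <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    unique(substring(s, 1:(L - k + 1L), k:L))
  })
  idx <- rep(seq_along(seqs), lengths(km))
  buckets <- split(idx, unlist(km))
  buckets <- buckets[lengths(buckets) > 1L]
  if (!length(buckets)) {
    return(matrix(integer(0), ncol = 2L))
  }
  pairs <- do.call(rbind, lapply(buckets, function(b) t(combn(sort(b), 2L))))
  unique(pairs)
}

#' Parse 12-column tabular alignment hits
#'
#' The classic tabular layout (qid, sid, pident, length, mismatch, gapopen,
#' qstart, qend, sstart, send, evalue, bitscore). Coverages are computed
#' from the coordinates and a sidecar of sequence lengths.
#'
#' @param path Tabular file.
#' @param seq_lengths Named numeric vector of sequence lengths.
#' @return A hit `data.frame` compatible with [passes_homology_filter()].
#' @export
parse_tabular_hits <- function(path, seq_lengths) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (NCOL(tab) != 12L) {
    stop("expected 12 tab-separated columns, got ", NCOL(tab), call. = FALSE)
  }
  names(tab) <- c("query_id", "subject_id", "pident", "aln_len", "mismatch",
                  "gapopen", "q_start", "q_end", "s_start", "s_end",
                  "evalue", "score")
  if (any(tab$q_start > tab$q_end) || any(tab$s_start > tab$s_end)) {
    stop("alignment start after end at row ",
         which(tab$q_start > tab$q_end | tab$s_start > tab$s_end)[1],
         call. = FALSE)
  }
  miss <- setdiff(unique(c(tab$query_id, tab$subject_id)),
                  names(seq_lengths))
  if (length(miss)) {
    stop("missing sequence length for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ql <- seq_lengths[tab$query_id]
  sl <- seq_lengths[tab$subject_id]
  data.frame(query_id = tab$query_id, subject_id = tab$subject_id,
             raw_score = NA_real_, score = tab$score, evalue = tab$evalue,
             percent_identity = tab$pident / 100, aln_len = tab$aln_len,
             q_start = tab$q_start, q_end = tab$q_end,
             s_start = tab$s_start, s_end = tab$s_end,
             q_cov = (tab$q_end - tab$q_start + 1) / ql,
             s_cov = (tab$s_end - tab$s_start + 1) / sl,
             stringsAsFactors = FALSE, row.names = NULL)
}
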