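#' Construct a table of protein records
#'
#' The package's working container for sequences: a `data.frame` with one
#' row per protein carrying its identifier, the genome it came from and the
#' amino-acid sequence. Sequences are validated against the 21-letter
#' alphabet (20 canonical residues plus `X`); the ambiguity codes `B`, `Z`
#' and `U` are mapped to `X` with a warning, and terminal `*` stop
#' characters are stripped.
#'
#' @param seq_id Character vector of unique sequence identifiers.
#' @param genome_id Character vector (recycled if length 1) of genome ids.
#' @param sequence Character vector of amino-acid sequences.
#' @return A `data.frame` with columns `seq_id`, `genome_id`, `sequence`
#'   and `length`.
#' @export
protein_records <- function(seq_id, genome_id, sequence) {
  stopifnot(length(seq_id) == length(sequence))
  if (length(genome_id) == 1L) genome_id <- rep(genome_id, length(seq_id))
  stopifnot(length(genome_id) == length(seq_id))
  seq_id <- as.character(seq_id)
  if (anyDuplicated(seq_id)) {
    stop("duplicate seq_id: ",
         paste(unique(seq_id[duplicated(seq_id)]), collapse = ", "),
         call. = FALSE)
  }
  sequence <- toupper(sequence)
  sequence <- sub("\\*+$", "", sequence)
  if (any(!nzchar(sequence))) {
    stop("empty sequence for seq_id: ",
         paste(seq_id[!nzchar(sequence)], collapse = ", "), call. = FALSE)
  }
  if (any(grepl("[BZU]", sequence))) {
    warning("ambiguity codes B/Z/U mapped to X", call. = FALSE)
    sequence <- gsub("[BZU]", "X", sequence)
  }
  bad <- regexpr(sprintf("[^%s]", paste(aa_alphabet(), collapse = "")),
                 sequence)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("invalid character '", substr(sequence[i], bad[i], bad[i]),
         "' at position ", bad[i], " in sequence ", seq_id[i], call. = FALSE)
  }
  data.frame(seq_id = unname(seq_id),
             genome_id = unname(as.character(genome_id)),
             sequence = unname(sequence), length = unname(nchar(sequence)),
             stringsAsFactors = FALSE)
}

#' Clustering and filtering thresholds
#'
#' Bundles every tunable cutoff of the pipeline, with the defaults used
#' throughout: a stringent e-value of `1e-10` for the initial clustering of
#' representative-genome proteins, `1e-5` everywhere else, 80% bidirectional
#' alignment coverage, MCL inflation 2, a universality cutoff of 50% for
#' calling a family widely distributed, at most 200 representative
#' subfamilies with an 80% similarity ceiling, excision of alignment columns
#' with more than 80% gaps, a 1.2x profile/sequence length ratio for calling
#' an unclustered sequence truncated, 80% reciprocal recruitment for clan
#' merging, precision below 0.75 as "low precision", and alpha 0.05.
#'
#' @param evalue_init E-value cutoff for the initial all-vs-all stage.
#' @param evalue_general E-value cutoff for every later stage.
#' @param coverage Minimum fraction of both lengths an alignment must cover.
#' @param inflation MCL inflation.
#' @param universality_min Minimum universality score for the
#'   widely-distributed call.
#' @param rep_cap Maximum number of representative subfamilies.
#' @param rep_sim_ceiling Starting similarity ceiling (fraction) for
#'   representative sub-clustering.
#' @param rep_trigger Families with more than this many members are aligned
#'   from representatives.
#' @param gap_col_max Alignment columns with a gap fraction strictly above
#'   this are excised.
#' @param fragment_len_ratio A profile at least this much longer than an
#'   unclustered sequence supports the "truncated" call.
#' @param clan_recruit_frac Reciprocal recruitment fraction for clans.
#' @param low_precision_cutoff Families strictly below this precision are
#'   flagged low-precision.
#' @param alpha Significance level for enrichment scans.
#' @param gap_open,gap_ext Affine gap penalties of the local aligner.
#' @param lambda,K Gapped BLOSUM62 Karlin-Altschul constants for the
#'   aligner's e-value.
#' @param n_shuffles Shuffled sequences used to calibrate each profile.
#' @param mcl_max_iter,mcl_prune,mcl_tol MCL iteration controls.
#' @return A classed list of thresholds.
#' @export
sfam_thresholds <- function(evalue_init = 1e-10, evalue_general = 1e-5,
                            coverage = 0.8, inflation = 2.0,
                            universality_min = 0.5, rep_cap = 200L,
                            rep_sim_ceiling = 0.8, rep_trigger = 250L,
                            gap_col_max = 0.8, fragment_len_ratio = 1.2,
                            clan_recruit_frac = 0.8,
                            low_precision_cutoff = 0.75, alpha = 0.05,
                            gap_open = 11, gap_ext = 1,
                            lambda = 0.267, K = 0.041,
                            n_shuffles = 100L,
                            mcl_max_iter = 200L, mcl_prune = 1e-10,
                            mcl_tol = 1e-8) {
  th <- list(evalue_init = evalue_init, evalue_general = evalue_general,
             coverage = coverage, inflation = inflation,
             universality_min = universality_min, rep_cap = as.integer(rep_cap),
             rep_sim_ceiling = rep_sim_ceiling,
             rep_trigger = as.integer(rep_trigger),
             gap_col_max = gap_col_max,
             fragment_len_ratio = fragment_len_ratio,
             clan_recruit_frac = clan_recruit_frac,
             low_precision_cutoff = low_precision_cutoff, alpha = alpha,
             gap_open = gap_open, gap_ext = gap_ext, lambda = lambda, K = K,
             n_shuffles = as.integer(n_shuffles),
             mcl_max_iter = as.integer(mcl_max_iter), mcl_prune = mcl_prune,
             mcl_tol = mcl_tol)
  fr <- c("coverage", "universality_min", "rep_sim_ceiling", "gap_col_max",
          "clan_recruit_frac")
  for (f in fr) {
    if (th[[f]] <= 0 || th[[f]] > 1) {
      stop(f, " must be in (0, 1]", call. = FALSE)
    }
  }
  if (th$evalue_init > th$evalue_general) {
    stop("evalue_init must be <= evalue_general", call. = FALSE)
  }
  if (th$inflation <= 1) stop("inflation must be > 1", call. = FALSE)
  structure(th, class = "sfam_thresholds")
}

#' Create a protein family
#'
#' @param family_id Integer identifier.
#' @param members Character vector of member seq_ids (at least 2).
#' @param construction_id Batch label: 1 = widely distributed seed families,
#'   2 = initial de novo families, 3+ = update rounds.
#' @return An `sfam_family` object.
#' @export
sfam_family <- function(family_id, members, construction_id) {
  if (length(members) < 2L) {
    stop("a family needs at least 2 members", call. = FALSE)
  }
  structure(list(family_id = as.integer(family_id),
                 construction_id = as.integer(construction_id),
                 members = as.character(members),
                 representatives = NULL, alignment = NULL, profile = NULL,
                 tree = NULL, consensus = NULL,
                 universality = NA_real_, precision = NA_real_,
                 recall = NA_real_, terms = character(0),
                 partially_annotated = FALSE),
            class = "sfam_family")
}

#' @export
print.sfam_family <- function(x, ...) {
  cat(sprintf("<sfam_family %d> construction %d, %d members%s\n",
              x$family_id, x$construction_id, length(x$members),
              if (!is.na(x$universality)) {
                sprintf(", universality %.2f", x$universality)
              } else ""))
  invisible(x)
}

#' @export
print.sfam_thresholds <- function(x, ...) {
  cat("<sfam_thresholds>\n")
  for (n in names(x)) cat(sprintf("  %-22s %s\n", n, format(x[[n]])))
  invisible(x)
}

# genome -> seq_ids mapping from a record table
genome_set <- function(records) {
  split(records$seq_id, records$genome_id)
}
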