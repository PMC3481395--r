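#' Build a profile model from a trimmed alignment
#'
#' Match states are the alignment columns with a gap fraction of at most
#' 0.5. Match emissions are `(counts + background) / (n_obs + 1)` (one
#' background-distributed pseudocount); state transitions get +1 smoothing.
#' Insert states emit at the background distribution. The model's consensus
#' is the highest-emission residue per match column, ties resolved to the
#' alphabetically first residue.
#'
#' @param aln Named character vector of aligned rows (at least 2).
#' @param family_id Integer id carried along for bookkeeping.
#' @return An `sfam_profile`: match emission matrix (`L` x 21),
#'   emission log2-odds, transition probabilities, consensus string,
#'   background frequencies, member lengths (for calibration), and an
#'   initially empty calibration slot.
#' @export
build_profile <- function(aln, family_id = NA_integer_) {
  if (length(aln) < 2L) stop("need at least 2 alignment rows",
                             call. = FALSE)
  ab <- aa_alphabet()
  nres <- 20L  # emissions over the canonical residues; X scores 0 bits
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  gap_frac <- colMeans(m == "-")
  match_cols <- which(gap_frac <= 0.5)
  L <- length(match_cols)
  if (L == 0L) stop("alignment has no match columns", call. = FALSE)
  bg <- aa_background()

  emis <- matrix(0, L, 21L, dimnames = list(NULL, ab))
  for (k in seq_len(L)) {
    col <- m[, match_cols[k]]
    cnt <- table(factor(col[col %in% ab[1:nres]], levels = ab[1:nres]))
    n_obs <- sum(cnt)
    p <- (as.numeric(cnt) + bg[1:nres] / sum(bg[1:nres])) / (n_obs + 1)
    emis[k, 1:nres] <- p / sum(p)
  }
  emis[, 21L] <- 0  # X never emitted by the model itself

  # Per-row path: state at each match slot (M residue / D gap) and the
  # number of insert-column residues between consecutive slots, attributed
  # to insert state I_s. Transitions restricted to the Plan7-like set
  # (M->M/I/D, I->M/I, D->M/D); inserts adjacent to a deletion are not
  # representable in that set and are skipped for counting purposes.
  nI <- max(L - 1L, 0L)
  cMM <- numeric(nI); cMI <- numeric(nI); cMD <- numeric(nI)
  cIM <- numeric(nI); cII <- numeric(nI)
  cDM <- numeric(nI); cDD <- numeric(nI)
  col_slot <- findInterval(seq_len(ncol(m)), match_cols)  # slot to the left
  is_match <- seq_len(ncol(m)) %in% match_cols
  for (r in seq_len(nrow(m))) {
    row <- m[r, ]
    state <- ifelse(row[match_cols] == "-", "D", "M")
    ins <- integer(nI)
    insert_res <- !is_match & row != "-"
    if (any(insert_res)) {
      s <- col_slot[insert_res]
      keep <- s >= 1L & s <= nI
      if (any(keep)) {
        tb <- table(s[keep])
        ins[as.integer(names(tb))] <- as.integer(tb)
      }
    }
    for (s in seq_len(nI)) {
      a <- state[s]; b <- state[s + 1L]
      if (ins[s] > 0L && a == "M") {
        cMI[s] <- cMI[s] + 1
        cII[s] <- cII[s] + ins[s] - 1L
        if (b == "M") cIM[s] <- cIM[s] + 1
      } else {
        if (a == "M" && b == "M") cMM[s] <- cMM[s] + 1
        else if (a == "M" && b == "D") cMD[s] <- cMD[s] + 1
        else if (a == "D" && b == "M") cDM[s] <- cDM[s] + 1
        else if (a == "D" && b == "D") cDD[s] <- cDD[s] + 1
      }
    }
  }
  tm <- cbind((cMM + 1) / (cMM + cMI + cMD + 3),
              (cMI + 1) / (cMM + cMI + cMD + 3),
              (cMD + 1) / (cMM + cMI + cMD + 3))   # M -> M,I,D
  ti <- cbind((cIM + 1) / (cIM + cII + 2),
              (cII + 1) / (cIM + cII + 2))          # I -> M,I
  td <- cbind((cDM + 1) / (cDM + cDD + 2),
              (cDD + 1) / (cDM + cDD + 2))          # D -> M,D

  lods <- emis
  lods[, 1:nres] <- log2(sweep(emis[, 1:nres, drop = FALSE], 2L,
                               bg[1:nres] / sum(bg[1:nres]), "/"))
  lods[, 21L] <- 0

  cons <- vapply(seq_len(L), function(k) {
    p <- emis[k, 1:nres]
    cand <- names(p)[p == max(p)]
    sort(cand)[1L]
  }, "")

  member_lengths <- nchar(gsub("-", "", aln, fixed = TRUE))

  structure(list(family_id = as.integer(family_id), L = L,
                 match = emis, mlods = lods,
                 tMM = if (L > 1) log2(tm[, 1]) else numeric(0),
                 tMI = if (L > 1) log2(tm[, 2]) else numeric(0),
                 tMD = if (L > 1) log2(tm[, 3]) else numeric(0),
                 tIM = if (L > 1) log2(ti[, 1]) else numeric(0),
                 tII = if (L > 1) log2(ti[, 2]) else numeric(0),
                 tDM = if (L > 1) log2(td[, 1]) else numeric(0),
                 tDD = if (L > 1) log2(td[, 2]) else numeric(0),
                 consensus = paste(cons, collapse = ""),
                 background = aa_background(),
                 member_lengths = unname(member_lengths),
                 calibration = NULL),
            class = "sfam_profile")
}

#' @export
print.sfam_profile <- function(x, ...) {
  cat(sprintf("<sfam_profile> family %s, L = %d, %s\n",
              ifelse(is.na(x$family_id), "?", x$family_id), x$L,
              if (is.null(x$calibration)) "uncalibrated"
              else sprintf("calibrated (lambda %.3f, mu %.2f)",
                           x$calibration[["lambda"]],
                           x$calibration[["mu"]])))
  invisible(x)
}

#' Score a sequence against a profile model
#'
#' Best local Viterbi alignment through the profile with uniform local
#' entry over match states and free exit; flanking sequence residues are
#' emitted by the null model at zero cost, so the bit score is a log2-odds
#' against the background. Coverages come from the alignment envelope:
#' `seq_cov` = spanned sequence residues / sequence length, `profile_cov` =
#' spanned match states / `L`. E-values require a calibrated profile and are
#' `n_comparisons * exp(-lambda * (score - mu))` under the fitted Gumbel.
#'
#' @param profile An `sfam_profile`.
#' @param record One record (list or one-row table with `seq_id`,
#'   `sequence`).
#' @param n_comparisons Search-space size multiplying the per-comparison
#'   tail probability.
#' @return One-row `data.frame`: `seq_id`, `family_id`, `score` (bits),
#'   `evalue`, `seq_cov`, `profile_cov` and the envelope coordinates.
#' @export
score_sequence <- function(profile, record, n_comparisons = 1) {
  rec <- as_record(record)
  if (!nzchar(rec$sequence)) stop("empty sequence", call. = FALSE)
  res <- viterbi_profile_cpp(profile$mlods, profile$tMM, profile$tMI,
                             profile$tMD, profile$tIM, profile$tII,
                             profile$tDM, profile$tDD,
                             encode_seq(rec$sequence),
                             entry_bits = -log2(profile$L))
  len <- nchar(rec$sequence)
  ev <- if (!is.null(profile$calibration) && is.finite(res$bits)) {
    cal <- profile$calibration
    n_comparisons * exp(-cal[["lambda"]] * (res$bits - cal[["mu"]]))
  } else NA_real_
  data.frame(seq_id = rec$seq_id, family_id = profile$family_id,
             score = res$bits, evalue = ev,
             seq_cov = if (is.finite(res$bits)) {
               (res$seq_end - res$seq_start + 1) / len
             } else 0,
             profile_cov = if (is.finite(res$bits)) {
               (res$model_end - res$model_start + 1) / profile$L
             } else 0,
             model_start = res$model_start, model_end = res$model_end,
             seq_start = res$seq_start, seq_end = res$seq_end,
             stringsAsFactors = FALSE)
}

#' Fit a Gumbel distribution by the method of moments
#'
#' `lambda = pi / (sd * sqrt(6))`, `mu = mean - gamma / lambda` with
#' Euler's constant gamma.
#'
#' @param scores Numeric vector with positive variance.
#' @return Named vector `c(lambda, mu)`.
#' @export
fit_gumbel <- function(scores) {
  s <- sd(scores)
  if (!is.finite(s) || s == 0) {
    stop("degenerate score distribution (zero variance)", call. = FALSE)
  }
  lambda <- pi / (s * sqrt(6))
  mu <- mean(scores) - 0.5772156649015329 / lambda
  c(lambda = lambda, mu = mu)
}

#' Calibrate a profile's e-value statistics
#'
#' Scores `n_shuffles` seeded random sequences (background residue
#' composition, lengths resampled from the family's member-length
#' distribution) and fits a Gumbel to the resulting bit scores by the
#' method of moments.
#'
#' @param profile An `sfam_profile`.
#' @param n_shuffles Number of random sequences (at least 50).
#' @param seed Integer seed.
#' @return The profile with its `calibration` slot set.
#' @export
calibrate_profile <- function(profile, n_shuffles = 100L, seed = 1L) {
  if (n_shuffles < 50L) stop("n_shuffles must be >= 50", call. = FALSE)
  bg <- profile$background[1:20]
  bg <- bg / sum(bg)
  scores <- with_seed(seed, {
    lens <- sample(profile$member_lengths, n_shuffles, replace = TRUE)
    vapply(lens, function(L) {
      s <- paste(sample(aa_alphabet()[1:20], L, replace = TRUE, prob = bg),
                 collapse = "")
      score_sequence(profile, list(seq_id = "shuffle", sequence = s))$score
    }, 0)
  })
  profile$calibration <- fit_gumbel(scores)
  profile
}

#' Recruit sequences with a calibrated profile
#'
#' Returns the hits passing the e-value gate and the named coverage rule:
#' `"both"` (sequence and profile coverage at least `coverage_min`; used
#' for sifting and evaluation), `"either"` (at least one of the two; used
#' to find fragment candidates), or `"seq_only"`.
#'
#' @param profile Calibrated `sfam_profile`.
#' @param records Record table.
#' @param evalue_max E-value gate.
#' @param coverage_rule One of `"both"`, `"either"`, `"seq_only"`.
#' @param coverage_min Coverage threshold (default 0.8).
#' @param n_comparisons Search-space size for the e-values.
#' @return Hit `data.frame` (possibly zero rows).
#' @export
recruit <- function(profile, records, evalue_max = 1e-5,
                    coverage_rule = c("both", "either", "seq_only"),
                    coverage_min = 0.8, n_comparisons = 1) {
  coverage_rule <- match.arg(coverage_rule)
  if (is.null(profile$calibration)) {
    stop("profile is not calibrated", call. = FALSE)
  }
  if (NROW(records) == 0L) {
    return(score_sequence(profile, list(seq_id = "x", sequence = "A"))[0, ])
  }
  hits <- do.call(rbind, lapply(seq_len(NROW(records)), function(i) {
    score_sequence(profile, records[i, , drop = FALSE], n_comparisons)
  }))
  pass <- hits$evalue <= evalue_max & switch(
    coverage_rule,
    both = hits$seq_cov >= coverage_min & hits$profile_cov >= coverage_min,
    either = hits$seq_cov >= coverage_min |
      hits$profile_cov >= coverage_min,
    seq_only = hits$seq_cov >= coverage_min)
  hits[which(pass), , drop = FALSE]
}

#' Consensus sequence of a profile
#'
#' Position `i` of the consensus is the residue with the maximum match
#' emission probability; ties go to the alphabetically first residue.
#'
#' @param profile An `sfam_profile`.
#' @return A one-row record table; the consensus id is
#'   `consensus_<family_id>`.
#' @export
emit_consensus <- function(profile) {
  protein_records(paste0("consensus_", profile$family_id), "consensus",
                  profile$consensus)
}

# ---- profile serialization ----------------------------------------------

write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cal <- profile$calibration
  writeLines(c(
    paste0("SFAMPROFILE 1"),
    paste0("FAMILY ", profile$family_id),
    paste0("L ", profile$L),
    paste0("CONSENSUS ", profile$consensus),
    paste0("CALIBRATION ", if (is.null(cal)) "NA NA" else
      paste(format(cal[["lambda"]], digits = 17),
            format(cal[["mu"]], digits = 17))),
    paste0("MEMBER_LENGTHS ", paste(profile$member_lengths,
                                    collapse = " "))), con)
  writeLines(paste0("MATCH ", apply(profile$match, 1L, function(r) {
    paste(format(r, digits = 17), collapse = " ")
  })), con)
  for (tn in c("tMM", "tMI", "tMD", "tIM", "tII", "tDM", "tDD")) {
    writeLines(paste0(tn, " ", paste(format(profile[[tn]], digits = 17),
                                     collapse = " ")), con)
  }
  invisible(path)
}

read_profile <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "SFAMPROFILE 1")) {
    stop("not a profile file: ", path, call. = FALSE)
  }
  field <- function(key) {
    ln <- lines[startsWith(lines, paste0(key, " "))]
    sub(paste0("^", key, " "), "", ln)
  }
  L <- as.integer(field("L"))
  match_rows <- field("MATCH")
  emis <- do.call(rbind, lapply(strsplit(match_rows, " +"), as.numeric))
  colnames(emis) <- aa_alphabet()
  bg <- aa_background()
  lods <- emis
  lods[, 1:20] <- log2(sweep(pmax(emis[, 1:20, drop = FALSE], 1e-300), 2L,
                             bg[1:20] / sum(bg[1:20]), "/"))
  lods[, 21L] <- 0
  getv <- function(key) {
    v <- field(key)
    if (!nzchar(v)) numeric(0) else as.numeric(strsplit(v, " +")[[1]])
  }
  cal <- suppressWarnings(as.numeric(strsplit(field("CALIBRATION"),
                                              " +")[[1]]))
  structure(list(
    family_id = as.integer(field("FAMILY")), L = L, match = emis,
    mlods = lods,
    tMM = getv("tMM"), tMI = getv("tMI"), tMD = getv("tMD"),
    tIM = getv("tIM"), tII = getv("tII"), tDM = getv("tDM"),
    tDD = getv("tDD"),
    consensus = field("CONSENSUS"), background = bg,
    member_lengths = as.integer(getv("MEMBER_LENGTHS")),
    calibration = if (anyNA(cal)) NULL else c(lambda = cal[1], mu = cal[2])),
    class = "sfam_profile")
}
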