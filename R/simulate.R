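#' Configuration for the synthetic-corpus generator
#'
#' Defaults describe the standard benchmark used throughout the test
#' suite: 20 planted families of 10 members each, mutated to a 70% identity
#' target around independent random ancestors of 180-240 residues, spread
#' over 4 genomes (half the families occupy every genome, the rest a
#' single genome), with 10% planted fragments, 20 ORFans and one
#' annotation term per family applied to 90% of its members.
#'
#' @param n_families Number of planted families.
#' @param members_per_family Members per family (scalar or range).
#' @param seed_length Ancestor length range.
#' @param within_identity Target member-to-ancestor identity.
#' @param indel_rate Per-site indel probability during mutation.
#' @param n_genomes Number of genomes.
#' @param universal_frac Fraction of families occupying all genomes; the
#'   others are restricted to one genome.
#' @param fragment_rate Planted fragments as a fraction of total family
#'   members (each fragment is a 30-60% prefix or suffix of a member, at
#'   most one per family).
#' @param fusion_rate Planted fusions (concatenations of members of two
#'   families) as a fraction of total members.
#' @param n_orfans Unrelated random sequences.
#' @param annotation_noise Probability that a member misses its family's
#'   term.
#' @param n_superfamily_pairs Pairs of families sharing a common 80-residue
#'   domain (flanked by short family-specific ends) to plant superfamilies.
#' @param superfamily_identity Member identity target within superfamily
#'   families.
#' @param seed RNG seed.
#' @return A classed config list.
#' @export
sim_config <- function(n_families = 20L, members_per_family = 10L,
                       seed_length = c(180L, 240L), within_identity = 0.7,
                       indel_rate = 0.01, n_genomes = 4L,
                       universal_frac = 0.5, fragment_rate = 0.1,
                       fusion_rate = 0, n_orfans = 20L,
                       annotation_noise = 0.1,
                       n_superfamily_pairs = 0L,
                       superfamily_identity = 0.85, seed = 1L) {
  stopifnot(n_families >= 1L, within_identity > 0, within_identity <= 1,
            fragment_rate >= 0, fragment_rate <= 1,
            fusion_rate >= 0, fusion_rate <= 1,
            annotation_noise >= 0, annotation_noise <= 1)
  if (within_identity < 0.3) {
    warning("identity target below 0.3: planted families may not be ",
            "recoverable", call. = FALSE)
  }
  structure(list(n_families = as.integer(n_families),
                 members_per_family = as.integer(members_per_family),
                 seed_length = as.integer(seed_length),
                 within_identity = within_identity,
                 indel_rate = indel_rate, n_genomes = as.integer(n_genomes),
                 universal_frac = universal_frac,
                 fragment_rate = fragment_rate, fusion_rate = fusion_rate,
                 n_orfans = as.integer(n_orfans),
                 annotation_noise = annotation_noise,
                 n_superfamily_pairs = as.integer(n_superfamily_pairs),
                 superfamily_identity = superfamily_identity,
                 seed = as.integer(seed)),
            class = "sfam_sim_config")
}

# BLOSUM62-conditional substitution probabilities P(y | x), reconstructed
# from the half-bit matrix and the background frequencies; the original
# residue is excluded so a substitution always changes the letter.
substitution_probs <- function() {
  if (is.null(.sfams_env$subprobs)) {
    bg <- aa_background()[1:20]
    bg <- bg / sum(bg)
    S <- scoring_matrix()[1:20, 1:20]
    joint <- outer(bg, bg) * 2^(S / 2)
    cond <- sweep(joint, 1L, rowSums(joint), "/")
    diag(cond) <- 0
    .sfams_env$subprobs <- sweep(cond, 1L, rowSums(cond), "/")
  }
  .sfams_env$subprobs
}

random_sequence <- function(len) {
  bg <- aa_background()[1:20]
  paste(sample(aa_alphabet()[1:20], len, replace = TRUE,
               prob = bg / sum(bg)), collapse = "")
}

#' Mutate a protein sequence towards an identity target
#'
#' Substitutes `round((1 - target_identity) * length)` distinct positions,
#' drawing each replacement from the BLOSUM62-conditional distribution of
#' the original residue (never the residue itself), then applies indels at
#' `indel_rate` per site with geometric lengths (mean 2); insertions draw
#' from the background composition. Deterministic for a given seed.
#'
#' @param seq Amino-acid string.
#' @param target_identity Fraction in (0, 1].
#' @param indel_rate Per-site indel probability.
#' @param seed Integer seed.
#' @return The mutated sequence.
#' @export
mutate_sequence <- function(seq, target_identity, indel_rate = 0,
                            seed = 1L) {
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  stopifnot(target_identity > 0, target_identity <= 1)
  with_seed(seed, mutate_sequence_impl(seq, target_identity, indel_rate))
}

# body shared with simulate_families, which manages the RNG itself
mutate_sequence_impl <- function(seq, target_identity, indel_rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  n_sub <- round((1 - target_identity) * L)
  if (n_sub > 0) {
    pos <- sample.int(L, n_sub)
    cond <- substitution_probs()
    ab <- aa_alphabet()[1:20]
    for (p in pos) {
      x <- chars[p]
      if (x %in% ab) {
        chars[p] <- sample(ab, 1L, prob = cond[x, ])
      }
    }
  }
  if (indel_rate > 0) {
    out <- character(0)
    bg <- aa_background()[1:20]
    bg <- bg / sum(bg)
    ab <- aa_alphabet()[1:20]
    L_now <- length(chars)
    p <- 1L
    while (p <= L_now) {
      if (runif(1) < indel_rate) {
        len <- stats::rgeom(1, 0.5) + 1L
        if (runif(1) < 0.5) {  # insertion before this position
          out <- c(out, sample(ab, len, replace = TRUE, prob = bg),
                   chars[p])
          p <- p + 1L
        } else {               # deletion of len residues from here
          p <- p + len
        }
      } else {
        out <- c(out, chars[p])
        p <- p + 1L
      }
    }
    if (length(out) == 0L) out <- chars[1]
    chars <- out
  }
  paste(chars, collapse = "")
}

#' Simulate a protein corpus with planted family structure
#'
#' Generates independent random ancestors (background composition), family
#' members mutated to the identity target, optional superfamily pairs
#' sharing a common 80-mer domain, planted fragments (30-60% prefixes or
#' suffixes of members, at most one per family), fusions, ORFans, genome
#' assignments per the universality profile, and one annotation term per
#' family.
#'
#' @param config An [sim_config()].
#' @return List with `records` (record table), `truth` (`data.frame`
#'   `seq_id`/`label`), `annotations` (named list seq_id -> terms),
#'   `family_genomes` (list), `family_terms` (named list) and the config.
#' @export
simulate_families <- function(config = sim_config()) {
  stopifnot(inherits(config, "sfam_sim_config"))
  with_seed(config$seed, simulate_families_impl(config))
}

simulate_families_impl <- function(cfg) {
  nfam <- cfg$n_families
  genomes <- sprintf("G%d", seq_len(cfg$n_genomes))
  n_universal <- round(cfg$universal_frac * nfam)
  fam_ids <- sprintf("FAM%02d", seq_len(nfam))

  # ancestors; superfamily pairs share a mutated copy of a common domain
  lens <- sample(seq(cfg$seed_length[1], cfg$seed_length[2]), nfam,
                 replace = TRUE)
  ancestors <- vapply(lens, random_sequence, "")
  sf_members_identity <- rep(cfg$within_identity, nfam)
  if (cfg$n_superfamily_pairs > 0) {
    for (p in seq_len(cfg$n_superfamily_pairs)) {
      i <- 2L * p - 1L; j <- 2L * p
      if (j > nfam) break
      domain <- random_sequence(80L)
      ancestors[i] <- paste0(random_sequence(5L),
                             mutate_sequence_impl(domain, 0.95, 0),
                             random_sequence(5L))
      ancestors[j] <- paste0(random_sequence(5L),
                             mutate_sequence_impl(domain, 0.95, 0),
                             random_sequence(5L))
      sf_members_identity[c(i, j)] <- cfg$superfamily_identity
    }
  }

  fam_genomes <- lapply(seq_len(nfam), function(i) {
    if (i <= n_universal) genomes else sample(genomes, 1L)
  })
  names(fam_genomes) <- fam_ids

  seq_id <- character(0); genome_id <- character(0); sequence <- character(0)
  label <- character(0)
  members_of <- vector("list", nfam)
  for (i in seq_len(nfam)) {
    ids <- sprintf("%s_M%02d", fam_ids[i], seq_len(cfg$members_per_family))
    occ <- fam_genomes[[i]]
    seqs <- vapply(seq_along(ids), function(m) {
      mutate_sequence_impl(ancestors[i], sf_members_identity[i],
                           cfg$indel_rate)
    }, "")
    seq_id <- c(seq_id, ids)
    genome_id <- c(genome_id, rep(occ, length.out = length(ids)))
    sequence <- c(sequence, seqs)
    label <- c(label, rep(fam_ids[i], length(ids)))
    members_of[[i]] <- ids
  }

  # fragments: 30-60% prefix/suffix of a member, parents in distinct
  # families so two fragments of one family cannot pair up
  n_frag <- round(cfg$fragment_rate * nfam * cfg$members_per_family)
  frag_fams <- sample(nfam, min(n_frag, nfam))
  for (k in seq_along(frag_fams)) {
    i <- frag_fams[k]
    parent <- sample(members_of[[i]], 1L)
    pseq <- sequence[seq_id == parent]
    keep <- round(runif(1, 0.3, 0.6) * nchar(pseq))
    fseq <- if (runif(1) < 0.5) {
      substr(pseq, 1L, keep)
    } else {
      substr(pseq, nchar(pseq) - keep + 1L, nchar(pseq))
    }
    fid <- sprintf("FRAG%02d", k)
    seq_id <- c(seq_id, fid)
    genome_id <- c(genome_id, sample(genomes, 1L))
    sequence <- c(sequence, fseq)
    label <- c(label, paste0("FRAGMENT-of:", fam_ids[i]))
  }

  n_fus <- round(cfg$fusion_rate * nfam * cfg$members_per_family)
  if (n_fus > 0 && nfam >= 2L) {
    for (k in seq_len(n_fus)) {
      ij <- sample(nfam, 2L)
      pa <- sample(members_of[[ij[1]]], 1L)
      pb <- sample(members_of[[ij[2]]], 1L)
      seq_id <- c(seq_id, sprintf("FUS%02d", k))
      genome_id <- c(genome_id, sample(genomes, 1L))
      sequence <- c(sequence, paste0(sequence[seq_id == pa],
                                     sequence[seq_id == pb]))
      label <- c(label, sprintf("FUSION-of:%s+%s", fam_ids[ij[1]],
                                fam_ids[ij[2]]))
    }
  }

  if (cfg$n_orfans > 0) {
    for (k in seq_len(cfg$n_orfans)) {
      seq_id <- c(seq_id, sprintf("ORF%02d", k))
      genome_id <- c(genome_id, sample(genomes, 1L))
      sequence <- c(sequence,
                    random_sequence(sample(seq(cfg$seed_length[1],
                                               cfg$seed_length[2]), 1L)))
      label <- c(label, "ORFAN")
    }
  }

  records <- protein_records(seq_id, genome_id, sequence)
  fam_terms <- setNames(sprintf("TERM%02d", seq_len(nfam)), fam_ids)
  annotations <- list()
  for (i in seq_len(nfam)) {
    for (m in members_of[[i]]) {
      if (runif(1) >= cfg$annotation_noise) {
        annotations[[m]] <- fam_terms[[i]]
      }
    }
  }

  list(records = records,
       truth = data.frame(seq_id = seq_id, label = label,
                          stringsAsFactors = FALSE),
       annotations = annotations,
       family_genomes = fam_genomes,
       family_terms = as.list(fam_terms),
       config = cfg)
}

#' Write a simulated corpus to disk
#'
#' Emits `sequences.fasta`, `annotations.tsv`, `genomes.tsv` and
#' `truth.json` into a directory.
#'
#' @param sim Result of [simulate_families()].
#' @param dir Output directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$records, file.path(dir, "sequences.fasta"))
  ann <- sim$annotations
  rows <- data.frame(
    seq_id = rep(names(ann), lengths(ann)),
    term_id = unlist(ann, use.names = FALSE),
    stringsAsFactors = FALSE)
  write.table(rows, file.path(dir, "annotations.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  write.table(sim$records[, c("seq_id", "genome_id")],
              file.path(dir, "genomes.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(truth = sim$truth,
                            family_genomes = sim$family_genomes,
                            family_terms = sim$family_terms,
                            config = unclass(sim$config)),
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
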