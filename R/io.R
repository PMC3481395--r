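#' Read protein sequences from FASTA
#'
#' Headers follow the dialect `>seq_id genome=GENOME_ID` (whitespace-separated
#' `key=value` pairs after the id). Terminal `*` stop characters are
#' stripped, lowercase is uppercased, and `B`/`Z`/`U` are mapped to `X` with
#' a warning. Duplicate ids, empty sequences and characters outside the
#' alphabet are errors.
#'
#' @param path FASTA file.
#' @return A record table (see [protein_records()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path, call. = FALSE)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  genomes <- rep(NA_character_, length(ids))
  has_g <- grepl("genome=", headers)
  genomes[has_g] <- sub(".*genome=(\\S+).*", "\\1", headers[has_g])
  if (anyNA(genomes)) {
    genomes[is.na(genomes)] <- "unknown"
  }
  protein_records(ids, genomes, as.character(ss))
}

#' Write protein records to FASTA
#'
#' Inverse of [read_fasta()]: emits `>seq_id genome=GENOME_ID` headers and
#' wraps sequence lines at 60 characters, so that reading the file back
#' reproduces the input records.
#'
#' @param records Record table.
#' @param path Output file.
#' @export
write_fasta <- function(records, path) {
  if (NROW(records) == 0L) stop("no records to write", call. = FALSE)
  ss <- Biostrings::BStringSet(records$sequence)
  names(ss) <- paste0(records$seq_id, " genome=", records$genome_id)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

# aligned FASTA ('-' gaps); returns named character vector of rows
read_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  aln <- as.character(ss)
  names(aln) <- sub("\\s.*$", "", names(ss))
  if (length(unique(nchar(aln))) != 1L) {
    stop("alignment rows have unequal lengths in ", path, call. = FALSE)
  }
  aln
}

write_alignment <- function(aln, path) {
  ss <- Biostrings::BStringSet(aln)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read a per-sequence annotation table
#'
#' Two-column TSV (`seq_id`, `term_id`), one row per sequence/term pair;
#' multiple terms per sequence are aggregated into a set.
#'
#' @param path TSV file.
#' @return Named list mapping `seq_id` to a character vector of term ids.
#'   Sequences absent from the file are simply absent (treat as empty set).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(structure(list(), names = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L)) {
    stop("malformed annotation row at line ", which(nf != 2L)[1],
         " (expected 2 tab-separated columns, got ", nf[nf != 2L][1], ")",
         call. = FALSE)
  }
  ids <- vapply(parts, `[`, "", 1L)
  terms <- vapply(parts, `[`, "", 2L)
  lapply(split(terms, ids), unique)
}

#' Write / read a similarity graph in ABC format
#'
#' Three tab-separated columns: node, node, weight. Isolated nodes are kept
#' in a `#nodes:` comment header so the graph round-trips exactly.
#'
#' @param graph An `sfam_graph` (see [build_similarity_graph()]).
#' @param path File path.
#' @return `read_abc` returns an `sfam_graph`.
#' @export
write_abc <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#nodes:\t", paste(graph$nodes, collapse = "\t")), con)
  if (NROW(graph$edges) > 0L) {
    writeLines(sprintf("%s\t%s\t%.6g", graph$edges$from, graph$edges$to,
                       graph$edges$weight), con)
  }
  invisible(path)
}

#' @rdname write_abc
#' @export
read_abc <- function(path) {
  lines <- readLines(path)
  nodes <- character(0)
  if (length(lines) && startsWith(lines[1], "#nodes:")) {
    nodes <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
    lines <- lines[-1]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 3L)) {
      stop("malformed ABC row at line ", which(lengths(parts) != 3L)[1],
           call. = FALSE)
    }
    edges <- data.frame(from = vapply(parts, `[`, "", 1L),
                        to = vapply(parts, `[`, "", 2L),
                        weight = as.numeric(vapply(parts, `[`, "", 3L)),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0))
  }
  nodes <- union(nodes, c(edges$from, edges$to))
  similarity_graph(nodes, edges)
}

# mcl-style cluster output: one cluster per line, tab-separated ids
write_clusters <- function(partition, path) {
  writeLines(vapply(partition$clusters, paste, "", collapse = "\t"), path)
  invisible(path)
}

read_clusters <- function(path) {
  cl <- strsplit(readLines(path), "\t", fixed = TRUE)
  names(cl) <- as.character(seq_along(cl))
  new_partition(cl)
}

DB_FORMAT_VERSION <- "sfamdb-1"

#' Save / load a family database
#'
#' The store is a directory of plain-text tables (`families.tsv`,
#' `familymembers.tsv`, `clans.tsv`, `unclustered.tsv`, `genomes` implicit
#' in `sequences.fasta`) plus per-family alignments, profiles and trees.
#' `load_db(save_db(db))` reproduces the database, including construction
#' ids and precision/recall fields.
#'
#' @param db An `sfam_db`.
#' @param path Directory to create / read.
#' @return `load_db` returns the reconstructed `sfam_db`.
#' @export
save_db <- function(db, path) {
  stopifnot(inherits(db, "sfam_db"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(version = DB_FORMAT_VERSION,
               next_construction_id = db$next_construction_id)
  jsonlite::write_json(meta, file.path(path, "version.json"),
                       auto_unbox = TRUE)
  write_fasta(db$records, file.path(path, "sequences.fasta"))

  fams <- db$families
  ftab <- data.frame(
    family_id = vapply(fams, `[[`, 0L, "family_id"),
    construction_id = vapply(fams, `[[`, 0L, "construction_id"),
    universality = vapply(fams, `[[`, 0, "universality"),
    precision = vapply(fams, `[[`, 0, "precision"),
    recall = vapply(fams, `[[`, 0, "recall"),
    terms = vapply(fams, function(f) paste(f$terms, collapse = ","), ""),
    partially_annotated = vapply(fams, `[[`, FALSE, "partially_annotated"),
    stringsAsFactors = FALSE)
  write.table(ftab, file.path(path, "families.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  mtab <- do.call(rbind, lapply(fams, function(f) {
    data.frame(family_id = f$family_id, seq_id = f$members,
               is_representative = f$members %in% (f$representatives %||%
                                                     character(0)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(mtab)) {
    mtab <- data.frame(family_id = integer(0), seq_id = character(0),
                       is_representative = logical(0))
  }
  write.table(mtab, file.path(path, "familymembers.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  writeLines(db$unclustered, file.path(path, "unclustered.tsv"))
  ctab <- db$clans %||% data.frame(method = character(0),
                                   clan_id = integer(0),
                                   family_id = integer(0))
  write.table(ctab, file.path(path, "clans.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)

  for (sub in c("alignments", "profiles", "trees")) {
    dir.create(file.path(path, sub), showWarnings = FALSE)
  }
  for (f in fams) {
    tag <- sprintf("%06d", f$family_id)
    if (!is.null(f$alignment)) {
      write_alignment(f$alignment,
                      file.path(path, "alignments", paste0(tag, ".fasta")))
    }
    if (!is.null(f$profile)) {
      write_profile(f$profile,
                    file.path(path, "profiles", paste0(tag, ".txt")))
    }
    if (!is.null(f$tree)) {
      writeLines(f$tree, file.path(path, "trees", paste0(tag, ".nwk")))
    }
  }
  invisible(path)
}

#' @rdname save_db
#' @export
load_db <- function(path) {
  vf <- file.path(path, "version.json")
  if (!file.exists(vf)) stop("not a family database: ", path, call. = FALSE)
  meta <- jsonlite::read_json(vf)
  if (!identical(meta$version, DB_FORMAT_VERSION)) {
    stop("database format version mismatch: found '", meta$version,
         "', expected '", DB_FORMAT_VERSION, "'", call. = FALSE)
  }
  needed <- c("sequences.fasta", "families.tsv", "familymembers.tsv",
              "unclustered.tsv", "clans.tsv")
  missing <- needed[!file.exists(file.path(path, needed))]
  if (length(missing)) {
    stop("corrupt database, missing table(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  records <- read_fasta(file.path(path, "sequences.fasta"))
  ftab <- read.table(file.path(path, "families.tsv"), sep = "\t",
                     header = TRUE, stringsAsFactors = FALSE)
  mtab <- read.table(file.path(path, "familymembers.tsv"), sep = "\t",
                     header = TRUE, stringsAsFactors = FALSE,
                     colClasses = c("integer", "character", "logical"))
  fams <- list()
  for (i in seq_len(NROW(ftab))) {
    fid <- ftab$family_id[i]
    mem <- mtab$seq_id[mtab$family_id == fid]
    if (!all(mem %in% records$seq_id)) {
      stop("corrupt database: family ", fid,
           " references unknown sequences", call. = FALSE)
    }
    f <- sfam_family(fid, mem, ftab$construction_id[i])
    f$universality <- ftab$universality[i]
    f$precision <- ftab$precision[i]
    f$recall <- ftab$recall[i]
    f$partially_annotated <- ftab$partially_annotated[i]
    if (nzchar(ftab$terms[i] %||% "")) {
      f$terms <- strsplit(ftab$terms[i], ",", fixed = TRUE)[[1]]
    }
    reps <- mtab$seq_id[mtab$family_id == fid & mtab$is_representative]
    if (length(reps)) f$representatives <- reps
    tag <- sprintf("%06d", fid)
    af <- file.path(path, "alignments", paste0(tag, ".fasta"))
    if (file.exists(af)) f$alignment <- read_alignment(af)
    pf <- file.path(path, "profiles", paste0(tag, ".txt"))
    if (file.exists(pf)) {
      f$profile <- read_profile(pf)
      f$consensus <- f$profile$consensus
    }
    tf <- file.path(path, "trees", paste0(tag, ".nwk"))
    if (file.exists(tf)) f$tree <- readLines(tf)[1]
    fams[[as.character(fid)]] <- f
  }
  uncl <- readLines(file.path(path, "unclustered.tsv"))
  uncl <- uncl[nzchar(uncl)]
  ctab <- read.table(file.path(path, "clans.tsv"), sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  db <- new_sfam_db(records, fams, uncl,
                    next_construction_id = meta$next_construction_id)
  if (NROW(ctab)) db$clans <- ctab
  validate_db(db)
  db
}

`%||%` <- function(a, b) if (is.null(a)) b else a
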