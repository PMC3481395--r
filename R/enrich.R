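#' Majority-rules family annotation
#'
#' A term is assigned to the family iff strictly more than half of its
#' members carry it. The `partially_annotated` flag marks families with at
#' least one annotated member but no majority term.
#'
#' @param family An `sfam_family`.
#' @param seq_terms Named list mapping seq_id to its term ids (sequences
#'   absent from the list carry no terms).
#' @return List with `terms` (character vector) and `partially_annotated`.
#' @export
annotate_family <- function(family, seq_terms) {
  if (length(family$members) == 0L) stop("empty family", call. = FALSE)
  member_terms <- seq_terms[intersect(family$members, names(seq_terms))]
  n <- length(family$members)
  if (length(member_terms) == 0L) {
    return(list(terms = character(0), partially_annotated = FALSE))
  }
  counts <- table(unlist(lapply(member_terms, unique)))
  terms <- names(counts)[counts > n / 2]
  list(terms = terms,
       partially_annotated = length(terms) == 0L)
}

#' Functional consistency of a network component
#'
#' Over the annotated families of the component only: the largest fraction
#' of them sharing any single term. 0 (with a flag) if no family in the
#' component is annotated.
#'
#' @param component_families List of `sfam_family` objects (or a list of
#'   character term vectors).
#' @param family_terms Optional named list family_id -> terms, used when
#'   `component_families` is a vector of ids.
#' @return Numeric fraction with attribute `no_annotation` when no family
#'   carries a term.
#' @export
component_consistency <- function(component_families, family_terms = NULL) {
  if (length(component_families) == 0L) {
    stop("empty component", call. = FALSE)
  }
  terms <- if (!is.null(family_terms)) {
    family_terms[as.character(component_families)]
  } else if (all(vapply(component_families, inherits, TRUE,
                        "sfam_family"))) {
    lapply(component_families, `[[`, "terms")
  } else {
    component_families
  }
  annotated <- terms[lengths(terms) > 0L]
  if (length(annotated) == 0L) {
    return(structure(0, no_annotation = TRUE))
  }
  counts <- table(unlist(lapply(annotated, unique)))
  max(counts) / length(annotated)
}

#' One-sided Fisher exact test for enrichment
#'
#' Exact hypergeometric tail probability (alternative "greater") on a 2x2
#' contingency table.
#'
#' @param table 2x2 matrix of nonnegative integer counts, oriented with the
#'   in-partition/with-term cell at `[1, 1]`.
#' @return The p-value.
#' @export
fisher_one_sided <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)))
  if (any(table < 0)) stop("negative counts", call. = FALSE)
  if (sum(table) == 0) stop("all-zero contingency table", call. = FALSE)
  fisher.test(table, alternative = "greater")$p.value
}

#' Enrichment scan over a family-property partition
#'
#' Splits the families by a property — `size_q4` and `degree_q4` put the
#' inclusive upper quartile (value at or above the 75th percentile) in the
#' partition, `low_precision` takes precision strictly below the cutoff —
#' and runs one one-sided Fisher test per term carried by at least one
#' family, with Bonferroni correction over the number of terms tested.
#'
#' @param families_df `data.frame` with columns `family_id` and the
#'   property column (`size`, `precision` or `degree`) for every family.
#' @param property One of `"size_q4"`, `"low_precision"`, `"degree_q4"`.
#' @param family_terms Named list family_id -> character vector of terms.
#' @param alpha Significance level applied to the corrected p-values.
#' @param low_precision_cutoff Cutoff for the `low_precision` partition.
#' @return `data.frame` sorted by corrected p-value: `term`, the four
#'   2x2 counts (`in_with`, `in_without`, `out_with`, `out_without`),
#'   `p_raw`, `p_bonferroni`, `significant`.
#' @export
enrichment_scan <- function(families_df,
                            property = c("size_q4", "low_precision",
                                         "degree_q4"),
                            family_terms, alpha = 0.05,
                            low_precision_cutoff = 0.75) {
  property <- match.arg(property)
  col <- switch(property, size_q4 = "size", low_precision = "precision",
                degree_q4 = "degree")
  if (!col %in% names(families_df)) {
    stop("families_df lacks the '", col, "' column", call. = FALSE)
  }
  vals <- families_df[[col]]
  if (anyNA(vals)) {
    stop("property '", col, "' missing for family ",
         paste(families_df$family_id[is.na(vals)], collapse = ", "),
         call. = FALSE)
  }
  in_part <- if (property == "low_precision") {
    vals < low_precision_cutoff
  } else {
    vals >= quantile(vals, 0.75, type = 7)
  }
  ids <- as.character(families_df$family_id)
  terms_of <- lapply(ids, function(i) unique(family_terms[[i]]))
  all_terms <- sort(unique(unlist(terms_of)))
  m <- length(all_terms)
  if (m == 0L) {
    return(data.frame(term = character(0), in_with = integer(0),
                      in_without = integer(0), out_with = integer(0),
                      out_without = integer(0), p_raw = numeric(0),
                      p_bonferroni = numeric(0), significant = logical(0)))
  }
  res <- lapply(all_terms, function(tm) {
    has <- vapply(terms_of, function(x) tm %in% x, TRUE)
    a <- sum(in_part & has); b <- sum(in_part & !has)
    cc <- sum(!in_part & has); d <- sum(!in_part & !has)
    p <- fisher_one_sided(matrix(c(a, cc, b, d), 2L))
    data.frame(term = tm, in_with = a, in_without = b, out_with = cc,
               out_without = d, p_raw = p,
               p_bonferroni = min(1, p * m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- out$p_bonferroni < alpha
  out <- out[order(out$p_bonferroni, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
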