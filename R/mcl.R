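#' Markov clustering of a similarity graph
#'
#' Dense implementation of the MCL process: the weighted adjacency matrix
#' gets a self-loop per node equal to its maximum incident edge weight, is
#' column-normalised, and then alternates expansion (matrix squaring) and
#' inflation (entrywise power followed by column renormalisation), pruning
#' entries below `mcl_prune` each round, until the matrix stops changing
#' (maximum absolute entry change below `mcl_tol`). Clusters are read off
#' the attractor structure of the limit matrix.
#'
#' @param graph An `sfam_graph` (or a `from`/`to`/`weight` edge table plus
#'   `nodes` attribute via `similarity_graph()`).
#' @param inflation Inflation exponent (> 1); the pipeline default is 2.
#' @param thresholds Iteration controls (`mcl_max_iter`, `mcl_prune`,
#'   `mcl_tol`).
#' @return An `sfam_partition`: a list with `clusters` (cluster id ->
#'   character vector of node ids), `membership` (named vector) and
#'   `is_singleton` flags.
#' @export
run_mcl <- function(graph, inflation = 2.0,
                    thresholds = sfam_thresholds()) {
  stopifnot(inherits(graph, "sfam_graph"))
  if (length(graph$nodes) == 0L) stop("empty graph", call. = FALSE)
  if (inflation <= 1) stop("inflation must be > 1", call. = FALSE)
  nodes <- graph$nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (NROW(graph$edges)) {
    i <- match(graph$edges$from, nodes)
    j <- match(graph$edges$to, nodes)
    if (anyNA(i) || anyNA(j)) stop("edge endpoint not in node set",
                                   call. = FALSE)
    A[cbind(i, j)] <- graph$edges$weight
    A[cbind(j, i)] <- graph$edges$weight
  }
  # self-loops: each node's maximum incident weight (1 for isolated nodes)
  loops <- apply(A, 2L, max)
  loops[loops == 0] <- 1
  diag(A) <- loops
  M <- sweep(A, 2L, colSums(A), "/")

  converged <- FALSE
  for (it in seq_len(thresholds$mcl_max_iter)) {
    M2 <- M %*% M            # expansion
    M2 <- M2^inflation       # inflation
    M2[M2 < thresholds$mcl_prune] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2L, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < thresholds$mcl_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("MCL did not converge within ", thresholds$mcl_max_iter,
         " iterations (residual change ", format(delta), ")", call. = FALSE)
  }
  extract_clusters(M)
}

#' Read clusters from a converged MCL matrix
#'
#' Attractors are the nodes with mass on their own diagonal; attractors
#' that support one another form an attractor system, and every other node
#' joins the system holding most of its column mass. A node with equal mass
#' on two systems goes to the larger cluster; remaining ties go to the
#' system whose smallest attractor id sorts first.
#'
#' @param M Converged column-stochastic matrix with node ids as dimnames.
#' @param tol Mass threshold for attractor detection.
#' @return An `sfam_partition`.
#' @export
extract_clusters <- function(M, tol = 1e-6) {
  nodes <- colnames(M)
  n <- length(nodes)
  att <- which(diag(M) > tol)
  if (length(att) == 0L) att <- seq_len(n)  # degenerate; treat all as attractors

  # attractor systems: components of the attractor-attractor support graph
  k <- length(att)
  sys_id <- seq_len(k)
  sub <- (M[att, att, drop = FALSE] > tol) |
    t(M[att, att, drop = FALSE] > tol)
  repeat {
    changed <- FALSE
    for (a in seq_len(k)) {
      nb <- which(sub[a, ])
      if (length(nb)) {
        m <- min(sys_id[c(a, nb)])
        if (any(sys_id[c(a, nb)] != m)) {
          sys_id[c(a, nb)] <- m
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  systems <- split(att, sys_id)

  # provisional clusters = the attractor systems; unambiguous nodes are
  # assigned first so that tie-broken nodes see realistic cluster sizes
  cl_of <- rep(NA_integer_, n)
  for (s in seq_along(systems)) cl_of[systems[[s]]] <- s
  min_att <- vapply(systems, function(s) nodes[min(s)], "")
  masses <- vector("list", n)
  ambiguous <- integer(0)
  for (j in seq_len(n)) {
    if (!is.na(cl_of[j])) next
    mass <- vapply(systems, function(s) sum(M[s, j]), 0)
    masses[[j]] <- mass
    if (max(mass) <= tol) {           # no attractor support: own singleton
      systems[[length(systems) + 1L]] <- integer(0)
      min_att <- c(min_att, nodes[j])
      cl_of[j] <- length(systems)
    } else if (sum(mass == max(mass)) == 1L) {
      cl_of[j] <- which.max(mass)
    } else {
      ambiguous <- c(ambiguous, j)
    }
  }
  sizes <- tabulate(cl_of[!is.na(cl_of)], nbins = length(systems))
  for (j in ambiguous) {
    mass <- masses[[j]]
    best <- which(mass == max(mass))
    best <- best[sizes[best] == max(sizes[best])]
    if (length(best) > 1L) best <- best[order(min_att[best])][1L]
    cl_of[j] <- best
    sizes[best] <- sizes[best] + 1L
  }

  clusters <- split(nodes, cl_of)
  # stable, deterministic cluster naming: by smallest member id
  ord <- order(vapply(clusters, function(x) sort(x)[1L], ""))
  clusters <- lapply(clusters[ord], sort)
  names(clusters) <- as.character(seq_along(clusters))
  new_partition(clusters)
}

new_partition <- function(clusters) {
  membership <- setNames(rep(names(clusters), lengths(clusters)),
                         unlist(clusters, use.names = FALSE))
  structure(list(clusters = clusters, membership = membership,
                 is_singleton = lengths(clusters) == 1L),
            class = "sfam_partition")
}

#' @export
print.sfam_partition <- function(x, ...) {
  cat(sprintf("<sfam_partition> %d clusters over %d nodes (%d singletons)\n",
              length(x$clusters), length(x$membership),
              sum(x$is_singleton)))
  invisible(x)
}
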