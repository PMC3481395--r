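# Independent reference implementations used as oracles. These are written
# against the mathematical definitions, not against the package internals.

# --- local affine-gap alignment, straightforward Gotoh with state-coded
#     traceback (states: 1 match, 2 gap-in-subject, 3 gap-in-query) --------
oracle_local_align <- function(a, b, S, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  open1 <- open + ext
  NEG <- -1e30
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  pM <- matrix(0L, n + 1, m + 1)
  pX <- matrix(0L, n + 1, m + 1)
  pY <- matrix(0L, n + 1, m + 1)
  best <- 0; bi <- 0; bj <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      v <- 0; p <- 0L
      if (M[i, j] > v) { v <- M[i, j]; p <- 1L }
      if (X[i, j] > v) { v <- X[i, j]; p <- 2L }
      if (Y[i, j] > v) { v <- Y[i, j]; p <- 3L }
      M[i + 1, j + 1] <- v + S[A[i], B[j]]
      pM[i + 1, j + 1] <- p
      cand <- c(M[i, j + 1] - open1, X[i, j + 1] - ext, Y[i, j + 1] - open1)
      w <- which.max(cand)
      X[i + 1, j + 1] <- cand[w]
      pX[i + 1, j + 1] <- c(1L, 2L, 3L)[w]
      cand <- c(M[i + 1, j] - open1, Y[i + 1, j] - ext, X[i + 1, j] - open1)
      w <- which.max(cand)
      Y[i + 1, j + 1] <- cand[w]
      pY[i + 1, j + 1] <- c(1L, 3L, 2L)[w]
      if (M[i + 1, j + 1] > best) {
        best <- M[i + 1, j + 1]; bi <- i + 1; bj <- j + 1
      }
    }
  }
  if (best <= 0) return(list(score = 0, aln_len = 0L, n_ident = 0L))
  i <- bi; j <- bj; state <- 1L
  n_ident <- 0L; aln_len <- 0L; qs <- bi - 1L; ss <- bj - 1L
  repeat {
    aln_len <- aln_len + 1L
    if (state == 1L) {
      if (A[i - 1] == B[j - 1]) n_ident <- n_ident + 1L
      qs <- i - 1L; ss <- j - 1L
      p <- pM[i, j]; i <- i - 1L; j <- j - 1L
      if (p == 0L) break
      state <- p
    } else if (state == 2L) {
      p <- pX[i, j]; i <- i - 1L; state <- p
    } else {
      p <- pY[i, j]; j <- j - 1L; state <- p
    }
  }
  list(score = best, n_ident = n_ident, aln_len = aln_len,
       q_start = qs, q_end = bi - 1L, s_start = ss, s_end = bj - 1L)
}

# --- reference Markov clustering: plain dense loop implementation, cluster
#     extraction via connected components of the limit-matrix support ------
oracle_mcl <- function(nodes, edges, inflation = 2, max_iter = 200,
                       prune = 1e-10, tol = 1e-8) {
  n <- length(nodes)
  A <- matrix(0, n, n)
  if (NROW(edges)) {
    for (r in seq_len(NROW(edges))) {
      i <- match(edges$from[r], nodes)
      j <- match(edges$to[r], nodes)
      A[i, j] <- edges$weight[r]
      A[j, i] <- edges$weight[r]
    }
  }
  for (v in seq_len(n)) {
    mx <- max(A[, v])
    A[v, v] <- if (mx > 0) mx else 1
  }
  for (v in seq_len(n)) A[, v] <- A[, v] / sum(A[, v])
  for (it in seq_len(max_iter)) {
    B <- A %*% A
    B <- B^inflation
    B[B < prune] <- 0
    for (v in seq_len(n)) {
      s <- sum(B[, v])
      if (s > 0) B[, v] <- B[, v] / s
    }
    if (max(abs(B - A)) < tol) { A <- B; break }
    A <- B
  }
  supp <- (A > 1e-6) | t(A > 1e-6)
  comp <- rep(0L, n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v] > 0L) next
    cur <- cur + 1L
    queue <- v
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      if (comp[x] > 0L) next
      comp[x] <- cur
      queue <- c(queue, which(supp[x, ] & comp == 0L))
    }
  }
  unname(lapply(split(seq_len(n), comp), function(ix) sort(nodes[ix])))
}

# --- brute-force graph statistics via BFS all-pairs shortest paths --------
oracle_network_stats <- function(nodes, edges) {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n)
  if (NROW(edges)) {
    for (r in seq_len(NROW(edges))) {
      i <- match(edges$from[r], nodes); j <- match(edges$to[r], nodes)
      adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  deg <- rowSums(adj)
  # all-pairs shortest-path distances and path counts (BFS per source)
  D <- matrix(Inf, n, n); diag(D) <- 0
  sigma <- matrix(0, n, n); diag(sigma) <- 1
  preds <- vector("list", n * n)
  for (s in seq_len(n)) {
    order_ <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order_ <- c(order_, v)
      for (w in which(adj[v, ])) {
        if (!is.finite(D[s, w])) {
          D[s, w] <- D[s, v] + 1
          queue <- c(queue, w)
        }
        if (D[s, w] == D[s, v] + 1) {
          sigma[s, w] <- sigma[s, w] + sigma[s, v]
          preds[[(s - 1) * n + w]] <- c(preds[[(s - 1) * n + w]], v)
        }
      }
    }
  }
  # betweenness: sum over pairs s<t of fraction of shortest paths through v
  btw <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || !is.finite(D[s, t]) || D[s, t] == 0) next
    # count paths through v: sigma(s,v) * sigma(v,t) / sigma(s,t) when on a
    # shortest path
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
        btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  trans <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ])
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(adj[nb, nb]) / 2
    links / (k * (k - 1) / 2)
  }, 0)
  comp <- rep(0L, n); cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v] > 0L) next
    cur <- cur + 1L
    queue <- v
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      if (comp[x] > 0L) next
      comp[x] <- cur
      queue <- c(queue, which(adj[x, ] & comp == 0L))
    }
  }
  clo <- vapply(seq_len(n), function(v) {
    same <- setdiff(which(comp == comp[v]), v)
    if (!length(same)) return(0)
    length(same) / sum(D[v, same])
  }, 0)
  list(degree = unname(deg), betweenness = btw, transitivity = trans,
       closeness = clo, component = comp)
}

# --- exact one-sided Fisher p by direct summation over the support -------
oracle_fisher_greater <- function(a, b, cc, d) {
  m <- a + b            # row 1 total (in partition)
  k <- a + cc           # col 1 total (with term)
  N <- a + b + cc + d
  lo <- max(0L, k - (N - m))
  hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    choose(m, x) * choose(N - m, k - x) / choose(N, k)
  }, 0)
  sum(probs[(lo:hi) >= a])
}

# --- connected components by union-find ----------------------------------
oracle_components <- function(nodes, from, to) {
  parent <- seq_along(nodes)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (r in seq_along(from)) {
    i <- find(match(from[r], nodes)); j <- find(match(to[r], nodes))
    if (i != j) parent[i] <- j
  }
  roots <- vapply(seq_along(nodes), find, 0L)
  unname(lapply(split(seq_along(nodes), roots),
                function(ix) sort(nodes[ix])))
}

# --- exhaustive best-path score through a tiny profile (local, matching
#     the scoring conventions: entry log2(1/L), inserts 0 bits) ------------
oracle_profile_best <- function(profile, seq) {
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1]], aa_alphabet())
  n <- length(codes)
  L <- profile$L
  best <- -Inf
  # enumerate all paths recursively: position in seq, model state
  rec <- function(i, j, kind, acc) {
    # i: next seq index to consume; j: current model slot; kind: M/I/D
    if (acc - (L + n) * 10 > best) {
      # no useful bound; small sizes only
    }
    # exit is free from a match state
    if (kind == "M") best <<- max(best, acc)
    if (j >= L) return(invisible())
    # transitions out of current state
    opts <- switch(kind,
      M = list(c("M", profile$tMM[j]), c("I", profile$tMI[j]),
               c("D", profile$tMD[j])),
      I = list(c("M", profile$tIM[j]), c("I", profile$tII[j])),
      D = list(c("M", profile$tDM[j]), c("D", profile$tDD[j])))
    for (o in opts) {
      tgt <- o[[1]]; tb <- as.numeric(o[[2]])
      if (tgt == "M" && i <= n) {
        rec(i + 1, j + 1, "M", acc + tb + profile$mlods[j + 1, codes[i]])
      } else if (tgt == "I" && i <= n) {
        rec(i + 1, j, "I", acc + tb)
      } else if (tgt == "D") {
        rec(i, j + 1, "D", acc + tb)
      }
    }
  }
  entry <- -log2(L)
  for (start_i in seq_len(n)) {
    for (start_j in seq_len(L)) {
      rec(start_i + 1, start_j, "M",
          entry + profile$mlods[start_j, codes[start_i]])
    }
  }
  best
}

# adjusted Rand index between two labelings (vectors aligned by position)
oracle_ari <- function(x, y) mclust::adjustedRandIndex(x, y)
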