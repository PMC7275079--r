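# Independent oracles used across the suite.  These stay deliberately
# naive (exhaustive subset enumeration, plain union-find) so they share
# no code path with the package's enumerator or percolation.

random_sgraph <- function(p, prob) {
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE) - 1L
  sgraph(p, pairs[runif(nrow(pairs)) < prob, , drop = FALSE])
}

# exhaustive-subset maximal k-plex oracle (graphs up to ~12 nodes)
brute_maximal_kplexes <- function(g, m, k) {
  p <- g$p
  adj <- matrix(FALSE, p, p)
  if (nrow(g$edges)) {
    adj[g$edges + 1L] <- TRUE
    adj[g$edges[, 2:1, drop = FALSE] + 1L] <- TRUE
  }
  ok <- function(S) {
    if (length(S) == 1L) return(TRUE)
    degs <- colSums(adj[S, S, drop = FALSE])
    all(degs >= length(S) - k)
  }
  subs <- list()
  for (mask in seq_len(2^p - 1L)) {
    S <- which(bitwAnd(mask, 2^(0:(p - 1L))) > 0)
    if (ok(S)) subs[[length(subs) + 1L]] <- S
  }
  maximal <- Filter(function(S) {
    !any(vapply(subs, function(T) length(T) > length(S) && all(S %in% T),
                logical(1)))
  }, subs)
  maximal <- Filter(function(S) length(S) >= m, maximal)
  maximal <- lapply(maximal, function(S) as.integer(S - 1L))
  maximal[order(vapply(maximal,
                       function(s) paste(sprintf("%04d", s), collapse = ","),
                       character(1)))]
}

# plain union-find closure of the >= threshold overlap relation
brute_overlap_groups <- function(sets, threshold) {
  n <- length(sets)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  if (n >= 2L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        if (length(intersect(sets[[i]], sets[[j]])) >= threshold) {
          parent[find(i)] <- find(j)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots)) - 1L
}

# independent clique percolation: igraph maximal cliques + union-find
brute_clique_percolation <- function(g, m) {
  ig <- igraph::graph_from_edgelist(g$edges + 1L, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, g$p - igraph::vcount(ig)))
  cl <- igraph::max_cliques(ig, min = m)
  cl <- lapply(cl, function(s) sort(as.integer(s) - 1L))
  if (!length(cl)) return(list())
  comp <- brute_overlap_groups(cl, m - 1L)
  lapply(unique(comp), function(cc) sort(unique(unlist(cl[comp == cc]))))
}

# canonical comparison form for a list of vertex sets
canon_sets <- function(sets) {
  sets <- lapply(sets, function(s) sort(as.integer(s)))
  sets[order(vapply(sets, function(s) paste(sprintf("%04d", s), collapse = ","),
                    character(1)))]
}

# constant-K4 layered fixture used in several places
constant_k4 <- function(N = 5L) {
  layered_graph(4L, replicate(N, rbind(c(0, 1), c(0, 2), c(0, 3),
                                       c(1, 2), c(1, 3), c(2, 3)),
                              simplify = FALSE))
}
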