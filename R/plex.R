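#' Plex percolation parameters
#'
#' Bundles the minimum plex size `m` and plex order `k`.  A k-plex of
#' size `m` is a vertex-induced subgraph in which every member has at
#' least `m - k` neighbors inside the subgraph, i.e. misses at most
#' `k - 1` of the others; a 1-plex is a clique.  The definition requires
#' `m > k >= 1`.
#'
#' @param m Integer minimum plex size.
#' @param k Integer plex order.
#' @return An object of class `plex_params`.
#' @export
plex_params <- function(m, k) {
  m <- as.integer(m)
  k <- as.integer(k)
  stopifnot(length(m) == 1L, length(k) == 1L)
  if (!(m > k && k >= 1L)) stop("plex parameters require m > k >= 1")
  structure(list(m = m, k = k), class = "plex_params")
}

#' @export
print.plex_params <- function(x, ...) {
  cat(sprintf("<plex_params> (m = %d, k = %d)%s\n", x$m, x$k,
              if (x$m - x$k <= 1L) " [degenerate regime m - k <= 1]" else ""))
  invisible(x)
}

#' Test the k-plex predicate on a vertex subset
#'
#' @param g An [sgraph()].
#' @param S Non-empty vector of 0-based node ids.
#' @param k Plex order.
#' @return `TRUE` iff every vertex of `S` has at least `|S| - k`
#'   neighbors inside `S`.
#' @examples
#' tri <- sgraph(3, rbind(c(0, 1), c(0, 2), c(1, 2)))
#' is_kplex(tri, 0:2, k = 1)  # a clique is a 1-plex
#' @export
is_kplex <- function(g, S, k) {
  S <- unique(as.integer(S))
  if (length(S) == 0L) stop("S must be non-empty")
  induced_min_degree(g, S) >= length(S) - as.integer(k)
}

#' Enumerate maximal k-plexes of size at least m
#'
#' Exact enumeration of all inclusion-maximal k-plexes with at least
#' `m` vertices, by recursive backtracking in the Bron–Kerbosch family.
#' The optional clique-first shortcut (`shortcut = TRUE`) first takes
#' all maximal cliques of size >= m and then enumerates k-plexes among
#' the vertices in no such clique; it is faster but can miss maximal
#' plexes that straddle a clique, so it is opt-in and labeled
#' approximate.
#'
#' @param g An [sgraph()].
#' @param params A [plex_params()].
#' @param shortcut Use the approximate clique-first variant.
#' @param cap Refuse exact enumeration on graphs with more than `cap`
#'   nodes (worst case is exponential).
#' @return List of sorted integer vectors (0-based members), in
#'   canonical lexicographic order.
#' @export
enumerate_maximal_kplexes <- function(g, params, shortcut = FALSE, cap = 512L) {
  stopifnot(inherits(g, "sgraph"), inherits(params, "plex_params"))
  if (g$p > cap) {
    stop(sprintf("refusing exact k-plex enumeration on %d > %d nodes; raise `cap` to override",
                 g$p, cap))
  }
  if (!shortcut) {
    return(.kplex_enum_cpp(g$p, g$edges, params$m, params$k))
  }
  enumerate_clique_first(g, params)
}

# Clique-first acceleration: maximal cliques of size >= m, then
# k-plexes among vertices not covered by any such clique.
enumerate_clique_first <- function(g, params) {
  cliques <- .kplex_enum_cpp(g$p, g$edges, params$m, 1L)
  covered <- sort(unique(unlist(cliques)))
  rest <- setdiff(seq_len(g$p) - 1L, covered)
  out <- cliques
  if (length(rest) >= params$m) {
    keep <- g$edges[, 1L] %in% rest & g$edges[, 2L] %in% rest
    sub <- g$edges[keep, , drop = FALSE]
    out <- c(out, .kplex_enum_cpp(g$p, sub, params$m, params$k))
  }
  out <- unique(out)
  key <- vapply(out, function(s) paste(sprintf("%06d", s), collapse = ","),
                character(1))
  out[order(key)]
}

#' Size of the vertex intersection of two plexes
#'
#' @param a,b Integer vectors of member ids (same host graph).
#' @return Non-negative overlap count.
#' @export
plex_overlap <- function(a, b) {
  length(intersect(as.integer(a), as.integer(b)))
}
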