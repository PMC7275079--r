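#' Static plex-percolation communities of one graph
#'
#' StatComm: enumerates the maximal k-plexes of `g` (size >= m) and
#' aggregates them into communities by percolation — two plexes belong
#' to the same community iff they are connected by a chain of pairwise
#' vertex overlaps of at least `m - 1`.  The plex-overlap graph is never
#' materialized; only its connected components are computed.  Member
#' vertices and all plex-internal edges receive the community label;
#' vertices in no plex receive no label.  With `k = 1` this is classic
#' clique percolation.
#'
#' @param g An [sgraph()].
#' @param params A [plex_params()].
#' @param cap Node-count guard passed to [enumerate_maximal_kplexes()].
#' @return A single-layer [community_assignment()] with canonical ids.
#' @export
static_communities <- function(g, params, cap = 512L) {
  stopifnot(inherits(g, "sgraph"))
  plexes <- enumerate_maximal_kplexes(g, params, cap = cap)
  comps <- percolate_plexes(plexes, params$m - 1L)
  assignment_from_plex_groups(g$p, 1L, plexes, comps, layer_of_plex = NULL,
                              edges_by_layer = list(g$edges))
}

# component id (0-based) per plex under the >= threshold overlap chain
percolate_plexes <- function(plexes, threshold) {
  if (!length(plexes)) return(integer(0))
  .overlap_components_cpp(plexes, as.integer(threshold))
}

# Build a community_assignment from plexes grouped into components.
# `layer_of_plex` gives each plex's layer (NULL = all layer 0);
# `edges_by_layer` the host edge matrices used to label plex-internal
# edges.  Used by both the static and the bislice passes.
assignment_from_plex_groups <- function(p, N, plexes, comps,
                                        layer_of_plex, edges_by_layer) {
  if (!length(plexes)) {
    return(community_assignment(p, N, NULL))
  }
  if (is.null(layer_of_plex)) layer_of_plex <- rep(0L, length(plexes))
  sizes <- lengths(plexes)
  vtab <- data.frame(layer = rep(layer_of_plex, sizes),
                     node = unlist(plexes, use.names = FALSE),
                     community = rep(comps, sizes))
  el <- eu <- ev <- ec <- vector("list", length(plexes))
  for (i in seq_along(plexes)) {
    S <- plexes[[i]]
    t <- layer_of_plex[i]
    e <- edges_by_layer[[t + 1L]]
    inS <- e[, 1L] %in% S & e[, 2L] %in% S
    if (any(inS)) {
      n <- sum(inS)
      el[[i]] <- rep(t, n)
      eu[[i]] <- e[inS, 1L]
      ev[[i]] <- e[inS, 2L]
      ec[[i]] <- rep(comps[i], n)
    }
  }
  etab <- data.frame(layer = unlist(el), u = unlist(eu), v = unlist(ev),
                     community = unlist(ec))
  canonicalize_ids(community_assignment(p, N, vtab, etab))
}
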