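#' DPPM configuration
#'
#' @param params A [plex_params()].
#' @param mode `"exact"` (default) walks plexes through every enhanced
#'   two-slice graph; `"heuristic"` links per-slice communities by raw
#'   vertex overlap, the strategy that is almost exact for parameters up
#'   to (5,3) and much cheaper on large inputs.
#' @param heuristic_overlap_strict Heuristic linking threshold: strictly
#'   greater than `m - 1` shared vertices (default) versus at least
#'   `m - 1` (the within-slice percolation wording).
#' @param heuristic_requires_shared_edge Additionally require an edge
#'   present in both slices and labeled in both communities before
#'   linking.
#' @param cross_slice_admissibility Apply the bislice admissibility rule
#'   (observed edge required on each side a plex touches).  Disabling it
#'   in the degenerate regime `m - k <= 1` is known to over-merge and
#'   triggers a warning.
#' @return An object of class `dppm_config`.
#' @export
dppm_config <- function(params, mode = c("exact", "heuristic"),
                        heuristic_overlap_strict = TRUE,
                        heuristic_requires_shared_edge = FALSE,
                        cross_slice_admissibility = TRUE) {
  stopifnot(inherits(params, "plex_params"))
  mode <- match.arg(mode)
  structure(list(params = params, mode = mode,
                 heuristic_overlap_strict = heuristic_overlap_strict,
                 heuristic_requires_shared_edge = heuristic_requires_shared_edge,
                 cross_slice_admissibility = cross_slice_admissibility),
            class = "dppm_config")
}

#' Dynamic plex percolation (DPPM driver)
#'
#' Exact mode runs StatComm at each time slice, then over each of the
#' `N - 1` enhanced two-slice graphs (restricted to admissible plexes),
#' and finally merges the resulting community fragments to a fixed
#' point: two fragments join iff they share an observed labeled edge at
#' a common slice or at least `m - 1` labeled vertices at a common
#' slice.  Every dynamic community receives one id spanning its full
#' extent forward and backward in time.  Heuristic mode links per-slice
#' communities at adjacent times by vertex overlap (see
#' [dppm_config()]).  The procedure involves no randomness.
#'
#' @param G A [layered_graph()].
#' @param config A [dppm_config()].
#' @param cap Node guard forwarded to the plex enumerator.
#' @return A [community_assignment()] with canonical ids.
#' @export
dppm <- function(G, config, cap = 512L) {
  stopifnot(inherits(G, "layered_graph"), inherits(config, "dppm_config"))
  m <- config$params$m
  k <- config$params$k
  if (m - k <= 1L && !config$cross_slice_admissibility) {
    warning("m - k <= 1 without cross-slice admissibility: self edges alone can bridge time and results are known to over-merge",
            call. = FALSE)
  }
  if (config$mode == "heuristic") {
    return(dppm_heuristic(G, config, cap))
  }
  fragments <- list()
  # pass 1: static communities per slice
  for (t in seq_len(G$N) - 1L) {
    ca <- static_communities(slice(G, t), config$params, cap = cap)
    fragments <- c(fragments, fragments_from_static(ca, t))
  }
  # pass 2: admissible plexes per bislice
  if (G$N >= 2L) {
    for (t in seq_len(G$N - 1L) - 1L) {
      B <- build_bislice(slice(G, t), slice(G, t + 1L))
      plexes <- admissible_bislice_plexes(B, config$params,
                                          admissibility = config$cross_slice_admissibility,
                                          cap = 2L * cap)
      if (!length(plexes)) next
      comps <- percolate_plexes(plexes, m - 1L)
      fragments <- c(fragments,
                     fragments_from_bislice(plexes, comps, B, t))
    }
  }
  propagate_labels(fragments, m, G$p, G$N)
}

# fragments (vertex + labeled-edge tables) from a single-layer assignment
fragments_from_static <- function(ca, t) {
  ids <- community_ids(ca)
  lapply(ids, function(id) {
    v <- ca$vertices[ca$vertices$community == id, , drop = FALSE]
    e <- ca$edges[ca$edges$community == id, , drop = FALSE]
    list(vertices = data.frame(layer = t, node = v$node),
         edges = if (nrow(e)) data.frame(layer = t, u = e$u, v = e$v)
                 else data.frame(layer = integer(0), u = integer(0), v = integer(0)))
  })
}

# fragments from percolated bislice plexes, mapped back to (layer, node)
fragments_from_bislice <- function(plexes, comps, B, t) {
  p <- B$p
  e0 <- B$edges[B$class == "observed" & !is.na(B$side) & B$side == 0L, ,
                drop = FALSE]
  e1 <- B$edges[B$class == "observed" & !is.na(B$side) & B$side == 1L, ,
                drop = FALSE]
  lapply(sort(unique(comps)), function(cid) {
    members <- unique(unlist(plexes[comps == cid]))
    vrows <- data.frame(layer = ifelse(members < p, t, t + 1L),
                        node = ifelse(members < p, members, members - p))
    erows <- list()
    for (S in plexes[comps == cid]) {
      left <- S[S < p]
      right <- S[S >= p]
      in0 <- e0[, 1L] %in% left & e0[, 2L] %in% left
      if (any(in0)) {
        erows[[length(erows) + 1L]] <-
          data.frame(layer = t, u = e0[in0, 1L], v = e0[in0, 2L])
      }
      in1 <- e1[, 1L] %in% right & e1[, 2L] %in% right
      if (any(in1)) {
        erows[[length(erows) + 1L]] <-
          data.frame(layer = t + 1L, u = e1[in1, 1L] - p, v = e1[in1, 2L] - p)
      }
    }
    edges <- if (length(erows)) unique(do.call(rbind, erows))
             else data.frame(layer = integer(0), u = integer(0), v = integer(0))
    list(vertices = unique(vrows), edges = edges)
  })
}

#' Merge community fragments to a fixed point
#'
#' Computes the transitive closure of the fragment merge relation —
#' shared observed labeled edge at a common slice, or at least `m - 1`
#' shared labeled vertices at a common slice — by union-find, so the
#' result is idempotent and independent of fragment order.
#'
#' @param fragments List of fragments, each a list with data frames
#'   `vertices` (`layer`, `node`) and `edges` (`layer`, `u`, `v`).
#' @param m Minimum plex size whose `m - 1` is the vertex threshold.
#' @param p,N Host graph dimensions.
#' @return A [community_assignment()] with canonical ids.
#' @export
propagate_labels <- function(fragments, m, p, N) {
  if (!length(fragments)) return(community_assignment(p, N, NULL))
  nf <- length(fragments)
  parent <- seq_len(nf)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[ra] <<- rb
  }
  layers_of <- lapply(fragments, function(f) unique(f$vertices$layer))
  for (t in sort(unique(unlist(layers_of)))) {
    here <- which(vapply(layers_of, function(l) t %in% l, logical(1)))
    if (length(here) < 2L) next
    vsets <- lapply(fragments[here], function(f)
      f$vertices$node[f$vertices$layer == t])
    gv <- .overlap_components_cpp(vsets, m - 1L)
    esets <- lapply(fragments[here], function(f) {
      e <- f$edges[f$edges$layer == t, , drop = FALSE]
      as.integer(e$u * as.double(p) + e$v)
    })
    ge <- .overlap_components_cpp(esets, 1L)
    for (grp in list(gv, ge)) {
      for (gid in unique(grp)) {
        idx <- here[grp == gid]
        if (length(idx) > 1L) for (j in idx[-1L]) unite(idx[1L], j)
      }
    }
  }
  roots <- vapply(seq_len(nf), find, integer(1))
  ids <- match(roots, unique(roots)) - 1L
  vrows <- do.call(rbind, lapply(seq_len(nf), function(i)
    cbind(fragments[[i]]$vertices, community = ids[i])))
  elist <- lapply(seq_len(nf), function(i) {
    e <- fragments[[i]]$edges
    if (nrow(e)) cbind(e, community = ids[i]) else NULL
  })
  erows <- do.call(rbind, elist[!vapply(elist, is.null, logical(1))])
  canonicalize_ids(community_assignment(p, N, vrows, erows))
}

# heuristic mode: per-slice StatComm + vertex-overlap linking in time
dppm_heuristic <- function(G, config, cap) {
  m <- config$params$m
  per_slice <- lapply(seq_len(G$N) - 1L, function(t)
    static_communities(slice(G, t), config$params, cap = cap))
  frag_idx <- list()   # (t, id) -> fragment number
  fragments <- list()
  for (t in seq_len(G$N) - 1L) {
    for (f in fragments_from_static(per_slice[[t + 1L]], t)) {
      fragments[[length(fragments) + 1L]] <- f
    }
  }
  # fragment lookup by slice, in per-slice community id order
  slice_frags <- split(seq_along(fragments),
                       vapply(fragments, function(f) f$vertices$layer[1L], integer(1)))
  parent <- seq_along(fragments)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  thr <- if (config$heuristic_overlap_strict) m - 1L else m - 2L  # overlap > thr
  for (t in seq_len(G$N - 1L) - 1L) {
    a_idx <- slice_frags[[as.character(t)]]
    b_idx <- slice_frags[[as.character(t + 1L)]]
    if (is.null(a_idx) || is.null(b_idx)) next
    pers <- shared_edges(G$layers[[t + 1L]], G$layers[[t + 2L]], G$p)
    pkey <- if (nrow(pers)) pers[, 1L] * as.double(G$p) + pers[, 2L] else double(0)
    for (ai in a_idx) {
      va <- fragments[[ai]]$vertices$node
      ea <- fragments[[ai]]$edges
      for (bi in b_idx) {
        vb <- fragments[[bi]]$vertices$node
        if (length(intersect(va, vb)) <= thr) next
        if (config$heuristic_requires_shared_edge) {
          eb <- fragments[[bi]]$edges
          ka <- ea$u * as.double(G$p) + ea$v
          kb <- eb$u * as.double(G$p) + eb$v
          if (!length(intersect(intersect(ka, kb), pkey))) next
        }
        ra <- find(ai); rb <- find(bi)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  nf <- length(fragments)
  if (!nf) return(community_assignment(G$p, G$N, NULL))
  roots <- vapply(seq_len(nf), find, integer(1))
  ids <- match(roots, unique(roots)) - 1L
  vrows <- do.call(rbind, lapply(seq_len(nf), function(i)
    cbind(fragments[[i]]$vertices, community = ids[i])))
  elist <- lapply(seq_len(nf), function(i) {
    e <- fragments[[i]]$edges
    if (nrow(e)) cbind(e, community = ids[i]) else NULL
  })
  erows <- do.call(rbind, elist[!vapply(elist, is.null, logical(1))])
  canonicalize_ids(community_assignment(G$p, G$N, vrows, erows))
}
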