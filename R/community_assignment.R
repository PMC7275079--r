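#' Community assignment over a layered graph
#'
#' Multi-label mapping from `(layer, node)` elements — and optionally
#' `(layer, edge)` elements — to community ids.  Communities may
#' overlap: an element may carry several labels, each on its own row.
#'
#' @param p Node count of the host layered graph.
#' @param N Layer count of the host layered graph.
#' @param vertices Data frame with integer columns `layer`, `node`,
#'   `community` (0-based layers/nodes; opaque integer ids).
#' @param edges Optional data frame with columns `layer`, `u`, `v`,
#'   `community` for labeled edges (`u < v`).
#' @return An object of class `community_assignment`.
#' @export
community_assignment <- function(p, N, vertices, edges = NULL) {
  p <- as.integer(p)
  N <- as.integer(N)
  if (is.null(vertices) || !nrow(vertices)) {
    vertices <- data.frame(layer = integer(0), node = integer(0),
                           community = integer(0))
  }
  vertices <- data.frame(layer = as.integer(vertices$layer),
                         node = as.integer(vertices$node),
                         community = as.integer(vertices$community))
  stopifnot(all(vertices$layer >= 0L & vertices$layer < N),
            all(vertices$node >= 0L & vertices$node < p))
  vertices <- unique(vertices)
  vertices <- vertices[order(vertices$layer, vertices$node, vertices$community), ,
                       drop = FALSE]
  rownames(vertices) <- NULL
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(layer = integer(0), u = integer(0), v = integer(0),
                        community = integer(0))
  } else {
    edges <- data.frame(layer = as.integer(edges$layer),
                        u = pmin(as.integer(edges$u), as.integer(edges$v)),
                        v = pmax(as.integer(edges$u), as.integer(edges$v)),
                        community = as.integer(edges$community))
    edges <- unique(edges)
    edges <- edges[order(edges$layer, edges$u, edges$v, edges$community), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(p = p, N = N, vertices = vertices, edges = edges),
            class = "community_assignment")
}

#' @export
print.community_assignment <- function(x, ...) {
  cat(sprintf("<community_assignment> %d communities over %d nodes x %d layers (%d vertex labels)\n",
              length(community_ids(x)), x$p, x$N, nrow(x$vertices)))
  invisible(x)
}

#' Community ids present in an assignment
#'
#' @param ca A [community_assignment()].
#' @return Sorted integer vector of distinct ids.
#' @export
community_ids <- function(ca) sort(unique(ca$vertices$community))

#' Number of distinct communities
#'
#' @param ca A [community_assignment()].
#' @export
n_communities <- function(ca) length(community_ids(ca))

#' Materialize one community for downstream statistics
#'
#' @param ca A [community_assignment()].
#' @param id Community id present in `ca`.
#' @return A list of class `community_view` with elements `id`,
#'   `members` (list of per-layer 0-based node vectors, one per layer of
#'   the host graph), `first_layer`, `last_layer`.
#' @export
community_view <- function(ca, id) {
  v <- ca$vertices[ca$vertices$community == id, , drop = FALSE]
  if (!nrow(v)) stop(sprintf("unknown community id %s", id))
  members <- lapply(seq_len(ca$N) - 1L, function(t) sort(v$node[v$layer == t]))
  structure(list(id = as.integer(id), members = members,
                 first_layer = min(v$layer), last_layer = max(v$layer)),
            class = "community_view")
}

# Canonicalize community ids: first-appearance order by
# (first layer, smallest member node at that layer), giving
# deterministic output ids for a given detection result.
canonicalize_ids <- function(ca) {
  v <- ca$vertices
  if (!nrow(v)) return(ca)
  first_layer <- tapply(v$layer, v$community, min)
  ids <- as.integer(names(first_layer))
  first_node <- vapply(seq_along(ids), function(i) {
    sel <- v$community == ids[i] & v$layer == first_layer[i]
    min(v$node[sel])
  }, integer(1))
  o <- order(first_layer, first_node, ids)
  remap <- integer(max(ids) + 1L)
  remap[ids[o] + 1L] <- seq_along(ids) - 1L
  v$community <- remap[v$community + 1L]
  e <- ca$edges
  if (nrow(e)) e$community <- remap[e$community + 1L]
  community_assignment(ca$p, ca$N, v, e)
}

#' Write community vertex labels to TSV
#'
#' One row per membership (`layer	node	community_id`); a node in
#' several communities at a layer occupies several rows.
#'
#' @param ca A [community_assignment()].
#' @param path Output file path.
#' @export
write_communities <- function(ca, path) {
  stopifnot(inherits(ca, "community_assignment"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# community vertex labels; 0-based node and layer ids",
               sprintf("#nodes=%d", ca$p),
               sprintf("#layers=%d", ca$N),
               "layer\tnode\tcommunity_id"), con)
  v <- ca$vertices
  if (nrow(v)) {
    writeLines(sprintf("%d\t%d\t%d", v$layer, v$node, v$community), con)
  }
  invisible(path)
}

#' Read community vertex labels from TSV
#'
#' Inverse of [write_communities()] (vertex labels only; edge labels
#' are not serialized).
#'
#' @param path File path.
#' @param p,N Optional host dimensions; default to the `#nodes=`/
#'   `#layers=` header comments, falling back to `1 + max` observed.
#' @return A [community_assignment()].
#' @export
read_communities <- function(path, p = NULL, N = NULL) {
  lines <- readLines(path)
  grab <- function(tag) {
    ln <- grep(sprintf("^#\\s*%s\\s*=", tag), lines, value = TRUE)
    if (length(ln)) as.integer(sub(sprintf("^#\\s*%s\\s*=\\s*", tag), "", ln[1L]))
    else NA_integer_
  }
  hp <- grab("nodes")
  hN <- grab("layers")
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(body) || !grepl("^layer\tnode\tcommunity_id$", body[1L])) {
    stop("expected header 'layer\\tnode\\tcommunity_id'")
  }
  rows <- body[-1L]
  if (length(rows)) {
    f <- do.call(rbind, strsplit(rows, "\t", fixed = TRUE))
    d <- matrix(as.integer(f), ncol = 3L)
    vertices <- data.frame(layer = d[, 1L], node = d[, 2L], community = d[, 3L])
  } else {
    vertices <- data.frame(layer = integer(0), node = integer(0),
                           community = integer(0))
  }
  if (is.null(p)) p <- if (!is.na(hp)) hp else max(vertices$node, 0L) + 1L
  if (is.null(N)) N <- if (!is.na(hN)) hN else max(vertices$layer, 0L) + 1L
  community_assignment(p, N, vertices)
}
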