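#' Single-slice binary graph
#'
#' Lightweight container for one simple undirected graph: a node count
#' `p` and a canonical edge matrix (two integer columns, 0-based ids,
#' `u < v`, no duplicates, no self-loops).
#'
#' @param p Number of nodes; nodes are `0 ... p - 1`.
#' @param edges Two-column matrix (or data frame) of 0-based node pairs;
#'   may be empty.
#' @return An object of class `sgraph` with elements `p` and `edges`.
#' @examples
#' g <- sgraph(3, rbind(c(0, 1), c(1, 2)))
#' graph_degree(g, 1)
#' @export
sgraph <- function(p, edges = NULL) {
  p <- as.integer(p)
  stopifnot(length(p) == 1L, p >= 1L)
  edges <- canonical_edges(edges, p)
  structure(list(p = p, edges = edges), class = "sgraph")
}

# canonicalize an edge container: integer matrix, u < v, unique, sorted
canonical_edges <- function(edges, p) {
  if (is.null(edges) || NROW(edges) == 0L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("u", "v"))))
  }
  edges <- as.matrix(edges)
  storage.mode(edges) <- "integer"
  if (ncol(edges) != 2L) stop("edges must have two columns")
  if (anyNA(edges)) stop("edges contain missing values")
  if (any(edges < 0L)) stop("negative node ids are not allowed")
  if (any(edges >= p)) stop("node id exceeds p - 1")
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
  u <- pmin(edges[, 1L], edges[, 2L])
  v <- pmax(edges[, 1L], edges[, 2L])
  key <- u * as.double(p) + v
  keep <- !duplicated(key)
  o <- order(key[keep])
  out <- cbind(u = u[keep][o], v = v[keep][o])
  out
}

#' @export
print.sgraph <- function(x, ...) {
  cat(sprintf("<sgraph> %d nodes, %d edges\n", x$p, nrow(x$edges)))
  invisible(x)
}

#' Layered binary network on a common vertex set
#'
#' A sequence of [sgraph()] slices sharing the vertex set
#' `0 ... p - 1`, one slice per time layer `0 ... N - 1`.  Empty layers
#' are legal.
#'
#' @param p Common node count.
#' @param layers List of edge matrices (one per layer, possibly empty),
#'   or a list of `sgraph` objects with matching `p`.
#' @return An object of class `layered_graph`.
#' @seealso [read_layered_edgelist()], [slice()]
#' @export
layered_graph <- function(p, layers) {
  p <- as.integer(p)
  stopifnot(p >= 1L, is.list(layers), length(layers) >= 1L)
  slices <- lapply(layers, function(l) {
    if (inherits(l, "sgraph")) {
      if (l$p != p) stop("slice p does not match layered graph p")
      l$edges
    } else {
      canonical_edges(l, p)
    }
  })
  structure(list(p = p, N = length(slices), layers = slices),
            class = "layered_graph")
}

#' @export
print.layered_graph <- function(x, ...) {
  ne <- vapply(x$layers, nrow, integer(1))
  cat(sprintf("<layered_graph> %d nodes x %d layers; %d edges total (%d-%d per layer)\n",
              x$p, x$N, sum(ne), min(ne), max(ne)))
  invisible(x)
}

#' Extract one layer of a layered graph
#'
#' @param G A [layered_graph()].
#' @param t 0-based layer index.
#' @return The layer as an [sgraph()].
#' @export
slice <- function(G, t) {
  stopifnot(inherits(G, "layered_graph"), t >= 0L, t < G$N)
  structure(list(p = G$p, edges = G$layers[[t + 1L]]), class = "sgraph")
}

#' Convert a stacked 0/1 adjacency array to a layered graph
#'
#' @param a Array of dimension `layers x p x p` (or `p x p` for a single
#'   layer) with 0/1 entries; only the upper triangle is read.
#' @return A [layered_graph()].
#' @export
as_layered_graph <- function(a) {
  if (length(dim(a)) == 2L) a <- array(a, c(1L, dim(a)))
  stopifnot(length(dim(a)) == 3L, dim(a)[2] == dim(a)[3])
  p <- dim(a)[2]
  layers <- lapply(seq_len(dim(a)[1]), function(t) {
    w <- which(a[t, , ] != 0 & upper.tri(a[t, , ]), arr.ind = TRUE)
    cbind(w[, 1L] - 1L, w[, 2L] - 1L)
  })
  layered_graph(p, layers)
}

neighbor_list <- function(g) {
  nb <- vector("list", g$p)
  for (i in seq_len(g$p)) nb[[i]] <- integer(0)
  e <- g$edges
  if (nrow(e)) {
    for (r in seq_len(nrow(e))) {
      u <- e[r, 1L] + 1L
      v <- e[r, 2L] + 1L
      nb[[u]] <- c(nb[[u]], v - 1L)
      nb[[v]] <- c(nb[[v]], u - 1L)
    }
  }
  nb
}

#' Node degree in one slice
#'
#' @param g An [sgraph()].
#' @param v 0-based node id.
#' @return Non-negative integer degree.
#' @export
graph_degree <- function(g, v) {
  stopifnot(inherits(g, "sgraph"), v >= 0L, v < g$p)
  sum(g$edges == as.integer(v))
}

#' Minimum induced degree of a vertex subset
#'
#' The minimum, over `v` in `S`, of the number of neighbors of `v`
#' inside `S` — the quantity bounded from below by `|S| - k` in the
#' k-plex condition.
#'
#' @param g An [sgraph()].
#' @param S Non-empty vector of 0-based node ids.
#' @return Integer minimum induced degree.
#' @export
induced_min_degree <- function(g, S) {
  stopifnot(inherits(g, "sgraph"))
  S <- unique(as.integer(S))
  if (length(S) == 0L) stop("S must be non-empty")
  if (any(S < 0L | S >= g$p)) stop("S contains ids outside 0..p-1")
  e <- g$edges
  inS <- e[, 1L] %in% S & e[, 2L] %in% S
  if (!any(inS)) return(0L)
  deg <- table(factor(c(e[inS, 1L], e[inS, 2L]), levels = S))
  as.integer(min(deg))
}

#' Read a layered edge-list TSV
#'
#' Expects a tab-separated file with header `layer	u	v` and one
#' 0-based edge per row.  Layers need not be sorted; missing
#' intermediate layers become empty layers.  The node count defaults to
#' `1 + max` node id and can be overridden with a `#nodes=p` comment
#' line before the header.
#'
#' @param path File path or connection.
#' @return A [layered_graph()].
#' @export
read_layered_edgelist <- function(path) {
  lines <- readLines(path)
  p_override <- NA_integer_
  comment <- grepl("^#", lines)
  nodes_line <- grep("^#\\s*nodes\\s*=", lines, value = TRUE)
  if (length(nodes_line)) {
    p_override <- as.integer(sub("^#\\s*nodes\\s*=\\s*", "", nodes_line[1L]))
  }
  body <- lines[!comment & nzchar(lines)]
  if (!length(body) || !grepl("^layer\tu\tv$", body[1L])) {
    stop("expected header 'layer\\tu\\tv'")
  }
  rows <- body[-1L]
  if (length(rows)) {
    f <- do.call(rbind, strsplit(rows, "\t", fixed = TRUE))
    d <- matrix(suppressWarnings(as.integer(f)), ncol = 3L)
    if (anyNA(d)) stop("non-integer field in edge list")
    bad <- which(d[, 2L] == d[, 3L])
    if (length(bad)) {
      stop(sprintf("self-loop at data line %d (%d-%d)",
                   bad[1L], d[bad[1L], 2L], d[bad[1L], 3L]))
    }
    if (any(d < 0L)) stop("negative ids in edge list")
  } else {
    d <- matrix(integer(0), ncol = 3L)
  }
  N <- if (nrow(d)) max(d[, 1L]) + 1L else 1L
  p <- if (!is.na(p_override)) p_override
       else if (nrow(d)) max(d[, 2L:3L]) + 1L else 1L
  layers <- lapply(seq_len(N) - 1L, function(t) d[d[, 1L] == t, 2L:3L, drop = FALSE])
  layered_graph(p, layers)
}

#' Write a layered edge-list TSV
#'
#' Inverse of [read_layered_edgelist()]; writes a `#nodes=p` comment,
#' the header, and one canonical edge per row.
#'
#' @param G A [layered_graph()].
#' @param path Output file path.
#' @export
write_layered_edgelist <- function(G, path) {
  stopifnot(inherits(G, "layered_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# layered edge list; 0-based node and layer ids",
               sprintf("#nodes=%d", G$p),
               "layer\tu\tv"), con)
  for (t in seq_len(G$N) - 1L) {
    e <- G$layers[[t + 1L]]
    if (nrow(e)) {
      writeLines(sprintf("%d\t%d\t%d", t, e[, 1L], e[, 2L]), con)
    }
  }
  invisible(path)
}

# edges present in both slices (canonical matrices) -> canonical matrix
shared_edges <- function(e1, e2, p) {
  if (!nrow(e1) || !nrow(e2)) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("u", "v"))))
  }
  k1 <- e1[, 1L] * as.double(p) + e1[, 2L]
  k2 <- e2[, 1L] * as.double(p) + e2[, 2L]
  e1[k1 %in% k2, , drop = FALSE]
}
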