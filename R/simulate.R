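#' Within-block degree-model parameters
#'
#' Parameters of the degree-corrected within-community edge sampler
#' used by the benchmark scenarios: expected degrees follow a truncated
#' power law and edges are realized Chung–Lu style inside each
#' same-label block (mixing 0: never across blocks).
#'
#' @param powerlaw_exponent Exponent of the power-law degree
#'   distribution (default -2).
#' @param min_degree,max_degree Degree bounds (defaults 3 and 20; the
#'   target is additionally capped at block size - 1).
#' @param mixing Between-block mixing (fixed at 0; only 0 supported).
#' @param max_rejections Maximum resampling attempts per block when an
#'   edge draw hits a self-loop or duplicate (default 100).
#' @return An object of class `degree_model_params`.
#' @export
degree_model_params <- function(powerlaw_exponent = -2,
                                min_degree = 3L, max_degree = 20L,
                                mixing = 0, max_rejections = 100L) {
  if (mixing != 0) stop("only mixing parameter 0 is supported")
  structure(list(powerlaw_exponent = powerlaw_exponent,
                 min_degree = as.integer(min_degree),
                 max_degree = as.integer(max_degree),
                 mixing = mixing,
                 max_rejections = as.integer(max_rejections)),
            class = "degree_model_params")
}

# draw n degrees from the truncated power law on [lo, hi]
draw_powerlaw_degrees <- function(n, lo, hi, exponent) {
  support <- lo:hi
  if (length(support) == 1L) return(rep(support, n))
  w <- support^exponent
  sample(support, n, replace = TRUE, prob = w / sum(w))
}

#' Sample one layer's edges from a node labeling
#'
#' Edges are placed only within groups of equal label (mixing 0).  In
#' each block of size >= 2, target degrees are drawn from the truncated
#' power law (capped at block size - 1) and edges realized by sampling
#' endpoint pairs proportional to target degree, rejecting self-loops
#' and duplicates up to `max_rejections` per block (best effort beyond
#' that; the rejection count is attached as attribute `rejections`).
#' Singleton groups get no edges.
#'
#' @param labels Integer vector of community labels, one per node.
#' @param params A [degree_model_params()].
#' @param seed Optional seed; `NULL` draws from the current RNG stream.
#' @return Canonical two-column edge matrix (0-based) with attribute
#'   `rejections`.
#' @export
sample_layer <- function(labels, params = degree_model_params(), seed = NULL) {
  local_seed(seed, {
    p <- length(labels)
    rows <- list()
    rejections <- 0L
    for (lab in unique(labels)) {
      block <- which(labels == lab) - 1L
      nb <- length(block)
      if (nb < 2L) next
      lo <- min(params$min_degree, nb - 1L)
      hi <- min(params$max_degree, nb - 1L)
      theta <- draw_powerlaw_degrees(nb, lo, hi, params$powerlaw_exponent)
      n_edges <- max(1L, round(sum(theta) / 2))
      n_edges <- min(n_edges, nb * (nb - 1L) %/% 2L)
      prob <- theta / sum(theta)
      seen <- numeric(0)
      ea <- integer(n_edges)
      eb <- integer(n_edges)
      got <- 0L
      rej <- 0L
      while (got < n_edges && rej < params$max_rejections) {
        pick <- sample.int(nb, 2L, replace = TRUE, prob = prob)
        if (pick[1L] == pick[2L]) {
          rej <- rej + 1L
          next
        }
        a <- block[min(pick)]
        b <- block[max(pick)]
        key <- a * as.double(p) + b
        if (key %in% seen) {
          rej <- rej + 1L
          next
        }
        seen <- c(seen, key)
        got <- got + 1L
        ea[got] <- a
        eb[got] <- b
      }
      rejections <- rejections + rej
      rows[[length(rows) + 1L]] <- cbind(ea[seq_len(got)], eb[seq_len(got)])
    }
    edges <- if (length(rows)) do.call(rbind, rows)
             else matrix(integer(0), ncol = 2L)
    edges <- canonical_edges(edges, p)
    attr(edges, "rejections") <- rejections
    edges
  })
}

#' Planted multilayer scenario truth
#'
#' Container for a scenario's planted label matrix and designated true
#' community trajectory.
#'
#' @param label_matrix `p x N` integer matrix of planted labels (0 =
#'   the planted dynamic community; 1..p = random noise labels).
#' @param true_community List of per-layer 0-based node vectors
#'   (`c_T(t)`); empty exactly in the random-label intervals.
#' @param scenario,seed Metadata.
#' @return An object of class `scenario_truth`.
#' @export
scenario_truth <- function(label_matrix, true_community, scenario, seed) {
  stopifnot(is.matrix(label_matrix),
            length(true_community) == ncol(label_matrix))
  structure(list(label_matrix = label_matrix,
                 true_community = true_community,
                 scenario = scenario, seed = seed,
                 p = nrow(label_matrix), N = ncol(label_matrix),
                 layer_seconds = 1),
            class = "scenario_truth")
}

#' @export
print.scenario_truth <- function(x, ...) {
  sz <- vapply(x$true_community, length, integer(1))
  cat(sprintf("<scenario_truth> %s: %d nodes x %d layers (1 s each); |c_T| in [%d, %d]\n",
              x$scenario, x$p, x$N, min(sz), max(sz)))
  invisible(x)
}

# label matrix schedules; planted community label = 0, noise labels
# uniform on 1..64 independently per node and layer
scenario_label_matrix <- function(name, p = 64L, interval = 20L) {
  blocks <- list(c1 = 0:14, c2 = 15:29, c3 = 30:44,
                 c4 = 45:54, c5 = 55:63)
  sched <- switch(
    name,
    # five 20-layer intervals; active sets per interval
    split = list(NULL, blocks$c2, c(blocks$c1, blocks$c2, blocks$c3),
                 c(blocks$c1, blocks$c3), NULL),
    merge = list(NULL, c(blocks$c1, blocks$c3),
                 c(blocks$c1, blocks$c2, blocks$c3), blocks$c2, NULL),
    # seven 20-layer intervals; communities of 15 then 10 nodes join
    expand = list(NULL, blocks$c1, c(blocks$c1, 15:24), c(blocks$c1, 15:34),
                  c(blocks$c1, 15:44), c(blocks$c1, 15:54), NULL),
    stop(sprintf("unknown scenario '%s'", name)))
  N <- length(sched) * interval
  lab <- matrix(0L, nrow = p, ncol = N)
  truth <- vector("list", N)
  for (i in seq_along(sched)) {
    cols <- ((i - 1L) * interval + 1L):(i * interval)
    active <- sched[[i]]
    for (tt in cols) {
      l <- sample.int(p, p, replace = TRUE)  # noise labels 1..p
      if (length(active)) l[active + 1L] <- 0L
      lab[, tt] <- l
      truth[[tt]] <- if (length(active)) sort(active) else integer(0)
    }
  }
  list(label_matrix = lab, true_community = truth)
}

#' Generate a benchmark community-evolution scenario
#'
#' Four scenarios over 64 nodes: `split` and `merge` (five 20-layer
#' intervals, 100 layers) plant three 15-node communities; `expand`
#' (seven 20-layer intervals, 140 layers) starts a 15-node community
#' that gains 10 nodes per interval up to 55; `contract` is `expand`
#' with the time axis reversed.  Outside active intervals every node
#' carries an independent uniform random label in 1..64, so only
#' coincidentally-equal-label pairs can share an edge.  Each layer
#' represents a functional network for a 1 s interval.
#'
#' @param name One of `"expand"`, `"contract"`, `"split"`, `"merge"`.
#' @param seed Integer seed; the scenario is deterministic given
#'   `(name, seed)`.
#' @param params A [degree_model_params()].
#' @return List with elements `graph` (a [layered_graph()]) and
#'   `truth` (a [scenario_truth()]).
#' @export
make_scenario <- function(name = c("expand", "contract", "split", "merge"),
                          seed, params = degree_model_params()) {
  name <- match.arg(name)
  base <- if (name == "contract") "expand" else name
  local_seed(seed, {
    sc <- scenario_label_matrix(base)
    layers <- lapply(seq_len(ncol(sc$label_matrix)), function(tt)
      sample_layer(sc$label_matrix[, tt], params))
    if (name == "contract") {
      idx <- rev(seq_along(layers))
      layers <- layers[idx]
      sc$label_matrix <- sc$label_matrix[, idx, drop = FALSE]
      sc$true_community <- sc$true_community[idx]
    }
    list(graph = layered_graph(nrow(sc$label_matrix), layers),
         truth = scenario_truth(sc$label_matrix, sc$true_community,
                                name, seed))
  })
}

# default 9-node, 8-edge template: double star with centers 3 and 5
default_noise_template <- function() {
  sgraph(9L, rbind(c(0, 3), c(1, 3), c(2, 3), c(3, 5),
                   c(4, 5), c(5, 6), c(5, 7), c(5, 8)))
}

#' Edge-deletion (type-II noise) dynamic network
#'
#' Replicates a connected 9-node, 8-edge template graph (a tree, forced
#' by the counts) across `steps` layers, removing `removals` uniformly
#' chosen edges (without replacement) independently at each layer —
#' the missing-edge noise a robust dynamic community tracker should
#' shrug off.
#'
#' @param template An [sgraph()]; default is a double star with centers
#'   3 and 5.  Templates violating the 9-node/8-edge/connected counts
#'   are rejected unless `force = TRUE`.
#' @param steps Number of layers (default 100).
#' @param removals Edges removed per layer (default 2).
#' @param seed Optional seed.
#' @param force Skip the template check.
#' @return A [layered_graph()].
#' @export
noise_template_sim <- function(template = NULL, steps = 100L, removals = 2L,
                               seed = NULL, force = FALSE) {
  if (is.null(template)) template <- default_noise_template()
  stopifnot(inherits(template, "sgraph"))
  ne <- nrow(template$edges)
  if (!force) {
    if (template$p != 9L || ne != 8L) {
      stop("template must have 9 nodes and 8 edges (use force = TRUE to override)")
    }
    comp <- connected_components(template)
    if (length(unique(comp)) != 1L) stop("template must be connected")
  }
  stopifnot(removals < ne)
  local_seed(seed, {
    layers <- lapply(seq_len(steps), function(i) {
      drop <- sample.int(ne, removals)
      template$edges[-drop, , drop = FALSE]
    })
    layered_graph(template$p, layers)
  })
}

# connected component id per vertex of an sgraph (0-based labels)
connected_components <- function(g) {
  parent <- seq_len(g$p)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  e <- g$edges
  if (nrow(e)) {
    for (r in seq_len(nrow(e))) {
      a <- find(e[r, 1L] + 1L)
      b <- find(e[r, 2L] + 1L)
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(g$p), find, integer(1))
  match(roots, unique(roots)) - 1L
}

#' Deterministic two-layer toy fixtures
#'
#' Seven-node, two-layer networks reconstructed from the textual
#' description of the deterministic comparison: layer 0 holds triangles
#' `{0,1,2}` and `{4,5,6}` with node 3 unattached; layer 1 is a single
#' connected component (7 edges) containing triangle `{2,3,4}` and
#' sharing no edge with layer 0.  `edges8` adds `{0,1}` (upper pair)
#' and `edges9` further adds `{4,5}` (lower pair), so the variants
#' share 0, 1, and 2 edges with layer 0 respectively.  These fixtures
#' are synthetic reconstructions consistent with every stated
#' constraint; the original adjacency matrices are figure-only.
#'
#' @param variant One of `"edges7"`, `"edges8"`, `"edges9"`.
#' @return A [layered_graph()] with `p = 7`, `N = 2`.
#' @export
toy_fixture <- function(variant = c("edges7", "edges8", "edges9")) {
  variant <- match.arg(variant)
  layer0 <- rbind(c(0, 1), c(0, 2), c(1, 2), c(4, 5), c(4, 6), c(5, 6))
  layer1 <- rbind(c(2, 3), c(3, 4), c(2, 4), c(1, 3), c(0, 3), c(3, 5), c(3, 6))
  if (variant %in% c("edges8", "edges9")) layer1 <- rbind(layer1, c(0, 1))
  if (variant == "edges9") layer1 <- rbind(layer1, c(4, 5))
  layered_graph(7L, list(layer0, layer1))
}
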