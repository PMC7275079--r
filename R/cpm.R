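#' CPM configuration
#'
#' Clique percolation baseline: per-slice communities are clique
#' percolation (1-plexes of size >= m), linked across adjacent times by
#' an ad hoc vertex-overlap rule with randomized tie-breaking.
#'
#' @param m Minimum clique size (>= 3).
#' @param seed RNG seed for the tie-breaking coin flips; recorded in
#'   the result.
#' @param link_threshold Minimum vertex overlap for a community at
#'   `t + 1` to inherit a label from time `t` (default 1, which the
#'   toy-fixture behavior pins down; configurable up to `m - 1`).
#' @return An object of class `cpm_config`.
#' @export
cpm_config <- function(m = 3L, seed = 1L, link_threshold = 1L) {
  m <- as.integer(m)
  if (m < 3L) stop("CPM requires minimum clique size m >= 3")
  link_threshold <- as.integer(link_threshold)
  stopifnot(link_threshold >= 1L, link_threshold <= m - 1L)
  structure(list(m = m, seed = as.integer(seed),
                 link_threshold = link_threshold),
            class = "cpm_config")
}

#' Clique percolation with across-time overlap linking
#'
#' Per-slice stage identical to [static_communities()] with `k = 1`.
#' Each community at `t + 1` overlapping at least `link_threshold`
#' vertices with some community at `t` inherits the dynamic label of a
#' maximal-overlap predecessor; exact ties are broken by a fair coin
#' flip (uniformly at random under the recorded seed).  Otherwise it
#' starts a new id.
#'
#' @param G A [layered_graph()].
#' @param config A [cpm_config()].
#' @param cap Node guard forwarded to the clique enumerator.
#' @return A [community_assignment()]; the seed used is attached as
#'   attribute `seed`.
#' @export
cpm <- function(G, config, cap = 512L) {
  stopifnot(inherits(G, "layered_graph"), inherits(config, "cpm_config"))
  params <- plex_params(config$m, 1L)
  local_seed(config$seed, {
    next_id <- 0L
    vrows <- list()
    erows <- list()
    prev <- list()  # list of (nodes, dynamic id) at time t
    for (t in seq_len(G$N) - 1L) {
      ca <- static_communities(slice(G, t), params, cap = cap)
      cur <- list()
      for (cid in community_ids(ca)) {
        nodes <- ca$vertices$node[ca$vertices$community == cid]
        if (length(prev)) {
          ov <- vapply(prev, function(pr) length(intersect(pr$nodes, nodes)),
                       integer(1))
          best <- max(ov)
        } else {
          best <- 0L
        }
        if (best >= config$link_threshold) {
          cands <- which(ov == best)
          pick <- if (length(cands) > 1L) cands[sample.int(length(cands), 1L)]
                  else cands
          id <- prev[[pick]]$id
        } else {
          id <- next_id
          next_id <- next_id + 1L
        }
        cur[[length(cur) + 1L]] <- list(nodes = nodes, id = id)
        vrows[[length(vrows) + 1L]] <-
          data.frame(layer = t, node = nodes, community = id)
        e <- ca$edges[ca$edges$community == cid, , drop = FALSE]
        if (nrow(e)) {
          erows[[length(erows) + 1L]] <-
            data.frame(layer = t, u = e$u, v = e$v, community = id)
        }
      }
      prev <- cur
    }
    out <- canonicalize_ids(community_assignment(
      G$p, G$N,
      if (length(vrows)) do.call(rbind, vrows) else NULL,
      if (length(erows)) do.call(rbind, erows) else NULL))
    attr(out, "seed") <- config$seed
    out
  })
}

#' Empirical CPM label-inheritance frequencies
#'
#' Runs [cpm()] `reps` times with seeds `seed, seed + 1, ...` and
#' tabulates, per `(layer, node)`, how often each dynamic community
#' label was assigned.
#'
#' @param G A [layered_graph()].
#' @param config A [cpm_config()]; its `seed` starts the sequence.
#' @param reps Number of independent repetitions (>= 1).
#' @return Data frame with columns `layer`, `node`, `community`,
#'   `freq` (frequency in `[0, 1]` over repetitions).
#' @export
cpm_label_distribution <- function(G, config, reps) {
  reps <- as.integer(reps)
  stopifnot(reps >= 1L)
  acc <- list()
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    ca <- cpm(G, cfg)
    acc[[r]] <- ca$vertices
  }
  all <- do.call(rbind, acc)
  agg <- stats::aggregate(list(count = rep(1L, nrow(all))),
                          by = all[c("layer", "node", "community")], FUN = sum)
  agg$freq <- agg$count / reps
  agg$count <- NULL
  agg[order(agg$layer, agg$node, agg$community), , drop = FALSE]
}
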