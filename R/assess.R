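#' Largest detected community
#'
#' The community with the greatest total `(node, layer)` extent; ties
#' broken by smallest first layer, then smallest member node id, so the
#' selection is deterministic.
#'
#' @param ca A [community_assignment()].
#' @return The winning community id, or `NA` if no community exists.
#' @export
largest_community <- function(ca) {
  v <- ca$vertices
  if (!nrow(v)) return(NA_integer_)
  ids <- sort(unique(v$community))
  extent <- vapply(ids, function(id) sum(v$community == id), integer(1))
  first <- vapply(ids, function(id) min(v$layer[v$community == id]), integer(1))
  node0 <- vapply(ids, function(id) min(v$node[v$community == id]), integer(1))
  ids[order(-extent, first, node0)][1L]
}

# per-layer member sets of one community as list of node vectors
community_layers <- function(ca, id) {
  v <- ca$vertices[ca$vertices$community == id, , drop = FALSE]
  lapply(seq_len(ca$N) - 1L, function(t) sort(unique(v$node[v$layer == t])))
}

#' Sensitivity and specificity of the largest detected community
#'
#' Compares the largest identified community `c_L(t)` against the true
#' community trajectory `c_T(t)`, summing per-layer set counts over all
#' layers:
#' `TP = sum_t |c_T(t) n c_L(t)|`, `FN = sum_t |c_T(t) n ~c_L(t)|`,
#' `FP = sum_t |~c_T(t) n c_L(t)|`, `TN = sum_t |~c_T(t) n ~c_L(t)|`,
#' with complements taken within the common vertex set; then
#' `S+ = TP / (TP + FN)` and `S- = TN / (TN + FP)`.
#'
#' @param truth A [scenario_truth()], or a list of per-layer 0-based
#'   node vectors of length `N`.
#' @param detected A [community_assignment()] with matching `p`, `N`.
#' @param id Community to score; default the [largest_community()].
#' @return List with `S_plus`, `S_minus`, `TP`, `FN`, `FP`, `TN`, and
#'   logical `S_plus_defined` / `S_minus_defined` flags (0/0 cases).
#' @export
sensitivity_specificity <- function(truth, detected, id = NULL) {
  stopifnot(inherits(detected, "community_assignment"))
  if (inherits(truth, "scenario_truth")) {
    if (truth$p != detected$p || truth$N != detected$N) {
      stop("truth and detection dimensions differ")
    }
    tsets <- truth$true_community
  } else {
    tsets <- truth
    if (length(tsets) != detected$N) {
      stop("truth and detection dimensions differ")
    }
  }
  p <- detected$p
  if (is.null(id)) id <- largest_community(detected)
  lsets <- if (is.na(id)) replicate(detected$N, integer(0), simplify = FALSE)
           else community_layers(detected, id)
  TP <- FN <- FP <- TN <- 0L
  for (t in seq_len(detected$N)) {
    ct <- tsets[[t]]
    cl <- lsets[[t]]
    tp <- length(intersect(ct, cl))
    TP <- TP + tp
    FN <- FN + length(ct) - tp
    FP <- FP + length(cl) - tp
    TN <- TN + p - length(union(ct, cl))
  }
  list(S_plus = if (TP + FN > 0L) TP / (TP + FN) else NA_real_,
       S_minus = if (TN + FP > 0L) TN / (TN + FP) else NA_real_,
       S_plus_defined = TP + FN > 0L,
       S_minus_defined = TN + FP > 0L,
       TP = TP, FN = FN, FP = FP, TN = TN)
}

#' Per-layer Jaccard index of a community against truth
#'
#' @param truth As in [sensitivity_specificity()].
#' @param detected A [community_assignment()].
#' @param id Community to score; default the largest.
#' @param active_only Restrict to layers where the true community is
#'   non-empty (default).
#' @return Numeric vector of per-layer Jaccard indices.
#' @export
layer_jaccard <- function(truth, detected, id = NULL, active_only = TRUE) {
  if (inherits(truth, "scenario_truth")) truth <- truth$true_community
  if (is.null(id)) id <- largest_community(detected)
  lsets <- if (is.na(id)) replicate(detected$N, integer(0), simplify = FALSE)
           else community_layers(detected, id)
  out <- vapply(seq_len(detected$N), function(t) {
    ct <- truth[[t]]
    cl <- lsets[[t]]
    un <- length(union(ct, cl))
    if (un == 0L) NA_real_ else length(intersect(ct, cl)) / un
  }, numeric(1))
  if (active_only) {
    out <- out[vapply(truth, length, integer(1)) > 0L]
  }
  out
}

#' Lifespan and maximum size per community
#'
#' Lifespan is first-to-last layer inclusive (interior gaps count),
#' converted to seconds by `layer_seconds`; maximum size is the largest
#' per-layer member count.
#'
#' @param detected A [community_assignment()].
#' @param layer_seconds Duration one layer represents (1 for the
#'   simulations; 0.5 for networks inferred with 0.5 s hops).
#' @return Data frame with columns `community`, `first_layer`,
#'   `last_layer`, `lifespan`, `max_size`.
#' @export
community_stats <- function(detected, layer_seconds = 1) {
  ids <- community_ids(detected)
  v <- detected$vertices
  rows <- lapply(ids, function(id) {
    vi <- v[v$community == id, , drop = FALSE]
    per_layer <- table(vi$layer)
    data.frame(community = id,
               first_layer = min(vi$layer),
               last_layer = max(vi$layer),
               lifespan = (max(vi$layer) - min(vi$layer) + 1L) * layer_seconds,
               max_size = as.integer(max(per_layer)))
  })
  if (!length(rows)) {
    return(data.frame(community = integer(0), first_layer = integer(0),
                      last_layer = integer(0), lifespan = numeric(0),
                      max_size = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Node loyalty
#'
#' Fraction of layers at which each node carries at least one
#' qualifying community label.
#'
#' @param detected A [community_assignment()].
#' @param ids Communities to count (default: all).
#' @return Numeric vector of length `p`, values in `[0, 1]`.
#' @export
node_loyalty <- function(detected, ids = NULL) {
  v <- detected$vertices
  if (!is.null(ids)) v <- v[v$community %in% ids, , drop = FALSE]
  v <- unique(v[c("layer", "node")])
  counts <- tabulate(v$node + 1L, nbins = detected$p)
  counts / detected$N
}

#' Node recruitment order into a community
#'
#' First layer at which each node joins the target community, and the
#' corresponding rank (first joiner = 1; ties share the mean rank).
#' Nodes that never join get `NA`.
#'
#' @param detected A [community_assignment()].
#' @param id Target community id.
#' @return Data frame with columns `node`, `first_layer`, `rank`.
#' @export
recruitment_order <- function(detected, id) {
  v <- detected$vertices[detected$vertices$community == id, , drop = FALSE]
  if (!nrow(v)) stop(sprintf("unknown community id %s", id))
  first <- rep(NA_integer_, detected$p)
  agg <- tapply(v$layer, v$node, min)
  first[as.integer(names(agg)) + 1L] <- as.integer(agg)
  rk <- rep(NA_real_, detected$p)
  ok <- !is.na(first)
  rk[ok] <- rank(first[ok], ties.method = "average")
  data.frame(node = seq_len(detected$p) - 1L, first_layer = first, rank = rk)
}

#' Median recruitment across runs
#'
#' Reduces per-run first-join layers (as produced by
#' [recruitment_order()]) to a per-node median, ignoring runs in which
#' a node never joined; nodes that never join in any run stay `NA`.
#'
#' @param first_layers List of numeric vectors (one per run, length
#'   `p`, `NA` = never joined).
#' @return Numeric vector of per-node medians.
#' @export
median_recruitment <- function(first_layers) {
  stopifnot(length(first_layers) >= 1L)
  mat <- do.call(cbind, first_layers)
  apply(mat, 1L, function(x) {
    if (all(is.na(x))) NA_real_ else median(x, na.rm = TRUE)
  })
}
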