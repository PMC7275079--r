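#' Enhanced two-slice (bislice) graph
#'
#' Builds the 2p-vertex graph over two adjacent layers on which plexes
#' walk across time.  Vertices `0 ... p-1` are the slice-t copies and
#' `p ... 2p-1` the slice-(t+1) copies.  Edge classes:
#' * `observed` — the edges of each slice, reproduced exactly;
#' * `self` — one maturation edge `v_t — v_(t+1)` per vertex;
#' * `railroad` — the mirrored pair `u_t — v_(t+1)`, `v_t — u_(t+1)`
#'   for every edge present in both slices.
#'
#' @param g_t,g_t1 Two [sgraph()] slices with the same `p`.
#' @return An object of class `bislice`: an [sgraph()] on `2p` vertices
#'   plus an edge-class vector and the persistent edge set.
#' @export
build_bislice <- function(g_t, g_t1) {
  stopifnot(inherits(g_t, "sgraph"), inherits(g_t1, "sgraph"))
  if (g_t$p != g_t1$p) stop("bislice requires slices with matching p")
  p <- g_t$p
  e0 <- g_t$edges
  e1 <- g_t1$edges
  pers <- shared_edges(e0, e1, p)
  obs0 <- e0
  obs1 <- e1 + p
  self <- cbind(seq_len(p) - 1L, seq_len(p) - 1L + p)
  rail <- if (nrow(pers)) {
    rbind(cbind(pers[, 1L], pers[, 2L] + p),
          cbind(pers[, 2L], pers[, 1L] + p))
  } else {
    matrix(integer(0), ncol = 2L)
  }
  edges <- rbind(obs0, obs1, self, rail)
  class_vec <- c(rep("observed", nrow(obs0) + nrow(obs1)),
                 rep("self", nrow(self)),
                 rep("railroad", nrow(rail)))
  side <- c(rep(0L, nrow(obs0)), rep(1L, nrow(obs1)),
            rep(NA_integer_, nrow(self) + nrow(rail)))
  g <- sgraph(2L * p, edges)
  structure(list(p = p, graph = g, edges = edges, class = class_vec,
                 side = side, persistent = pers),
            class = "bislice")
}

#' @export
print.bislice <- function(x, ...) {
  tab <- table(x$class)
  cat(sprintf("<bislice> 2x%d vertices; %s\n", x$p,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Admissible maximal k-plexes of a bislice graph
#'
#' Enumerates the maximal k-plexes (size >= m) of the enhanced
#' two-slice graph, then applies the cross-slice admissibility rule:
#' a plex with vertices on both sides must contain at least one
#' railroad edge — self (maturation) edges alone must not bridge time,
#' since railroads are what certify an edge persisted across the two
#' slices.  Single-side plexes pass unfiltered.  For `m - k >= 2` the
#' rule is vacuous — the degree condition already forces railroads —
#' but it is what keeps the degenerate regime `m - k <= 1` from
#' over-merging.
#'
#' @param B A [build_bislice()] result.
#' @param params A [plex_params()].
#' @param admissibility Apply the rule (default); `FALSE` returns all
#'   maximal plexes.
#' @param cap Node guard forwarded to the enumerator (counts 2p).
#' @return List of sorted integer vectors over the 2p bislice vertices.
#' @export
admissible_bislice_plexes <- function(B, params, admissibility = TRUE,
                                      cap = 1024L) {
  stopifnot(inherits(B, "bislice"))
  plexes <- enumerate_maximal_kplexes(B$graph, params, cap = cap)
  if (!admissibility || !length(plexes)) return(plexes)
  p <- B$p
  rail <- B$edges[B$class == "railroad", , drop = FALSE]
  keep <- vapply(plexes, function(S) {
    left <- S[S < p]
    right <- S[S >= p]
    if (!length(left) || !length(right)) return(TRUE)
    any(rail[, 1L] %in% left & rail[, 2L] %in% right)
  }, logical(1))
  plexes[keep]
}
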