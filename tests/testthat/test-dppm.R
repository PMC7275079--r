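test_that("the toy ladder separates the three shared-edge scenarios", {
  cfg <- dppm_config(plex_params(3, 2))
  expect_equal(n_communities(dppm(toy_fixture("edges7"), cfg)), 3L)
  expect_equal(n_communities(dppm(toy_fixture("edges8"), cfg)), 2L)
  expect_equal(n_communities(dppm(toy_fixture("edges9"), cfg)), 1L)
})

test_that("a persistent clique forms one community spanning all layers", {
  G <- constant_k4(5L)
  ca <- dppm(G, dppm_config(plex_params(4, 2)))
  expect_equal(n_communities(ca), 1L)
  expect_equal(nrow(ca$vertices), 4L * 5L)  # every (node, layer) labeled
})

test_that("label propagation is a fixed point and order independent", {
  frag <- function(t, nodes, eu = integer(0), ev = integer(0)) {
    list(vertices = data.frame(layer = t, node = nodes),
         edges = data.frame(layer = rep(t[1], length(eu)), u = eu, v = ev))
  }
  # chain of bislice fragments sharing one persistent edge per junction
  chain <- list(frag(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L), 0L, 1L),
                frag(c(1L, 1L, 2L, 2L), c(0L, 1L, 0L, 1L), 0L, 1L),
                frag(c(2L, 2L, 3L, 3L), c(0L, 1L, 0L, 1L), 0L, 1L))
  chain[[1]]$edges <- data.frame(layer = c(0L, 1L), u = c(0L, 0L), v = c(1L, 1L))
  chain[[2]]$edges <- data.frame(layer = c(1L, 2L), u = c(0L, 0L), v = c(1L, 1L))
  chain[[3]]$edges <- data.frame(layer = c(2L, 3L), u = c(0L, 0L), v = c(1L, 1L))
  ca <- propagate_labels(chain, m = 4L, p = 4L, N = 4L)
  expect_equal(n_communities(ca), 1L)
  ca_rev <- propagate_labels(rev(chain), m = 4L, p = 4L, N = 4L)
  expect_equal(n_communities(ca_rev), 1L)

  # fragments sharing only one vertex at the common slice (m = 4): no merge
  a <- frag(c(0L, 0L, 0L), c(0L, 1L, 2L))
  b <- frag(c(0L, 0L, 0L), c(2L, 3L, 4L))
  ca <- propagate_labels(list(a, b), m = 4L, p = 5L, N = 1L)
  expect_equal(n_communities(ca), 2L)

  # no fragments: empty assignment
  expect_equal(n_communities(propagate_labels(list(), 4L, 3L, 2L)), 0L)
})

test_that("dynamic communities are symmetric under time reversal", {
  cfg <- dppm_config(plex_params(3, 2))
  for (variant in c("edges7", "edges8", "edges9")) {
    G <- toy_fixture(variant)
    Grev <- layered_graph(G$p, rev(G$layers))
    ca <- dppm(G, cfg)
    car <- dppm(Grev, cfg)
    expect_equal(n_communities(ca), n_communities(car))
    flipped <- car$vertices
    flipped$layer <- G$N - 1L - flipped$layer
    expect_equal(
      canon_sets(unname(split(flipped$layer * G$p + flipped$node,
                              flipped$community))),
      canon_sets(unname(split(ca$vertices$layer * G$p + ca$vertices$node,
                              ca$vertices$community))))
  }
})

test_that("communities coalesce while bridged and fragment when not", {
  # K4 on {0..3} splits into two triangles that drift apart:
  # layer0: K4; layer1: K4 (persists, one community so far);
  # layer2: triangles {0,1,2} and {3,4,5} with no shared edge to layer 1
  # beyond the first triangle's edges
  k4 <- rbind(c(0, 1), c(0, 2), c(0, 3), c(1, 2), c(1, 3), c(2, 3))
  tri_a <- rbind(c(0, 1), c(0, 2), c(1, 2))
  tri_b <- rbind(c(3, 4), c(3, 5), c(4, 5))
  G <- layered_graph(6, list(k4, k4, rbind(tri_a, tri_b)))
  ca <- dppm(G, dppm_config(plex_params(3, 1)))
  # the K4 community continues into triangle {0,1,2}; {3,4,5} is new
  expect_equal(n_communities(ca), 2L)
  big <- largest_community(ca)
  v <- ca$vertices
  expect_true(all(0:3 %in% v$node[v$layer == 0L & v$community == big]))
  expect_equal(sort(v$node[v$layer == 2L & v$community == big]), 0:2)
})

test_that("dppm output is deterministic", {
  G <- toy_fixture("edges8")
  cfg <- dppm_config(plex_params(3, 2))
  a <- dppm(G, cfg)
  b <- dppm(G, cfg)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$edges, b$edges)
})

test_that("the degenerate regime without admissibility warns loudly", {
  G <- toy_fixture("edges7")
  cfg <- dppm_config(plex_params(3, 2), cross_slice_admissibility = FALSE)
  expect_warning(dppm(G, cfg), "over-merge")
})

test_that("heuristic mode agrees with exact walking on persistent structure", {
  # On a perfectly persistent network every slice community simply
  # continues, and the cheap overlap heuristic must reach the same
  # answer as formal bislice walking.  On noisy or independent layers
  # the modes legitimately diverge (the heuristic trades cross-slice
  # plex detail for speed), so there the discrepancy is only recorded.
  set.seed(47)
  for (mk in list(c(4, 2), c(5, 3))) {
    for (rep in 1:4) {
      # vertex-disjoint cliques of size >= m, constant across layers
      sizes <- sample(mk[1]:(mk[1] + 2L), sample(2:3, 1), replace = TRUE)
      p <- sum(sizes) + sample(0:3, 1)
      perm <- sample.int(p) - 1L
      edges <- NULL
      off <- 0L
      for (s in sizes) {
        mem <- perm[(off + 1L):(off + s)]
        edges <- rbind(edges, t(combn(sort(mem), 2L)))
        off <- off + s
      }
      N <- sample(3:5, 1)
      G <- layered_graph(p, replicate(N, edges, simplify = FALSE))
      ex <- dppm(G, dppm_config(plex_params(mk[1], mk[2]), mode = "exact"))
      he <- dppm(G, dppm_config(plex_params(mk[1], mk[2]), mode = "heuristic"))
      expect_identical(ex$vertices, he$vertices)
      expect_equal(n_communities(ex), length(sizes))
    }
  }
  # record (not bound) the discrepancy rate on independent random layers
  iid_differ <- 0L
  for (rep in 1:8) {
    Gi <- layered_graph(9L, replicate(3, random_sgraph(9L, 0.45)$edges,
                                      simplify = FALSE))
    ex <- dppm(Gi, dppm_config(plex_params(4, 2), mode = "exact"))
    he <- dppm(Gi, dppm_config(plex_params(4, 2), mode = "heuristic"))
    if (!identical(ex$vertices, he$vertices)) iid_differ <- iid_differ + 1L
  }
  expect_lte(iid_differ, 8L)
})
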