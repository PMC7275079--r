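test_that("layered edge-list parsing canonicalizes rows and fills empty layers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("layer\tu\tv", "0\t1\t2", "0\t2\t3", "1\t1\t2"), path)
  G <- read_layered_edgelist(path)
  expect_equal(G$p, 4L)
  expect_equal(G$N, 2L)
  expect_equal(nrow(G$layers[[1]]), 2L)
  expect_equal(nrow(G$layers[[2]]), 1L)

  # duplicate rows in either orientation collapse to one canonical edge
  writeLines(c("layer\tu\tv", "0\t1\t2", "0\t2\t1"), path)
  G <- read_layered_edgelist(path)
  expect_equal(unname(G$layers[[1]]), cbind(1L, 2L))

  # a layer gap becomes an empty layer; #nodes overrides p
  writeLines(c("#nodes=10", "layer\tu\tv", "0\t0\t1", "2\t0\t1"), path)
  G <- read_layered_edgelist(path)
  expect_equal(G$N, 3L)
  expect_equal(nrow(G$layers[[2]]), 0L)
  expect_equal(G$p, 10L)
})

test_that("malformed edge lists are rejected with a usable diagnostic", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("layer\tu\tv", "0\t1\t2", "0\t5\t5"), path)
  expect_error(read_layered_edgelist(path), "self-loop at data line 2")
  writeLines(c("layer\tu\tv", "0\t-1\t2"), path)
  expect_error(read_layered_edgelist(path), "negative")
  writeLines(c("u\tv"), path)
  expect_error(read_layered_edgelist(path), "header")
})

test_that("layered graph round-trips through the TSV format", {
  set.seed(11)
  for (rep in 1:5) {
    p <- sample(4:10, 1)
    N <- sample(1:6, 1)
    G <- layered_graph(p, replicate(N, random_sgraph(p, 0.4)$edges,
                                    simplify = FALSE))
    path <- withr::local_tempfile(fileext = ".tsv")
    write_layered_edgelist(G, path)
    G2 <- read_layered_edgelist(path)
    expect_equal(G2$p, G$p)
    expect_equal(G2$N, G$N)
    for (t in seq_len(N)) {
      expect_equal(unname(G2$layers[[t]]), unname(G$layers[[t]]))
    }
  }
})

test_that("graph equality is invariant to row order and edge orientation", {
  e1 <- rbind(c(0, 1), c(2, 1), c(0, 3))
  e2 <- rbind(c(3, 0), c(1, 0), c(1, 2))
  expect_equal(sgraph(4, e1)$edges, sgraph(4, e2)$edges)
})

test_that("community labels round-trip with multi-membership preserved", {
  v <- data.frame(layer = c(5L, 5L, 0L), node = c(3L, 3L, 0L),
                  community = c(7L, 9L, 7L))
  ca <- community_assignment(8L, 6L, v)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_communities(ca, path)
  lines <- readLines(path)
  expect_true(all(c("5\t3\t7", "5\t3\t9") %in% lines))
  back <- read_communities(path)
  expect_equal(back$vertices, ca$vertices)
  expect_equal(back$p, 8L)
  expect_equal(back$N, 6L)

  # empty assignment writes a header-only file and reads back empty
  empty <- community_assignment(4L, 2L, NULL)
  write_communities(empty, path)
  body <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  expect_equal(body, "layer\tnode\tcommunity_id")
  expect_equal(nrow(read_communities(path)$vertices), 0L)
})

test_that("community round-trip holds on randomized assignments", {
  set.seed(21)
  for (rep in 1:5) {
    p <- sample(5:12, 1)
    N <- sample(2:5, 1)
    n <- sample(10:40, 1)
    v <- unique(data.frame(layer = sample(0:(N - 1), n, TRUE),
                           node = sample(0:(p - 1), n, TRUE),
                           community = sample(0:4, n, TRUE)))
    ca <- community_assignment(p, N, v)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_communities(ca, path)
    expect_equal(read_communities(path)$vertices, ca$vertices)
  }
})

test_that("degree and induced minimum degree follow the plex arithmetic", {
  tri <- sgraph(3, rbind(c(0, 1), c(0, 2), c(1, 2)))
  expect_equal(induced_min_degree(tri, 0:2), 2L)
  path3 <- sgraph(3, rbind(c(0, 1), c(1, 2)))
  expect_equal(induced_min_degree(path3, 0:2), 1L)
  expect_equal(induced_min_degree(path3, 0L), 0L)
  expect_equal(graph_degree(path3, 1L), 2L)
  expect_error(induced_min_degree(tri, integer(0)), "non-empty")
})

test_that("stacked adjacency arrays convert to layered graphs", {
  a <- array(0, c(2, 3, 3))
  a[1, 1, 2] <- a[1, 2, 1] <- 1
  a[2, 2, 3] <- 1
  G <- as_layered_graph(a)
  expect_equal(G$N, 2L)
  expect_equal(unname(G$layers[[1]]), cbind(0L, 1L))
  expect_equal(unname(G$layers[[2]]), cbind(1L, 2L))
})

test_that("community view materializes extent and bounds", {
  v <- data.frame(layer = c(1L, 2L, 2L), node = c(0L, 0L, 3L),
                  community = 0L)
  ca <- community_assignment(5L, 4L, v)
  cv <- community_view(ca, 0L)
  expect_equal(cv$first_layer, 1L)
  expect_equal(cv$last_layer, 2L)
  expect_equal(cv$members[[3]], c(0L, 3L))
  expect_error(community_view(ca, 99L), "unknown")
})
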