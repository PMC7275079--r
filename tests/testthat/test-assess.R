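test_that("sensitivity and specificity follow the printed set formulas", {
  # perfect detection
  truth <- list(c(0L, 1L), c(0L, 1L, 2L))
  v <- data.frame(layer = c(0L, 0L, 1L, 1L, 1L), node = c(0L, 1L, 0L, 1L, 2L),
                  community = 0L)
  ca <- community_assignment(4L, 2L, v)
  r <- sensitivity_specificity(truth, ca)
  expect_equal(r$S_plus, 1)
  expect_equal(r$S_minus, 1)

  # nothing detected: S+ = 0 by convention, S- = 1
  empty <- community_assignment(4L, 2L, NULL)
  r <- sensitivity_specificity(truth, empty)
  expect_equal(r$S_plus, 0)
  expect_equal(r$S_minus, 1)

  # worked single-layer example: c_T = {1,2,3}, c_L = {2,3,4} on p = 6
  truth <- list(c(1L, 2L, 3L))
  ca <- community_assignment(6L, 1L, data.frame(layer = 0L, node = c(2L, 3L, 4L),
                                                community = 0L))
  r <- sensitivity_specificity(truth, ca)
  expect_equal(c(r$TP, r$FN, r$FP, r$TN), c(2L, 1L, 1L, 2L))
  expect_equal(r$S_plus, 2 / 3)
  expect_equal(r$S_minus, 2 / 3)
})

test_that("confusion cells always sum to p * N and match a direct count", {
  set.seed(83)
  for (rep in 1:20) {
    p <- sample(5:12, 1)
    N <- sample(1:6, 1)
    truth <- lapply(seq_len(N), function(t)
      sort(sample(0:(p - 1), sample(0:p, 1))))
    n <- sample(5:30, 1)
    v <- unique(data.frame(layer = sample(0:(N - 1), n, TRUE),
                           node = sample(0:(p - 1), n, TRUE),
                           community = sample(0:2, n, TRUE)))
    ca <- community_assignment(p, N, v)
    r <- sensitivity_specificity(truth, ca)
    expect_equal(r$TP + r$FN + r$FP + r$TN, p * N)
    # direct per-element recount
    id <- largest_community(ca)
    tp <- 0L
    for (t in seq_len(N) - 1L) {
      cl <- v$node[v$layer == t & v$community == id]
      tp <- tp + length(intersect(truth[[t + 1L]], cl))
    }
    expect_equal(r$TP, tp)
  }
})

test_that("scores are invariant to community id relabeling", {
  set.seed(89)
  p <- 8L
  N <- 4L
  truth <- lapply(seq_len(N), function(t) sort(sample(0:7, 4)))
  v <- unique(data.frame(layer = sample(0:3, 30, TRUE),
                         node = sample(0:7, 30, TRUE),
                         community = sample(c(0L, 5L), 30, TRUE)))
  ca <- community_assignment(p, N, v)
  v2 <- v
  v2$community <- ifelse(v$community == 0L, 10L, 2L)
  ca2 <- community_assignment(p, N, v2)
  r1 <- sensitivity_specificity(truth, ca)
  r2 <- sensitivity_specificity(truth, ca2)
  expect_equal(r1$S_plus, r2$S_plus)
  expect_equal(r1$S_minus, r2$S_minus)
})

test_that("largest-community selection follows the tie ladder", {
  # equal extent: smaller first layer wins, then smaller node id
  v <- data.frame(layer = c(1L, 1L, 0L, 0L), node = c(0L, 1L, 3L, 4L),
                  community = c(7L, 7L, 9L, 9L))
  ca <- community_assignment(6L, 2L, v)
  expect_equal(largest_community(ca),
               ca$vertices$community[ca$vertices$layer == 0L][1])
})

test_that("community lifespan and size statistics convert layers to seconds", {
  v <- data.frame(layer = c(10:29, 5L), node = c(rep(0L, 20), 2L),
                  community = c(rep(0L, 20), 1L))
  ca <- community_assignment(4L, 40L, v)
  st <- community_stats(ca, layer_seconds = 0.5)
  expect_equal(st$lifespan[st$community == 0L], 10)
  expect_equal(st$lifespan[st$community == 1L], 0.5)  # single layer
  st_k4 <- community_stats(dppm(constant_k4(5L),
                                dppm_config(plex_params(4, 2))))
  expect_equal(st_k4$max_size, 4L)
  expect_equal(st_k4$lifespan, 5)
})

test_that("node loyalty is the labeled-layer fraction", {
  v <- data.frame(layer = 0:49, node = 1L, community = 0L)
  ca <- community_assignment(3L, 100L, v)
  expect_equal(node_loyalty(ca), c(0, 0.5, 0))
  # randomized cross-check against a direct per-layer count
  set.seed(97)
  v <- unique(data.frame(layer = sample(0:9, 40, TRUE),
                         node = sample(0:4, 40, TRUE),
                         community = sample(0:3, 40, TRUE)))
  ca <- community_assignment(5L, 10L, v)
  want <- vapply(0:4, function(n)
    length(unique(v$layer[v$node == n])) / 10, numeric(1))
  expect_equal(node_loyalty(ca), want)
})

test_that("recruitment order uses mid-ranks and propagates missingness", {
  v <- data.frame(layer = c(2L, 2L, 7L), node = 0:2, community = 5L)
  ca <- community_assignment(4L, 10L, v)
  ro <- recruitment_order(ca, 5L)
  expect_equal(ro$rank[1:3], c(1.5, 1.5, 3))
  expect_true(is.na(ro$first_layer[4]))
  expect_true(is.na(ro$rank[4]))
  expect_error(recruitment_order(ca, 42L), "unknown")

  expect_equal(median_recruitment(list(c(3, NA), c(5, NA), c(9, NA))),
               c(5, NA))
})
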