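test_that("the simple ratio index hits its boundary semantics", {
  # always together -> 1; never together -> 0; half of occasions -> 0.5
  expect_equal(simple_ratio_index(5, 0, 0, 0), 1)
  expect_equal(simple_ratio_index(0, 0, 2, 1), 0)
  expect_equal(simple_ratio_index(2, 0, 1, 1), 0.5)
  expect_error(simple_ratio_index(0, 0, 0, 0), "undefined")
  expect_error(simple_ratio_index(-1, 0, 0, 0), "nonnegative")
})

test_that("sri_counts matches the trivial cases and errors on unknowns", {
  m <- make_membership(list(c("A", "B"), c("A", "B"), c("A", "B"),
                            c("A", "B"), c("A", "B")))
  expect_equal(sri_counts(m, "A", "B"),
               c(x = 5, y_ab = 0, y_a = 0, y_b = 0))
  m2 <- make_membership(list("A", "A", "B"))
  expect_equal(sri_counts(m2, "A", "B"),
               c(x = 0, y_ab = 0, y_a = 2, y_b = 1))
  expect_error(sri_counts(m2, "A", "Z"), "'Z'")
  expect_error(sri_counts(m2, "A", "A"), "differ")
})

test_that("sri_counts matches exhaustive enumeration on random tables", {
  set.seed(97)
  for (case in 1:30) {
    m <- rand_membership(sample(3:10, 1), sample(3:6, 1))
    birds <- colnames(m)
    pair <- sample(birds, 2)
    expect_identical(sri_counts(m, pair[1], pair[2]),
                     brute_sri_counts(m, pair[1], pair[2]))
  }
})

test_that("time-overlapping groups at one feeder populate y_AB", {
  ev <- data.frame(feeder_id = c("F1", "F1", "F2"),
                   start_s = c(0, 50, 0), end_s = c(100, 150, 100))
  m <- make_membership(list("A", "B", "A"), events = ev)
  # A in G1 while B is in the overlapping G2 -> both contribute to y_AB;
  # A's read at F2 has no overlapping group -> y_A
  expect_equal(sri_counts(m, "A", "B"),
               c(x = 0, y_ab = 2, y_a = 1, y_b = 0))
  expect_identical(sri_counts(m, "A", "B"), brute_sri_counts(m, "A", "B"))
  # non-overlapping events leave y_AB at zero
  ev2 <- data.frame(feeder_id = c("F1", "F1"),
                    start_s = c(0, 500), end_s = c(100, 600))
  m2 <- make_membership(list("A", "B"), events = ev2)
  expect_equal(unname(sri_counts(m2, "A", "B")["y_ab"]), 0)
})

test_that("the minimum-group filter drops below-threshold birds once", {
  groups <- c(rep(list(c("A", "B")), 4), list(c("B", "C")))
  m <- make_membership(groups)
  f <- apply_min_group_filter(m, min_groups = 5)
  expect_false("A" %in% colnames(f))  # 4 groups -> dropped
  expect_true("B" %in% colnames(f))   # 5 groups -> retained
  expect_false("C" %in% colnames(f))
  # identity when min_groups = 1 and no empty groups
  expect_equal(dim(apply_min_group_filter(m, 1)), dim(m))
  # idempotence on its own output
  expect_identical(apply_min_group_filter(f, 5), f)
})

test_that("network building matches brute-force SRI over all pairs", {
  set.seed(131)
  for (case in 1:10) {
    m <- rand_membership(sample(6:12, 1), sample(3:6, 1), p = 0.5)
    net <- suppressWarnings(build_network(m, "w", min_groups = 1))
    for (a in net$birds) for (b in net$birds) {
      if (a == b) next
      cn <- brute_sri_counts(m, a, b)
      expect_equal(net$sri[a, b],
                   cn["x"] / sum(cn), ignore_attr = TRUE)
    }
    expect_true(isSymmetric(net$sri))
    expect_true(all(net$sri >= 0 & net$sri <= 1))
  }
})

test_that("two birds always together share an edge of exactly 1", {
  m <- make_membership(rep(list(c("A", "B")), 6))
  net <- build_network(m, "w", min_groups = 5)
  expect_equal(net$sri["A", "B"], 1)
  el <- as_edge_list(net)
  expect_equal(nrow(el), 1)
  expect_equal(el$sri, 1)
})

test_that("SRI moves in the right direction as observations accrue", {
  base <- rep(list(c("A", "B")), 3)
  m0 <- make_membership(c(base, list("A")), birds = c("A", "B"))
  m_joint <- make_membership(c(base, list("A"), list(c("A", "B"))),
                             birds = c("A", "B"))
  m_lone <- make_membership(c(base, list("A"), list("A")),
                            birds = c("A", "B"))
  s0 <- build_network(m0, "w", 1)$sri["A", "B"]
  expect_gte(build_network(m_joint, "w", 1)$sri["A", "B"], s0)
  expect_lte(build_network(m_lone, "w", 1)$sri["A", "B"], s0)
})

test_that("a filtered network warns and degrades gracefully", {
  m <- make_membership(list(c("A", "B"), c("A", "B")))
  expect_warning(net <- build_network(m, "w", min_groups = 5), "fewer")
  expect_equal(length(net$birds), 0)
  expect_equal(nrow(as_edge_list(net)), 0)
})

test_that("pooling deployments sums group counts before filtering", {
  mk <- function(prefix, groups) {
    m <- make_membership(groups)
    rownames(m) <- paste0(prefix, seq_len(nrow(m)))
    m
  }
  d1 <- mk("a", rep(list(c("A", "B")), 2))
  d2 <- mk("b", rep(list(c("A", "C")), 2))
  d3 <- mk("c", rep(list(c("A", "B")), 2))
  pooled <- pool_deployments(list(d1, d2, d3))
  expect_equal(unname(colSums(pooled)[c("A", "B", "C")]), c(6L, 4L, 2L))
  # 2+2+2 groups -> retained at the seasonal threshold; 4+0+0 -> dropped
  f <- apply_min_group_filter(pooled, 5)
  expect_true("A" %in% colnames(f))
  expect_false("B" %in% colnames(f))
  # counting then summing equals pooling then counting
  expect_equal(colSums(pooled)[colnames(d1)],
               colSums(d1) + colSums(d3)[colnames(d1)] +
                 c(A = 2, B = 0))
  expect_error(pool_deployments(list(d1, d1)), "duplicated")
})

test_that("GraphML export writes a readable graph", {
  m <- make_membership(rep(list(c("A", "B"), c("B", "C"), c("A", "C")), 3))
  net <- build_network(m, "w", min_groups = 5)
  td <- withr::local_tempdir()
  path <- write_graphml(net, file.path(td, "net.graphml"))
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), nrow(as_edge_list(net)))
})
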