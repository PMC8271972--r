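toy_union <- function() {
  parts <- toy_participants()
  nets <- list(
    fake_network("stroke_1", 1L, list(c(1, 2), c(2, 3), c(1, 4))),
    fake_network("stroke_1", 2L, list(c(1, 2))),
    fake_network("stroke_2", 1L, list(c(1, 2), c(2, 3))),
    fake_network("stroke_3", 1L, list(c(5, 6))),
    fake_network("ctrl_1_L", 1L, list(c(2, 3), c(3, 4))),
    fake_network("ctrl_1_R", 2L, list())
  )
  list(u = build_union_set(nets, fake_cohort_meta(parts)), nets = nets,
       parts = parts)
}

test_that("the union set is a provenance-tagged multiset of all edges", {
  tu <- toy_union()
  expect_s3_class(tu$u, "union_edge_set")
  expect_equal(nrow(tu$u), 3 + 1 + 2 + 1 + 2 + 0)
  one <- build_union_set(tu$nets[3], fake_cohort_meta(tu$parts))
  expect_equal(nrow(one), 2)
  empty <- build_union_set(list(), fake_cohort_meta(tu$parts))
  expect_equal(nrow(empty), 0)
  expect_error(
    build_union_set(list(fake_network("ghost", 1L, list(c(1, 2)))),
                    fake_cohort_meta(tu$parts)),
    class = "kinegraph_provenance_error"
  )
})

test_that("domain filtering keeps exactly the matching records", {
  tu <- toy_union()
  f <- filter_edges(tu$u, edge_filter("strokeL", 1L))
  expect_true(all(f$participant %in% c("stroke_1", "stroke_2")))
  expect_true(all(f$movement == 1L))
  expect_equal(nrow(f), 5)

  # full domain is the identity
  full <- filter_edges(tu$u, edge_filter(movements = 1:3))
  expect_equal(nrow(full), nrow(tu$u))

  # an individual with no networks yields an empty set
  none <- filter_edges(tu$u, edge_filter(movements = 1:3,
                                         individuals = "stroke_99"))
  expect_equal(nrow(none), 0)

  expect_error(filter_edges(tu$u, edge_filter("strokeL", 9L)),
               class = "kinegraph_domain_error")
})

test_that("disjoint domains partition the union set", {
  tu <- toy_union()
  doms <- lapply(c("strokeL", "strokeR", "ctrlL", "ctrlR"), function(g)
    filter_edges(tu$u, edge_filter(g, 1:3)))
  expect_equal(sum(vapply(doms, nrow, 1L)), nrow(tu$u))
})

test_that("edge support matches brute-force counting on random toy sets", {
  set.seed(30)
  parts <- toy_participants()
  meta <- fake_cohort_meta(parts)
  all_pairs <- utils::combn(6, 2, simplify = FALSE)
  for (r in 1:25) {
    nets <- list()
    for (p in parts$id) for (m in 1:3) {
      pick <- all_pairs[runif(15) < 0.3]
      nets[[length(nets) + 1]] <- fake_network(p, m, pick)
    }
    u <- build_union_set(nets, meta)
    groups <- sample(c("strokeL", "strokeR", "ctrlL", "ctrlR"),
                     sample(1:3, 1))
    movements <- sort(sample(1:3, sample(1:3, 1)))
    spec <- edge_filter(groups, movements)
    for (pair in sample(all_pairs, 4)) {
      expect_identical(
        edge_support(u, spec, pair),
        brute_support(nets, pair, parts, groups, movements)
      )
    }
  }
})

test_that("support never exceeds the number of in-domain networks", {
  tu <- toy_union()
  spec <- edge_filter(c("strokeL", "strokeR"), 1:2)
  dom <- filter_edges(tu$u, spec)
  n_networks <- nrow(dplyr::distinct(dom, participant, movement))
  for (pair in list(c(1, 2), c(2, 3), c(5, 6), c(1, 6))) {
    expect_lte(edge_support(tu$u, spec, pair), n_networks)
  }
})

test_that("top-K ranking is support-descending with lexicographic ties", {
  tu <- toy_union()
  spec <- edge_filter(c("strokeL", "strokeR", "ctrlL", "ctrlR"), 1:3)
  top1 <- most_prevalent_edges(tu$u, spec, k = 1)
  expect_equal(top1$angle_i, 1)
  expect_equal(top1$angle_j, 2)
  expect_equal(top1$support, 3L)
  top2 <- most_prevalent_edges(tu$u, spec, k = 2)
  expect_equal(top2$support, c(3L, 3L))
  # (1,2) and (2,3) tie at 3; lexicographic order breaks the tie
  expect_equal(c(top2$angle_i[2], top2$angle_j[2]), c(2, 3))
  # ordering matches a sorted brute-force support table
  all_pairs <- utils::combn(6, 2, simplify = FALSE)
  sup <- vapply(all_pairs, function(p) brute_support(tu$nets, p), 1L)
  want <- order(-sup, vapply(all_pairs, min, 1), vapply(all_pairs, max, 1))
  topk <- most_prevalent_edges(tu$u, spec, k = 5)
  for (i in 1:5) {
    expect_equal(c(topk$angle_i[i], topk$angle_j[i]),
                 sort(all_pairs[[want[i]]]))
  }
})

test_that("group-exclusive pairs partition the distinct pairs of both domains", {
  tu <- toy_union()
  sa <- edge_filter(c("strokeL", "strokeR"), 1:3)
  sb <- edge_filter(c("ctrlL", "ctrlR"), 1:3)
  res <- group_exclusive_edges(tu$u, sa, sb)
  key <- function(d) paste(d$angle_i, d$angle_j)
  expect_length(intersect(key(res$only_a), key(res$only_b)), 0)
  all_keys <- sort(unique(key(dplyr::distinct(tu$u, angle_i, angle_j))))
  expect_equal(sort(c(key(res$only_a), key(res$only_b), key(res$shared))),
               all_keys)
  expect_equal(key(res$shared), "2 3")
  # identical domains have no exclusive pairs
  same <- group_exclusive_edges(tu$u, sa, sa)
  expect_equal(nrow(same$only_a), 0)
  expect_equal(nrow(same$only_b), 0)

  # worked set-algebra example
  parts <- toy_participants()
  nets <- list(fake_network("stroke_1", 1L, list(c(1, 2), c(2, 3))),
               fake_network("ctrl_1_L", 1L, list(c(2, 3), c(3, 4))))
  u <- build_union_set(nets, fake_cohort_meta(parts))
  r <- group_exclusive_edges(u, edge_filter("strokeL", 1L),
                             edge_filter("ctrlL", 1L))
  expect_equal(key(r$only_a), "1 2")
  expect_equal(key(r$only_b), "3 4")
  expect_equal(key(r$shared), "2 3")
})

test_that("apply_edge_filter dispatches on mode", {
  tu <- toy_union()
  sa <- edge_filter(c("strokeL", "strokeR"), 1:3, mode = "differences")
  sb <- edge_filter(c("ctrlL", "ctrlR"), 1:3)
  res <- apply_edge_filter(tu$u, sa, sb)
  expect_named(res, c("only_a", "only_b", "shared"))
  shared <- apply_edge_filter(
    tu$u, edge_filter(c("strokeL", "strokeR"), 1:3, mode = "intersection"), sb)
  expect_equal(nrow(shared), 1)
  topk <- apply_edge_filter(
    tu$u, edge_filter(c("strokeL", "strokeR"), 1:3, mode = "topk", k = 2))
  expect_equal(nrow(topk), 2)
})
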