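test_that("series measures agree with brute-force definitions", {
  expect_equal(series_measures(c(1, 2, 3))$mean, 2)
  expect_equal(series_measures(c(1, 2))$energy, 5)
  expect_equal(series_measures(rep(4.2, 50))$entropy, 0)
  set.seed(40)
  v <- smooth_curve(500)
  m <- series_measures(v)
  expect_equal(m$mean, sum(v) / length(v), tolerance = 1e-12)
  expect_equal(m$energy, sum(v * v), tolerance = 1e-12)
  expect_gt(m$entropy, 0)
  expect_lte(m$entropy, log(100))
  expect_error(series_measures(c(1, NaN)), class = "kinegraph_invalid_input")
})

test_that("group summaries are pointwise moments with the right display length", {
  set.seed(41)
  s <- smooth_curve(80)
  two_same <- tibble::tibble(values = list(s, s), original_length = c(80, 80))
  gs <- group_summary(two_same)
  expect_equal(gs$curve$mean, s)
  expect_equal(gs$curve$sd, rep(0, 80))
  opp <- tibble::tibble(values = list(s, -s), original_length = c(80, 80))
  expect_equal(group_summary(opp)$curve$mean, rep(0, 80))

  prop <- tibble::tibble(values = list(s, s), original_length = c(1000, 1400))
  expect_equal(group_summary(prop, mode = "Proportional")$display_length, 1200)
  expect_equal(group_summary(prop, mode = "SameLength")$display_length, 80)
  expect_error(group_summary(list()), class = "kinegraph_domain_error")
})

triangle_net <- function() {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- W[1, 3] <- W[3, 1] <- W[2, 3] <- W[3, 2] <- 1
  structure(
    list(participant = "p", movement = 1L, weights = W,
         edges = tibble::tibble(angle_i = c(1, 1, 2), angle_j = c(2, 3, 3),
                                weight = 1),
         config = NULL),
    class = "motion_network"
  )
}

test_that("network features concatenate degree, closeness, eigencentrality, clustering", {
  net <- triangle_net()  # triangle on 1-3, vertex 4 isolated
  f <- network_features(net)
  expect_length(f, 4 * 4)
  deg <- f[1:4]; clo <- f[5:8]; eig <- f[9:12]; clu <- f[13:16]
  expect_equal(deg, c(2, 2, 2, 0))
  expect_equal(clu[1:3], rep(1, 3))   # every triangle vertex clusters fully
  expect_equal(c(clo[4], eig[4], clu[4]), rep(0, 3))  # isolated conventions
  expect_equal(eig[1:3], rep(1, 3))

  # path on 3 vertices: middle vertex has strictly highest closeness;
  # cross-check against the graph library's unweighted closeness ordering
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- W[2, 3] <- W[3, 2] <- 1
  path_net <- structure(
    list(participant = "p", movement = 1L, weights = W,
         edges = tibble::tibble(angle_i = c(1, 2), angle_j = c(2, 3),
                                weight = 1), config = NULL),
    class = "motion_network")
  fp <- network_features(path_net)
  clo <- fp[4:6]
  expect_true(clo[2] > clo[1] && clo[2] > clo[3])
  g <- igraph::make_graph(c(1, 2, 2, 3), directed = FALSE)
  expect_equal(order(clo), order(igraph::closeness(g)))
})

test_that("feature vector length follows the 4*N_A (per movement) law", {
  co <- resample_cohort(tiny_cohort(seed = 42))
  nets <- build_all_networks(co)
  fv1 <- network_feature_vectors(nets, movement = 1L)
  expect_true(all(lengths(fv1$features) == 4 * 3))
  fv_all <- network_feature_vectors(nets)
  expect_true(all(lengths(fv_all$features) == 2 * 4 * 3))
})

test_that("PCA projection is rank-revealing, distance-preserving and deterministic", {
  set.seed(43)
  # collinear points: second coordinate variance ~ 0
  base <- rnorm(6)
  coll <- lapply(seq(0, 2, length.out = 8), function(t) t * base)
  pc <- pca_project(coll)
  expect_lt(stats::var(pc$y), 1e-18)

  # intrinsically 2-D data: pairwise distances preserved
  X <- cbind(rnorm(10), rnorm(10))
  pc2 <- pca_project(X)
  expect_equal(as.matrix(dist(cbind(pc2$x, pc2$y))), as.matrix(dist(X)),
               tolerance = 1e-9, ignore_attr = TRUE)

  # duplicated vector set projects to duplicated points
  dup <- rbind(X, X)
  pd <- pca_project(dup)
  expect_equal(pd[1:10, ], pd[11:20, ])

  expect_error(pca_project(rbind(base, base)),
               class = "kinegraph_degenerate_input")
})

test_that("classical MDS reproduces realizable distance geometries", {
  # 3-4-5 right triangle
  tri <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0))
  md <- mds_project(tri)
  got <- sort(as.vector(dist(cbind(md$x, md$y))))
  expect_equal(got, c(3, 4, 5), tolerance = 1e-6)

  # 2-D input: full distance matrix reproduced
  set.seed(44)
  X <- cbind(runif(12), runif(12))
  md2 <- mds_project(X)
  expect_equal(dist(cbind(md2$x, md2$y)), dist(X), tolerance = 1e-9,
               ignore_attr = TRUE)

  expect_warning(md3 <- mds_project(rbind(c(1, 1), c(1, 1), c(1, 1))))
  expect_equal(unlist(md3), rep(0, 6), ignore_attr = TRUE)
})

test_that("cohort projection returns one annotated point per participant-side", {
  co <- resample_cohort(tiny_cohort(seed = 45))
  # add a third participant so MDS/PCA have enough points
  extra <- co$series[co$series$participant == "stroke_1", ]
  extra$participant <- "stroke_2"
  set.seed(46)
  extra$values <- lapply(extra$values, function(v) v + rnorm(length(v)))
  parts <- dplyr::bind_rows(
    co$participants,
    tibble::tibble(id = "stroke_2", group = "stroke", side = "L",
                   fma_total = 22L, fma_item = list(NULL)))
  co3 <- motion_cohort(dplyr::bind_rows(co$series, extra), parts, co$angles,
                       m_max = co$m_max)
  nets <- build_all_networks(co3)
  for (method in c("net-pca", "curve-pca")) {
    pr <- project_cohort(co3, 1L, method = method, networks = nets)
    expect_setequal(pr$participant, parts$id)
    expect_true(all(c("x", "y", "group", "side", "fma_total") %in% names(pr)))
  }
})
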