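no_scaling <- gl_config(z_scaling = "none")

test_that("objective evaluates the Dirichlet + barrier + Frobenius form", {
  W <- matrix(c(0, 1, 1, 0), 2)
  Z <- matrix(c(0, 4, 4, 0), 2)
  cfg <- gl_config(barrier_weight = 1, frobenius_weight = 0)
  expect_equal(gl_objective(W, Z, cfg), 4)
  expect_identical(gl_objective(W * 0, Z, cfg), Inf)

  # scaling W by c changes the barrier term by -alpha * n * log(c)
  set.seed(10)
  n <- 5
  W5 <- random_z(n, 0.5, 2)
  Z5 <- random_z(n)
  cfg0 <- gl_config(barrier_weight = 1.3, frobenius_weight = 0)
  for (c_fac in c(2, 7)) {
    lhs <- gl_objective(c_fac * W5, Z5, cfg0)
    rhs <- c_fac * sum(W5 * Z5) / 2 + gl_objective(W5, Z5, cfg0) -
      sum(W5 * Z5) / 2 - 1.3 * n * log(c_fac)
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
  expect_error(gl_objective(W, Z5), class = "kinegraph_invalid_input")
})

test_that("primal-dual solution matches a generic convex solve on small instances", {
  set.seed(11)
  worst <- 0
  for (r in 1:20) {
    n <- sample(3:6, 1)
    Z <- random_z(n)
    W <- learn_graph(Z, no_scaling)
    Wref <- gl_reference_solve(Z, no_scaling)
    f <- gl_objective(W, Z, no_scaling)
    fref <- gl_objective(Wref, Z, no_scaling)
    worst <- max(worst, abs(f - fref) / abs(fref))
    # feasibility of every learned W
    expect_lte(max(abs(W - t(W))), 1e-12)
    expect_true(all(W >= 0))
    expect_equal(diag(W), rep(0, n))
    expect_true(all(rowSums(W) > 0))
  }
  expect_lt(worst, 1e-6)
})

test_that("equal off-diagonal dissimilarities give equal weights", {
  for (n in c(3, 5)) {
    Z <- matrix(2, n, n); diag(Z) <- 0
    W <- learn_graph(Z, no_scaling)
    offs <- W[upper.tri(W)]
    expect_lt(diff(range(offs)), 1e-6)
  }
})

test_that("the most similar pair carries the strictly largest weight", {
  Z <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3)
  W <- learn_graph(Z, no_scaling)
  expect_true(W[1, 2] > max(W[1, 3], W[2, 3]))
  Wref <- gl_reference_solve(Z, no_scaling)
  expect_true(which.max(Wref[upper.tri(Wref)]) ==
                which.max(W[upper.tri(W)]))
})

test_that("increasing one dissimilarity never increases that weight", {
  set.seed(12)
  for (r in 1:8) {
    Z <- random_z(4)
    W0 <- learn_graph(Z, no_scaling)
    Z2 <- Z
    Z2[1, 2] <- Z2[2, 1] <- Z[1, 2] * 2 + 0.5
    W1 <- learn_graph(Z2, no_scaling)
    expect_lte(W1[1, 2], W0[1, 2] + 1e-8)
    Wr <- gl_reference_solve(Z2, no_scaling)
    expect_lte(Wr[1, 2], W0[1, 2] + 1e-6)
  }
})

test_that("solving is deterministic and non-convergence raises a convergence error", {
  set.seed(13)
  Z <- random_z(5)
  expect_identical(learn_graph(Z), learn_graph(Z))
  expect_error(
    learn_graph(Z, gl_config(max_iterations = 3, tolerance = 1e-14)),
    class = "kinegraph_convergence_error"
  )
})

test_that("build_network wires dissimilarity into the solver with provenance", {
  set.seed(14)
  latent <- smooth_curve(300, amplitude = 40)
  series <- list(
    latent + rnorm(300, 0, 0.3),
    latent + rnorm(300, 0, 0.3),
    smooth_curve(300), smooth_curve(300), smooth_curve(300)
  )
  net <- build_network(series, "p1", 3L)
  expect_s3_class(net, "motion_network")
  expect_true(any(net$edges$angle_i == 1 & net$edges$angle_j == 2))
  # identical input gives identical networks
  net2 <- build_network(series, "p1", 3L)
  expect_identical(net$weights, net2$weights)

  # an all-zero channel keeps no edge after thresholding
  series_null <- c(series, list(rep(0, 300)))
  netn <- build_network(series_null, "p1", 3L)
  expect_false(any(netn$edges$angle_i == 6 | netn$edges$angle_j == 6))
  # but the barrier still gives it positive total weight
  expect_gt(rowSums(netn$weights)[6], 0)
})

test_that("build_all_networks enumerates participant x movement deterministically", {
  co <- resample_cohort(tiny_cohort(seed = 21))
  nets <- build_all_networks(co)
  expect_equal(nrow(nets), 2 * 2)
  expect_true(all(vapply(nets$network, function(n) nrow(n$weights), 1) == 3))
  expect_equal(nets$participant, rep(co$participants$id, each = 2))
})

test_that("networks round-trip through GraphML and JSON", {
  set.seed(15)
  series <- replicate(4, smooth_curve(100), simplify = FALSE)
  series[[2]] <- series[[1]] + rnorm(100, 0, 0.2)
  net <- build_network(series, "stroke_9", 2L)
  angles <- default_joint_angles(4)

  f1 <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, f1, angles)
  back <- read_network_graphml(f1)
  expect_equal(back$participant, "stroke_9")
  expect_equal(back$movement, 2L)
  ord <- function(e) e[order(e$angle_i, e$angle_j), ]
  expect_equal(ord(back$edges), ord(net$edges), tolerance = 1e-12)

  f2 <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, f2)
  back2 <- read_network_json(f2)
  expect_equal(back2$weights, net$weights, ignore_attr = TRUE)
  expect_equal(ord(back2$edges), ord(net$edges))
})
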