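test_that("resampling interpolates, preserves endpoints and hits the target length", {
  expect_equal(resample_to_common_length(rep(5, 4), 10), rep(5, 10))
  expect_equal(resample_to_common_length(c(0, 1), 3), c(0, 0.5, 1))
  set.seed(1)
  v <- smooth_curve(700)
  out <- resample_to_common_length(v)
  expect_length(out, 1500)
  expect_equal(out[1], v[1])
  expect_equal(out[1500], v[700])
  # exact at original knots mapped onto the new grid (700-1 divides 1500-1? no;
  # use a divisor case instead)
  v2 <- smooth_curve(101)
  out2 <- resample_to_common_length(v2, 201)
  expect_equal(out2[seq(1, 201, by = 2)], v2, tolerance = 1e-12)
})

test_that("resampling is idempotent at the target length", {
  set.seed(2)
  for (len in c(5, 37, 700)) {
    v <- smooth_curve(len)
    r1 <- resample_to_common_length(v, 300)
    expect_equal(resample_to_common_length(r1, 300), r1, tolerance = 1e-9)
  }
})

test_that("monotone series keep their extrema at the endpoints", {
  set.seed(3)
  for (rep in 1:5) {
    v <- cumsum(runif(50, 0, 2))  # increasing
    out <- resample_to_common_length(v, 400)
    expect_equal(min(out), v[1], tolerance = 1e-9)
    expect_equal(max(out), v[50], tolerance = 1e-9)
  }
  # down-sampling through the same path
  v <- sort(runif(2000, -10, 80))
  out <- resample_to_common_length(v, 1500)
  expect_length(out, 1500)
  expect_gte(min(out), v[1] - 1e-9)
})

test_that("invalid resampling inputs are rejected", {
  expect_error(resample_to_common_length(c(1), 10), class = "kinegraph_invalid_input")
  expect_error(resample_to_common_length(c(1, NA), 10), class = "kinegraph_invalid_input")
  expect_error(resample_to_common_length(c(1, Inf, 2), 10), class = "kinegraph_invalid_input")
})

test_that("count_series equals the index product and brute-force enumeration", {
  co <- tiny_cohort()
  expect_identical(count_series(co), 2L * 2L * 3L)
  expect_identical(count_series(co), nrow(co$series))
})

test_that("cohort construction enforces completeness and schema", {
  co <- tiny_cohort()
  broken <- co$series[-4, ]
  expect_error(
    motion_cohort(broken, co$participants, co$angles, m_max = co$m_max),
    class = "kinegraph_completeness_error"
  )
  bad_part <- co$participants
  bad_part$group[1] <- "strke"
  expect_error(
    motion_cohort(co$series, bad_part, co$angles, m_max = co$m_max),
    class = "kinegraph_schema_error"
  )
})

test_that("save/load round-trips values and metadata and resamples on load", {
  co <- resample_cohort(tiny_cohort())
  dir <- withr::local_tempdir()
  save_cohort(co, dir)
  back <- load_cohort(dir)
  expect_equal(back$participants$fma_total, co$participants$fma_total)
  expect_equal(back$participants$fma_item, co$participants$fma_item)
  expect_equal(back$angles, co$angles)
  ord <- function(s) s[order(s$participant, s$movement, s$angle), ]
  a <- ord(co$series); b <- ord(back$series)
  expect_equal(b$values, a$values, tolerance = 1e-12)
  expect_equal(b$original_length, a$original_length)

  # a long raw series is resampled to m_max on load
  raw <- tiny_cohort(seed = 5)
  raw$series$values[[1]] <- smooth_curve(200)
  raw$series$original_length[1] <- 200L  # longer than m_max = 150
  dir2 <- withr::local_tempdir()
  # per-movement files need equal lengths across angles; stretch all three
  idx <- which(raw$series$participant == raw$series$participant[1] &
                 raw$series$movement == raw$series$movement[1])
  for (i in idx) {
    raw$series$values[[i]] <- smooth_curve(200)
    raw$series$original_length[i] <- 200L
  }
  save_cohort(raw, dir2)
  back2 <- load_cohort(dir2)
  expect_true(all(lengths(back2$series$values) == raw$m_max))
})

test_that("loading a cohort with a missing movement file names the triple", {
  co <- resample_cohort(tiny_cohort())
  dir <- withr::local_tempdir()
  save_cohort(co, dir)
  file.remove(file.path(dir, "stroke_1", "M02.csv"))
  expect_error(load_cohort(dir), class = "kinegraph_completeness_error")
  expect_error(load_cohort(dir), regexp = "stroke_1")
})
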