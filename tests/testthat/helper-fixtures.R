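# Fixtures are generated in code; nothing is read from disk.

# smooth joint-angle-like curve: low-frequency sinusoids plus drift
smooth_curve <- function(len = 200, amplitude = 30) {
  t <- seq(0, 1, length.out = len)
  amplitude * sin(2 * pi * runif(1, 0.5, 3) * t + runif(1, 0, 2 * pi)) +
    0.5 * amplitude * sin(2 * pi * runif(1, 0.5, 3) * t + runif(1, 0, 2 * pi)) +
    runif(1, -10, 10) * t
}

# random valid dissimilarity matrix (symmetric, non-negative, zero diagonal)
random_z <- function(n, lo = 0.2, hi = 3) {
  Z <- matrix(0, n, n)
  Z[upper.tri(Z)] <- runif(n * (n - 1) / 2, lo, hi)
  Z + t(Z)
}

# a small but structured synthetic config: every movement of every group has
# at least one planted coupling, plus one null channel per group
recovery_config <- function(seed, noise_sd = 0.4) {
  synthetic_config(
    n_stroke_L = 3, n_stroke_R = 0, n_ctrl = 2,
    n_movements = 2, n_angles = 8,
    couplings = list(
      stroke = list(list(pair = c(1L, 2L), movement = 1L),
                    list(pair = c(4L, 5L), movement = 1L),
                    list(pair = c(4L, 5L), movement = 2L),
                    list(pair = c(2L, 6L), movement = 2L)),
      control = list(list(pair = c(4L, 5L), movement = 1L),
                     list(pair = c(4L, 5L), movement = 2L),
                     list(pair = c(2L, 6L), movement = 2L))
    ),
    null_channels = list(stroke = 7L, control = 7L),
    noise_sd = noise_sd, individual_sd = 1.5, seed = seed
  )
}

# tiny complete cohort built directly (2 participants x 2 movements x
# 3 angles), deterministic given seed
tiny_cohort <- function(seed = 1, m_len = 120, m_max = 150) {
  set.seed(seed)
  participants <- tibble::tibble(
    id = c("stroke_1", "ctrl_1_L"),
    group = c("stroke", "control"),
    side = c("L", "L"),
    fma_total = c(30L, 65L),
    fma_item = list(c(M1 = 1L, M2 = 2L), c(M1 = 2L, M2 = 2L))
  )
  angles <- tibble::tibble(
    id = 1:3, name = paste0("Angle ", 1:3, ", deg"),
    region = c("shoulder", "elbow", "thorax"), display_rank = 1:3
  )
  grid <- tidyr::expand_grid(participant = participants$id,
                             movement = 1:2, angle = 1:3)
  grid$values <- lapply(seq_len(nrow(grid)), function(i) smooth_curve(m_len))
  grid$original_length <- m_len
  motion_cohort(grid, participants, angles, m_max = m_max)
}

# lightweight stand-ins for filtering tests: a network is just its edge set
fake_network <- function(participant, movement, pairs, weight = 1) {
  edges <- if (length(pairs) == 0) {
    tibble::tibble(angle_i = integer(), angle_j = integer(),
                   weight = numeric())
  } else {
    tibble::tibble(
      angle_i = vapply(pairs, function(p) as.integer(min(p)), 1L),
      angle_j = vapply(pairs, function(p) as.integer(max(p)), 1L),
      weight = weight
    )
  }
  structure(
    list(participant = participant, movement = movement,
         weights = matrix(0, 1, 1), edges = edges, config = NULL),
    class = "motion_network"
  )
}

fake_cohort_meta <- function(participants) {
  structure(
    list(
      participants = participants,
      movements = tibble::tibble(id = 1:3, label = paste0("M", 1:3)),
      angles = tibble::tibble(id = 1:6, name = paste0("a", 1:6),
                              region = "shoulder", display_rank = 1:6),
      m_max = 100L
    ),
    class = "motion_cohort"
  )
}

toy_participants <- function() {
  tibble::tibble(
    id = c("stroke_1", "stroke_2", "stroke_3", "ctrl_1_L", "ctrl_1_R"),
    group = c("stroke", "stroke", "stroke", "control", "control"),
    side = c("L", "L", "R", "L", "R"),
    fma_total = c(20L, 40L, 55L, 64L, 64L),
    fma_item = vector("list", 5)
  )
}

# brute-force support count over an explicit network list
brute_support <- function(networks, pair, participants = NULL,
                          groups = NULL, movements = NULL) {
  gs <- if (!is.null(participants)) {
    stats::setNames(group_side_token_test(participants), participants$id)
  }
  hits <- 0L
  for (net in networks) {
    if (!is.null(movements) && !net$movement %in% movements) next
    if (!is.null(groups) && !is.null(gs) &&
        !gs[[net$participant]] %in% groups) next
    e <- net$edges
    if (any(e$angle_i == min(pair) & e$angle_j == max(pair))) hits <- hits + 1L
  }
  hits
}

group_side_token_test <- function(participants) {
  paste0(ifelse(participants$group == "stroke", "stroke", "ctrl"),
         participants$side)
}

# minimal cohort-shaped object for cohort_embeddings
resample_cohort_stub <- function(series) {
  structure(
    list(series = tibble::tibble(
      participant = "p1", movement = 1L, angle = seq_along(series),
      values = series, original_length = 1500L)),
    class = "motion_cohort"
  )
}
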