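#' Synthetic cohort configuration
#'
#' Describes a synthetic cohort with the statistical structure the method
#' assumes: smooth per-(movement, angle) template curves shared by the
#' cohort, per-participant smooth deviations plus white noise, planted
#' couplings (channel pairs sharing one latent curve), and per-group null /
#' constant channels. Group differences are encoded through the couplings
#' (and optionally through group-specific templates for selected movements,
#' which is what makes whole-curve embeddings separate the groups).
#'
#' @param n_stroke_L,n_stroke_R numbers of left-/right-paretic stroke
#'   participant-sides.
#' @param n_ctrl control participants per side (each contributes one L and
#'   one R participant-side).
#' @param n_movements,n_angles cohort dimensions.
#' @param couplings named list (`stroke`, `control`) of planted couplings,
#'   each a `list(pair = c(i, j), movement = m)`.
#' @param noise_sd white-noise standard deviation in degrees (default 1).
#' @param individual_sd amplitude (degrees) of the smooth per-participant
#'   deviation from the template (default 3).
#' @param null_channels,constant_channels named list (`stroke`, `control`)
#'   of angle ids that are all-zero / a random constant in that group.
#' @param group_template_movements movement ids whose templates are drawn
#'   per group instead of cohort-wide.
#' @param outlier_couplings extra per-participant couplings, each a
#'   `list(participant =, pair =, movement =)`; ids follow the generated
#'   naming (`stroke_1`, ..., `ctrl_1_L`, ...).
#' @param duration_range integer interval of series durations (samples at
#'   the native rate), default `c(600, 1500)`.
#' @param angles optional angle metadata tibble; defaults to
#'   [default_joint_angles()].
#' @param m_max common length after resampling (default 1500).
#' @param seed integer seed; the cohort is a deterministic function of the
#'   config.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_stroke_L = 28, n_stroke_R = 23, n_ctrl = 18,
                             n_movements = 13, n_angles = 20,
                             couplings = list(stroke = list(),
                                              control = list()),
                             noise_sd = 1, individual_sd = 3,
                             null_channels = list(stroke = integer(),
                                                  control = integer()),
                             constant_channels = list(stroke = integer(),
                                                      control = integer()),
                             group_template_movements = integer(0),
                             outlier_couplings = list(),
                             duration_range = c(600, 1500),
                             angles = NULL, m_max = 1500, seed = 1L) {
  cfg <- list(
    n_stroke_L = n_stroke_L, n_stroke_R = n_stroke_R, n_ctrl = n_ctrl,
    n_movements = as.integer(n_movements), n_angles = as.integer(n_angles),
    couplings = couplings, noise_sd = noise_sd,
    individual_sd = individual_sd,
    null_channels = null_channels, constant_channels = constant_channels,
    group_template_movements = as.integer(group_template_movements),
    outlier_couplings = outlier_couplings,
    duration_range = as.integer(duration_range),
    angles = angles, m_max = as.integer(m_max), seed = as.integer(seed)
  )
  if (cfg$duration_range[1] < 2 || cfg$duration_range[2] > cfg$m_max) {
    stop_invalid("duration_range must lie within [2, m_max]")
  }
  for (g in c("stroke", "control")) {
    dead <- union(cfg$null_channels[[g]] %||% integer(),
                  cfg$constant_channels[[g]] %||% integer())
    for (cp in cfg$couplings[[g]] %||% list()) {
      if (any(cp$pair < 1) || any(cp$pair > n_angles) ||
          cp$movement < 1 || cp$movement > n_movements) {
        stop_invalid("planted coupling references an invalid angle/movement",
                     class = "kinegraph_config_error")
      }
      if (any(cp$pair %in% dead)) {
        abort(sprintf(
          "planted %s coupling (%d, %d) references a null/constant channel",
          g, cp$pair[1], cp$pair[2]),
          class = c("kinegraph_config_error", "kinegraph_error"))
      }
    }
  }
  structure(cfg, class = "synthetic_config")
}

# smooth latent curve parameterization: 2-4 low-frequency sinusoids
# (<= 3 cycles over the series) plus linear drift, amplitudes summing into
# the 10-90 degree range typical of single-execution joint excursions
draw_curve_params <- function(amplitude = c(10, 45),
                              drift_scale = 15, offset_scale = 10) {
  k <- sample(2:4, 1)
  list(
    amp = runif(k, amplitude[1], amplitude[2]),
    freq = runif(k, 0.5, 3),
    phase = runif(k, 0, 2 * pi),
    drift = runif(1, -drift_scale, drift_scale),
    offset = runif(1, -offset_scale, offset_scale)
  )
}

# smooth per-participant deviation, all parts scaled by individual_sd
draw_deviation_params <- function(individual_sd) {
  draw_curve_params(c(0.25, 1) * individual_sd,
                    drift_scale = 0.5 * individual_sd,
                    offset_scale = 0.3 * individual_sd)
}

eval_curve <- function(p, len) {
  s <- seq(0, 1, length.out = len)
  y <- rep(p$offset, len) + p$drift * s
  for (i in seq_along(p$amp)) {
    y <- y + p$amp[i] * sin(2 * pi * p$freq[i] * s + p$phase[i])
  }
  y
}

# connected coupling components for one (group, movement)
coupling_components <- function(couplings, movement, n_angles) {
  pairs <- Filter(function(cp) cp$movement == movement, couplings)
  if (length(pairs) == 0) return(list())
  parent <- seq_len(n_angles)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (cp in pairs) {
    parent[find(cp$pair[1])] <- find(cp$pair[2])
  }
  members <- unique(unlist(lapply(pairs, `[[`, "pair")))
  split(members, vapply(members, find, 1L))
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws the cohort described by the config. Each (movement, angle) has a
#' smooth template curve; a participant's channel is the template plus a
#' smooth individual deviation plus white noise, evaluated over a duration
#' drawn uniformly from `duration_range`. Members of a planted coupling
#' share one latent curve (the template of the smallest member angle active
#' in every group) and one individual deviation, so at zero noise they are
#' identical. Null channels are all-zero, constant channels a random
#' constant. Fully reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @param resample resample all series to `m_max` (default TRUE); with
#'   FALSE series keep their drawn durations (the on-disk convention).
#' @return list with elements `cohort` (a `motion_cohort`) and
#'   `ground_truth` (tibble per (participant, movement): planted pairs,
#'   null and constant channels).
#' @export
generate_cohort <- function(config, resample = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  with_local_seed(cfg$seed, {
    angles <- cfg$angles %||% default_joint_angles(cfg$n_angles)
    participants <- tibble(
      id = c(
        if (cfg$n_stroke_L > 0) paste0("stroke_", seq_len(cfg$n_stroke_L)),
        if (cfg$n_stroke_R > 0)
          paste0("stroke_", cfg$n_stroke_L + seq_len(cfg$n_stroke_R)),
        if (cfg$n_ctrl > 0) paste0("ctrl_", seq_len(cfg$n_ctrl), "_L"),
        if (cfg$n_ctrl > 0) paste0("ctrl_", seq_len(cfg$n_ctrl), "_R")
      ),
      group = c(rep("stroke", cfg$n_stroke_L + cfg$n_stroke_R),
                rep("control", 2 * cfg$n_ctrl)),
      side = c(rep("L", cfg$n_stroke_L), rep("R", cfg$n_stroke_R),
               rep("L", cfg$n_ctrl), rep("R", cfg$n_ctrl))
    )
    participants$fma_total <- ifelse(
      participants$group == "stroke",
      as.integer(sample(8:65, nrow(participants), replace = TRUE)),
      as.integer(sample(62:66, nrow(participants), replace = TRUE))
    )
    participants$fma_item <- lapply(seq_len(nrow(participants)), function(i) {
      scores <- if (participants$group[i] == "stroke") {
        sample(0:2, cfg$n_movements, replace = TRUE)
      } else {
        rep(2L, cfg$n_movements)
      }
      setNames(as.integer(scores), movement_label(seq_len(cfg$n_movements)))
    })

    # templates: cohort-wide by default, per group for selected movements
    templates <- list()
    for (m in seq_len(cfg$n_movements)) {
      shared <- lapply(seq_len(cfg$n_angles), function(a) draw_curve_params())
      if (m %in% cfg$group_template_movements) {
        templates[[m]] <- list(
          stroke = lapply(seq_len(cfg$n_angles),
                          function(a) draw_curve_params()),
          control = lapply(seq_len(cfg$n_angles),
                           function(a) draw_curve_params())
        )
      } else {
        templates[[m]] <- list(stroke = shared, control = shared)
      }
    }

    dead_any <- union(
      union(cfg$null_channels$stroke %||% integer(),
            cfg$null_channels$control %||% integer()),
      union(cfg$constant_channels$stroke %||% integer(),
            cfg$constant_channels$control %||% integer())
    )
    comp_latent_angle <- function(members) {
      active <- sort(setdiff(members, dead_any))
      if (length(active) > 0) active[1] else sort(members)[1]
    }
    components <- list(
      stroke = lapply(seq_len(cfg$n_movements), function(m)
        coupling_components(cfg$couplings$stroke %||% list(), m,
                            cfg$n_angles)),
      control = lapply(seq_len(cfg$n_movements), function(m)
        coupling_components(cfg$couplings$control %||% list(), m,
                            cfg$n_angles))
    )

    n_series <- nrow(participants) * cfg$n_movements * cfg$n_angles
    col_participant <- character(n_series)
    col_movement <- integer(n_series)
    col_angle <- integer(n_series)
    col_values <- vector("list", n_series)
    col_len <- integer(n_series)
    gt_rows <- list()
    k <- 0L
    for (i in seq_len(nrow(participants))) {
      pid <- participants$id[i]
      grp <- participants$group[i]
      extra <- Filter(function(oc) oc$participant == pid,
                      cfg$outlier_couplings)
      for (m in seq_len(cfg$n_movements)) {
        dur <- sample(cfg$duration_range[1]:cfg$duration_range[2], 1)
        comps <- components[[grp]][[m]]
        pairs_here <- Filter(function(cp) cp$movement == m,
                             cfg$couplings[[grp]] %||% list())
        if (length(extra) > 0) {
          more <- Filter(function(oc) oc$movement == m, extra)
          if (length(more) > 0) {
            pairs_here <- c(pairs_here, more)
            allc <- c(cfg$couplings[[grp]] %||% list(), more)
            comps <- coupling_components(allc, m, cfg$n_angles)
          }
        }
        angle_comp <- integer(cfg$n_angles)
        for (ci in seq_along(comps)) angle_comp[comps[[ci]]] <- ci
        comp_dev <- lapply(comps, function(members)
          draw_deviation_params(cfg$individual_sd))
        nulls <- cfg$null_channels[[grp]] %||% integer()
        consts <- cfg$constant_channels[[grp]] %||% integer()
        for (a in seq_len(cfg$n_angles)) {
          if (a %in% nulls) {
            v <- rep(0, dur)
          } else if (a %in% consts) {
            v <- rep(runif(1, -45, 45), dur)
          } else if (angle_comp[a] > 0) {
            ci <- angle_comp[a]
            latent <- templates[[m]][[grp]][[comp_latent_angle(comps[[ci]])]]
            v <- eval_curve(latent, dur) + eval_curve(comp_dev[[ci]], dur) +
              rnorm(dur, 0, cfg$noise_sd)
          } else {
            dev <- draw_deviation_params(cfg$individual_sd)
            v <- eval_curve(templates[[m]][[grp]][[a]], dur) +
              eval_curve(dev, dur) + rnorm(dur, 0, cfg$noise_sd)
          }
          k <- k + 1L
          col_participant[k] <- pid
          col_movement[k] <- m
          col_angle[k] <- a
          col_values[[k]] <- v
          col_len[k] <- dur
        }
        gt_rows[[length(gt_rows) + 1L]] <- tibble(
          participant = pid, movement = m,
          planted_pairs = list(lapply(pairs_here, `[[`, "pair")),
          null_channels = list(nulls), constant_channels = list(consts)
        )
      }
    }
    series <- tibble(
      participant = col_participant, movement = col_movement,
      angle = col_angle, values = col_values, original_length = col_len
    )
    cohort <- motion_cohort(series, participants, angles,
                            m_max = cfg$m_max)
    if (resample) cohort <- resample_cohort(cohort)
    list(cohort = cohort, ground_truth = bind_rows(gt_rows))
  })
}

#' Preset case-study configurations
#'
#' Two deterministic synthetic scenarios with documented ground truth.
#'
#' `"shoulder-flexion-like"` plants, on its focal movement (M2), a shared
#' flexion/elbow coupling in both groups plus two stroke-only couplings that
#' attach an abduction-like angle (a null channel in controls — healthy
#' subjects do not abduct during this movement) to both members; the
#' Differences filter therefore yields exactly two stroke-only pairs and no
#' control-only pair.
#'
#' `"flexor-synergy-like"` draws group-specific templates for its focal
#' movement (M1), so whole-curve embeddings separate the groups, and gives
#' one stroke participant an extra trunk-to-elbow coupling (a compensation
#' outlier).
#'
#' @param name preset name.
#' @return a [synthetic_config()] with attribute `"expected"` documenting
#'   the planted structure (focal movement, stroke-only pairs, comparison
#'   groups).
#' @export
preset_case_study <- function(name = c("shoulder-flexion-like",
                                       "flexor-synergy-like")) {
  name <- tryCatch(match.arg(name), error = function(e) {
    abort(sprintf("unknown preset '%s'", paste(name, collapse = ", ")),
          class = c("kinegraph_domain_error", "kinegraph_error"))
  })
  if (name == "shoulder-flexion-like") {
    cfg <- synthetic_config(
      n_stroke_L = 8, n_stroke_R = 6, n_ctrl = 6,
      n_movements = 2, n_angles = 8,
      couplings = list(
        stroke = list(
          list(pair = c(1L, 5L), movement = 2L),  # flexion ~ elbow (shared)
          list(pair = c(1L, 3L), movement = 2L),  # abduction intrusion
          list(pair = c(3L, 5L), movement = 2L),
          list(pair = c(2L, 4L), movement = 2L),
          list(pair = c(6L, 7L), movement = 2L)
        ),
        control = list(
          list(pair = c(1L, 5L), movement = 2L),
          list(pair = c(2L, 4L), movement = 2L),
          list(pair = c(6L, 7L), movement = 2L)
        )
      ),
      null_channels = list(stroke = 8L, control = c(3L, 8L)),
      noise_sd = 0.5, individual_sd = 1.5,
      duration_range = c(600, 1500), seed = 101L
    )
    attr(cfg, "expected") <- list(
      focal_movement = 2L,
      stroke_only_pairs = list(c(1L, 3L), c(3L, 5L)),
      control_only_pairs = list(),
      groups_a = "strokeL", groups_b = "ctrlL"
    )
    return(cfg)
  }
  angles <- tibble(
    id = 1:8,
    name = c("Shoulder Flexion LT, deg", "Shoulder Rotation LT, deg",
             "Shoulder Abduction LT, deg", "Elbow Flexion LT, deg",
             "Wrist Flexion LT, deg", "Thoracic Flexion, deg",
             "Thoracic Lateral, deg", "Lumbar Flexion, deg"),
    region = c("shoulder", "shoulder", "shoulder", "elbow", "wrist",
               "thorax", "thorax", "lumbar"),
    display_rank = 1:8
  )
  cfg <- synthetic_config(
    n_stroke_L = 8, n_stroke_R = 4, n_ctrl = 6,
    n_movements = 2, n_angles = 8,
    couplings = list(
      stroke = list(list(pair = c(1L, 3L), movement = 1L)),  # flexor synergy
      control = list(list(pair = c(1L, 4L), movement = 1L))
    ),
    group_template_movements = 1L,
    outlier_couplings = list(
      list(participant = "stroke_1", pair = c(4L, 6L), movement = 1L)
    ),
    noise_sd = 1, individual_sd = 2, angles = angles,
    duration_range = c(600, 1500), seed = 202L
  )
  attr(cfg, "expected") <- list(
    focal_movement = 1L,
    stroke_only_pairs = list(c(1L, 3L)),
    outlier = "stroke_1",
    groups_a = "strokeL", groups_b = "ctrlL"
  )
  cfg
}
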