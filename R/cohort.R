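#' Default joint-angle table
#'
#' A 20-angle upper-body set used when none is supplied: seven side-specific
#' limb angles for each side plus three thoracic and three lumbar angles,
#' ordered head-to-pelvis for display. The list is illustrative — any angle
#' table with unique contiguous ids and a display-rank permutation works.
#'
#' @param n_angles number of angles to return (the first `n_angles` rows of
#'   the default ordering; at most 20 are predefined, beyond that generic
#'   labels are appended).
#' @return tibble with columns `id`, `name`, `region`, `display_rank`.
#' @export
default_joint_angles <- function(n_angles = 20) {
  limb <- c(
    "Shoulder Flexion", "Shoulder Rotation", "Shoulder Abduction",
    "Shoulder Total Flexion", "Elbow Flexion", "Wrist Flexion",
    "Forearm Pronation"
  )
  limb_region <- c(rep("shoulder", 4), "elbow", rep("wrist", 2))
  name <- c(
    paste0(limb, " LT, deg"), paste0(limb, " RT, deg"),
    "Thoracic Flexion, deg", "Thoracic Axial, deg", "Thoracic Lateral, deg",
    "Lumbar Flexion, deg", "Lumbar Axial, deg", "Lumbar Lateral, deg"
  )
  region <- c(limb_region, limb_region, rep("thorax", 3), rep("lumbar", 3))
  if (n_angles > length(name)) {
    extra <- seq_len(n_angles - length(name))
    name <- c(name, paste0("Angle ", length(name) + extra, ", deg"))
    region <- c(region, rep("thorax", length(extra)))
  }
  tibble(
    id = seq_len(n_angles),
    name = name[seq_len(n_angles)],
    region = region[seq_len(n_angles)],
    display_rank = seq_len(n_angles)
  )
}

#' Construct a motion cohort
#'
#' Bundles the per-(participant, movement, angle) joint-angle time series with
#' the participant, movement and angle metadata. The series table must be
#' total: exactly one row per (participant, movement, angle) triple.
#'
#' @param series tibble with columns `participant`, `movement`, `angle`,
#'   `values` (list column of numeric vectors, degrees) and
#'   `original_length`.
#' @param participants tibble with columns `id`, `group` ("stroke"/"control"),
#'   `side` ("L"/"R"), `fma_total` (integer 0-66 or NA) and `fma_item`
#'   (list column of named integer vectors or NULL).
#' @param angles tibble as produced by [default_joint_angles()].
#' @param movements tibble with columns `id`, `label`; derived from the series
#'   when omitted.
#' @param m_max common series length after preprocessing (default 1500).
#' @return object of class `motion_cohort`.
#' @export
motion_cohort <- function(series, participants, angles,
                          movements = NULL, m_max = 1500) {
  series <- as_tibble(series)
  participants <- as_tibble(participants)
  angles <- as_tibble(angles)
  if (!all(c("id", "group", "side") %in% names(participants))) {
    stop_invalid("participants need columns id, group, side",
                 class = "kinegraph_schema_error")
  }
  bad <- !participants$group %in% c("stroke", "control") |
    !participants$side %in% c("L", "R")
  if (any(bad)) {
    stop_invalid(
      sprintf("unknown group/side token for participant(s): %s",
              paste(participants$id[bad], collapse = ", ")),
      class = "kinegraph_schema_error"
    )
  }
  if (!"fma_total" %in% names(participants)) participants$fma_total <- NA_integer_
  if (!"fma_item" %in% names(participants)) {
    participants$fma_item <- vector("list", nrow(participants))
  }
  if (anyDuplicated(angles$id) || !setequal(angles$id, seq_len(nrow(angles)))) {
    stop_invalid("angle ids must be unique and contiguous (1..N_A)")
  }
  if (!setequal(angles$display_rank, seq_len(nrow(angles)))) {
    stop_invalid("display_rank must be a permutation of the angle ids")
  }
  if (is.null(movements)) {
    ids <- sort(unique(series$movement))
    movements <- tibble(id = ids, label = movement_label(ids))
  }
  check_cohort_complete(series, participants$id, movements$id, angles$id)
  structure(
    list(
      series = series, participants = participants, angles = angles,
      movements = movements, m_max = as.integer(m_max)
    ),
    class = "motion_cohort"
  )
}

check_cohort_complete <- function(series, participants, movements, angles) {
  want <- tidyr::expand_grid(
    participant = participants, movement = movements, angle = angles
  )
  have <- series[c("participant", "movement", "angle")]
  missing <- dplyr::anti_join(want, have,
                              by = c("participant", "movement", "angle"))
  if (nrow(missing) > 0) {
    m <- missing[1, ]
    abort(
      sprintf(
        "cohort is missing %d series; first missing triple: (%s, M%s, angle %s)",
        nrow(missing), m$participant, m$movement, m$angle
      ),
      class = c("kinegraph_completeness_error", "kinegraph_error")
    )
  }
  if (nrow(have) != nrow(want)) {
    abort("cohort has duplicated (participant, movement, angle) series",
          class = c("kinegraph_completeness_error", "kinegraph_error"))
  }
  invisible(TRUE)
}

#' @export
print.motion_cohort <- function(x, ...) {
  cat(sprintf(
    "<motion_cohort> %d participant-sides x %d movements x %d angles = %d series (m_max = %d)\n",
    nrow(x$participants), nrow(x$movements), nrow(x$angles),
    count_series(x), x$m_max
  ))
  tab <- table(group_side_token(x$participants$group, x$participants$side))
  cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of series in a cohort
#'
#' The cohort is total over its index set, so the count equals
#' `N_P * N_M * N_A` and also the number of stored series.
#'
#' @param cohort a `motion_cohort`.
#' @return integer count.
#' @export
count_series <- function(cohort) {
  stopifnot(inherits(cohort, "motion_cohort"))
  nrow(cohort$series)
}

#' Resample a series to a common length
#'
#' Interpolates the input at `target_length` positions placed affinely over
#' the original index range, preserving both endpoints and reproducing the
#' input exactly at the original sample positions. A cubic interpolating
#' spline is used for inputs of length >= 4 (a shape-preserving Hyman filter
#' for monotone inputs, so monotone series stay monotone); lengths 2 and 3
#' fall back to linear interpolation. Series longer than the target are
#' down-sampled through the same spline.
#'
#' @param values numeric vector, length >= 2, all finite.
#' @param target_length output length (>= 2), default 1500.
#' @return numeric vector of length `target_length`.
#' @export
resample_to_common_length <- function(values, target_length = 1500) {
  m <- length(values)
  if (m < 2) stop_invalid("cannot resample a series of length < 2")
  if (target_length < 2) stop_invalid("target_length must be >= 2")
  check_finite_numeric(values, "series values")
  x <- seq(0, 1, length.out = m)
  xout <- seq(0, 1, length.out = target_length)
  if (m < 4) {
    return(approx(x, values, xout = xout)$y)
  }
  monotone <- all(diff(values) >= 0) || all(diff(values) <= 0)
  method <- if (monotone && length(unique(values)) > 1) "hyman" else "fmm"
  spline(x, values, xout = xout, method = method)$y
}

#' Resample every series in a cohort to the common length
#'
#' @param cohort a `motion_cohort`.
#' @return the cohort with every `values` entry of length `m_max`.
#' @export
resample_cohort <- function(cohort) {
  m_max <- cohort$m_max
  cohort$series$values <- map(cohort$series$values, function(v) {
    if (length(v) == m_max) v else resample_to_common_length(v, m_max)
  })
  cohort
}

#' Save a cohort to a directory
#'
#' Layout: one sub-directory per participant-side; inside, one CSV per
#' movement (`M<k>.csv`) with a header of angle names and one column per
#' angle; a cohort-level `cohort.json` with participant records, the ordered
#' angle list and the movement table. Series are written at their stored
#' length, so a raw (un-resampled) cohort keeps its original durations on
#' disk.
#'
#' @param cohort a `motion_cohort`.
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
save_cohort <- function(cohort, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    m_max = cohort$m_max,
    movements = cohort$movements,
    angles = cohort$angles,
    participants = lapply(seq_len(nrow(cohort$participants)), function(i) {
      p <- cohort$participants[i, ]
      list(
        id = p$id, group = p$group, side = p$side,
        fma_total = if (is.na(p$fma_total)) NULL else p$fma_total,
        fma_item = if (is.null(p$fma_item[[1]])) NULL
                   else as.list(p$fma_item[[1]]),
        original_lengths = local({
          s <- cohort$series[cohort$series$participant == p$id, ]
          stats::setNames(as.list(s$original_length),
                          paste0("M", s$movement, "_A", s$angle))
        })
      )
    })
  )
  jsonlite::write_json(meta, file.path(path, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  angle_names <- cohort$angles$name[order(cohort$angles$id)]
  for (pid in cohort$participants$id) {
    pdir <- file.path(path, pid)
    dir.create(pdir, showWarnings = FALSE)
    for (mv in cohort$movements$id) {
      s <- cohort$series[cohort$series$participant == pid &
                           cohort$series$movement == mv, ]
      s <- s[order(s$angle), ]
      lens <- lengths(s$values)
      if (length(unique(lens)) != 1) {
        stop_invalid(sprintf(
          "series of (%s, M%d) have unequal lengths; resample before saving or store raw per-movement lengths",
          pid, mv))
      }
      mat <- do.call(cbind, s$values)
      colnames(mat) <- angle_names[s$angle]
      readr::write_csv(as.data.frame(mat),
                       file.path(pdir, sprintf("M%02d.csv", mv)),
                       progress = FALSE)
    }
  }
  invisible(path)
}

#' Load a cohort from a directory
#'
#' Reads the layout written by [save_cohort()]. Every series whose stored
#' length differs from `m_max` is resampled on load with
#' [resample_to_common_length()]; `original_length` records the stored
#' length. A missing per-movement CSV or a missing series triple raises a
#' completeness error naming the triple; an unknown group/side token raises a
#' schema error.
#'
#' @param path cohort directory.
#' @return a `motion_cohort` with all series of length `m_max`.
#' @export
load_cohort <- function(path) {
  meta_file <- file.path(path, "cohort.json")
  if (!file.exists(meta_file)) {
    stop_invalid(sprintf("no cohort.json under '%s'", path),
                 class = "kinegraph_schema_error")
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = FALSE)
  angles <- bind_rows(map(meta$angles, as_tibble))
  angles$id <- as.integer(angles$id)
  angles$display_rank <- as.integer(angles$display_rank)
  movements <- bind_rows(map(meta$movements, as_tibble))
  movements$id <- as.integer(movements$id)
  parts <- meta$participants
  participants <- tibble(
    id = map_chr(parts, "id"),
    group = map_chr(parts, "group"),
    side = map_chr(parts, "side"),
    fma_total = map_int(parts, ~ {
      v <- .x$fma_total
      if (is.null(v)) NA_integer_ else as.integer(v)
    }),
    fma_item = map(parts, ~ {
      v <- .x$fma_item
      if (is.null(v) || length(v) == 0) NULL
      else vapply(v, as.integer, 1L)
    })
  )
  m_max <- as.integer(meta$m_max)
  rows <- list()
  for (p in parts) {
    for (mv in movements$id) {
      f <- file.path(path, p$id, sprintf("M%02d.csv", mv))
      if (!file.exists(f)) {
        abort(sprintf("missing series file for (%s, M%d): %s", p$id, mv, f),
              class = c("kinegraph_completeness_error", "kinegraph_error"))
      }
      mat <- as.matrix(readr::read_csv(f, show_col_types = FALSE,
                                       progress = FALSE))
      if (ncol(mat) != nrow(angles)) {
        abort(sprintf("(%s, M%d) has %d angle columns, expected %d",
                      p$id, mv, ncol(mat), nrow(angles)),
              class = c("kinegraph_completeness_error", "kinegraph_error"))
      }
      for (a in angles$id) {
        v <- as.numeric(mat[, a])
        orig <- length(v)
        if (orig != m_max) v <- resample_to_common_length(v, m_max)
        # stored duration wins over row count (a resampled cohort keeps the
        # duration the movement originally took)
        key <- paste0("M", mv, "_A", a)
        if (!is.null(p$original_lengths[[key]])) {
          orig <- as.integer(p$original_lengths[[key]])
        }
        rows[[length(rows) + 1L]] <- tibble(
          participant = p$id, movement = mv, angle = a,
          values = list(v), original_length = orig
        )
      }
    }
  }
  series <- bind_rows(rows)
  motion_cohort(series, participants, angles, movements, m_max = m_max)
}
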