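#' Edge filter specification
#'
#' Declarative filter over the union edge set: which participant groups
#' (group-by-side tokens), movements and optionally individuals are in the
#' domain, and how edges are reported (`all` records, `topk` most prevalent
#' pairs, `differences` / `intersection` between two domains).
#'
#' @param groups subset of `c("strokeL","strokeR","ctrlL","ctrlR")`.
#' @param movements movement ids.
#' @param individuals optional participant-side ids restricting the domain.
#' @param mode one of `"all"`, `"topk"`, `"differences"`, `"intersection"`.
#' @param k top-K cut when `mode = "topk"` (>= 1).
#' @return an `edge_filter` list.
#' @export
edge_filter <- function(groups = all_group_sides, movements,
                        individuals = NULL,
                        mode = c("all", "topk", "differences", "intersection"),
                        k = 1L) {
  mode <- match.arg(mode)
  if (length(groups) == 0 || !all(groups %in% all_group_sides)) {
    stop_invalid(sprintf("groups must be a non-empty subset of {%s}",
                         paste(all_group_sides, collapse = ", ")))
  }
  if (length(movements) == 0) stop_invalid("movements must be non-empty")
  if (mode == "topk" && k < 1) stop_invalid("k must be >= 1 for top-K mode")
  structure(
    list(groups = groups, movements = as.integer(movements),
         individuals = individuals, mode = mode, k = as.integer(k)),
    class = "edge_filter"
  )
}

#' Union edge set of a network collection
#'
#' The multiset of all thresholded edges from all networks, each record
#' tagged with its provenance (participant, group-side, movement, weight).
#' Records are never deduplicated: a pair occurring in several networks
#' contributes one record per network.
#'
#' @param networks tibble from [build_all_networks()] (columns `participant`,
#'   `movement`, `network`) or a plain list of `motion_network` objects.
#' @param cohort the `motion_cohort` the networks came from (provides the
#'   participant group/side).
#' @return tibble of class `union_edge_set` with columns `angle_i`,
#'   `angle_j`, `participant`, `movement`, `group_side`, `weight`.
#' @export
build_union_set <- function(networks, cohort) {
  if (is.data.frame(networks)) networks <- networks$network
  part <- cohort$participants
  gs <- setNames(group_side_token(part$group, part$side), part$id)
  recs <- map(networks, function(net) {
    if (!net$participant %in% part$id) {
      abort(sprintf("network references unknown participant '%s'",
                    net$participant),
            class = c("kinegraph_provenance_error", "kinegraph_error"))
    }
    if (nrow(net$edges) == 0) return(NULL)
    mutate(net$edges,
           participant = net$participant, movement = net$movement,
           group_side = gs[[net$participant]])
  })
  out <- bind_rows(recs)
  if (nrow(out) == 0) {
    out <- tibble(angle_i = integer(), angle_j = integer(), weight = numeric(),
                  participant = character(), movement = integer(),
                  group_side = character())
  }
  class(out) <- c("union_edge_set", class(out))
  attr(out, "movement_ids") <- cohort$movements$id
  out
}

#' Filter the union edge set
#'
#' Keeps the records whose participant's group-side, movement and (when
#' given) participant id fall in the filter domain. The result is again a
#' union edge set, so filters compose.
#'
#' @param union_set a `union_edge_set`.
#' @param spec an [edge_filter()] with `mode = "all"`, or the domain given
#'   directly through `groups` / `movements` / `individuals`.
#' @param groups,movements,individuals domain given directly (ignored when
#'   `spec` is supplied).
#' @return filtered `union_edge_set`.
#' @export
filter_edges <- function(union_set, spec = NULL, groups = all_group_sides,
                         movements = NULL, individuals = NULL) {
  if (!is.null(spec)) {
    groups <- spec$groups
    movements <- spec$movements
    individuals <- spec$individuals
  }
  known <- attr(union_set, "movement_ids") %||% unique(union_set$movement)
  if (is.null(movements)) movements <- known
  if (length(setdiff(movements, known)) > 0) {
    abort(sprintf("unknown movement id(s): %s",
                  paste(setdiff(movements, known), collapse = ", ")),
          class = c("kinegraph_domain_error", "kinegraph_error"))
  }
  out <- union_set[union_set$group_side %in% groups &
                     union_set$movement %in% movements, ]
  if (!is.null(individuals)) {
    out <- out[out$participant %in% individuals, ]
  }
  class(out) <- unique(c("union_edge_set", class(out)))
  attr(out, "movement_ids") <- known
  out
}

#' Support of an angle pair
#'
#' Number of distinct (participant, movement) networks in the filter domain
#' whose edge set contains the pair.
#'
#' @param union_set a `union_edge_set`.
#' @param spec an [edge_filter()] giving the domain, or NULL for the whole
#'   set.
#' @param pair length-2 integer vector of angle ids (order irrelevant).
#' @return non-negative integer.
#' @export
edge_support <- function(union_set, spec = NULL, pair) {
  dom <- if (is.null(spec)) union_set else filter_edges(union_set, spec)
  i <- min(pair); j <- max(pair)
  hits <- dom[dom$angle_i == i & dom$angle_j == j, ]
  nrow(distinct(hits, .data$participant, .data$movement))
}

support_table <- function(dom) {
  if (nrow(dom) == 0) {
    return(tibble(angle_i = integer(), angle_j = integer(),
                  support = integer()))
  }
  dom |>
    distinct(.data$angle_i, .data$angle_j, .data$participant,
             .data$movement) |>
    count(.data$angle_i, .data$angle_j, name = "support") |>
    mutate(support = as.integer(.data$support))
}

#' Most prevalent angle pairs
#'
#' Distinct pairs of the filter domain ordered by support (number of
#' networks containing the pair) descending; ties broken lexicographically
#' on (smaller id, larger id) for determinism. `k = 1` returns the head of
#' the argmax set.
#'
#' @param union_set a `union_edge_set`.
#' @param spec an [edge_filter()] domain or NULL.
#' @param k number of pairs to return (>= 1).
#' @return tibble `angle_i`, `angle_j`, `support`, at most `k` rows.
#' @export
most_prevalent_edges <- function(union_set, spec = NULL, k = 1L) {
  if (k < 1) stop_invalid("k must be >= 1")
  dom <- if (is.null(spec)) union_set else filter_edges(union_set, spec)
  support_table(dom) |>
    arrange(dplyr::desc(.data$support), .data$angle_i, .data$angle_j) |>
    slice_head(n = k)
}

#' Pairs exclusive to one of two domains
#'
#' Partitions the distinct angle pairs occurring in either domain by
#' presence pattern: present only under `spec_a`, only under `spec_b`, or
#' shared. Presence means support >= 1 anywhere in the domain; support
#' magnitudes are not compared.
#'
#' @param union_set a `union_edge_set`.
#' @param spec_a,spec_b [edge_filter()] domains (`mode = "all"`).
#' @return list with tibbles `only_a`, `only_b`, `shared` (columns
#'   `angle_i`, `angle_j`).
#' @export
group_exclusive_edges <- function(union_set, spec_a, spec_b) {
  pa <- distinct(filter_edges(union_set, spec_a), .data$angle_i, .data$angle_j)
  pb <- distinct(filter_edges(union_set, spec_b), .data$angle_i, .data$angle_j)
  key <- function(d) paste(d$angle_i, d$angle_j)
  list(
    only_a = arrange(pa[!key(pa) %in% key(pb), ], .data$angle_i, .data$angle_j),
    only_b = arrange(pb[!key(pb) %in% key(pa), ], .data$angle_i, .data$angle_j),
    shared = arrange(pa[key(pa) %in% key(pb), ], .data$angle_i, .data$angle_j)
  )
}

#' Apply an edge filter end-to-end
#'
#' Dispatch on the filter mode: `all` returns the filtered records, `topk`
#' the prevalence ranking, `intersection`/`differences` the shared /
#' exclusive pairs against a second domain.
#'
#' @param union_set a `union_edge_set`.
#' @param spec an [edge_filter()].
#' @param other second [edge_filter()] for `differences` / `intersection`.
#' @return depends on mode (see the individual functions).
#' @export
apply_edge_filter <- function(union_set, spec, other = NULL) {
  switch(spec$mode,
    all = filter_edges(union_set, spec),
    topk = most_prevalent_edges(union_set, spec, k = spec$k),
    differences = {
      if (is.null(other)) stop_invalid("differences mode needs a second domain")
      group_exclusive_edges(union_set, spec, other)
    },
    intersection = {
      if (is.null(other)) stop_invalid("intersection mode needs a second domain")
      group_exclusive_edges(union_set, spec, other)$shared
    }
  )
}

#' Write filtered edges as JSON
#'
#' @param union_set a `union_edge_set` (typically already filtered).
#' @param path output JSON file.
#' @param angles optional angle metadata to attach names.
#' @return `path`, invisibly.
#' @export
write_edges_json <- function(union_set, path, angles = NULL) {
  sup <- support_table(union_set)
  contributors <- union_set |>
    distinct(.data$angle_i, .data$angle_j, .data$participant) |>
    group_by(.data$angle_i, .data$angle_j) |>
    summarise(participants = list(sort(unique(.data$participant))),
              .groups = "drop")
  out <- left_join(sup, contributors, by = c("angle_i", "angle_j"))
  if (!is.null(angles)) {
    nm <- setNames(angles$name, angles$id)
    out$name_i <- unname(nm[as.character(out$angle_i)])
    out$name_j <- unname(nm[as.character(out$angle_j)])
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
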