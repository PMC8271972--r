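#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr filter mutate select arrange group_by summarise ungroup
#'   left_join bind_rows distinct n pull across rename count slice_head
#' @importFrom purrr map map2 pmap map_dbl map_int map_chr map_lgl
#' @importFrom stats spline approx prcomp cmdscale dist optim rnorm runif sd
#'   setNames
#' @importFrom utils head
NULL

stop_invalid <- function(msg, class = "kinegraph_invalid_input") {
  abort(msg, class = c(class, "kinegraph_error"))
}

check_finite_numeric <- function(x, what = "values") {
  if (!is.numeric(x)) {
    stop_invalid(sprintf("%s must be numeric", what))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop_invalid(sprintf("%s contain non-finite entries", what))
  }
  invisible(x)
}

# group/side token used throughout the filtering algebra
group_side_token <- function(group, side) {
  paste0(ifelse(group == "stroke", "stroke", "ctrl"), side)
}

all_group_sides <- c("strokeL", "strokeR", "ctrlL", "ctrlR")

movement_label <- function(id) paste0("M", id)
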