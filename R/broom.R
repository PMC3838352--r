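#' Tidy and summarize strucnet result objects
#'
#' broom-style accessors: `tidy()` returns one row per element (node, residue,
#' cell), `glance()` one row per object.
#'
#' @param x A strucnet result object.
#' @param ... Ignored.
#' @return A tibble.
#' @name strucnet-broom
NULL

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname strucnet-broom
#' @export
tidy.node_scores <- function(x, ...) {
  as_tibble(x) |> mutate(method = attr(x, "method")) |>
    arrange(desc(.data$score))
}

#' @rdname strucnet-broom
#' @export
glance.node_scores <- function(x, ...) {
  tibble(method = attr(x, "method"), n_nodes = nrow(x),
         n_seeds = sum(x$is_seed),
         n_unresolved = length(attr(x, "unresolved")),
         min_score = min(x$score), max_score = max(x$score))
}

#' @rdname strucnet-broom
#' @export
tidy.location_pref_test <- function(x, ...) {
  tibble(estimate = x$odds_ratio, p.value = x$p,
         method = paste0("Fisher exact (two-tailed), ", x$convention))
}

#' @rdname strucnet-broom
#' @export
glance.ppi_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         average_degree = average_degree(x),
         n_components = igraph::components(as_igraph(x))$no)
}
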