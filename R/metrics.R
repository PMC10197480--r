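#' Network parameters of a plant trait network
#'
#' Computes the three classical PTN parameters on the binary graph:
#' \describe{
#'   \item{degree}{number of edges incident to each trait node; a trait with a
#'     high degree is a hub trait.}
#'   \item{edge density}{realized edges divided by the maximum possible
#'     `p(p-1)/2`, in `[0, 1]`.}
#'   \item{modularity}{Newman-Girvan quality `Q = sum_c (e_cc - a_c^2)` of a
#'     community partition found by modularity maximisation.}
#' }
#' The default community algorithm is deterministic greedy agglomeration
#' (Clauset-Newman-Moore, `igraph::cluster_fast_greedy`), so module memberships
#' are bit-reproducible across runs; Louvain is available behind
#' `method = "louvain"` with a mandatory seed. Isolated traits form singleton
#' modules. The modularity of an edgeless network is defined as 0 by
#' convention (the formula is 0/0 there).
#'
#' @param net A `ptn` object from [threshold_network()].
#' @param method `"greedy"` (default, deterministic) or `"louvain"`.
#' @param seed Integer seed, required for `"louvain"`.
#' @return An object of class `ptn_metrics`: per-trait `degree`, scalar
#'   `edge_density` and `modularity`, the `membership` map trait -> module
#'   label, and `n_modules`. `tidy()` gives one row per trait
#'   (trait, degree, module); `glance()` gives the scalar parameters.
#' @examples
#' net <- simulate_traits(n = 150, rho_in = 0.8, rho_out = 0, seed = 1) |>
#'   log_transform() |>
#'   threshold_network()
#' glance(network_metrics(net))
#' @export
network_metrics <- function(net, method = c("greedy", "louvain"), seed = NULL) {
  method <- match.arg(method)
  if (!inherits(net, "ptn")) abort("`net` must be a `ptn` object")
  p <- length(net$traits)
  if (p < 2) abort("network needs at least two traits")

  degree <- stats::setNames(as.integer(rowSums(net$adjacency)), net$traits)
  edge_density <- sum(degree) / 2 / choose(p, 2)

  g <- ptn_igraph(net)
  if (sum(degree) == 0) {
    membership <- stats::setNames(seq_len(p), net$traits)
    q <- 0
  } else if (method == "greedy") {
    comm <- igraph::cluster_fast_greedy(g)
    # cut the merge dendrogram at the modularity maximum ourselves:
    # igraph's default membership can stop one merge short when the final
    # merges change Q only at floating-point noise (e.g. complete graphs)
    best <- which.max(comm$modularity)
    membership <- stats::setNames(as.integer(igraph::cut_at(comm, steps = best - 1)),
                                  net$traits)
    q <- igraph::modularity(g, membership)
  } else {
    if (is.null(seed)) abort("`seed` is required for louvain (the algorithm is randomized)")
    comm <- withr::with_seed(as.integer(seed), igraph::cluster_louvain(g))
    membership <- stats::setNames(as.integer(igraph::membership(comm)), net$traits)
    q <- igraph::modularity(g, membership)
  }

  structure(list(degree = degree, edge_density = edge_density, modularity = q,
                 membership = membership, n_modules = length(unique(membership)),
                 method = method, traits = net$traits, alpha = net$alpha),
            class = "ptn_metrics")
}

#' @export
print.ptn_metrics <- function(x, ...) {
  cat(sprintf("<ptn_metrics> %d traits | edge density %.3f | modularity %.3f | %d modules (%s)\n",
              length(x$traits), x$edge_density, x$modularity, x$n_modules, x$method))
  invisible(x)
}

#' @rdname network_metrics
#' @param x A `ptn_metrics` object.
#' @param ... Unused.
#' @method tidy ptn_metrics
#' @export
tidy.ptn_metrics <- function(x, ...) {
  tibble(trait = x$traits,
         degree = as.integer(x$degree[x$traits]),
         module = as.integer(x$membership[x$traits]))
}

#' @rdname network_metrics
#' @method glance ptn_metrics
#' @export
glance.ptn_metrics <- function(x, ...) {
  tibble(edge_density = x$edge_density, modularity = x$modularity,
         n_modules = x$n_modules, n_edges = sum(x$degree) / 2,
         method = x$method, alpha = x$alpha)
}

#' Hub traits: the most connected nodes
#'
#' Ranks traits by degree (descending), ties broken lexicographically by trait
#' name so the ranking is deterministic, and returns the top `k`.
#'
#' @param metrics A `ptn_metrics` object.
#' @param k Number of traits to return (default 1).
#' @return A tibble (trait, degree, rank) with `k` rows.
#' @export
hub_traits <- function(metrics, k = 1) {
  assert_scalar_number(k, "k", lower = 1)
  tidy(metrics) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$trait) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::slice_head(n = as.integer(k)) |>
    dplyr::select("trait", "degree", "rank")
}

#' Absolute and relative importance of trait categories
#'
#' The absolute importance of a functional category is the mean degree of its
#' traits; the relative importance divides that by the sum of all trait
#' degrees. On an edgeless network both are 0 (relative importance is defined
#' as 0 when the total degree is 0).
#'
#' @param metrics A `ptn_metrics` object, or a tidy per-trait degree tibble
#'   with columns `trait` and `degree` (degrees may be non-integer, e.g.
#'   bootstrap means).
#' @param categories Category scheme tibble covering all traits
#'   (default [trait_categories()]).
#' @return A tibble (category, n_traits, absolute_importance,
#'   relative_importance), ordered by decreasing absolute importance.
#' @examples
#' net <- simulate_traits(n = 150, seed = 1) |> log_transform() |> threshold_network()
#' trait_importance(network_metrics(net))
#' @export
trait_importance <- function(metrics, categories = trait_categories()) {
  deg <- if (inherits(metrics, "ptn_metrics")) tidy(metrics) else as_tibble(metrics)
  if (!all(c("trait", "degree") %in% names(deg))) {
    abort("`metrics` must be a ptn_metrics object or a tibble with columns `trait` and `degree`")
  }
  check_categories(categories, deg$trait)
  total <- sum(deg$degree)
  deg |>
    dplyr::inner_join(categories, by = "trait") |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n_traits = dplyr::n(),
                     absolute_importance = mean(.data$degree),
                     .groups = "drop") |>
    dplyr::mutate(relative_importance =
                    if (total > 0) .data$absolute_importance / total else 0) |>
    dplyr::arrange(dplyr::desc(.data$absolute_importance), .data$category)
}

#' Write per-trait metrics and scalar parameters
#'
#' Writes the tidy per-trait table (degree, module) as CSV and the scalar
#' block (edge density, modularity, number of modules) as JSON.
#'
#' @param metrics A `ptn_metrics` object.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_ptn_metrics <- function(metrics, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) readr::write_csv(tidy(metrics), csv_path, progress = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(edge_density = metrics$edge_density, modularity = metrics$modularity,
           n_modules = metrics$n_modules, method = metrics$method),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csv_path, json_path))
}
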