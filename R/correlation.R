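#' Pairwise Pearson correlations with p-values
#'
#' Computes, for every pair of trait columns, the Pearson correlation over
#' pairwise-complete records together with a two-sided p-value from the
#' t-transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of
#' freedom. Trait tables should be log-transformed first ([log_transform()]);
#' the correlation itself is invariant to the log base and to affine rescaling
#' of the raw traits.
#'
#' Pairs with fewer than `min_n` complete observations, and pairs where one
#' trait has zero variance, get `r = NA` and `p = 1` (never an edge), with a
#' warning for the zero-variance case.
#'
#' @param data A (log-transformed) trait tibble.
#' @param traits Trait columns (default: auto-detected).
#' @param min_n Minimum pairwise-complete sample size for a defined p-value
#'   (default 4, the smallest n giving the t reference >= 2 df).
#' @return An object of class `ptn_cor`: list with `p x p` matrices `r`,
#'   `pvalue`, `n_eff` and the trait names. `tidy()` returns one row per
#'   unordered pair.
#' @examples
#' x <- log_transform(simulate_traits(n = 60, seed = 1))
#' cc <- pairwise_pearson(x)
#' tidy(cc)
#' @export
pairwise_pearson <- function(data, traits = NULL, min_n = 4) {
  traits <- resolve_traits(data, traits)
  assert_scalar_number(min_n, "min_n", lower = 4)
  if (length(traits) < 2) abort("need at least two trait columns")
  m <- as.matrix(as_tibble(data)[traits])
  storage.mode(m) <- "double"

  n_eff <- crossprod(!is.na(m))
  suppressWarnings(r <- stats::cor(m, use = "pairwise.complete.obs"))

  zero_var <- is.na(r) & n_eff >= min_n
  diag(zero_var) <- FALSE
  if (any(zero_var)) {
    warn("zero-variance trait pair(s): correlation undefined, treated as no edge")
  }
  r[n_eff < min_n] <- NA_real_

  df <- n_eff - 2
  tstat <- r * sqrt(df) / sqrt(pmax(1 - r^2, 0))
  pvalue <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  pvalue[r^2 >= 1] <- 0  # |r| = 1: t infinite
  pvalue[is.na(pvalue)] <- 1
  diag(r) <- 1
  diag(pvalue) <- 0
  dimnames(r) <- dimnames(pvalue) <- dimnames(n_eff) <- list(traits, traits)

  structure(list(r = r, pvalue = pvalue, n_eff = n_eff, traits = traits),
            class = "ptn_cor")
}

#' @export
print.ptn_cor <- function(x, ...) {
  cat(sprintf("<ptn_cor> %d traits, %d pairs\n", length(x$traits),
              choose(length(x$traits), 2)))
  invisible(x)
}

#' @rdname pairwise_pearson
#' @param x A `ptn_cor` object.
#' @param ... Unused.
#' @method tidy ptn_cor
#' @export
tidy.ptn_cor <- function(x, ...) {
  p <- length(x$traits)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(
    trait_a = x$traits[idx[, 1]],
    trait_b = x$traits[idx[, 2]],
    r = x$r[idx],
    p_value = x$pvalue[idx],
    n = as.integer(x$n_eff[idx]),
    sign = ifelse(is.na(x$r[idx]), NA_character_,
                  ifelse(x$r[idx] >= 0, "positive", "negative"))
  )
}

#' Threshold a correlation structure into a plant trait network
#'
#' Builds the binary adjacency matrix of the PTN: a pair of traits is joined by
#' an (unsigned) edge when its correlation p-value is strictly below `alpha`.
#' Both positive and negative significant correlations become edges; the sign
#' is preserved in the edge list for inspection but not in the adjacency.
#' No multiple-testing correction is applied by default — the classical PTN
#' recipe thresholds raw p-values; `adjust = "BH"` enables a
#' Benjamini-Hochberg variant as a clearly non-default extension.
#'
#' @param x A `ptn_cor` object from [pairwise_pearson()], or a trait tibble
#'   (then [pairwise_pearson()] is called first with `...` forwarded).
#' @param alpha Significance threshold in (0, 1); default 0.05. The inequality
#'   is strict: `p == alpha` yields no edge.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param ... Passed to [pairwise_pearson()] when `x` is a data frame.
#' @return An object of class `ptn`: list with the binary symmetric `adjacency`
#'   matrix (zero diagonal), `traits`, `alpha` and the source `ptn_cor`.
#'   `tidy()` returns the edge list with `r`, `p_value` and sign.
#' @examples
#' net <- simulate_traits(n = 100, seed = 1) |> log_transform() |> threshold_network()
#' net
#' @export
threshold_network <- function(x, alpha = 0.05, adjust = c("none", "BH"), ...) {
  adjust <- match.arg(adjust)
  if (is.data.frame(x)) x <- pairwise_pearson(x, ...)
  if (!inherits(x, "ptn_cor")) abort("`x` must be a trait table or a `ptn_cor` object")
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie strictly in (0, 1)")

  pv <- x$pvalue
  if (adjust == "BH") {
    up <- upper.tri(pv)
    adj_p <- stats::p.adjust(pv[up], method = "BH")
    pv[up] <- adj_p
    pv[lower.tri(pv)] <- t(pv)[lower.tri(pv)]
  }
  adjacency <- (pv < alpha) * 1L
  diag(adjacency) <- 0L
  dimnames(adjacency) <- list(x$traits, x$traits)

  structure(list(adjacency = adjacency, traits = x$traits, alpha = alpha,
                 adjust = adjust, cor = x),
            class = "ptn")
}

n_edges <- function(net) sum(net$adjacency) / 2

#' @export
print.ptn <- function(x, ...) {
  p <- length(x$traits)
  cat(sprintf("<ptn> %d traits, %d edges (density %.3f), alpha = %s\n",
              p, n_edges(x), n_edges(x) / choose(p, 2), format(x$alpha)))
  invisible(x)
}

#' @rdname threshold_network
#' @method tidy ptn
#' @export
tidy.ptn <- function(x, ...) {
  el <- tidy(x$cor)
  idx <- which(upper.tri(x$adjacency), arr.ind = TRUE)
  el$edge <- x$adjacency[idx] == 1L
  dplyr::filter(el, .data$edge) |> dplyr::select(-"edge")
}

ptn_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected", diag = FALSE)
}

#' Export a trait network
#'
#' `write_ptn_edges()` writes the edge list (trait pair, r, p, sign) as CSV;
#' `write_ptn_graphml()` writes GraphML with trait name and functional
#' category as node attributes, for use in external graph tools.
#'
#' @param net A `ptn` object.
#' @param path Output file path.
#' @param categories Category scheme tibble (default [trait_categories()]
#'   where it covers the traits).
#' @return `path`, invisibly.
#' @export
write_ptn_edges <- function(net, path) {
  readr::write_csv(tidy(net), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_ptn_edges
#' @export
write_ptn_graphml <- function(net, path, categories = NULL) {
  g <- ptn_igraph(net)
  if (is.null(categories) && all(net$traits %in% trait_categories()$trait)) {
    categories <- trait_categories()
  }
  if (!is.null(categories)) {
    check_categories(categories, net$traits)
    igraph::V(g)$category <- categories$category[match(net$traits, categories$trait)]
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_ptn_edges
#' @export
write_ptn_matrices <- function(net, path) {
  stem <- sub("\\.csv$", "", path)
  for (nm in c("r", "pvalue")) {
    out <- as_tibble(net$cor[[nm]], rownames = "trait")
    readr::write_csv(out, paste0(stem, "_", nm, ".csv"), progress = FALSE)
  }
  invisible(path)
}
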