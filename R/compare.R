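#' Split a trait table into comparison groups
#'
#' Splits records by life-form (woody vs herbaceous) or by aridity region:
#' records with aridity index below `aridity_boundary` are `arid`, records at
#' or above it are `semi_arid`. The boundary value itself (conventionally 0.2)
#' is assigned to the semi-arid region. Records with a missing group value are
#' excluded with a message reporting the count.
#'
#' @param data A trait tibble with the relevant grouping column
#'   (`life_form` or `aridity_index`).
#' @param by `"life_form"` or `"aridity"`.
#' @param aridity_boundary Aridity-index boundary (default 0.2).
#' @param min_n Minimum records per group (default 4, the smallest n with a
#'   defined correlation p-value).
#' @param drop_empty If `FALSE` (default), an expected group with fewer than
#'   `min_n` records — including zero — is an error naming the group; if
#'   `TRUE`, entirely absent groups are dropped with a warning instead
#'   (groups present with 1 to `min_n - 1` records still error).
#' @return A named list of tibbles, one per group.
#' @examples
#' x <- simulate_traits(n = 30, group_effects = c(woody = 0.7, herbaceous = 1), seed = 1)
#' lengths(lapply(split_groups(x, "life_form"), nrow))
#' @export
split_groups <- function(data, by = c("life_form", "aridity"),
                         aridity_boundary = 0.2, min_n = 4, drop_empty = FALSE) {
  by <- match.arg(by)
  data <- as_tibble(data)
  if (by == "life_form") {
    if (!"life_form" %in% names(data)) abort("column `life_form` not found")
    key <- as.character(data$life_form)
    observed <- sort(unique(stats::na.omit(key)))
    # canonical woody/herbaceous labels imply both are expected; other label
    # sets are taken as-is
    expected <- if (any(observed %in% c("woody", "herbaceous"))) {
      union(c("woody", "herbaceous"), observed)
    } else observed
  } else {
    if (!"aridity_index" %in% names(data)) abort("column `aridity_index` not found")
    assert_scalar_number(aridity_boundary, "aridity_boundary")
    ai <- data$aridity_index
    key <- ifelse(is.na(ai), NA_character_,
                  ifelse(ai < aridity_boundary, "arid", "semi_arid"))
    expected <- c("arid", "semi_arid")
  }
  n_missing <- sum(is.na(key))
  if (n_missing > 0) {
    inform(sprintf("%d record(s) with missing group value excluded", n_missing))
  }
  groups <- purrr::map(stats::setNames(expected, expected),
                       function(g) data[!is.na(key) & key == g, , drop = FALSE])
  sizes <- vapply(groups, nrow, integer(1))
  empty <- names(groups)[sizes == 0]
  if (length(empty) && drop_empty) {
    warn(paste0("group(s) with no records dropped: ", paste(empty, collapse = ", ")))
    groups <- groups[sizes > 0]
    sizes <- sizes[sizes > 0]
  }
  small <- names(groups)[sizes < min_n]
  if (length(small)) {
    abort(sprintf("group(s) with fewer than %d records: %s", min_n,
                  paste(small, collapse = ", ")))
  }
  groups
}

as_sample_list <- function(samples) {
  if (is.data.frame(samples)) {
    if (!all(c("item", "value") %in% names(samples))) {
      abort("`samples` data frame needs columns `item` and `value`")
    }
    samples <- split(samples$value, samples$item)
  }
  if (!is.list(samples) || is.null(names(samples))) {
    abort("`samples` must be a named list of numeric vectors or an item/value data frame")
  }
  samples
}

#' Duncan's multiple range test
#'
#' Step-down multiple-comparison procedure over item means (here typically
#' bootstrap degree distributions of the traits), reported as letter
#' groupings: items sharing a letter do not differ at level `alpha`. Items are
#' ranked by mean; the shortest significant range for a span of `p` ordered
#' means uses the studentized-range quantile at Duncan's protection level
#' `1 - (1 - alpha)^(p - 1)`, scaled by `sqrt(MSE / n_h)` with the pooled
#' within-item mean square and the harmonic mean `n_h` of the replicate
#' counts. A range not exceeding its critical value renders all sub-ranges
#' non-significant (the step-down protection rule). Letters are assigned
#' deterministically, `a` to the group containing the highest mean.
#'
#' @param samples Named list of numeric replicate vectors (>= 2 items, each of
#'   length >= 2), or a long data frame with columns `item` and `value`.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `ptn_duncan`; `tidy()` returns a tibble
#'   (item, mean, n, letters) sorted by decreasing mean.
#' @examples
#' duncan_mrt(list(a = rnorm(20), b = rnorm(20), c = rnorm(20, 5))) |> tidy()
#' @export
duncan_mrt <- function(samples, alpha = 0.05) {
  samples <- as_sample_list(samples)
  if (length(samples) < 2) abort("need at least two items")
  ns <- lengths(samples)
  if (any(ns < 2)) abort("every item needs at least two replicates")
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1)

  k <- length(samples)
  means <- vapply(samples, mean, numeric(1))
  vars <- vapply(samples, stats::var, numeric(1))
  dfe <- sum(ns - 1)
  mse <- sum((ns - 1) * vars) / dfe
  n_h <- k / sum(1 / ns)

  ord <- order(-means, names(means))  # descending mean, name-stable ties
  m <- means[ord]

  # critical range for each span p = 2..k
  crit <- c(NA_real_, vapply(2:k, function(p) {
    stats::qtukey((1 - alpha)^(p - 1), nmeans = p, df = dfe) * sqrt(mse / n_h)
  }, numeric(1)))

  # step-down: largest spans first; a non-significant range shields sub-ranges
  nsd <- diag(TRUE, k)
  for (span in k:2) {
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      if (nsd[i, j]) next
      if ((m[i] - m[j]) <= crit[span]) nsd[i:j, i:j] <- TRUE
    }
  }

  # letters: maximal runs of mutually non-different sorted items
  runs <- purrr::map(seq_len(k), function(i) {
    j <- i
    while (j < k && nsd[i, j + 1]) j <- j + 1
    c(i, j)
  })
  keep <- purrr::map_lgl(seq_along(runs), function(a) {
    !any(purrr::map_lgl(seq_along(runs), function(b) {
      b != a && runs[[b]][1] <= runs[[a]][1] && runs[[b]][2] >= runs[[a]][2]
    }))
  })
  runs <- runs[keep]
  runs <- runs[order(vapply(runs, `[`, numeric(1), 1))]
  letter_of <- vapply(seq_along(runs), function(g) {
    paste0(rep(letters, length.out = g)[g], strrep("'", (g - 1) %/% 26))
  }, character(1))
  lab <- vapply(seq_len(k), function(i) {
    paste(letter_of[purrr::map_lgl(runs, function(rg) rg[1] <= i && i <= rg[2])],
          collapse = "")
  }, character(1))

  out <- tibble(item = names(m), mean = unname(m), n = unname(ns[ord]),
                letters = lab)
  structure(list(table = out, alpha = alpha, mse = mse, dfe = dfe, n_h = n_h,
                 critical_ranges = crit, nonsignificant = nsd),
            class = "ptn_duncan")
}

#' @export
print.ptn_duncan <- function(x, ...) {
  cat(sprintf("<ptn_duncan> %d items, alpha = %s, MSE = %.4g (df = %d)\n",
              nrow(x$table), format(x$alpha), x$mse, x$dfe))
  print(x$table, n = Inf)
  invisible(x)
}

#' @rdname duncan_mrt
#' @param x A `ptn_duncan` object.
#' @param ... Unused.
#' @method tidy ptn_duncan
#' @export
tidy.ptn_duncan <- function(x, ...) x$table

#' Do two items share a Duncan letter?
#'
#' @param x A `ptn_duncan` object.
#' @return Logical symmetric matrix over items (original order of `tidy(x)`).
#' @export
duncan_shared <- function(x) {
  stopifnot(inherits(x, "ptn_duncan"))
  s <- x$nonsignificant
  dimnames(s) <- list(x$table$item, x$table$item)
  s
}

#' Independent two-sample t-test
#'
#' Welch's unequal-variance t-test by default (`var_equal = TRUE` for the
#' pooled-variance Student's t), as used to compare network parameters between
#' life-forms or aridity regions. When both samples have zero variance and
#' equal means the statistic is taken as `t = 0`, `p = 1` by convention.
#'
#' When the inputs are bootstrap replicate distributions of a network
#' parameter, note that bootstrap replicates are not independent samples: the
#' resulting p-values are descriptive, not confirmatory.
#'
#' @param a,b Numeric replicate vectors, each of length >= 2.
#' @param var_equal Pool the variances (default `FALSE` = Welch).
#' @return A one-row tibble: mean_a, mean_b, estimate (mean_a - mean_b),
#'   statistic (t), df, p_value, method.
#' @examples
#' welch_ttest(rnorm(30), rnorm(30, 1))
#' @export
welch_ttest <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2 || length(b) < 2) abort("each sample needs at least two values")
  res <- tryCatch(
    stats::t.test(a, b, var.equal = var_equal),
    error = function(e) {
      if (grepl("essentially constant", conditionMessage(e))) NULL else stop(e)
    }
  )
  if (is.null(res)) {
    d <- mean(a) - mean(b)
    inform("zero variance in both samples: t-test degenerate, using sign convention")
    return(tibble(mean_a = mean(a), mean_b = mean(b), estimate = d,
                  statistic = if (d == 0) 0 else sign(d) * Inf,
                  df = NA_real_, p_value = if (d == 0) 1 else 0,
                  method = if (var_equal) "student" else "welch"))
  }
  tibble(mean_a = mean(a), mean_b = mean(b), estimate = mean(a) - mean(b),
         statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = res$p.value,
         method = if (var_equal) "student" else "welch")
}

#' Compare trait networks between groups
#'
#' Runs the full pipeline per group — log-transform (optional), network
#' construction, metrics, category importance, species bootstrap — then
#' compares groups by Welch t-tests on the bootstrap distributions of edge
#' density and modularity, and compares traits within each group by Duncan's
#' multiple range test on the bootstrap degree distributions (and categories
#' on per-replicate importance).
#'
#' @param data A raw trait tibble with the grouping column.
#' @param by `"life_form"` or `"aridity"`.
#' @param aridity_boundary Boundary for aridity groups (default 0.2).
#' @param B Bootstrap replicates per group (default 1000).
#' @param log Log-transform the traits first (default `TRUE`).
#' @param categories Category scheme (default [trait_categories()] when it
#'   covers the traits, else skipped).
#' @inheritParams bootstrap_ptn
#' @return An object of class `ptn_comparison`: per-group results in
#'   `$groups` (each with `net`, `metrics`, `importance`, `boot`,
#'   `duncan_degree`, `duncan_importance`), pairwise tests in `$tests`.
#'   `tidy()` returns the tests tibble.
#' @export
compare_group_ptns <- function(data, by = c("life_form", "aridity"),
                               aridity_boundary = 0.2, B = 1000,
                               fraction_min = 0.75, alpha = 0.05,
                               method = "greedy", traits = NULL,
                               categories = NULL, log = TRUE, seed) {
  if (missing(seed)) abort("`seed` is required")
  by <- match.arg(by)
  traits <- resolve_traits(data, traits)
  if (is.null(categories) && all(traits %in% trait_categories()$trait)) {
    categories <- trait_categories()
  }
  groups <- split_groups(data, by, aridity_boundary, drop_empty = TRUE)
  if (length(groups) < 2) {
    warn("only one group present: no between-group tests")
  }
  group_seeds <- derive_seeds(seed, length(groups))

  results <- purrr::imap(groups, function(gd, gname) {
    gseed <- group_seeds[match(gname, names(groups))]
    if (log) gd <- log_transform(gd, traits)
    net <- threshold_network(gd, alpha = alpha, traits = traits)
    met <- network_metrics(net, method = method,
                           seed = if (method == "louvain") gseed else NULL)
    imp <- if (!is.null(categories)) trait_importance(met, categories) else NULL
    bt <- bootstrap_ptn(gd, B = B, fraction_min = fraction_min, alpha = alpha,
                        method = method, traits = traits, seed = gseed)
    deg_reps <- dplyr::filter(bt$replicates, .data$parameter == "degree")
    dd <- duncan_mrt(dplyr::transmute(deg_reps, item = .data$trait,
                                      value = .data$value), alpha = alpha)
    di <- NULL
    if (!is.null(categories)) {
      imp_reps <- deg_reps |>
        dplyr::inner_join(categories, by = c(trait = "trait")) |>
        dplyr::group_by(.data$replicate, .data$category) |>
        dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
        dplyr::transmute(item = .data$category, value = .data$value)
      di <- duncan_mrt(imp_reps, alpha = alpha)
    }
    list(data = gd, net = net, metrics = met, importance = imp, boot = bt,
         duncan_degree = dd, duncan_importance = di)
  })

  tests <- tibble()
  gn <- names(results)
  if (length(gn) >= 2) {
    pairs <- utils::combn(gn, 2, simplify = FALSE)
    tests <- purrr::map(pairs, function(pr) {
      purrr::map(c("edge_density", "modularity"), function(param) {
        va <- dplyr::filter(results[[pr[1]]]$boot$replicates,
                            .data$parameter == param)$value
        vb <- dplyr::filter(results[[pr[2]]]$boot$replicates,
                            .data$parameter == param)$value
        dplyr::bind_cols(tibble(parameter = param,
                                group_a = pr[1], group_b = pr[2]),
                         welch_ttest(va, vb))
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }

  structure(list(groups = results, tests = tests, by = by, B = as.integer(B),
                 alpha = alpha, seed = seed),
            class = "ptn_comparison")
}

#' @export
print.ptn_comparison <- function(x, ...) {
  cat(sprintf("<ptn_comparison> by %s: %s\n", x$by,
              paste(names(x$groups), collapse = " vs ")))
  for (g in names(x$groups)) {
    gl <- glance(x$groups[[g]]$metrics)
    cat(sprintf("  %-12s edge density %.3f, modularity %.3f, %d modules\n",
                g, gl$edge_density, gl$modularity, gl$n_modules))
  }
  if (nrow(x$tests)) {
    cat("between-group Welch tests on bootstrap distributions:\n")
    print(dplyr::select(x$tests, "parameter", "group_a", "group_b",
                        "statistic", "df", "p_value"), n = Inf)
  }
  invisible(x)
}

#' @rdname compare_group_ptns
#' @param x A `ptn_comparison` object.
#' @param ... Unused.
#' @method tidy ptn_comparison
#' @export
tidy.ptn_comparison <- function(x, ...) x$tests

#' @rdname compare_group_ptns
#' @method glance ptn_comparison
#' @export
glance.ptn_comparison <- function(x, ...) {
  purrr::imap(x$groups, function(res, g) {
    dplyr::bind_cols(tibble(group = g), glance(res$metrics))
  }) |> dplyr::bind_rows()
}
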