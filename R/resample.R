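# One network build: trait table (already log-transformed) -> the three
# parameters. Zero-variance pairs inside a resample degrade to missing edges.
ptn_params <- function(data, traits, alpha, method = "greedy", min_n = 4) {
  cc <- suppressWarnings(pairwise_pearson(data, traits, min_n = min_n))
  net <- threshold_network(cc, alpha = alpha)
  met <- network_metrics(net, method = method)
  list(edge_density = met$edge_density, modularity = met$modularity,
       degree = met$degree)
}

summarise_replicates <- function(reps) {
  reps |>
    dplyr::group_by(.data$parameter, .data$trait) |>
    dplyr::summarise(
      B = dplyr::n(),
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
      se = .data$sd / sqrt(.data$B),
      min = min(.data$value),
      max = max(.data$value),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$parameter, c("edge_density", "modularity", "degree")),
                   .data$trait)
}

replicates_to_long <- function(res_list) {
  purrr::imap(res_list, function(res, b) {
    dplyr::bind_rows(
      tibble(replicate = b, parameter = c("edge_density", "modularity"),
             trait = NA_character_,
             value = c(res$edge_density, res$modularity)),
      tibble(replicate = b, parameter = "degree",
             trait = names(res$degree), value = as.numeric(res$degree))
    )
  }) |> dplyr::bind_rows()
}

#' Species bootstrap of network parameters
#'
#' Rebuilds the trait network on `B` random subsets of the records and
#' summarises the distribution of each network parameter (edge density,
#' modularity, per-trait degree) by its mean, SD, SE (`sd / sqrt(B)`), minimum
#' and maximum — the uncertainty summary conventional for PTN studies, where
#' 5000 resamples each retain at least three-fourths of the species.
#'
#' Each replicate draws a subset size uniformly from
#' `[ceiling(fraction_min * n), n]` and samples that many records without
#' replacement (with `fixed_fraction = TRUE` the size is always
#' `ceiling(fraction_min * n)`). Supply a log-transformed table: the bootstrap
#' resamples rows as-is.
#'
#' @param data A log-transformed trait tibble.
#' @param B Number of bootstrap replicates (default 5000).
#' @param fraction_min Minimum fraction of records retained (default 0.75).
#' @param fixed_fraction If `TRUE`, every replicate uses exactly
#'   `ceiling(fraction_min * n)` records.
#' @param alpha Significance threshold for edges (default 0.05).
#' @param method Community-detection method, see [network_metrics()].
#' @param traits Trait columns (default: auto-detected).
#' @param seed Integer seed; results are bit-reproducible from it, and each
#'   replicate has its own derived sub-seed.
#' @param keep_replicates Keep the per-replicate parameter values (default
#'   `TRUE`; set `FALSE` to save memory at large `B`).
#' @return An object of class `ptn_boot`; `tidy()` returns the summary tibble
#'   (parameter, trait, B, mean, sd, se, min, max).
#' @examples
#' x <- log_transform(simulate_traits(n = 80, seed = 1))
#' bt <- bootstrap_ptn(x, B = 50, seed = 2)
#' tidy(bt)
#' @export
bootstrap_ptn <- function(data, B = 5000, fraction_min = 0.75,
                          fixed_fraction = FALSE, alpha = 0.05,
                          method = "greedy", traits = NULL, seed,
                          keep_replicates = TRUE) {
  if (missing(seed)) abort("`seed` is required for a reproducible bootstrap")
  assert_scalar_number(B, "B", lower = 1)
  assert_scalar_number(fraction_min, "fraction_min", lower = 0, upper = 1)
  if (fraction_min <= 0) abort("`fraction_min` must be in (0, 1]")
  traits <- resolve_traits(data, traits)
  n <- nrow(data)
  m_min <- ceiling(fraction_min * n)
  if (m_min < 4) abort("fraction_min * n must be at least 4 records")

  rep_seeds <- derive_seeds(seed, B)
  retries <- 0L
  max_retries <- max(1, ceiling(0.01 * B))

  run_one <- function(b) {
    withr::with_seed(rep_seeds[b], {
      # sample() treats a length-1 vector as 1:x, so guard the m_min = n case
      m <- if (fixed_fraction || m_min == n) m_min else sample(m_min:n, 1L)
      rows <- sample.int(n, m, replace = FALSE)
      ptn_params(data[rows, , drop = FALSE], traits, alpha, method)
    })
  }
  res_list <- purrr::map(seq_len(B), function(b) {
    out <- tryCatch(run_one(b), error = function(e) NULL)
    while (is.null(out)) {
      retries <<- retries + 1L
      if (retries > max_retries) {
        abort(sprintf("bootstrap replicate failures exceed 1%% of B (%d retries): degenerate input", retries))
      }
      rep_seeds[b] <<- rep_seeds[b] %% (.Machine$integer.max - 1L) + 1L
      out <- tryCatch(run_one(b), error = function(e) NULL)
    }
    out
  })

  reps <- replicates_to_long(res_list)
  structure(list(summary = summarise_replicates(reps),
                 replicates = if (keep_replicates) reps else NULL,
                 B = as.integer(B), fraction_min = fraction_min,
                 fixed_fraction = fixed_fraction, alpha = alpha,
                 method = method, seed = seed, n = n, retries = retries),
            class = "ptn_boot")
}

#' @export
print.ptn_boot <- function(x, ...) {
  sc <- dplyr::filter(x$summary, is.na(.data$trait))
  cat(sprintf("<ptn_boot> B = %d resamples of %d records (fraction >= %.2f)\n",
              x$B, x$n, x$fraction_min))
  for (i in seq_len(nrow(sc))) {
    cat(sprintf("  %-12s mean %.4f  sd %.4f  se %.5f  [%.4f, %.4f]\n",
                sc$parameter[i], sc$mean[i], sc$sd[i], sc$se[i], sc$min[i], sc$max[i]))
  }
  invisible(x)
}

#' @rdname bootstrap_ptn
#' @param x A `ptn_boot` object.
#' @param ... Unused.
#' @method tidy ptn_boot
#' @export
tidy.ptn_boot <- function(x, ...) x$summary

#' @rdname bootstrap_ptn
#' @method glance ptn_boot
#' @export
glance.ptn_boot <- function(x, ...) {
  x$summary |>
    dplyr::filter(is.na(.data$trait)) |>
    dplyr::select(-"trait")
}

#' Species-richness rarefaction of network parameters
#'
#' Charts how the network parameters depend on the number of species: for each
#' count `c` it builds `R` networks from `c` sampled records (by default with
#' replacement, duplicates retained as rows) and summarises edge density and
#' modularity per count. On data with genuine trait correlations, edge density
#' rises and modularity falls as species are added — small samples lack the
#' power to detect correlations, so their networks are sparse and fragment
#' into modules.
#'
#' Sampling with replacement duplicates rows, which inflates the effective n
#' of the correlation p-values; `replace = FALSE` avoids this but caps counts
#' at `nrow(data)`.
#'
#' @param data A log-transformed trait tibble.
#' @param counts Increasing integer vector of species counts (each >= 4).
#'   Default: 10 to `nrow(data)` in 8 steps.
#' @param R Replicates per count (default 500).
#' @param replace Sample records with replacement (default `TRUE`).
#' @inheritParams bootstrap_ptn
#' @return An object of class `ptn_rarefaction`; `tidy()` returns the per-count
#'   summary (species_count, parameter, B, mean, sd, se, min, max).
#'   `autoplot()` draws the mean +/- SE curves.
#' @examples
#' x <- log_transform(simulate_traits(n = 100, rho_in = 0.4, seed = 1))
#' rar <- rarefy_ptn(x, counts = c(10, 30, 90), R = 20, seed = 2)
#' tidy(rar)
#' @export
rarefy_ptn <- function(data, counts = NULL, R = 500, alpha = 0.05,
                       replace = TRUE, method = "greedy", traits = NULL, seed) {
  if (missing(seed)) abort("`seed` is required for a reproducible rarefaction")
  assert_scalar_number(R, "R", lower = 1)
  traits <- resolve_traits(data, traits)
  n <- nrow(data)
  if (is.null(counts)) counts <- unique(round(seq(10, n, length.out = 8)))
  counts <- sort(unique(as.integer(counts)))
  if (any(counts < 4)) abort("every species count must be at least 4")
  if (!replace && any(counts > n)) abort("counts exceed the number of records and `replace = FALSE`")

  count_seeds <- derive_seeds(seed, length(counts))
  per_count <- purrr::map2(counts, count_seeds, function(cnt, cseed) {
    rep_seeds <- derive_seeds(cseed, R)
    res_list <- purrr::map(seq_len(R), function(b) {
      withr::with_seed(rep_seeds[b], {
        rows <- sample.int(n, cnt, replace = replace)
        ptn_params(data[rows, , drop = FALSE], traits, alpha, method)
      })
    })
    reps <- replicates_to_long(res_list) |>
      dplyr::filter(.data$parameter != "degree")
    dplyr::mutate(summarise_replicates(reps), species_count = cnt, .before = 1)
  })
  summary <- dplyr::bind_rows(per_count) |> dplyr::select(-"trait")

  structure(list(summary = summary, counts = counts, R = as.integer(R),
                 alpha = alpha, replace = replace, method = method, seed = seed),
            class = "ptn_rarefaction")
}

#' @export
print.ptn_rarefaction <- function(x, ...) {
  cat(sprintf("<ptn_rarefaction> counts %s | R = %d per count (%s replacement)\n",
              paste(x$counts, collapse = ", "), x$R,
              if (x$replace) "with" else "without"))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @rdname rarefy_ptn
#' @param x A `ptn_rarefaction` object.
#' @param ... Unused.
#' @method tidy ptn_rarefaction
#' @export
tidy.ptn_rarefaction <- function(x, ...) x$summary
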