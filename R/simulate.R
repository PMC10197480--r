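# Block correlation matrix: rho_in within each planted block, rho_out between
# blocks, optional global hub trait correlated rho_hub with every trait outside
# its own block. Returns list(sigma, membership).
build_block_sigma <- function(blocks, rho_in, rho_out, hub_trait = NULL, rho_hub = 0.4) {
  traits <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(traits)) abort("planted blocks overlap")
  p <- length(traits)
  if (length(rho_in) == 1L) rho_in <- rep(rho_in, length(blocks))
  if (length(rho_in) != length(blocks)) abort("`rho_in` must be scalar or one value per block")
  if (any(rho_in < 0 | rho_in >= 1)) abort("`rho_in` must lie in [0, 1)")
  if (rho_out < 0) abort("`rho_out` must be non-negative")
  if (any(rho_out > rho_in)) abort("`rho_out` must not exceed `rho_in` (planted modules must be detectable)")

  sigma <- matrix(rho_out, p, p, dimnames = list(traits, traits))
  membership <- integer(p)
  names(membership) <- traits
  for (b in seq_along(blocks)) {
    idx <- match(blocks[[b]], traits)
    sigma[idx, idx] <- rho_in[b]
    membership[idx] <- b
  }
  if (!is.null(hub_trait)) {
    if (!hub_trait %in% traits) abort(sprintf("hub trait `%s` not among the planted traits", hub_trait))
    h <- match(hub_trait, traits)
    others <- which(membership != membership[h])
    sigma[h, others] <- pmax(sigma[h, others], rho_hub)
    sigma[others, h] <- sigma[h, others]
  }
  diag(sigma) <- 1

  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    repaired <- as.matrix(Matrix::nearPD(sigma, corr = TRUE)$mat)
    shift <- max(abs(repaired - sigma))
    if (shift > 0.1) {
      abort(sprintf("block correlation matrix is not positive semi-definite and nearest-PSD repair moves entries by %.3f (> 0.1)", shift))
    }
    warn(sprintf("block correlation matrix repaired to nearest PSD (max entry change %.4f)", shift))
    sigma <- repaired
    dimnames(sigma) <- list(traits, traits)
  }
  names(blocks) <- names(blocks) %||% paste0("M", seq_along(blocks))
  list(sigma = sigma, membership = stats::setNames(names(blocks)[membership], traits))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

draw_lognormal <- function(n, sigma, log_mean, log_sd) {
  p <- ncol(sigma)
  traits <- colnames(sigma)
  if (length(log_mean) == 1L) log_mean <- rep(log_mean, p)
  if (length(log_sd) == 1L) log_sd <- rep(log_sd, p)
  z <- matrix(stats::rnorm(n * p), n, p) %*% chol(sigma)
  x <- exp(sweep(sweep(z, 2, log_sd, `*`), 2, log_mean, `+`))
  colnames(x) <- traits
  as_tibble(x)
}

#' Simulate trait tables with planted correlation structure
#'
#' Generates species-by-trait records from a multivariate Gaussian on the log
#' scale — so trait values are lognormal (always positive) and the pipeline's
#' [log_transform()] recovers the planted correlations exactly — with a block
#' ("module") correlation structure: correlation `rho_in` within each planted
#' block and `rho_out` between blocks. Optionally one trait is planted as a
#' global hub, correlated at least `rho_hub` with every other trait. Optional
#' groups scale the correlation strengths by a per-group multiplier,
#' emulating life-forms or aridity regions whose trait networks differ in
#' connectivity rather than in trait means.
#'
#' The defaults mimic a dryland trait survey: 188 records of the 16 standard
#' traits, blocks equal to the economic/chemical/structural categories.
#'
#' @param n Number of records (default 188). With groups, records per group.
#' @param blocks Named list of trait-name vectors defining the planted
#'   modules. Default: the three functional categories of [trait_categories()].
#' @param rho_in Within-block correlation in `[0, 1)`; scalar or one per block.
#' @param rho_out Between-block correlation, `0 <= rho_out <= rho_in`.
#' @param hub_trait Optional trait name planted as a global hub.
#' @param rho_hub Correlation of the hub with traits outside its block.
#' @param log_mean,log_sd Mean and SD of log trait values; scalar or per trait.
#' @param group_effects Optional named numeric vector of multipliers applied to
#'   `(rho_in, rho_out)` per group, e.g. `c(woody = 0.75, herbaceous = 1)`.
#' @param group_col Name of the label column when `group_effects` is given;
#'   if `"aridity_index"`, groups named `"arid"`/`"semi_arid"` receive aridity
#'   values below / at-or-above 0.2 instead of a label column.
#' @param seed Integer seed; the output is fully reproducible from it.
#' @return A tibble of positive trait values with a `record_id` column, an
#'   `aridity_index` column, and (with groups) the group label column. The
#'   planted ground truth (module membership, correlation matrix, hub) is
#'   attached as attribute `"ptn_truth"` and returned by [ptn_truth()].
#' @examples
#' x <- simulate_traits(n = 50, rho_in = 0.8, rho_out = 0, seed = 1)
#' ptn_truth(x)$membership
#' @export
simulate_traits <- function(n = 188, blocks = NULL, rho_in = 0.6, rho_out = 0.1,
                            hub_trait = NULL, rho_hub = 0.4,
                            log_mean = 0, log_sd = 0.6,
                            group_effects = NULL, group_col = "life_form",
                            seed) {
  if (missing(seed)) abort("`seed` is required: synthetic data are reproducible by contract")
  assert_scalar_number(n, "n", lower = 4)
  if (is.null(blocks)) {
    blocks <- split(trait_categories()$trait, trait_categories()$category)
    blocks <- blocks[c("economic", "chemical", "structural")]
  }

  withr::with_seed(as.integer(seed), {
    if (is.null(group_effects)) {
      bs <- build_block_sigma(blocks, rho_in, rho_out, hub_trait, rho_hub)
      data <- draw_lognormal(n, bs$sigma, log_mean, log_sd)
      data$aridity_index <- stats::runif(n, 0.02, 0.51)
      truth <- list(membership = bs$membership, sigma = bs$sigma,
                    hub_trait = hub_trait, groups = NULL, seed = seed)
    } else {
      if (is.null(names(group_effects)) || any(!nzchar(names(group_effects)))) {
        abort("`group_effects` must be a named numeric vector of multipliers")
      }
      parts <- purrr::imap(group_effects, function(mult, label) {
        bs <- build_block_sigma(blocks, pmin(rho_in * mult, 0.99),
                                min(rho_out * mult, 0.99), hub_trait, rho_hub)
        part <- draw_lognormal(n, bs$sigma, log_mean, log_sd)
        if (identical(group_col, "aridity_index")) {
          part$aridity_index <- if (label %in% c("arid", "low")) {
            stats::runif(n, 0.02, 0.199)
          } else {
            stats::runif(n, 0.2, 0.51)
          }
        } else {
          part[[group_col]] <- label
          part$aridity_index <- stats::runif(n, 0.02, 0.51)
        }
        part
      })
      data <- dplyr::bind_rows(parts)
      bs <- build_block_sigma(blocks, rho_in, rho_out, hub_trait, rho_hub)
      truth <- list(membership = bs$membership, sigma = bs$sigma,
                    hub_trait = hub_trait, groups = group_effects, seed = seed)
    }
    data <- dplyr::bind_cols(tibble(record_id = sprintf("rec%04d", seq_len(nrow(data)))), data)
    attr(data, "ptn_truth") <- truth
    data
  })
}

#' Simulate a null trait table (all traits independent)
#'
#' All traits are mutually independent lognormal draws. On such data the
#' significance-thresholded network contains only false-positive edges, so the
#' expected edge density equals the threshold `alpha` — the calibration check
#' for the network construction.
#'
#' @param n Number of records.
#' @param p Number of traits (default 16; named per [ptn_traits()] when 16).
#' @param log_mean,log_sd Lognormal parameters.
#' @param seed Integer seed.
#' @return A tibble of positive trait values with a `record_id` column.
#' @export
simulate_null <- function(n, p = 16, log_mean = 0, log_sd = 1, seed) {
  if (missing(seed)) abort("`seed` is required")
  assert_scalar_number(n, "n", lower = 4)
  assert_scalar_number(p, "p", lower = 2)
  traits <- if (p == 16) ptn_traits() else paste0("T", seq_len(p))
  withr::with_seed(as.integer(seed), {
    sigma <- diag(p)
    dimnames(sigma) <- list(traits, traits)
    data <- draw_lognormal(n, sigma, log_mean, log_sd)
    dplyr::bind_cols(tibble(record_id = sprintf("rec%04d", seq_len(n))), data)
  })
}

#' Planted ground truth of a simulated trait table
#'
#' @param data A tibble produced by [simulate_traits()].
#' @return A list with elements `membership` (named vector: trait to planted
#'   module), `sigma` (the planted correlation matrix), `hub_trait`, `groups`
#'   and `seed`; `NULL` if `data` carries no ground truth.
#' @export
ptn_truth <- function(data) attr(data, "ptn_truth")
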