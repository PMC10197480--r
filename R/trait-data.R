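#' The sixteen standard plant functional traits
#'
#' Trait symbols follow common usage in dryland trait ecology: six economic
#' traits (area-based photosynthetic rate `A_area`, leaf mass per area `LMA`,
#' leaf thickness `LT`, leaf nitrogen/carbon/phosphorus concentrations `LNC`,
#' `LCC`, `LPC`), six chemical traits (root and stem C, N, P concentrations
#' `RCC`, `RNC`, `RPC`, `SCC`, `SNC`, `SPC`) and four structural traits (leaf
#' tissue density `LD`, leaf volume `LV`, leaf dry matter content `LDMC`,
#' leaf area `LA`).
#'
#' @return Character vector of the 16 trait names.
#' @export
ptn_traits <- function() {
  c("A_area", "LMA", "LT", "LNC", "LCC", "LPC",
    "RCC", "RNC", "RPC", "SCC", "SNC", "SPC",
    "LD", "LV", "LDMC", "LA")
}

#' Default functional-category scheme for the sixteen traits
#'
#' Partitions the traits of [ptn_traits()] into three functional categories:
#' economic (6 traits), chemical (6) and structural (4). The scheme is a
#' two-column tibble so alternative groupings can be supplied anywhere a
#' `categories` argument is accepted.
#'
#' @return A tibble with columns `trait` and `category`.
#' @examples
#' trait_categories()
#' @export
trait_categories <- function() {
  tibble(
    trait = ptn_traits(),
    category = rep(c("economic", "chemical", "structural"), times = c(6, 6, 4))
  )
}

check_categories <- function(categories, traits) {
  if (!is.data.frame(categories) || !all(c("trait", "category") %in% names(categories))) {
    abort("`categories` must be a data frame with columns `trait` and `category`")
  }
  if (anyDuplicated(categories$trait)) {
    abort("`categories` assigns some trait to more than one category")
  }
  missing <- setdiff(traits, categories$trait)
  if (length(missing)) {
    abort(paste0("`categories` does not cover trait(s): ", paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(categories$trait, traits)
  if (length(unknown)) {
    abort(paste0("`categories` references unknown trait(s): ", paste(unknown, collapse = ", ")))
  }
  invisible(categories)
}

# Resolve which columns of `data` hold trait values. Explicit `traits` wins;
# otherwise the standard 16 names present in the table; otherwise every
# numeric column not playing a known metadata role.
resolve_traits <- function(data, traits = NULL) {
  if (!is.null(traits)) {
    missing <- setdiff(traits, names(data))
    if (length(missing)) {
      abort(paste0("trait column(s) absent from data: ", paste(missing, collapse = ", ")))
    }
    return(traits)
  }
  std <- intersect(ptn_traits(), names(data))
  if (length(std)) return(std)
  meta <- c("record_id", "species", "site", "life_form", "aridity_index", "group")
  cand <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], meta)
  if (!length(cand)) abort("no trait columns found; pass `traits` explicitly")
  cand
}

validate_trait_table <- function(data, traits, id_col = NULL, require_positive = TRUE) {
  data <- as_tibble(data)
  if (nrow(data) == 0L) abort("trait table has no rows")
  if (!is.null(id_col)) {
    if (!id_col %in% names(data)) abort(sprintf("id column `%s` not found", id_col))
    ids <- data[[id_col]]
    if (anyDuplicated(ids)) {
      dups <- unique(ids[duplicated(ids)])
      abort(paste0("duplicate record ids: ", paste(utils::head(dups, 5), collapse = ", ")))
    }
  }
  for (tr in traits) {
    col <- data[[tr]]
    if (!is.numeric(col)) abort(sprintf("trait column `%s` is not numeric", tr))
    if (all(is.na(col))) abort(sprintf("trait column `%s` is entirely missing", tr))
    if (require_positive && any(col <= 0, na.rm = TRUE)) {
      bad <- which(col <= 0)[1]
      abort(sprintf(
        "non-positive value in trait `%s` (row %d): log-transform undefined", tr, bad
      ))
    }
  }
  data
}

#' Read a species-by-trait table from delimited text
#'
#' Reads a CSV/TSV file with a header row into a validated trait tibble. Cells
#' that do not parse as numbers become `NA` (missing); row order is preserved.
#' Values must be strictly positive because the analysis log-transforms traits.
#'
#' @param path Path to a delimited text file (`.csv` or tab-separated).
#' @param traits Character vector naming the trait columns. Default: the
#'   standard 16 names of [ptn_traits()] that are present in the file.
#' @param id_col Optional name of a column holding unique record identifiers.
#' @param delim Field delimiter; guessed from the file extension by default.
#' @return A tibble with one row per record.
#' @export
read_trait_table <- function(path, traits = NULL, id_col = NULL, delim = NULL) {
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  if (is.null(delim)) delim <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  data <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE, na = c("", "NA", "na", "NaN"))
  traits <- resolve_traits(data, traits)
  for (tr in traits) {
    if (!is.numeric(data[[tr]])) {
      suppressWarnings(data[[tr]] <- as.numeric(data[[tr]]))
    }
  }
  validate_trait_table(data, traits, id_col = id_col)
}

#' Write a trait table to CSV
#'
#' Canonical wide-format writer; the counterpart of [read_trait_table()].
#' Finite decimal values round-trip bit-identically.
#'
#' @param data A trait tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(data, path) {
  readr::write_csv(as_tibble(data), path, progress = FALSE)
  invisible(path)
}

#' Natural-log transform of trait columns
#'
#' Replaces every observed trait value by its natural logarithm, as is standard
#' before computing trait correlations. Missing values stay missing; metadata
#' columns are untouched. Pearson correlations downstream are invariant to the
#' log base, so natural log is used throughout.
#'
#' @param data A trait tibble with strictly positive trait values.
#' @param traits Trait columns to transform (default: auto-detected, see
#'   [read_trait_table()]).
#' @return The tibble with transformed trait columns.
#' @examples
#' log_transform(tibble::tibble(LA = c(1, exp(1))))
#' @export
log_transform <- function(data, traits = NULL) {
  traits <- resolve_traits(data, traits)
  data <- validate_trait_table(data, traits)
  dplyr::mutate(data, dplyr::across(dplyr::all_of(traits), log))
}

#' Aggregate records to unit means
#'
#' Collapses multiple records per unit (for example several site-level records
#' of one species) to per-unit arithmetic means on the raw scale. Aggregation
#' is an explicit, optional pre-step: whether rows are species means or
#' species-by-site records is a study design choice the pipeline never makes
#' silently. Note that aggregating then log-transforming differs from
#' log-transforming then aggregating; the package convention is to aggregate
#' raw values first.
#'
#' @param data A trait tibble.
#' @param by Name of the grouping column defining the aggregation unit.
#' @param traits Trait columns to average (default: auto-detected).
#' @return A tibble with one row per unit; a unit whose values for a trait are
#'   all missing gets `NA` for that trait.
#' @export
aggregate_records <- function(data, by, traits = NULL) {
  traits <- resolve_traits(data, traits)
  if (!by %in% names(data)) abort(sprintf("grouping column `%s` not found", by))
  if (all(is.na(data[[by]]))) abort("grouping column is entirely missing")
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(traits),
                    ~ if (all(is.na(.x))) NA_real_ else mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
}
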