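#' Per-item nutrient values on a serving basis
#'
#' Returns the value of one nutrient for every item on the requested
#' basis: `per100g` (the `_100g` column), `reported_serving` (the `_serv`
#' column — for Pizzas this is the serving as provided by the restaurant),
#' or `subcat_avg_serving`, which rescales every item's per-100g value by
#' its subcategory's mean serving size (per-100g x mean/100), as a parallel
#' basis for all items rather than a fill-in for missing ones.
#'
#' @param items Completed menu-table tibble.
#' @param nutrient One of the [nutrient_fields()].
#' @param basis `"per100g"`, `"reported_serving"`, or
#'   `"subcat_avg_serving"`.
#' @param stats Serving statistics ([serving_stats()]); computed from
#'   `items` when omitted (only used for `subcat_avg_serving`).
#' @return Numeric vector (NA where the value is unavailable).
#' @export
nutrient_values <- function(items, nutrient,
                            basis = c("per100g", "reported_serving",
                                      "subcat_avg_serving"),
                            stats = NULL) {
  basis <- match.arg(basis)
  stopifnot(nutrient %in% nutrient_fields())
  switch(basis,
    per100g = items[[paste0(nutrient, "_100g")]],
    reported_serving = items[[paste0(nutrient, "_serv")]],
    subcat_avg_serving = {
      if (is.null(stats)) stats <- serving_stats(items)
      mean_ss <- setNames(stats$mean, stats$subcategory)
      items[[paste0(nutrient, "_100g")]] *
        unname(mean_ss[items$subcategory]) / 100
    })
}

sample_sd <- function(v) if (length(v) < 2) 0 else sd(v)

#' Grouped nutrient summaries on three serving bases
#'
#' Mean, median, and sample standard deviation (n-1 denominator; 0 for a
#' single item) of nutrient content per group, on any of the three bases.
#' Items missing the nutrient on the requested basis are excluded from
#' that row's n. Groups with no usable value are omitted with a warning.
#'
#' @param items Completed menu-table tibble.
#' @param grouping `"overall"`, `"restaurant"`, `"subcategory"`, or
#'   `"restaurant_type"`.
#' @param nutrients Nutrient names (default kcal, salt, sugar, fat).
#' @param bases Bases to compute (default all three).
#' @param groups Group map (for `restaurant_type`).
#' @param stats Serving statistics for the `subcat_avg_serving` basis.
#' @return Tibble: `grouping`, `label`, `nutrient`, `basis`, `n`, `mean`,
#'   `median`, `sd`.
#' @export
summarize_nutrients <- function(items,
                                grouping = c("overall", "restaurant",
                                             "subcategory",
                                             "restaurant_type"),
                                nutrients = c("kcal", "salt", "sugar", "fat"),
                                bases = c("per100g", "reported_serving",
                                          "subcat_avg_serving"),
                                groups = NULL, stats = NULL) {
  grouping <- match.arg(grouping)
  label <- grouping_labels(items, grouping, groups)
  if (is.null(stats) && "subcat_avg_serving" %in% bases) {
    stats <- serving_stats(items)
  }

  rows <- list()
  for (nut in nutrients) {
    for (b in bases) {
      v <- nutrient_values(items, nut, b, stats = stats)
      keep <- !is.na(v)
      empty <- setdiff(unique(label), unique(label[keep]))
      if (length(empty) > 0) {
        warning(sprintf("no '%s' values on basis '%s' for group(s): %s",
                        nut, b, paste(empty, collapse = ", ")),
                call. = FALSE)
      }
      df <- tibble::tibble(label = label[keep], v = v[keep])
      out <- dplyr::summarise(
        dplyr::group_by(df, .data$label),
        n = dplyr::n(),
        mean = mean(.data$v),
        median = median(.data$v),
        sd = sample_sd(.data$v),
        .groups = "drop")
      out$grouping <- grouping
      out$nutrient <- nut
      out$basis <- b
      rows[[length(rows) + 1]] <- out
    }
  }
  res <- dplyr::bind_rows(rows)
  res[c("grouping", "label", "nutrient", "basis", "n", "mean", "median",
        "sd")]
}

#' Five-number distribution summary per group
#'
#' Min, lower quartile, median, upper quartile, max — the statistics needed
#' to draw a box-and-whisker plot of nutrient content per group. Quartiles
#' use the same linear-interpolation rule as [serving_stats()].
#'
#' @inheritParams summarize_nutrients
#' @param nutrient A single nutrient name.
#' @param basis A single basis.
#' @return Tibble: `grouping`, `label`, `nutrient`, `basis`, `n`, `min`,
#'   `lq`, `median`, `uq`, `max`.
#' @export
distribution_export <- function(items,
                                grouping = c("overall", "restaurant",
                                             "subcategory",
                                             "restaurant_type"),
                                nutrient = "kcal",
                                basis = "per100g",
                                groups = NULL, stats = NULL) {
  grouping <- match.arg(grouping)
  label <- grouping_labels(items, grouping, groups)
  v <- nutrient_values(items, nutrient, basis, stats = stats)
  keep <- !is.na(v)
  df <- tibble::tibble(label = label[keep], v = v[keep])
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$label),
    n = dplyr::n(),
    min = min(.data$v),
    lq = quantile(.data$v, 0.25, type = 7, names = FALSE),
    median = median(.data$v),
    uq = quantile(.data$v, 0.75, type = 7, names = FALSE),
    max = max(.data$v),
    .groups = "drop")
  out$grouping <- grouping
  out$nutrient <- nutrient
  out$basis <- basis
  out[c("grouping", "label", "nutrient", "basis", "n", "min", "lq",
        "median", "uq", "max")]
}
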