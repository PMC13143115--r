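#' Fill missing energy fields within one basis
#'
#' Applies the deterministic energy formulas on the given basis: a missing
#' kcal is derived from kJ (kcal = kJ/4.184) and vice versa (kJ =
#' kcal x 4.184); when both energy fields are missing but protein, fat, and
#' carbohydrate are all present, kcal is reconstructed from macronutrients
#' as 4 x protein + 9 x fat + 3.75 x carbohydrate (Atwater-style factors).
#' The macronutrient rule is strictly a fallback: it never overrides the
#' unit conversion, and reported values are never overwritten.
#'
#' @param items Menu-table tibble.
#' @param basis `"100g"` or `"serv"`.
#' @return The tibble with energy fields completed; provenance of filled
#'   fields is `derived`.
#' @export
complete_energy <- function(items, basis = c("100g", "serv")) {
  basis <- match.arg(basis)
  col <- function(n) paste0(n, "_", basis)
  kcal <- col("kcal"); kj <- col("kj")

  fill <- is.na(items[[kcal]]) & !is.na(items[[kj]])
  items[[kcal]][fill] <- items[[kj]][fill] / KJ_PER_KCAL
  items[[paste0("src_", kcal)]][fill] <- "derived"

  fill <- is.na(items[[kj]]) & !is.na(items[[kcal]])
  items[[kj]][fill] <- items[[kcal]][fill] * KJ_PER_KCAL
  items[[paste0("src_", kj)]][fill] <- "derived"

  prot <- items[[col("protein")]]; fat <- items[[col("fat")]]
  carb <- items[[col("carb")]]
  fill <- is.na(items[[kcal]]) & is.na(items[[kj]]) &
    !is.na(prot) & !is.na(fat) & !is.na(carb)
  items[[kcal]][fill] <- 4 * prot[fill] + 9 * fat[fill] + 3.75 * carb[fill]
  items[[paste0("src_", kcal)]][fill] <- "derived"
  # the unit conversion now applies to the reconstructed kcal
  items[[kj]][fill] <- items[[kcal]][fill] * KJ_PER_KCAL
  items[[paste0("src_", kj)]][fill] <- "derived"

  items
}

#' Fill the missing member of the salt/sodium pair within one basis
#'
#' sodium (mg) = salt (g) x 1000 / 2.5, and inversely
#' salt (g) = sodium (mg) x 2.5 / 1000. Reported values are never
#' overwritten.
#'
#' @inheritParams complete_energy
#' @return The tibble with salt/sodium completed.
#' @export
complete_salt_sodium <- function(items, basis = c("100g", "serv")) {
  basis <- match.arg(basis)
  salt <- paste0("salt_", basis); sodium <- paste0("sodium_", basis)

  fill <- is.na(items[[sodium]]) & !is.na(items[[salt]])
  items[[sodium]][fill] <- items[[salt]][fill] * 1000 / 2.5
  items[[paste0("src_", sodium)]][fill] <- "derived"

  fill <- is.na(items[[salt]]) & !is.na(items[[sodium]])
  items[[salt]][fill] <- items[[sodium]][fill] * 2.5 / 1000
  items[[paste0("src_", salt)]][fill] <- "derived"

  items
}

# Priority order for deriving serving size from a nutrient present on both
# bases: kcal is the most consistently reported field.
SERVING_DERIVE_PRIORITY <- c("kcal", "salt", "sugar", "carb", "fat", "protein")

#' Derive missing serving sizes and scale nutrients across bases
#'
#' Two steps, in order. (a) Where `serving_size` is missing and some
#' nutrient is present on both bases with a positive per-100g value,
#' serving size is derived as 100 x per-serving / per-100g, trying
#' nutrients in the fixed priority order kcal, salt, sugar, carbohydrate,
#' fat, protein. (b) Where serving size is known (any provenance), every
#' nutrient present on exactly one basis is copied to the other:
#' per-100g = per-serving / (serving_size/100) and per-serving =
#' (serving_size/100) x per-100g. Filled fields get provenance `derived`.
#'
#' Where a nutrient is reported on both bases but disagrees with the
#' serving-size scaling by more than 5% (relative), a warning is issued and
#' reported values are kept untouched.
#'
#' @param items Menu-table tibble (energy and salt/sodium completion should
#'   run first so a kJ-only or sodium-only item can seed derivation).
#' @param warn_discrepancy Emit the >5% cross-basis discrepancy warning?
#'   [complete_items()] silences it after the first pass of its fixpoint
#'   loop so each discrepancy is reported once.
#' @return The tibble with serving sizes derived and bases scaled; a
#'   derived serving size that is not positive is discarded (left missing).
#' @export
complete_basis <- function(items, warn_discrepancy = TRUE) {
  ss <- items$serving_size
  src_ss <- items$src_serving_size

  for (nut in SERVING_DERIVE_PRIORITY) {
    g100 <- items[[paste0(nut, "_100g")]]
    serv <- items[[paste0(nut, "_serv")]]
    can <- is.na(ss) & !is.na(g100) & !is.na(serv) & g100 > 0
    ss[can] <- 100 * serv[can] / g100[can]
    src_ss[can] <- "derived"
  }
  invalid <- !is.na(ss) & ss <= 0
  ss[invalid] <- NA_real_
  src_ss[invalid] <- NA_character_
  items$serving_size <- ss
  items$src_serving_size <- src_ss

  factor <- items$serving_size / 100
  for (nut in nutrient_fields()) {
    c100 <- paste0(nut, "_100g"); cserv <- paste0(nut, "_serv")
    g100 <- items[[c100]]; serv <- items[[cserv]]

    both <- !is.na(g100) & !is.na(serv) & !is.na(factor) &
      items[[paste0("src_", c100)]] == "reported" &
      items[[paste0("src_", cserv)]] == "reported"
    expect <- g100 * factor
    off <- both & expect > 0 & abs(serv - expect) / expect > 0.05
    if (warn_discrepancy && any(off, na.rm = TRUE)) {
      warning(sprintf(
        "%d item(s) report '%s' on both bases inconsistent with serving size by >5%%; reported values kept",
        sum(off, na.rm = TRUE), nut), call. = FALSE)
    }

    fill <- is.na(serv) & !is.na(g100) & !is.na(factor)
    items[[cserv]][fill] <- g100[fill] * factor[fill]
    items[[paste0("src_", cserv)]][fill] <- "derived"

    fill <- is.na(g100) & !is.na(serv) & !is.na(factor) & factor > 0
    items[[c100]][fill] <- serv[fill] / factor[fill]
    items[[paste0("src_", c100)]][fill] <- "derived"
  }
  items
}

completion_pass <- function(items, warn_discrepancy = TRUE) {
  items <- complete_energy(items, "100g")
  items <- complete_energy(items, "serv")
  items <- complete_salt_sodium(items, "100g")
  items <- complete_salt_sodium(items, "serv")
  complete_basis(items, warn_discrepancy = warn_discrepancy)
}

#' Run the full deterministic completion pipeline
#'
#' Unit conversions (kJ/kcal, salt/sodium) run first on both bases, then
#' serving-size derivation and basis scaling; the sequence is repeated to a
#' fixpoint (at most a handful of passes) so that, for example, a kJ-only
#' per-serving panel can seed serving-size derivation and the derived
#' per-100g panel is then itself unit-completed. The pipeline is
#' idempotent and never changes a reported value.
#'
#' @param items Menu-table tibble.
#' @return The completed tibble.
#' @export
complete_items <- function(items) {
  for (i in 1:6) {
    out <- completion_pass(items, warn_discrepancy = (i == 1))
    if (identical(out, items)) break
    items <- out
  }
  items
}

usable_items <- function(items) {
  has <- function(n) {
    !is.na(items[[paste0(n, "_100g")]]) | !is.na(items[[paste0(n, "_serv")]])
  }
  macro <- function(basis) {
    !is.na(items[[paste0("protein_", basis)]]) &
      !is.na(items[[paste0("fat_", basis)]]) &
      !is.na(items[[paste0("carb_", basis)]])
  }
  kcal_derivable <- has("kcal") | has("kj") | macro("100g") | macro("serv")
  salt_derivable <- has("salt") | has("sodium")
  kcal_derivable | salt_derivable | has("sugar")
}

#' Exclude items with no usable nutrient of interest
#'
#' An item is unusable when all three nutrients of interest (kcal, salt,
#' sugar) are missing on both bases and underivable by any completion
#' formula: kJ counts as kcal-derivable, a full macronutrient panel counts
#' as kcal-derivable, and sodium counts as salt-derivable.
#'
#' @param items Menu-table tibble.
#' @return List with `items` (kept rows), `excluded` (dropped rows), and
#'   `report` (a one-row tibble with `n_excluded_all_missing`).
#' @export
exclude_unusable <- function(items) {
  keep <- usable_items(items)
  list(items = items[keep, ],
       excluded = items[!keep, ],
       report = tibble::tibble(n_excluded_all_missing = sum(!keep)))
}

#' Serving-size statistics per subcategory
#'
#' Mean, median, and lower/upper quartiles of serving size per subcategory,
#' computed only over items whose serving size was reported or derived by
#' formula — never over imputed ones, so imputation has no feedback loop.
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param items Menu-table tibble (after [complete_items()]).
#' @return Tibble with columns `subcategory`, `n_known`, `mean`, `median`,
#'   `lq`, `uq`.
#' @export
serving_stats <- function(items) {
  eligible <- !is.na(items$serving_size) &
    items$src_serving_size %in% c("reported", "derived")
  sub <- items$subcategory[eligible]
  ss <- items$serving_size[eligible]
  out <- lapply(split(ss, sub), function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble::tibble(n_known = length(v), mean = mean(v), median = q[2],
                   lq = q[1], uq = q[3])
  })
  dplyr::bind_cols(tibble::tibble(subcategory = names(out)),
                   dplyr::bind_rows(out))
}

#' Impute missing serving sizes from subcategory statistics
#'
#' Items still lacking a serving size after completion receive the chosen
#' subcategory statistic (mean for the primary analysis; lower or upper
#' quartile for the sensitivity analyses), with provenance
#' `subcategory_imputed`, and basis scaling is then re-run so the imputed
#' size propagates to the missing basis. Reported or derived serving sizes
#' are never overwritten.
#'
#' @param items Menu-table tibble after [complete_items()].
#' @param strategy One of `"mean"`, `"lq"`, `"uq"`.
#' @param stats Serving statistics from [serving_stats()]; computed from
#'   `items` when omitted. Sensitivity runs pass the primary run's
#'   statistics so quartile strategies perturb imputation only.
#' @return The tibble with serving sizes imputed and bases rescaled.
#' @export
impute_serving_size <- function(items, strategy = c("mean", "lq", "uq"),
                                stats = NULL) {
  strategy <- match.arg(strategy)
  if (is.null(stats)) stats <- serving_stats(items)
  need <- which(is.na(items$serving_size))
  if (length(need) == 0) return(items)
  missing_sub <- setdiff(unique(items$subcategory[need]), stats$subcategory)
  if (length(missing_sub) > 0) {
    stop("no serving-size statistics for subcategory: ",
         paste(missing_sub, collapse = ", "), call. = FALSE)
  }
  lookup <- setNames(stats[[strategy]], stats$subcategory)
  items$serving_size[need] <- unname(lookup[items$subcategory[need]])
  items$src_serving_size[need] <- "subcategory_imputed"
  # propagate imputed sizes; discrepancies were already reported upstream
  for (i in 1:6) {
    out <- completion_pass(items, warn_discrepancy = FALSE)
    if (identical(out, items)) break
    items <- out
  }
  items
}

#' Count items whose serving size was imputed
#'
#' @param items Completed menu-table tibble.
#' @return Integer count.
#' @export
n_serving_imputed <- function(items) {
  sum(items$src_serving_size %in% "subcategory_imputed")
}
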