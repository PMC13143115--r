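#!/usr/bin/env Rscript

# Step 2: exclusion and deterministic nutrient completion.
#
# Items with kcal, salt, and sugar all missing and underivable are
# excluded. The remaining items are completed with the unit-conversion
# formulas (kJ/4.184, salt x 1000/2.5), the macro-energy fallback, and
# per-100g/per-serving scaling; items still lacking a serving size get
# their subcategory mean, and the per-field provenance records which rule
# produced each value.

suppressPackageStartupMessages(library(menutargets))

menu <- read_menu_table("results/data/menu_corpus.csv")

excl <- exclude_unusable(menu)
items <- complete_items(excl$items)
stats <- serving_stats(items)
items <- impute_serving_size(items, "mean", stats)

write_menu_table(items, "results/items_completed.csv")
readr::write_csv(stats, "results/serving_stats.csv")

n_imputed <- n_serving_imputed(items)
cat(sprintf("Excluded %d unusable item(s); %d analysed.\n",
            excl$report$n_excluded_all_missing, nrow(items)))
cat(sprintf(
  "Serving size: %d reported, %d derived from dual-basis data, %d imputed from subcategory means (%.0f%% of items).\n",
  sum(items$src_serving_size %in% "reported"),
  sum(items$src_serving_size %in% "derived"),
  n_imputed, 100 * n_imputed / nrow(items)))
cat("Subcategory serving-size statistics written to results/serving_stats.csv\n")
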