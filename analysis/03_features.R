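#!/usr/bin/env Rscript
# Assemble the 14-predictor modeling tables (one per dataset x age band,
# plus the aggregated bands) and write them with a sidecar JSON schema.
# Run analysis/01_simulate.R first.

library(lexscreen)

dir.create("results/features", showWarnings = FALSE, recursive = TRUE)
bundles <- list(eirli = read_bundle("results/bundles/eirli"),
                laser = read_bundle("results/bundles/laser"))

write_table <- function(ft, name) {
  f <- file.path("results/features", paste0(name, ".csv"))
  write.csv(ft, f, row.names = FALSE)
  schema <- lapply(ft[ll_predictor_names()], function(x) {
    if (is.factor(x)) list(type = "categorical", levels = levels(x))
    else list(type = "numeric")
  })
  jsonlite::write_json(schema, sub("\\.csv$", "_schema.json", f),
                       auto_unbox = TRUE)
  cat(sprintf("%s: %d x 14, %d positive\n", name, nrow(ft),
              sum(ft$outcome_LL)))
}

for (ds in names(bundles)) {
  metrics <- metrics_for_bundle(bundles[[ds]])
  for (band in c("younger", "older")) {
    write_table(assemble_features(bundles[[ds]], metrics, band = band),
                paste(ds, band, sep = "_"))
  }
}
for (band in c("younger", "older")) {
  agg <- aggregate_datasets(unname(bundles), band)
  write_table(assemble_features(agg, band = band),
              paste("aggregated", band, sep = "_"))
}
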