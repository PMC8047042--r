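#!/usr/bin/env Rscript
# Internal validation: nested cross-validated random-forest classification
# of LL outcome on each dataset x band table (plus the aggregated bands),
# with SMOTE balancing, drop-one importance pruning to 7 features, mtry
# tuning, and the clinical screening report. Uses a reduced shape (2 runs,
# 3x2 outer, 5x1 inner) so the whole driver finishes in minutes; the
# desk_scale() and full-protocol configurations are one argument away.
# Run analysis/01_simulate.R and 03_features.R first.

library(lexscreen)

cfg <- rf_config(outer_repeats = 2, inner_repeats = 1, n_runs = 2)
seed <- 20260919
tables <- c("eirli_younger", "eirli_older", "laser_younger", "laser_older",
            "aggregated_younger", "aggregated_older")

read_features <- function(name) {
  ft <- read.csv(file.path("results/features", paste0(name, ".csv")),
                 stringsAsFactors = FALSE)
  for (v in ll_demographics()) ft[[v]] <- factor(ft[[v]])
  class(ft) <- c("ll_features", "data.frame")
  ft
}

fits <- list()
for (nm in tables) {
  ft <- read_features(nm)
  fits[[nm]] <- nested_cv_fit(ft, cfg, seed = seed)
  tt <- balanced_accuracy_test(fits[[nm]]$run_balacc)
  cat(sprintf("%s: pooled balacc %.2f, t(%d)=%.1f vs 0.5, p=%.2g\n", nm,
              mean(fits[[nm]]$run_balacc), tt$df, tt$t, tt$p))
  sel <- sort(fits[[nm]]$selection, decreasing = TRUE)
  cat("  top selections:", paste0(names(sel)[1:7], " (", round(sel[1:7], 2),
                                  ")", collapse = ", "), "\n")
  write.csv(data.frame(feature = names(fits[[nm]]$selection),
                       selection_frequency = fits[[nm]]$selection),
            file.path("results", paste0("selection_", nm, ".csv")),
            row.names = FALSE)
}

report <- screening_report(fits, file = "results/table1_internal.csv")
print(report, digits = 3)
cat("internal-validation report written to results/table1_internal.csv\n")
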