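#!/usr/bin/env Rscript
# Stage 3: posterior tables of the derived quantities: species-by-year
# growth-rate trajectories, guild process SDs, regime mean growth rates, and
# the growth-versus-zooplankton regression curves with their slope summary.

library(guildgrowth)

fit <- readRDS("results/fit.rds")
paths <- write_derived_tables(fit, "results")
cat("Wrote:", paste(basename(unlist(paths)), collapse = ", "), "\n")

slopes <- read.csv("results/fig8_slopes.csv")
cat("\nGuild-level covariate slopes (posterior median [95% CRI]):\n")
for (i in seq_len(nrow(slopes)))
  cat(sprintf("  %-22s %+.2f [%+.2f, %+.2f]\n", slopes$group[i],
              slopes$median[i], slopes$lower[i], slopes$upper[i]))

sds <- read.csv("results/fig6_process_sd.csv")
cat("\nProcess SD by guild (posterior median):",
    paste(sprintf("%s %.2f", sds$group, sds$median), collapse = "; "), "\n")
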