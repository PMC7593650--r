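#!/usr/bin/env Rscript
# Frequency plots of cartilage contact pressure per condyle across the four
# variants, from the tables written by 04_variants.R.
suppressMessages(library(kneefem))

src <- "results/04_variants"
out <- "results/05_figures"
if (!file.exists(file.path(src, "pressure_histograms.json")))
  stop("run analysis/04_variants.R first")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

hists <- jsonlite::fromJSON(file.path(src, "pressure_histograms.json"),
                            simplifyVector = TRUE)
hl <- lapply(hists, function(h) lapply(h, function(x)
  list(breaks = as.numeric(x$breaks), counts = as.numeric(x$counts))))
for (cond in c("lateral", "medial")) {
  plot_pressure_frequency(hl, cond,
                          path = file.path(out, paste0("frequency_", cond, ".svg")))
}
cmp <- utils::read.csv(file.path(src, "comparison.csv"))
print(cmp[, c("variant", "condyle", "mean_pressure", "peak_pressure",
              "contact_area", "pct_mean", "pct_peak")], digits = 3)
cat("figures in", out, "\n")
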