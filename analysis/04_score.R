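#!/usr/bin/env Rscript
# Stage 4 — score both cohorts with the constructed panel.
#
# Each cohort is binarized against its own per-gene medians (the way the
# published panel was applied to the external ICGC cohort) and stratified
# at the cohort median mPS into two groups; the published 22/30 cut points
# are constants of the published weight scale and do not transfer to a
# freshly trained panel.

suppressPackageStartupMessages(library(mpscore))

cohort_dir <- "results/cohort"
out <- "results/scores"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

panel <- read_panel("results/panel/panel.tsv")

for (tag in c("discovery", "validation")) {
  suffix <- if (tag == "discovery") "" else "_validation"
  expr <- read_expression(file.path(cohort_dir,
                                    paste0("expression", suffix, ".tsv")))
  raw <- score_cohort(expr, panel,
                      scheme = stratification_scheme(sum(panel$weight) / 2,
                                                     c("low", "high")))
  scored <- stratify(raw[c("sample_id", "mps")],
                     stratification_scheme(median(raw$mps), c("low", "high")))
  write_scores(scored, file.path(out, paste0("scores_", tag, ".tsv")))
  cat(sprintf("%s cohort: %d samples, mPS %.2f-%.2f (median %.2f), %d low / %d high.\n",
              tag, nrow(scored), min(scored$mps), max(scored$mps),
              median(scored$mps), sum(scored$stratum == "low"),
              sum(scored$stratum == "high")))
}
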