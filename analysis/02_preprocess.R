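#!/usr/bin/env Rscript
# Stage 2: nonspecific probe filtering on the two normalization tracks
# (linear mean intensity >= 50 intersected with a 10-100% CV window on the
# log2 track) and probe-to-gene collapse by maximum mean expression. The
# probe chosen on the log2 track also indexes the linear track so both
# gene-level matrices describe the same probe.

library(crosspath)

dat <- "results/data"
out <- "results/preprocess"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (side in c("a", "b")) {
  phen <- read_cls(file.path(dat, paste0(side, ".cls")))
  lin <- read_expr_tsv(file.path(dat, paste0(side, "_linear.tsv")),
                       "linear", phen)
  lg <- read_expr_tsv(file.path(dat, paste0(side, "_log2.tsv")),
                      "log2", phen)
  annot <- read.delim(file.path(dat, paste0(side, "_annotation.tsv")),
                      stringsAsFactors = FALSE)
  keep <- nonspecific_filter(lin, lg, filter_config())
  col_log <- collapse_to_genes(subset_rows(lg, keep), annot)
  col_lin <- collapse_to_genes(subset_rows(lin, keep), annot,
                               chosen = col_log$chosen_probes)
  write_expr_tsv(col_log$matrix,
                 file.path(out, paste0(side, "_genes_log2.tsv")))
  write_expr_tsv(col_lin$matrix,
                 file.path(out, paste0(side, "_genes_linear.tsv")))
  cat(sprintf("cohort %s: %d probes -> %d pass filter -> %d genes\n",
              toupper(side), nrow(lin$values), length(keep),
              nrow(col_log$matrix$values)))
}
cat("wrote", out, "\n")
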