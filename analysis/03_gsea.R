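#!/usr/bin/env Rscript
# Stage 3: absolute-ranked GSEA with phenotype permutations on each
# cohort's gene-level log2 matrix. Genes are ranked by |signal-to-noise|;
# 150 label permutations feed the NES / nominal p / FDR q / FWER null.

library(crosspath)

seed <- 1L
pre <- "results/preprocess"
dat <- "results/data"
out <- "results/gsea"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sets <- read_gmt(file.path(dat, "collection.gmt"))
for (side in c("a", "b")) {
  phen <- read_cls(file.path(dat, paste0(side, ".cls")))
  gm <- read_expr_tsv(file.path(pre, paste0(side, "_genes_log2.tsv")),
                      "log2", phen)
  cfg <- gsea_config(n_permutations = 150,
                     seed = seed + match(side, c("a", "b")))
  res <- gsea(gm, sets, cfg)
  sig <- significant_sets(res, cfg)
  write_enrichment_report(res, file.path(out, paste0(side, "_enrichment.tsv")))
  write_enrichment_report(sig, file.path(out, paste0(side, "_significant.tsv")))
  cat(sprintf("cohort %s: %d sets tested, %d significant (p < 0.05, q <= 0.25); top set %s (NES %.2f)\n",
              toupper(side), nrow(res), nrow(sig), res$set[1], res$nes[1]))
}
cat("wrote", out, "\n")
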