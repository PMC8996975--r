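#!/usr/bin/env Rscript
# Stage 1: simulate the benchmark study — two disease-vs-control cohorts
# (20 vs 20 samples, 600 genes x 3 probes) with five planted up-regulated
# gene sets per cohort, all built around the same 7-gene shared panel, plus
# 20 size-matched decoy sets. Writes the on-disk exchange formats every
# later stage consumes (TSV matrices, CLS phenotypes, GMT sets, JSON truth).

library(crosspath)

seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

dd <- shared_panel_design(seed)
both <- generate_two_cohorts(dd$a, dd$b, shared_genes = dd$shared)

for (side in c("a", "b")) {
  co <- both[[side]]
  write_expr_tsv(co$linear, file.path(out, paste0(side, "_linear.tsv")),
                 comments = sprintf("cohort %s linear-intensity track, seed %d",
                                    side, seed))
  write_expr_tsv(co$log2, file.path(out, paste0(side, "_log2.tsv")),
                 comments = sprintf("cohort %s log2 track, seed %d", side, seed))
  write_cls(co$log2$phenotype, file.path(out, paste0(side, ".cls")))
  write.table(co$annotation, file.path(out, paste0(side, "_annotation.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
write_gmt(both$a$sets, file.path(out, "collection.gmt"))
jsonlite::write_json(both$truth, file.path(out, "truth.json"),
                     auto_unbox = TRUE)

cat(sprintf("cohort A: %d probes x %d samples; cohort B: %d probes x %d samples\n",
            nrow(both$a$log2$values), ncol(both$a$log2$values),
            nrow(both$b$log2$values), ncol(both$b$log2$values)))
cat(sprintf("gene-set collection: %d sets (%d planted per cohort, %d decoys)\n",
            length(both$a$sets), 5, 20))
cat(sprintf("planted shared panel: %s\n", paste(dd$shared, collapse = ", ")))
cat("wrote", out, "\n")
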