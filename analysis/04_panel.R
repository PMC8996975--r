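#!/usr/bin/env Rscript
# Stage 4: cross-cohort panel assembly. Each gene is scored by how many
# significant gene sets carry it in their leading edge; the high-frequency
# genes (top 10, ties kept) are mapped to linear-scale fold changes and
# classified up/down with the cohort-specific cutoffs (1.0/0.75 for cohort
# A, 1.5/0.5 for cohort B); the panel is the intersection of both cohorts'
# selections with an agreeing call. Recovery is judged against the
# generator's truth record.

library(crosspath)

pre <- "results/preprocess"
gse <- "results/gsea"
dat <- "results/data"
out <- "results/panel"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

side_results <- lapply(c("a", "b"), function(side) {
  sig <- read.delim(file.path(gse, paste0(side, "_significant.tsv")),
                    check.names = FALSE, stringsAsFactors = FALSE)
  sig$leading_edge <- I(strsplit(sig$leading_edge, ";", fixed = TRUE))
  freq <- leading_edge_frequency(sig)
  sel <- select_high_frequency_genes(freq, top_k = 10)
  phen <- read_cls(file.path(dat, paste0(side, ".cls")))
  lin <- read_expr_tsv(file.path(pre, paste0(side, "_genes_linear.tsv")),
                       "linear", phen)
  cuts <- if (side == "a") c(up = 1.0, down = 0.75) else c(up = 1.5, down = 0.5)
  fc <- fold_change(lin, sel)
  fc$call <- classify_deg(fc$fc, cuts[["up"]], cuts[["down"]])
  list(sig = sig, freq = freq, sel = sel, fc = fc)
})
names(side_results) <- c("a", "b")
a <- side_results$a; b <- side_results$b

pw <- intersect_pathways(a$sig$set, b$sig$set)
panel <- build_panel(a$sel, b$sel, a$fc, b$fc, a$freq, b$freq)
panel_genes <- panel$gene[panel$in_panel]

write.table(panel, file.path(out, "panel.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(list(pathways = as.list(pw$venn),
                          panel = panel_genes),
                     file.path(out, "venn.json"), auto_unbox = TRUE)

truth <- jsonlite::read_json(file.path(dat, "truth.json"),
                             simplifyVector = TRUE)
cat(sprintf("pathways significant in both cohorts: %d (A-only %d, B-only %d)\n",
            pw$venn[["both"]], pw$venn[["only_a"]], pw$venn[["only_b"]]))
cat(sprintf("high-frequency genes: %d (A) and %d (B); final panel: %d genes\n",
            length(a$sel), length(b$sel), length(panel_genes)))
cat(sprintf("planted shared genes recovered: %d of %d; false positives: %d\n",
            length(intersect(panel_genes, truth$shared_panel)),
            length(truth$shared_panel),
            length(setdiff(panel_genes, truth$shared_panel))))
cat("panel:", paste(panel_genes, collapse = ", "), "\n")
cat("wrote", out, "\n")
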