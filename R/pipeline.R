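#' Run the full two-cohort discovery pipeline
#'
#' Chains, per cohort: nonspecific two-track filter -> probe-to-gene
#' collapse (probe chosen on the log2 track, reused on the linear track)
#' -> absolute GSEA with phenotype permutations -> significant-set filter
#' -> leading-edge frequency -> high-frequency selection -> linear-scale
#' fold change and up/down classification; then intersects the two
#' cohorts' pathways and genes and assembles the shared panel.
#'
#' @param cohort_a,cohort_b cohort bundles: lists with elements `linear`,
#'   `log2` ([expr_matrix()]), `annotation` (probe_id/gene_symbol) and
#'   `sets` (named list), e.g. from [generate_cohort()].
#' @param filter_cfg a [filter_config()] (shared by both cohorts).
#' @param gsea_cfg a [gsea_config()]; its seed is split per cohort.
#' @param fc_cuts_a,fc_cuts_b `c(up, down)` fold-change cutoffs per cohort
#'   (defaults: 1.0/0.75 for cohort A, 1.5/0.5 for cohort B, the airway
#'   and tumor conventions).
#' @param top_k,min_count high-frequency selection rule (exactly one;
#'   default `top_k = 10`, ties kept).
#' @param out_dir optional directory; when given, per-stage artifacts
#'   (filtered matrices, enrichment reports, panel TSV, Venn JSON, run
#'   report JSON) are written there.
#' @return a run report: list with `counts` (per-stage bookkeeping for both
#'   cohorts), `enrichment` (both results), `frequency`, `panel`
#'   (the [build_panel()] table), `panel_genes`, `pathways` (intersection),
#'   `config_hash` and `seed`.
#' @export
run_pipeline <- function(cohort_a, cohort_b,
                         filter_cfg = filter_config(),
                         gsea_cfg = gsea_config(),
                         fc_cuts_a = c(up = 1.0, down = 0.75),
                         fc_cuts_b = c(up = 1.5, down = 0.5),
                         top_k = 10, min_count = NULL,
                         out_dir = NULL) {
  if (!is.null(min_count)) top_k <- NULL
  stage <- function(cohort, label, fc_cuts, seed) {
    keep <- nonspecific_filter(cohort$linear, cohort$log2, filter_cfg)
    if (!length(keep)) stop("stage filter [", label, "]: no probe passed")
    lin_f <- subset_rows(cohort$linear, keep)
    log_f <- subset_rows(cohort$log2, keep)
    col_log <- collapse_to_genes(log_f, cohort$annotation)
    col_lin <- collapse_to_genes(lin_f, cohort$annotation,
                                 chosen = col_log$chosen_probes)
    cfg <- gsea_cfg
    cfg$seed <- derive_seed(seed, paste0("gsea-", label))
    enr <- gsea(col_log$matrix, cohort$sets, cfg)
    sig <- significant_sets(enr, cfg)
    freq <- leading_edge_frequency(sig)
    sel <- if (nrow(freq))
      select_high_frequency_genes(freq, top_k = top_k, min_count = min_count)
    else character(0)
    fc <- if (length(sel)) fold_change(col_lin$matrix, sel)
    else data.frame(gene = character(), fc = numeric(), usable = logical())
    fc$call <- classify_deg(fc$fc, up_cut = fc_cuts[["up"]],
                            down_cut = fc_cuts[["down"]])
    list(label = label, keep = keep,
         genes = col_log$matrix, linear_genes = col_lin$matrix,
         enrichment = enr, significant = sig, frequency = freq,
         selected = sel, fc = fc,
         counts = c(probes_in = nrow(cohort$linear$values),
                    probes_pass = length(keep),
                    genes_collapsed = nrow(col_log$matrix$values),
                    sets_tested = nrow(enr),
                    sets_significant = nrow(sig),
                    genes_selected = length(sel),
                    genes_up = sum(fc$call == "up", na.rm = TRUE),
                    genes_down = sum(fc$call == "down", na.rm = TRUE)))
  }
  a <- stage(cohort_a, "A", fc_cuts_a, gsea_cfg$seed)
  b <- stage(cohort_b, "B", fc_cuts_b, gsea_cfg$seed)

  pw <- intersect_pathways(a$significant$set, b$significant$set)
  panel <- build_panel(a$selected, b$selected, a$fc, b$fc,
                       a$frequency, b$frequency)
  panel_genes <- panel$gene[panel$in_panel]
  gene_venn <- intersect_panels(a$selected, b$selected)

  cfg_sem <- list(filter = unclass(filter_cfg), gsea = unclass(gsea_cfg),
                  fc_cuts_a = fc_cuts_a, fc_cuts_b = fc_cuts_b,
                  top_k = top_k, min_count = min_count)
  report <- list(
    counts = list(a = a$counts, b = b$counts),
    enrichment = list(a = a$enrichment, b = b$enrichment),
    significant = list(a = a$significant, b = b$significant),
    frequency = list(a = a$frequency, b = b$frequency),
    fc = list(a = a$fc, b = b$fc),
    pathways = pw,
    gene_venn = gene_venn,
    panel = panel,
    panel_genes = panel_genes,
    config_hash = config_hash(cfg_sem),
    seed = gsea_cfg$seed)
  if (!is.null(out_dir)) write_run_artifacts(report, out_dir)
  report
}

# md5 of the canonical JSON serialization of the semantic config fields
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tf))
}

write_run_artifacts <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (side in c("a", "b")) {
    write_enrichment_report(report$enrichment[[side]],
                            file.path(out_dir, paste0("enrichment_", side, ".tsv")))
    utils::write.table(report$frequency[[side]],
                       file.path(out_dir, paste0("frequency_", side, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(report$panel, file.path(out_dir, "panel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(pathways = as.list(report$pathways$venn),
         genes = as.list(report$gene_venn$venn),
         panel = report$panel_genes,
         counts = lapply(report$counts, as.list),
         config_hash = report$config_hash, seed = report$seed),
    file.path(out_dir, "run_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Load a pipeline run configuration from YAML
#'
#' The YAML lists, per cohort, the linear/log2 matrix TSVs, the CLS
#' phenotype file, the probe-annotation TSV and the GMT collection, plus
#' optional `filter`, `gsea`, `fc_cuts_a`, `fc_cuts_b` and `top_k` /
#' `min_count` overrides. [run_pipeline_config()] reads everything and
#' delegates to [run_pipeline()].
#'
#' @param path YAML file.
#' @return [read_run_config()]: the parsed config list;
#'   [run_pipeline_config()]: the run report.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (side in c("cohort_a", "cohort_b")) {
    if (is.null(cfg[[side]]))
      stop("run config misses section ", side)
    for (f in c("linear", "log2", "cls", "annotation", "gmt")) {
      p <- cfg[[side]][[f]]
      if (is.null(p)) stop("run config ", side, " misses path '", f, "'")
      if (!file.exists(p)) stop("run config ", side, ": missing file ", p)
    }
  }
  cfg
}

#' @rdname read_run_config
#' @export
run_pipeline_config <- function(path) {
  cfg <- read_run_config(path)
  load_side <- function(sc) {
    phen <- read_cls(sc$cls)
    list(linear = read_expr_tsv(sc$linear, "linear", phen),
         log2 = read_expr_tsv(sc$log2, "log2", phen),
         annotation = utils::read.delim(sc$annotation,
                                        stringsAsFactors = FALSE),
         sets = read_gmt(sc$gmt))
  }
  fcfg <- do.call(filter_config, as.list(cfg$filter %||% list()))
  gcfg <- do.call(gsea_config, as.list(cfg$gsea %||% list()))
  run_pipeline(load_side(cfg$cohort_a), load_side(cfg$cohort_b),
               filter_cfg = fcfg, gsea_cfg = gcfg,
               fc_cuts_a = unlist(cfg$fc_cuts_a %||% c(up = 1.0, down = 0.75)),
               fc_cuts_b = unlist(cfg$fc_cuts_b %||% c(up = 1.5, down = 0.5)),
               top_k = cfg$top_k %||% 10, min_count = cfg$min_count,
               out_dir = cfg$out_dir)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
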