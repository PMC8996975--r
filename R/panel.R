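#' Leading-edge frequency table
#'
#' Counts, for every gene, how many significant gene sets carry it in
#' their leading edge. Genes that drive many enriched pathways at once are
#' the panel candidates.
#'
#' @param significant a [significant_sets()] result (needs the
#'   `leading_edge` list-column).
#' @return data.frame `gene`, `count`, ordered by (count desc, gene asc);
#'   attribute `total_sets` records the number of significant sets.
#' @export
leading_edge_frequency <- function(significant) {
  total <- nrow(significant)
  if (!total) {
    out <- data.frame(gene = character(), count = integer())
    attr(out, "total_sets") <- 0L
    return(out)
  }
  tab <- table(unlist(lapply(significant$leading_edge, unique)))
  out <- data.frame(gene = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_sets") <- total
  out
}

#' Select the high-frequency genes
#'
#' Exactly one of `top_k` or `min_count` must be given. `top_k` keeps the
#' genes with the k highest counts and keeps all ties at the boundary;
#' `min_count` keeps every gene whose count reaches the threshold.
#'
#' @param freq a [leading_edge_frequency()] table.
#' @param top_k number of top genes (boundary ties kept).
#' @param min_count minimum leading-edge count.
#' @return character vector of gene symbols (count desc, gene asc).
#' @export
select_high_frequency_genes <- function(freq, top_k = NULL, min_count = NULL) {
  if (is.null(top_k) == is.null(min_count))
    stop("supply exactly one of top_k or min_count")
  if (!nrow(freq)) stop("frequency table is empty")
  if (!is.null(min_count)) return(freq$gene[freq$count >= min_count])
  if (top_k >= nrow(freq)) return(freq$gene)
  cutoff <- freq$count[top_k]
  freq$gene[freq$count >= cutoff]
}

#' Linear-scale fold change between phenotype classes
#'
#' fc = mean(disease) / mean(control) computed on the linear-intensity
#' track (the raw-scale values, not re-exponentiated log2 means). The
#' disease class is the first phenotype level.
#'
#' @param linear gene-level linear [expr_matrix()].
#' @param genes genes to report (default: all rows).
#' @return data.frame `gene`, `fc`, `usable` (`FALSE` when the control
#'   mean is zero and the ratio is undefined).
#' @export
fold_change <- function(linear, genes = rownames(linear$values)) {
  stopifnot(inherits(linear, "expr_matrix"))
  if (linear$scale != "linear")
    stop("fold change is defined on the linear track")
  missing_g <- setdiff(genes, rownames(linear$values))
  if (length(missing_g))
    stop("genes absent from the matrix: ",
         paste(utils::head(missing_g, 5), collapse = ", "))
  m <- linear$values[genes, , drop = FALSE]
  dis <- linear$phenotype == levels(linear$phenotype)[1]
  mu_d <- rowMeans(m[, dis, drop = FALSE])
  mu_c <- rowMeans(m[, !dis, drop = FALSE])
  data.frame(gene = genes,
             fc = ifelse(mu_c == 0, NA_real_, mu_d / mu_c),
             usable = mu_c != 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify a fold change as up, down or neither
#'
#' Strict comparisons: `fc > up_cut` is up, `fc < down_cut` is down. The
#' cutoffs are cohort-specific (e.g. 1.0/0.75 for the airway cohort,
#' 1.5/0.5 for the tumor cohort).
#'
#' @param fc numeric fold change(s).
#' @param up_cut,down_cut positive cutoffs with `down_cut < up_cut`.
#' @return character vector `"up"`/`"down"`/`"neither"` (`NA` in, `NA` out).
#' @export
classify_deg <- function(fc, up_cut = 1.5, down_cut = 0.5) {
  if (!(up_cut > 0 && down_cut > 0)) stop("cutoffs must be positive")
  if (!(down_cut < up_cut)) stop("need down_cut < up_cut")
  ifelse(is.na(fc), NA_character_,
         ifelse(fc > up_cut, "up", ifelse(fc < down_cut, "down", "neither")))
}

#' Cross-cohort intersections
#'
#' [intersect_panels()] intersects gene symbols exactly;
#' [intersect_pathways()] intersects set names case-insensitively after
#' whitespace normalization (two enrichment runs may stylize names
#' differently). Both return the sorted common elements plus the Venn
#' counts.
#'
#' @param a,b character vectors (deduplicated internally).
#' @return list `common` (sorted), `venn` (named counts `only_a`, `only_b`,
#'   `both`).
#' @export
intersect_panels <- function(a, b) {
  a <- unique(a); b <- unique(b)
  common <- sort(intersect(a, b))
  list(common = common,
       venn = c(only_a = length(setdiff(a, b)),
                only_b = length(setdiff(b, a)),
                both = length(common)))
}

#' @rdname intersect_panels
#' @export
intersect_pathways <- function(a, b) {
  norm <- function(x) toupper(gsub("\\s+", " ", trimws(unique(x))))
  a <- unique(a); b <- unique(b)
  na <- norm(a); nb <- norm(b)
  common <- sort(a[na %in% nb])
  list(common = common,
       venn = c(only_a = sum(!na %in% nb),
                only_b = sum(!nb %in% na),
                both = length(common)))
}

#' Assemble the cross-cohort panel table
#'
#' Joins the two cohorts' high-frequency gene lists with their fold-change
#' calls. A gene enters the final panel when it was selected in both
#' cohorts and its up/down call agrees across cohorts (and is not
#' `"neither"`).
#'
#' @param sel_a,sel_b high-frequency gene vectors per cohort.
#' @param fc_a,fc_b [fold_change()] tables covering those genes, with a
#'   `call` column already added.
#' @param freq_a,freq_b [leading_edge_frequency()] tables.
#' @return data.frame `gene`, `in_a`, `in_b`, `freq_a`, `freq_b`, `fc_a`,
#'   `fc_b`, `call_a`, `call_b`, `in_panel`, ordered by gene; only genes
#'   selected in at least one cohort are listed.
#' @export
build_panel <- function(sel_a, sel_b, fc_a, fc_b, freq_a, freq_b) {
  genes <- sort(union(sel_a, sel_b))
  pick <- function(tab, col, g) tab[[col]][match(g, tab$gene)]
  out <- data.frame(
    gene = genes,
    in_a = genes %in% sel_a, in_b = genes %in% sel_b,
    freq_a = pick(freq_a, "count", genes),
    freq_b = pick(freq_b, "count", genes),
    fc_a = pick(fc_a, "fc", genes), fc_b = pick(fc_b, "fc", genes),
    call_a = pick(fc_a, "call", genes), call_b = pick(fc_b, "call", genes),
    stringsAsFactors = FALSE)
  out$in_panel <- out$in_a & out$in_b &
    !is.na(out$call_a) & !is.na(out$call_b) &
    out$call_a != "neither" & out$call_a == out$call_b
  out
}
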