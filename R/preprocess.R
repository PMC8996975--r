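#' Nonspecific-filter configuration
#'
#' @param intensity_floor linear-track intensity floor (default 50,
#'   MAS5-style units).
#' @param cv_low,cv_high coefficient-of-variation window in percent
#'   (default 10-100, closed interval), applied to the log2 track.
#' @param strict_floor if `TRUE`, every sample must clear the intensity
#'   floor; by default the mean across all samples is compared to it.
#' @return a `filter_config` list.
#' @export
filter_config <- function(intensity_floor = 50, cv_low = 10, cv_high = 100,
                          strict_floor = FALSE) {
  if (intensity_floor < 0) stop("intensity_floor must be >= 0")
  if (!(cv_low >= 0 && cv_low < cv_high))
    stop("need 0 <= cv_low < cv_high")
  structure(list(intensity_floor = intensity_floor, cv_low = cv_low,
                 cv_high = cv_high, strict_floor = isTRUE(strict_floor)),
            class = "filter_config")
}

#' Per-row coefficient of variation (percent)
#'
#' CV_i = 100 * sd_i / mean_i across all samples of the cohort (both
#' classes pooled), with the sample (n-1) standard deviation. Rows with a
#' zero mean get `NA` (they can never pass a CV window) rather than an
#' error.
#'
#' @param x an [expr_matrix()] or plain numeric matrix with >= 2 columns.
#' @return named numeric vector of CVs in percent.
#' @export
compute_cv <- function(x) {
  m <- if (inherits(x, "expr_matrix")) x$values else x
  if (ncol(m) < 2L) stop("CV needs at least 2 samples")
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  cv <- ifelse(mu == 0, NA_real_, 100 * sdv / mu)
  names(cv) <- rownames(m)
  cv
}

#' Two-track nonspecific probe filter
#'
#' Keeps the probes whose linear-track (MAS5-style) mean intensity clears
#' `intensity_floor` AND whose log2-track (gcRMA-style) CV lies inside the
#' closed window `[cv_low, cv_high]` percent; the two predicate sets are
#' intersected. Probes are returned in input row order.
#'
#' @param linear linear-scale [expr_matrix()].
#' @param log2m log2-scale [expr_matrix()] over the same probes and samples.
#' @param cfg a [filter_config()].
#' @return character vector of passing probe IDs.
#' @export
nonspecific_filter <- function(linear, log2m, cfg = filter_config()) {
  stopifnot(inherits(linear, "expr_matrix"), inherits(log2m, "expr_matrix"),
            inherits(cfg, "filter_config"))
  if (linear$scale != "linear" || log2m$scale != "log2")
    stop("expected a linear-scale and a log2-scale matrix, in that order")
  pa <- rownames(linear$values); pb <- rownames(log2m$values)
  if (!setequal(pa, pb)) {
    only_a <- setdiff(pa, pb); only_b <- setdiff(pb, pa)
    stop("probe sets differ between tracks: ", length(only_a),
         " only in linear (e.g. ", paste(utils::head(only_a, 3), collapse = ", "),
         "), ", length(only_b), " only in log2 (e.g. ",
         paste(utils::head(only_b, 3), collapse = ", "), ")")
  }
  if (!identical(colnames(linear$values), colnames(log2m$values)))
    stop("the two tracks must share the same samples in the same order")
  lm <- linear$values[pa, , drop = FALSE]
  pass_floor <- if (cfg$strict_floor)
    apply(lm >= cfg$intensity_floor, 1L, all)
  else rowMeans(lm) >= cfg$intensity_floor
  cv <- compute_cv(log2m)[pa]
  pass_cv <- !is.na(cv) & cv >= cfg$cv_low & cv <= cfg$cv_high
  unique(pa[pass_floor & pass_cv])
}

#' Collapse probes to genes by maximum mean expression
#'
#' Drops probes without a gene symbol, then keeps for each gene the single
#' probe with the highest mean expression across all samples; that probe's
#' full row becomes the gene's row. Ties break to the lexicographically
#' smallest probe ID.
#'
#' @param x an [expr_matrix()] at probe level.
#' @param annotation data.frame with columns `probe_id`, `gene_symbol`
#'   (one symbol per mapped probe; `NA`/empty = unmapped).
#' @param chosen optional named character vector (gene -> probe) forcing
#'   the probe choice, e.g. to reuse the log2-track selection on the linear
#'   track so both tracks describe the same probe per gene.
#' @return list with `matrix` (gene-level [expr_matrix()]) and
#'   `chosen_probes` (named character vector gene -> probe_id).
#' @export
collapse_to_genes <- function(x, annotation, chosen = NULL) {
  stopifnot(inherits(x, "expr_matrix"),
            all(c("probe_id", "gene_symbol") %in% names(annotation)))
  if (anyDuplicated(annotation$probe_id))
    stop("annotation maps some probe to more than one symbol")
  map <- annotation$gene_symbol[match(rownames(x$values), annotation$probe_id)]
  mapped <- !is.na(map) & nzchar(map)
  m <- x$values[mapped, , drop = FALSE]
  gene <- map[mapped]
  if (!nrow(m)) stop("no mapped probes to collapse")
  if (is.null(chosen)) {
    mu <- rowMeans(m)
    ord <- order(gene, -mu, rownames(m), method = "radix")
    first <- !duplicated(gene[ord])
    chosen <- stats::setNames(rownames(m)[ord][first], gene[ord][first])
    # genes keep the input's first-appearance order, so collapsing an
    # already gene-level matrix is the identity
    chosen <- chosen[order(match(names(chosen), unique(gene)))]
  } else {
    keep <- names(chosen)[chosen %in% rownames(m)]
    chosen <- chosen[keep]
    if (!length(chosen)) stop("none of the pre-chosen probes are present")
  }
  out <- m[unname(chosen), , drop = FALSE]
  rownames(out) <- names(chosen)
  list(matrix = expr_matrix(out, scale = x$scale, phenotype = x$phenotype),
       chosen_probes = chosen)
}
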