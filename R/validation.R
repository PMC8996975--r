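#' Relative expression by the 2^-DeltaDeltaCt method
#'
#' Per sample and gene, replicate Ct values are QC'd (replicates more than
#' one cycle from the replicate median are discarded; at least two usable
#' replicates are required) and averaged; DeltaCt = mean target Ct minus
#' mean reference-gene Ct. The calibrator DeltaCt is the mean DeltaCt of
#' the calibrator group per gene; DeltaDeltaCt = DeltaCt - calibrator
#' DeltaCt; rq = 2^-DeltaDeltaCt; log2_rq = -DeltaDeltaCt exactly.
#'
#' @param measurements long-format data.frame with columns `sample`,
#'   `group`, `gene`, `replicate`, `ct_gene`, `ct_ref` (as produced by
#'   [generate_qpcr_fixture()]).
#' @param calibrator_group group label whose mean DeltaCt anchors the
#'   comparison (rq = 1 on average in that group).
#' @return data.frame `sample`, `group`, `gene`, `delta_ct`,
#'   `delta_delta_ct`, `rq`, `log2_rq`; samples excluded by replicate QC
#'   are listed in the `excluded` attribute.
#' @export
relative_expression <- function(measurements, calibrator_group) {
  need <- c("sample", "group", "gene", "ct_gene", "ct_ref")
  if (!all(need %in% names(measurements)))
    stop("measurements need columns: ", paste(need, collapse = ", "))
  if (!calibrator_group %in% measurements$group)
    stop("calibrator group '", calibrator_group, "' not present")
  if (any(measurements$ct_gene <= 0 | measurements$ct_gene >= 45,
          measurements$ct_ref <= 0 | measurements$ct_ref >= 45,
          na.rm = TRUE))
    stop("Ct values must lie in (0, 45)")

  qc_mean <- function(ct) {
    ct <- ct[is.finite(ct)]
    keep <- abs(ct - stats::median(ct)) <= 1   # > 1 cycle off the median: out
    if (sum(keep) < 2) return(NA_real_)
    mean(ct[keep])
  }
  key <- interaction(measurements$sample, measurements$gene, drop = TRUE)
  rows <- !duplicated(key)
  out <- data.frame(sample = measurements$sample[rows],
                    group = measurements$group[rows],
                    gene = measurements$gene[rows],
                    stringsAsFactors = FALSE)
  out$delta_ct <- vapply(which(rows), function(i) {
    sel <- key == key[i]
    qc_mean(measurements$ct_gene[sel]) - qc_mean(measurements$ct_ref[sel])
  }, numeric(1))
  excluded <- out[is.na(out$delta_ct), c("sample", "gene")]
  out <- out[!is.na(out$delta_ct), , drop = FALSE]
  if (!nrow(out)) stop("no sample survived replicate QC")
  out$delta_delta_ct <- NA_real_
  for (g in unique(out$gene)) {
    cal <- out$delta_ct[out$gene == g & out$group == calibrator_group]
    if (!length(cal))
      stop("calibrator group empty for gene ", g, " after QC")
    sel <- out$gene == g
    out$delta_delta_ct[sel] <- out$delta_ct[sel] - mean(cal)
  }
  out$rq <- 2^(-out$delta_delta_ct)
  out$log2_rq <- -out$delta_delta_ct
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Mann-Whitney U test (two-sided)
#'
#' Wraps the rank-sum machinery of [stats::wilcox.test()] behind the
#' conventions used throughout this pipeline: exact p by enumeration when
#' the combined sample is small (n_a + n_b <= 12) and untied, otherwise
#' the normal approximation with midrank tie handling and continuity
#' correction. Both groups need at least three observations.
#'
#' @param group_a,group_b numeric vectors (>= 3 each).
#' @return list `U` (statistic for `group_a`), `p` (two-sided), `exact`.
#' @export
mann_whitney <- function(group_a, group_b) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 3 || length(group_b) < 3)
    stop("each group needs >= 3 observations")
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  use_exact <- !ties && (length(group_a) + length(group_b)) <= 12
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                            exact = use_exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = min(1, wt$p.value), exact = use_exact)
}
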